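#' Observation schedule for departure monitoring
#'
#' The mazes are checked every `day_interval` hours during daytime and once
#' per night block. Trials are assumed to start at dawn (t = 0 at the start
#' of a `day_length`-hour day), so each 24 h cycle contributes checks at
#' `day_interval` spacing over the day followed by a single check at the end
#' of the night.
#'
#' @param horizon Trial duration, h.
#' @param day_length Daylight duration per cycle, h.
#' @param day_interval Daytime check spacing, h.
#' @return Increasing numeric vector of check times in (0, horizon].
#' @export
observation_schedule <- function(horizon = 96, day_length = 12,
                                 day_interval = 0.5) {
  stopifnot(horizon > 0, day_length > 0, day_length <= 24, day_interval > 0)
  cycles <- ceiling(horizon / 24)
  checks <- unlist(lapply(seq_len(cycles) - 1, function(d) {
    c(24 * d + seq(day_interval, day_length, by = day_interval), 24 * (d + 1))
  }))
  checks[checks <= horizon]
}

#' Map a true departure time onto the observation grid
#'
#' A departure is first noticed at the next scheduled check, so true times
#' are mapped to the smallest check time not less than them (idempotent and
#' never decreasing). Times beyond the last check are censored (`NA`).
#'
#' @param true_time True departure time(s), h.
#' @param schedule Check times, as from [observation_schedule()].
#' @return Recorded departure time(s); `NA` where censored.
#' @export
discretize_departure <- function(true_time, schedule = observation_schedule()) {
  stopifnot(is.numeric(true_time), is.numeric(schedule), length(schedule) > 0,
            !is.unsorted(schedule))
  idx <- findInterval(true_time, schedule, left.open = TRUE) + 1L
  out <- rep(NA_real_, length(true_time))
  ok <- !is.na(true_time) & idx <= length(schedule)
  out[ok] <- schedule[idx[ok]]
  out
}

t_ci_halfwidth <- function(x, conf = 0.95) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Average giving-up time (GUT)
#'
#' Mean time on the resource patch before departure, over leavers only:
#' individuals still present at the horizon are censored and excluded from
#' this descriptor (not treated by survival methods). If every individual is
#' censored the GUT is undefined (`NA`) but the counts are still returned.
#'
#' @param foragers data.frame with columns `entry_time` and
#'   `departure_time` (h; `NA` departure = censored).
#' @param conf Confidence level for the t-based CI on the mean.
#' @return List with `mean`, `ci` (half-width), `n_leavers`, `n_censored`.
#' @export
giving_up_time <- function(foragers, conf = 0.95) {
  if (!is.data.frame(foragers) || nrow(foragers) == 0)
    stop("giving_up_time: need at least one forager record")
  stopifnot(all(c("entry_time", "departure_time") %in% names(foragers)))
  gut <- foragers$departure_time - foragers$entry_time
  leavers <- !is.na(foragers$departure_time)
  if (any(gut[leavers] <= 0))
    stop("giving_up_time: departure at or before entry")
  vals <- gut[leavers]
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       ci = t_ci_halfwidth(vals, conf),
       n_leavers = sum(leavers),
       n_censored = sum(!leavers))
}

#' Net tracer accumulation rate of individual foragers
#'
#' Final body charge divided by time on the patch (nCi h^-1). Censored
#' individuals accumulated charge for the whole trial, so their denominator
#' is `horizon - entry_time`.
#'
#' @param body_charge Final body charges, nCi (non-negative).
#' @param entry_time Patch entry times, h.
#' @param departure_time Departure times, h; `NA` = censored.
#' @param horizon Trial duration, h.
#' @return Rates, nCi h^-1 (vectorised).
#' @export
net_accumulation_rate <- function(body_charge, entry_time, departure_time,
                                  horizon = 96) {
  if (any(body_charge < 0)) stop("net_accumulation_rate: negative body charge")
  time_on <- ifelse(is.na(departure_time), horizon - entry_time,
                    departure_time - entry_time)
  if (any(time_on <= 0))
    stop("net_accumulation_rate: non-positive time on patch")
  body_charge / time_on
}

#' Average giving-up density (GUD)
#'
#' Mean residual charge of the grazed leaf disks at the end of the trial
#' (nCi per disk), with a t-based CI.
#'
#' @param charges Residual charges of the grazed disks, nCi.
#' @param conf Confidence level.
#' @return List with `mean`, `ci`, `n_disks`.
#' @export
giving_up_density <- function(charges, conf = 0.95) {
  charges <- charges[!is.na(charges)]
  if (length(charges) == 0) stop("giving_up_density: no grazed disks")
  if (any(charges < 0)) stop("giving_up_density: negative disk charge")
  list(mean = mean(charges), ci = t_ci_halfwidth(charges, conf),
       n_disks = length(charges))
}

#' Fraction of the labelled resource exploited
#'
#' The complement of the grazed/ungrazed charge ratio,
#' `1 - grazed_mean / control_mean`: the share of the initially available
#' labelled resource that the foragers removed. The raw ratio is returned
#' alongside; a negative exploitation (grazed disks hotter than the
#' final-control disks, possible through disk heterogeneity) is reported
#' with a warning, not suppressed.
#'
#' @param grazed_mean Mean residual charge of grazed disks, nCi.
#' @param control_mean Mean charge of ungrazed final-control disks, nCi
#'   (strictly positive).
#' @return List with `exploited` (fraction), `ratio` (grazed/control).
#' @export
exploitation_fraction <- function(grazed_mean, control_mean) {
  if (any(control_mean <= 0))
    stop("exploitation_fraction: control mean must be strictly positive")
  ratio <- grazed_mean / control_mean
  expl <- 1 - ratio
  if (any(expl < 0))
    warning("exploitation_fraction: negative exploitation (grazed disks exceed control)")
  list(exploited = expl, ratio = ratio)
}

#' Per-series descriptor sets for a whole study
#'
#' Computes the four patch-departure descriptors for every treatment x
#' series combination from forager and disk record tables. The
#' final-control disks of the same series provide the exploitation
#' denominator.
#'
#' @param foragers data.frame with columns `forager_id`, `species`,
#'   `treatment_id`, `series_id`, `entry_time`, `departure_time`,
#'   `body_charge` (and optionally `size`).
#' @param disks data.frame with columns `disk_id`, `series_id`,
#'   `treatment_id` (`NA` for controls), `role`
#'   (`"grazed"`, `"start_control"`, `"final_control"`), `charge`.
#' @param horizon Trial duration, h.
#' @return data.frame, one row per treatment x series, with columns
#'   `treatment_id`, `series_id`, `species`, `n_foragers`, `gut_mean`,
#'   `gut_ci`, `n_leavers`, `n_censored`, `accumulation_rate`, `gud`,
#'   `gud_ci`, `control_mean`, `exploitation`, `modelled` (all FALSE here).
#' @export
compute_descriptors <- function(foragers, disks, horizon = 96) {
  stopifnot(all(c("treatment_id", "series_id", "entry_time", "departure_time",
                  "body_charge", "species") %in% names(foragers)),
            all(c("series_id", "treatment_id", "role", "charge") %in% names(disks)))
  combos <- unique(foragers[c("treatment_id", "series_id", "species")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- combos$treatment_id[i]; se <- combos$series_id[i]
    f <- foragers[foragers$treatment_id == tr & foragers$series_id == se, ]
    g <- disks[disks$role == "grazed" & !is.na(disks$treatment_id) &
                 disks$treatment_id == tr & disks$series_id == se, ]
    ctrl <- disks[disks$role == "final_control" & disks$series_id == se, ]
    if (nrow(ctrl) == 0)
      stop(sprintf("compute_descriptors: no final-control disks for series %s (needed by exploitation)", se))
    gut <- giving_up_time(f)
    rate <- mean(net_accumulation_rate(f$body_charge, f$entry_time,
                                       f$departure_time, horizon))
    gud <- giving_up_density(g$charge)
    expl <- exploitation_fraction(gud$mean, mean(ctrl$charge))
    data.frame(treatment_id = tr, series_id = se, species = combos$species[i],
               n_foragers = nrow(f),
               gut_mean = gut$mean, gut_ci = gut$ci,
               n_leavers = gut$n_leavers, n_censored = gut$n_censored,
               accumulation_rate = rate,
               gud = gud$mean, gud_ci = gud$ci,
               control_mean = mean(ctrl$charge),
               exploitation = expl$exploited,
               modelled = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-series descriptors over replicate series
#'
#' Treatment-level summaries: the mean over the (typically four) series
#' means, with t-based CIs on that between-series mean — the replicate unit
#' of the study is the series, not the individual.
#'
#' @param per_series Output of [compute_descriptors()] (optionally with
#'   modelled rows appended).
#' @param conf Confidence level.
#' @return data.frame, one row per treatment, columns `<descriptor>` and
#'   `<descriptor>_ci` for `gut`, `accumulation_rate`, `gud`,
#'   `exploitation`, plus counts.
#' @export
aggregate_descriptors <- function(per_series, conf = 0.95) {
  split_by <- split(per_series, per_series$treatment_id)
  rows <- lapply(split_by, function(d) {
    gut <- d$gut_mean[!is.na(d$gut_mean)]
    data.frame(
      treatment_id = d$treatment_id[1], species = d$species[1],
      modelled = any(d$modelled),
      n_series = nrow(d),
      gut = if (length(gut)) mean(gut) else NA_real_,
      gut_ci = t_ci_halfwidth(gut, conf),
      accumulation_rate = mean(d$accumulation_rate),
      accumulation_rate_ci = t_ci_halfwidth(d$accumulation_rate, conf),
      gud = mean(d$gud), gud_ci = t_ci_halfwidth(d$gud, conf),
      exploitation = mean(d$exploitation),
      exploitation_ci = t_ci_halfwidth(d$exploitation, conf),
      n_leavers = sum(d$n_leavers), n_censored = sum(d$n_censored)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
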
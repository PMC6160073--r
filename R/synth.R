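#' Configuration for the synthetic mesocosm generator
#'
#' Bundles every parameter of the individual-based two-patch foraging
#' simulation. Defaults reproduce the study conditions: 3 gastropod
#' species at their observed mean sizes, the 7 observed treatments over 4
#' replicate series, 16 labelled leaf disks per patch with a mean initial
#' charge of 31.2 nCi, a 96 h horizon observed every 30 min by day and once
#' per 12 h night, 70% assimilation efficiency, and an ingestion rate
#' scaling with size as `M^0.75`.
#'
#' The departure mechanism is a noisy quitting-harvest-rate rule: a forager
#' abandons the patch once its instantaneous intake rate falls below a
#' threshold proportional to its own metabolic rate (`quitting_coef` x
#' `I(M)`, perturbed per forager by multiplicative logistic noise). Since
#' intake declines monotonically as the patch is drained, the crossing is
#' absorbing; after crossing, the forager leaves with hazard
#' `departure_rate` per hour by day and `night_hazard_factor` times that by
#' night.
#'
#' @param species Species profiles, as [study_species()].
#' @param design Treatment design, as [study_design()].
#' @param n_series Replicate series per treatment.
#' @param n_disks Labelled disks per patch.
#' @param disk_charge_mean Study-wide mean initial disk charge, nCi.
#' @param series_charge_cv CV of the series-level mean charge (each series
#'   uses its own conditioning batch of disks).
#' @param disk_charge_cv CV of per-disk charges around the series mean
#'   (lognormal).
#' @param horizon Trial duration, h.
#' @param dt Simulation step, h.
#' @param ingestion_coef Ingestion coefficient `c`: intake rate at unit
#'   size and full patch is `c` nCi h^-1.
#' @param ingestion_exponent Size exponent of ingestion, `gamma`
#'   (intake ~ `c * M^gamma * f(R)`).
#' @param quitting_coef Quitting threshold per unit metabolic rate,
#'   nCi h^-1 per mJ day^-1. Zero disables departures.
#' @param threshold_noise Scale of the per-forager logistic perturbation of
#'   the quitting threshold (relative).
#' @param forager_rate_cv Lognormal CV of individual ingestion coefficients
#'   (physiological heterogeneity).
#' @param assimilation_efficiency Fraction of ingested label retained in
#'   tissue.
#' @param departure_rate Daytime departure hazard once the threshold is
#'   crossed, h^-1.
#' @param night_hazard_factor Multiplier on the departure hazard at night.
#' @param day_length,day_interval Observation schedule parameters, see
#'   [observation_schedule()].
#' @param functional_response `"linear"` (intake scales with remaining
#'   fraction of patch charge) or `"holling2"`.
#' @param holling_h Half-saturation mean disk charge (nCi) for
#'   `"holling2"`.
#' @param model A [metabolic_model()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(species = study_species(),
                              design = study_design(),
                              n_series = 4,
                              n_disks = 16,
                              disk_charge_mean = 31.2,
                              series_charge_cv = 0.08,
                              disk_charge_cv = 0.10,
                              horizon = 96,
                              dt = 0.1,
                              ingestion_coef = 0.3,
                              ingestion_exponent = 0.75,
                              quitting_coef = 0.25,
                              threshold_noise = 0.08,
                              forager_rate_cv = 0.2,
                              assimilation_efficiency = 0.70,
                              departure_rate = 2,
                              night_hazard_factor = 0.1,
                              day_length = 12,
                              day_interval = 0.5,
                              functional_response = c("linear", "holling2"),
                              holling_h = 15,
                              model = metabolic_model()) {
  functional_response <- match.arg(functional_response)
  cfg <- list(species = species, design = design, n_series = n_series,
              n_disks = n_disks, disk_charge_mean = disk_charge_mean,
              series_charge_cv = series_charge_cv,
              disk_charge_cv = disk_charge_cv,
              horizon = horizon, dt = dt,
              ingestion_coef = ingestion_coef,
              ingestion_exponent = ingestion_exponent,
              quitting_coef = quitting_coef,
              threshold_noise = threshold_noise,
              forager_rate_cv = forager_rate_cv,
              assimilation_efficiency = assimilation_efficiency,
              departure_rate = departure_rate,
              night_hazard_factor = night_hazard_factor,
              day_length = day_length, day_interval = day_interval,
              functional_response = functional_response,
              holling_h = holling_h, model = model)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  pos <- c("n_series", "n_disks", "disk_charge_mean", "horizon", "dt",
           "ingestion_coef", "departure_rate", "holling_h")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("simulation_config: '", p, "' must be positive")
  nonneg <- c("series_charge_cv", "disk_charge_cv", "quitting_coef",
              "threshold_noise", "forager_rate_cv", "night_hazard_factor")
  for (p in nonneg)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      stop("simulation_config: '", p, "' must be non-negative")
  if (cfg$ingestion_exponent <= 0 || cfg$ingestion_exponent >= 2)
    stop("simulation_config: 'ingestion_exponent' must lie in (0, 2)")
  if (cfg$assimilation_efficiency <= 0 || cfg$assimilation_efficiency > 1)
    stop("simulation_config: 'assimilation_efficiency' must lie in (0, 1]")
  if (!inherits(cfg$model, "metabolic_model"))
    stop("simulation_config: 'model' must be a metabolic_model")
  stopifnot(all(cfg$design$species %in% cfg$species$species))
  invisible(cfg)
}

# mean-preserving lognormal draws: E[x] = mean, CV = cv
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# individual sizes around the species mean (95% CI half-width -> sd)
draw_sizes <- function(n, mean_size, size_ci) {
  sizes <- stats::rnorm(n, mean_size, size_ci / 1.96)
  while (any(sizes <= 0))
    sizes[sizes <= 0] <- stats::rnorm(sum(sizes <= 0), mean_size, size_ci / 1.96)
  sizes
}

#' Simulate one foraging trial
#'
#' Discrete-time (`dt` h) individual-based dynamics of `n` conspecific
#' foragers on one patch of labelled disks. Each active forager ingests
#' label at `c_i * M_i^gamma * f(R)` nCi h^-1 where `f` is the functional
#' response in the remaining patch charge; the ingested charge is removed
#' from the disks in proportion to their current charges and a fraction
#' `assimilation_efficiency` accrues to the forager's body. Departure
#' follows the noisy quitting-harvest-rate rule described in
#' [simulation_config()]; recorded departure times pass through
#' [discretize_departure()] and foragers still present at the horizon are
#' censored.
#'
#' Uses the current RNG state (call [set.seed()] or use [generate_study()]
#' for reproducibility).
#'
#' @param config A [simulation_config()].
#' @param species_name Species to simulate (must be in `config$species`).
#' @param n Number of foragers.
#' @param treatment_id,series_id Labels copied into the output records.
#' @param disk_charges Initial disk charges, nCi (length `n_disks`); drawn
#'   from the study-wide distribution when omitted.
#' @return List with `foragers` (one row per individual: `forager_id`,
#'   `species`, `size`, `treatment_id`, `series_id`, `entry_time`,
#'   `true_departure`, `departure_time`, `body_charge`), `disks` (grazed
#'   disks with `initial_charge` and final `charge`), and
#'   `initial_total` (nCi).
#' @export
simulate_trial <- function(config, species_name, n,
                           treatment_id = species_name, series_id = 1L,
                           disk_charges = NULL) {
  stopifnot(inherits(config, "simulation_config"), n >= 1)
  sp <- config$species[config$species$species == species_name, ]
  if (nrow(sp) != 1) stop("simulate_trial: unknown species ", species_name)

  if (is.null(disk_charges))
    disk_charges <- rlnorm_mean_cv(config$n_disks, config$disk_charge_mean,
                                   config$disk_charge_cv)
  stopifnot(length(disk_charges) == config$n_disks, all(disk_charges > 0))
  disks <- disk_charges
  R0 <- sum(disks)

  sizes <- draw_sizes(n, sp$mean_size, sp$size_ci)
  c_i <- config$ingestion_coef * rlnorm_mean_cv(n, 1, config$forager_rate_cv)
  demand_i <- c_i * sizes^config$ingestion_exponent
  I_i <- individual_metabolic_rate(sizes, config$model)
  thr_base <- config$quitting_coef * I_i
  thr_i <- if (config$quitting_coef > 0)
    thr_base * (1 + stats::rlogis(n, 0, config$threshold_noise))
  else thr_base
  thr_i <- pmax(thr_i, 0)

  steps <- ceiling(config$horizon / config$dt)
  # pre-drawn departure uniforms keep RNG streams aligned across configs
  u <- matrix(stats::runif(steps * n), nrow = steps, ncol = n)

  schedule <- observation_schedule(config$horizon, config$day_length,
                                   config$day_interval)
  body <- numeric(n)
  true_dep <- rep(NA_real_, n)
  active <- rep(TRUE, n)

  for (k in seq_len(steps)) {
    t0 <- (k - 1) * config$dt
    if (!any(active)) break
    resp <- switch(config$functional_response,
                   linear = sum(disks) / R0,
                   holling2 = {
                     rbar <- mean(disks)
                     rbar / (config$holling_h + rbar)
                   })
    intake <- demand_i * resp                      # nCi / h, per active forager
    ing <- intake * config$dt
    ing[!active] <- 0
    total_ing <- sum(ing)
    if (total_ing > 0) {
      avail <- sum(disks)
      if (total_ing > avail) {                     # cannot ingest more than remains
        ing <- ing * avail / total_ing
        total_ing <- avail
      }
      disks <- disks - disks * (total_ing / avail)
      body <- body + config$assimilation_efficiency * ing
    }
    if (config$quitting_coef > 0) {
      is_day <- (t0 %% 24) < config$day_length
      rate <- config$departure_rate *
        if (is_day) 1 else config$night_hazard_factor
      p_leave <- 1 - exp(-rate * config$dt)
      crossed <- active & (intake < thr_i)
      leaving <- crossed & (u[k, ] < p_leave)
      if (any(leaving)) {
        true_dep[leaving] <- t0 + config$dt
        active[leaving] <- FALSE
      }
    }
  }

  foragers <- data.frame(
    forager_id = sprintf("%s_s%s_f%02d", treatment_id, series_id, seq_len(n)),
    species = species_name, size = sizes,
    treatment_id = treatment_id, series_id = series_id,
    entry_time = 0,
    true_departure = true_dep,
    departure_time = discretize_departure(true_dep, schedule),
    body_charge = body
  )
  disks_df <- data.frame(
    disk_id = sprintf("%s_s%s_d%02d", treatment_id, series_id,
                      seq_len(config$n_disks)),
    series_id = series_id, treatment_id = treatment_id, role = "grazed",
    initial_charge = disk_charges, charge = disks,
    dry_weight = stats::rnorm(config$n_disks, 14, 0.5)
  )
  list(foragers = foragers, disks = disks_df, initial_total = R0)
}

#' Generate a full synthetic mesocosm study
#'
#' Runs every treatment of the design across `n_series` replicate series.
#' Each series has its own mean disk charge (its own conditioning batch)
#' and its own start-control and final-control disk sets: the start
#' controls are measured (dismantled) at t = 0 and the final controls sit
#' ungrazed until the horizon, so both report their initial charges.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the whole study is deterministic given
#'   `config` and `seed`.
#' @return List of class `mesocosm_study`: `foragers` and `disks` tables
#'   (schemas of [simulate_trial()], controls have `treatment_id = NA`),
#'   and `ground_truth` (generating parameters incl. the seed and per-trial
#'   initial disk totals).
#' @export
generate_study <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  foragers <- list(); disks <- list(); totals <- list()
  for (s in seq_len(config$n_series)) {
    series_mean <- rlnorm_mean_cv(1, config$disk_charge_mean,
                                  config$series_charge_cv)
    for (role in c("start_control", "final_control")) {
      ch <- rlnorm_mean_cv(config$n_disks, series_mean, config$disk_charge_cv)
      disks[[length(disks) + 1L]] <- data.frame(
        disk_id = sprintf("%s_s%d_d%02d", role, s, seq_len(config$n_disks)),
        series_id = s, treatment_id = NA_character_, role = role,
        initial_charge = ch, charge = ch,
        dry_weight = stats::rnorm(config$n_disks, 14, 0.5))
    }
    for (i in seq_len(nrow(config$design))) {
      tr <- config$design[i, ]
      dch <- rlnorm_mean_cv(config$n_disks, series_mean, config$disk_charge_cv)
      trial <- simulate_trial(config, tr$species, tr$n,
                              treatment_id = tr$treatment_id, series_id = s,
                              disk_charges = dch)
      foragers[[length(foragers) + 1L]] <- trial$foragers
      disks[[length(disks) + 1L]] <- trial$disks
      totals[[paste0(tr$treatment_id, "_s", s)]] <- trial$initial_total
    }
  }
  structure(list(
    foragers = do.call(rbind, foragers),
    disks = do.call(rbind, disks),
    ground_truth = list(
      seed = seed,
      ingestion_exponent = config$ingestion_exponent,
      ingestion_coef = config$ingestion_coef,
      quitting_coef = config$quitting_coef,
      assimilation_efficiency = config$assimilation_efficiency,
      metabolic_exponent = config$model$b,
      initial_totals = unlist(totals))
  ), class = "mesocosm_study")
}

#' Configuration for an ingestion-exponent recovery study
#'
#' A balanced calibration design for recovering the generating ingestion
#' exponent `gamma` from per-forager net accumulation rates: all three
#' species at the same modest abundance, on patches enriched by
#' `enrichment` times the experimental initial charge. Enrichment keeps the
#' functional response near its plateau for the whole trial, so individual
#' rates isolate `c * M^gamma`; at experimental charge levels the
#' cross-species fit is confounded by the treatments' different depletion
#' histories and is biased away from `gamma`.
#'
#' @param n_per_species Foragers per trial (x `n_series` trials per
#'   species).
#' @param enrichment Multiplier on the mean initial disk charge.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
recovery_config <- function(n_per_species = 6, enrichment = 50, ...) {
  sp <- study_species()
  design <- data.frame(
    treatment_id = paste0(abbreviate_species(sp$species), n_per_species),
    species = sp$species,
    n = as.integer(n_per_species),
    equivalence_class = "numeric")
  simulation_config(design = design,
                    disk_charge_mean = 31.2 * enrichment, ...)
}

#' Write and read a study as plain-text artifacts
#'
#' `write_study()` writes the forager and disk record tables as CSV and the
#' generating ground truth as JSON; `read_study()` reads them back. These
#' are the interchange schemas consumed by the descriptor and tracer
#' stages, so simulated studies can be inspected or re-analysed outside R.
#'
#' @param study A `mesocosm_study`.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_study()`: invisibly, the written paths; `read_study()`:
#'   a `mesocosm_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- file.path(dir, "forager_records.csv")
  dp <- file.path(dir, "disk_records.csv")
  gp <- file.path(dir, "ground_truth.json")
  utils::write.csv(study$foragers, fp, row.names = FALSE)
  utils::write.csv(study$disks, dp, row.names = FALSE)
  jsonlite::write_json(study$ground_truth, gp, auto_unbox = TRUE, digits = NA)
  invisible(c(fp, dp, gp))
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  structure(list(
    foragers = utils::read.csv(file.path(dir, "forager_records.csv")),
    disks = utils::read.csv(file.path(dir, "disk_records.csv")),
    ground_truth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                       simplifyVector = TRUE)
  ), class = "mesocosm_study")
}

#' @export
print.mesocosm_study <- function(x, ...) {
  cat(sprintf("Synthetic mesocosm study: %d foragers in %d trials, %d disks (seed %d)\n",
              nrow(x$foragers),
              length(unique(paste(x$foragers$treatment_id, x$foragers$series_id))),
              nrow(x$disks), x$ground_truth$seed))
  invisible(x)
}
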
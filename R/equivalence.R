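#' Linear interpolation of a descriptor across observed abundances
#'
#' Piecewise-linear interpolation between the two observed abundances that
#' bracket the target: exact passthrough at observed abundances, linear
#' extrapolation from the nearest segment (with a warning) outside the
#' observed range. A global least-squares line through all points is
#' available as an alternative but does not reproduce observed endpoints.
#'
#' @param abundance Observed abundances (>= 2 distinct values).
#' @param value Descriptor values at those abundances.
#' @param target_n Abundance at which to evaluate (> 0).
#' @param method `"piecewise"` (default) or `"global_linear"`.
#' @return Interpolated descriptor value.
#' @examples
#' interpolate_descriptor(c(12, 145), c(58, 41), 66)
#' @export
interpolate_descriptor <- function(abundance, value, target_n,
                                   method = c("piecewise", "global_linear")) {
  method <- match.arg(method)
  stopifnot(length(abundance) == length(value), is.numeric(target_n),
            length(target_n) == 1L)
  if (target_n <= 0) stop("interpolate_descriptor: 'target_n' must be positive")
  keep <- !is.na(value) & !is.na(abundance)
  abundance <- abundance[keep]; value <- value[keep]
  if (length(unique(abundance)) < 2)
    stop("interpolate_descriptor: need >= 2 distinct abundances")
  o <- order(abundance)
  x <- abundance[o]; y <- value[o]
  if (method == "global_linear") {
    fit <- stats::lm(y ~ x)
    return(unname(stats::predict(fit, data.frame(x = target_n))))
  }
  if (target_n < min(x) || target_n > max(x)) {
    warning(sprintf("interpolate_descriptor: target %g outside observed range [%g, %g]; extrapolating",
                    target_n, min(x), max(x)))
  }
  # rule = 2 would clamp; linear extrapolation from the nearest segment instead
  if (target_n < min(x)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    return(y[1] + s * (target_n - x[1]))
  }
  k <- length(x)
  if (target_n > max(x)) {
    s <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    return(y[k] + s * (target_n - x[k]))
  }
  stats::approx(x, y, xout = target_n, ties = mean)$y
}

#' Modelled energy-equivalence descriptor rows
#'
#' Builds the modelled "energy equivalence" treatment for each species
#' smaller than the reference cohort: the abundance with the same overall
#' metabolic rate as the reference (4 G. truncatula by default) is computed
#' from unrounded allometric rates via [equivalent_count()], and each of the
#' four descriptors is linearly interpolated to that abundance within each
#' replicate series separately. Interpolated rows are flagged
#' `modelled = TRUE` and are meant to be excluded from cross-species
#' regression fits.
#'
#' @param per_series Per-series descriptor table from
#'   [compute_descriptors()], covering >= 2 abundances per species.
#' @param design Treatment design (maps `treatment_id` to `n`), as from
#'   [study_design()].
#' @param species Species profiles, as from [study_species()].
#' @param model A [metabolic_model()].
#' @param reference_n,reference_species Reference cohort (default 4
#'   G. truncatula).
#' @param method Interpolation method, see [interpolate_descriptor()].
#' @return data.frame in the schema of [compute_descriptors()] with
#'   `modelled = TRUE` rows, one per non-reference species x series, plus
#'   attribute `targets` (named vector of interpolation abundances).
#' @export
energy_equivalence_table <- function(per_series,
                                     design = study_design(),
                                     species = study_species(),
                                     model = metabolic_model(),
                                     reference_n = 4L,
                                     reference_species = "G. truncatula",
                                     method = "piecewise") {
  ref_size <- species$mean_size[species$species == reference_species]
  ref_rate <- reference_n * individual_metabolic_rate(ref_size, model)
  d <- merge(per_series, design[c("treatment_id", "n")], by = "treatment_id")
  others <- setdiff(unique(d$species), reference_species)
  descriptors <- c("gut_mean", "accumulation_rate", "gud", "exploitation")

  targets <- numeric(0)
  rows <- list()
  for (sp in others) {
    ind_rate <- individual_metabolic_rate(
      species$mean_size[species$species == sp], model)
    target_n <- equivalent_count(ref_rate, ind_rate, mode = "energy")$count
    targets[sp] <- target_n
    dsp <- d[d$species == sp, ]
    if (length(unique(dsp$n)) < 2) {
      warning(sprintf("energy_equivalence_table: species %s has < 2 abundances; skipped", sp))
      next
    }
    for (se in sort(unique(dsp$series_id))) {
      dse <- dsp[dsp$series_id == se, ]
      if (nrow(dse) < 2 || length(unique(dse$n)) < 2) {
        warning(sprintf("energy_equivalence_table: series %s of %s lacks abundance spread; skipped", se, sp))
        next
      }
      vals <- vapply(descriptors, function(col) {
        ok <- !is.na(dse[[col]])
        if (sum(ok) < 2) return(NA_real_)
        interpolate_descriptor(dse$n[ok], dse[[col]][ok], target_n,
                               method = method)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        treatment_id = paste0(abbreviate_species(sp), target_n, "E"),
        series_id = se, species = sp, n_foragers = target_n,
        gut_mean = vals[["gut_mean"]], gut_ci = NA_real_,
        n_leavers = NA_integer_, n_censored = NA_integer_,
        accumulation_rate = vals[["accumulation_rate"]],
        gud = vals[["gud"]], gud_ci = NA_real_,
        control_mean = NA_real_,
        exploitation = vals[["exploitation"]],
        modelled = TRUE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    d[0, setdiff(names(d), "n")]
  rownames(out) <- NULL
  attr(out, "targets") <- targets
  out
}
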
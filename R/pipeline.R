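#' Cross-forager scaling fit of net tracer accumulation rate on body size
#'
#' Computes each forager's net accumulation rate and fits the cross-species
#' power law rate ~ size ([fit_power_law()] on the individual records).
#' This is the parameter-recovery probe for the simulator's ingestion
#' exponent: on synthetic data generated with exponent `gamma`, the fitted
#' slope estimates `gamma` (up to the mild depletion-history differences
#' between treatments).
#'
#' @param foragers Forager records with `size`, `body_charge`,
#'   `entry_time`, `departure_time`.
#' @param horizon Trial duration, h.
#' @return A `scaling_fit` (see [fit_power_law()]).
#' @export
fit_accumulation_scaling <- function(foragers, horizon = 96) {
  rate <- net_accumulation_rate(foragers$body_charge, foragers$entry_time,
                                foragers$departure_time, horizon)
  keep <- rate > 0
  fit_power_law(foragers$size[keep], rate[keep])
}

scaling_fit_row <- function(fit, descriptor, group) {
  if (fit$link == "log-log") {
    int <- fit$a
    int_ci <- (fit$a_ci_upper - fit$a_ci_lower) / 2
    r2 <- fit$r_squared
  } else {
    int <- fit$a; int_ci <- fit$a_ci; r2 <- fit$pseudo_r_squared
  }
  data.frame(descriptor = descriptor, group = group, link = fit$link,
             n = fit$n, R = fit$r, R_ci95 = fit$r_ci, p = fit$p_value,
             Int = int, Int_ci95 = int_ci,
             Slp = fit$b, Slp_ci95 = fit$b_ci, R2 = r2)
}

fit_descriptor <- function(x, y, descriptor) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (descriptor == "exploitation") {
    ok2 <- y >= 0 & y <= 1
    fit_logit_fraction(x[ok2], y[ok2])
  } else {
    ok2 <- y > 0
    fit_power_law(x[ok2], y[ok2])
  }
}

#' Within-species descriptor-vs-abundance scaling fits
#'
#' For one species, fits each of the four descriptors against forager
#' abundance over the per-series observations (power laws; exploitation via
#' the logit link). Modelled (interpolated) rows are excluded.
#'
#' @param per_series Per-series descriptor table ([compute_descriptors()]).
#' @param design Treatment design mapping `treatment_id` to `n`.
#' @param species_name Species to fit.
#' @return data.frame of fit parameters, one row per descriptor.
#' @export
abundance_fit_table <- function(per_series, design = study_design(),
                                species_name) {
  d <- merge(per_series[!per_series$modelled, ],
             design[c("treatment_id", "n")], by = "treatment_id")
  d <- d[d$species == species_name, ]
  if (length(unique(d$n)) < 2)
    stop("abundance_fit_table: need >= 2 abundances for ", species_name)
  specs <- c(gut = "gut_mean", accumulation_rate = "accumulation_rate",
             gud = "gud", exploitation = "exploitation")
  out <- lapply(names(specs), function(desc) {
    scaling_fit_row(fit_descriptor(d$n, d[[specs[[desc]]]], desc),
                    desc, species_name)
  })
  do.call(rbind, out)
}

#' Cross-species descriptor-vs-size scaling fits per equivalence class
#'
#' Fits each descriptor against mean species size within one equivalence
#' class: numeric (4 individuals of each species), biomass (cohorts of
#' equal total AFDW) or energy (the reference cohort plus the modelled
#' interpolated treatments, which are only available through
#' [energy_equivalence_table()]).
#'
#' @param per_series Per-series descriptors, including modelled rows for
#'   the energy class.
#' @param design Treatment design.
#' @param species Species profiles (supplies mean sizes).
#' @param class_treatments Named list mapping each equivalence class to its
#'   treatment ids.
#' @return data.frame of fit parameters, one row per descriptor x class.
#' @export
cross_species_fit_table <- function(per_series, design = study_design(),
                                    species = study_species(),
                                    class_treatments = list(
                                      numeric = c("Gt4", "Bt4", "Ev4"),
                                      energy = NULL,
                                      biomass = c("Gt4", "Bt7", "Ev145"))) {
  specs <- c(gut = "gut_mean", accumulation_rate = "accumulation_rate",
             gud = "gud", exploitation = "exploitation")
  out <- list()
  for (cls in names(class_treatments)) {
    ids <- class_treatments[[cls]]
    d <- if (cls == "energy" && is.null(ids)) {
      # reference cohort observed + modelled interpolated treatments
      rbind(per_series[per_series$treatment_id == "Gt4", ],
            per_series[per_series$modelled, ])
    } else per_series[per_series$treatment_id %in% ids, ]
    if (nrow(d) == 0) {
      warning("cross_species_fit_table: no rows for class ", cls)
      next
    }
    d$mean_size <- species$mean_size[match(d$species, species$species)]
    for (desc in names(specs)) {
      out[[paste(cls, desc)]] <-
        scaling_fit_row(fit_descriptor(d$mean_size, d[[specs[[desc]]]], desc),
                        desc, cls)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full analysis pipeline on a study
#'
#' Executes the whole analysis over a (synthetic or imported) study:
#' descriptor computation per treatment x series, interpolation to the
#' energy-equivalence treatment, treatment-level aggregation, the
#' within-species abundance fits, the cross-species equivalence-class fits,
#' the residual-charge ANOVA (grazed disks by treatment plus the ungrazed
#' final controls as their own group), and the cross-forager
#' accumulation-rate scaling fit.
#'
#' @param study A `mesocosm_study` (from [generate_study()]) or a list with
#'   `foragers` and `disks` tables in the same schemas.
#' @param design,species,model Study design, species profiles and
#'   allometric model.
#' @param horizon Trial duration, h.
#' @param abundance_species Species with enough abundance spread for
#'   within-species fits.
#' @return List of class `gudscale_report`: `design_table`, `per_series`,
#'   `aggregated`, `abundance_fits`, `cross_species_fits`, `anova`,
#'   `accumulation_fit`, `log` (row-accounting of exclusions).
#' @export
run_pipeline <- function(study,
                         design = study_design(),
                         species = study_species(),
                         model = metabolic_model(),
                         horizon = 96,
                         abundance_species = c("B. tentaculata", "E. ventrosa")) {
  stopifnot(is.list(study), !is.null(study$foragers), !is.null(study$disks))
  log <- list(n_foragers = nrow(study$foragers), n_disks = nrow(study$disks))

  per_series <- compute_descriptors(study$foragers, study$disks, horizon)
  log$n_censored <- sum(per_series$n_censored)
  log$n_leavers <- sum(per_series$n_leavers)
  log$series_without_leavers <- sum(is.na(per_series$gut_mean))

  modelled <- energy_equivalence_table(per_series, design, species, model)
  all_series <- rbind(per_series, modelled)
  aggregated <- aggregate_descriptors(all_series)

  abundance_fits <- do.call(rbind, lapply(abundance_species, function(sp)
    abundance_fit_table(per_series, design, sp)))
  cross_fits <- cross_species_fit_table(all_series, design, species)

  grazed <- study$disks[study$disks$role == "grazed", ]
  ctrl <- study$disks[study$disks$role == "final_control", ]
  if (nrow(ctrl) == 0)
    stop("run_pipeline: descriptors stage requires final-control disks")
  anova_res <- residual_charge_anova(
    c(grazed$charge, ctrl$charge),
    c(grazed$treatment_id, rep("final_control", nrow(ctrl))))

  structure(list(
    design_table = design_table(design, species, model),
    per_series = all_series,
    aggregated = aggregated,
    abundance_fits = abundance_fits,
    cross_species_fits = cross_fits,
    anova = anova_res,
    accumulation_fit = fit_accumulation_scaling(study$foragers, horizon),
    log = log
  ), class = "gudscale_report")
}

#' Write a report bundle as commented CSV files
#'
#' Each file starts with a `#` header carrying the package version and the
#' seed, so every artifact is traceable to its generating run.
#'
#' @param report A `gudscale_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the headers.
#' @return Invisibly, the written file paths.
#' @export
write_report_bundle <- function(report, dir, seed = NA) {
  stopifnot(inherits(report, "gudscale_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# gudscale %s; seed=%s; written=%s",
                 as.character(utils::packageVersion("gudscale")),
                 seed, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  tables <- list(design_table = report$design_table,
                 descriptors_per_series = report$per_series,
                 descriptors_aggregated = report$aggregated,
                 abundance_fits = report$abundance_fits,
                 cross_species_fits = report$cross_species_fits)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  anova_path <- file.path(dir, "residual_charge_anova.csv")
  con <- file(anova_path, "w")
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(report$anova), con, row.names = FALSE)
  close(con)
  invisible(c(paths, anova_path))
}
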
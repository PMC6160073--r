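#' Allometric metabolic-rate model
#'
#' Constructs the power-law model `I = a * M^b` that predicts an individual's
#' metabolic rate `I` (mJ day^-1) from its body size `M` (mg ash-free dry
#' weight, AFDW). The defaults reduce empirical respiration estimates for
#' surficial motile gastropods at 18 degrees C to a single power law,
#' together with the tissue energy density used to convert between biomass
#' and energy.
#'
#' @param a Coefficient, mJ day^-1 (mg AFDW)^-b. Must be positive.
#' @param b Dimensionless size exponent, in (0, 2). The canonical metabolic
#'   expectation is 0.75; the gastropod reduction used here is 0.79.
#' @param energy_density Tissue energy density, J per mg AFDW.
#'
#' @return An object of class `metabolic_model`: a list with elements
#'   `a`, `b`, `energy_density`.
#' @examples
#' m <- metabolic_model()
#' individual_metabolic_rate(7.77, m)
#' @export
metabolic_model <- function(a = 0.69, b = 0.79, energy_density = 21.5) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(energy_density), length(energy_density) == 1L)
  if (a <= 0) stop("metabolic_model: coefficient 'a' must be positive")
  if (b <= 0 || b >= 2) stop("metabolic_model: exponent 'b' must lie in (0, 2)")
  if (energy_density <= 0) stop("metabolic_model: 'energy_density' must be positive")
  structure(list(a = a, b = b, energy_density = energy_density),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Allometric metabolic model: I = %g * M^%g  (mJ/day, M in mg AFDW)\n",
              x$a, x$b))
  cat(sprintf("Energy density: %g J / mg AFDW\n", x$energy_density))
  invisible(x)
}

#' Individual metabolic rate from body size
#'
#' Evaluates `I = a * M^b` (mJ day^-1) for one or more body sizes.
#'
#' @param M Body size(s), mg AFDW. All values must be strictly positive.
#' @param model A [metabolic_model()].
#' @return Metabolic rate(s), mJ day^-1.
#' @examples
#' round(individual_metabolic_rate(c(12.88, 7.77, 0.37)), 2)
#' @export
individual_metabolic_rate <- function(M, model = metabolic_model()) {
  stopifnot(inherits(model, "metabolic_model"), is.numeric(M))
  if (any(!is.finite(M)) || any(M <= 0))
    stop("individual_metabolic_rate: body size 'M' must be positive and finite")
  model$a * M^model$b
}

#' Delta-method propagation of size uncertainty to metabolic rate
#'
#' First-order (delta-method) propagation of a 95% CI half-width on mean
#' body size through the allometric model:
#' `dI = a * b * M^(b - 1) * dM`.
#'
#' Only size uncertainty is propagated; uncertainty in the model
#' coefficients themselves is not included.
#'
#' @param M Mean body size, mg AFDW (positive).
#' @param dM 95% CI half-width of the mean size, mg AFDW (non-negative).
#'   A half-width at least as large as `M` itself triggers a warning, since
#'   the implied size interval spans non-positive sizes.
#' @param model A [metabolic_model()].
#' @return 95% CI half-width of the metabolic rate, mJ day^-1.
#' @examples
#' propagate_size_ci(7.77, 2.99)
#' @export
propagate_size_ci <- function(M, dM, model = metabolic_model()) {
  stopifnot(inherits(model, "metabolic_model"), is.numeric(M), is.numeric(dM))
  if (any(M <= 0)) stop("propagate_size_ci: 'M' must be positive")
  if (any(dM < 0)) stop("propagate_size_ci: 'dM' must be non-negative")
  if (any(dM >= M))
    warning("propagate_size_ci: CI half-width >= mean size; the size interval spans non-positive values")
  model$a * model$b * M^(model$b - 1) * dM
}

#' Theoretical individual and per-biomass scaling exponents
#'
#' For individual rates scaling as `M^b`, the population energy demand per
#' unit biomass of an `n`-cohort scales as `M^(b - 1)`: with `b < 1` a given
#' biomass of smaller individuals demands more energy than the same biomass
#' of larger ones.
#'
#' @param model A [metabolic_model()].
#' @return Named numeric vector `c(individual = b, per_biomass = b - 1)`.
#' @export
theoretical_exponents <- function(model = metabolic_model()) {
  stopifnot(inherits(model, "metabolic_model"))
  c(individual = model$b, per_biomass = model$b - 1)
}

#' Population energetics of a single-species cohort
#'
#' Aggregates individual allometry to the cohort level: total biomass
#' `n * M`, overall metabolic rate `n * I(M)` (the population requirement is
#' the sum of individual requirements), and the per-biomass rate
#' `I(M) / M`, which is independent of `n`. CI half-widths on the mean size
#' scale linearly with `n` as well.
#'
#' @param n Number of individuals (non-negative integer; `n = 0` is allowed
#'   as a degenerate empty cohort and is flagged with a warning).
#' @param mean_size Mean individual size, mg AFDW.
#' @param size_ci 95% CI half-width of the mean size, mg AFDW.
#' @param model A [metabolic_model()].
#' @return A one-row data.frame with columns `n`, `mean_size`,
#'   `individual_rate`, `individual_rate_ci`, `total_biomass`,
#'   `total_biomass_ci`, `overall_rate`, `overall_rate_ci`,
#'   `per_biomass_rate`.
#' @examples
#' population_energetics(7, 7.77, 2.99)
#' @export
population_energetics <- function(n, mean_size, size_ci = 0,
                                  model = metabolic_model()) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  if (n == 0) warning("population_energetics: empty cohort (n = 0)")
  I <- individual_metabolic_rate(mean_size, model)
  dI <- propagate_size_ci(mean_size, size_ci, model)
  data.frame(
    n = n,
    mean_size = mean_size,
    individual_rate = I,
    individual_rate_ci = dI,
    total_biomass = n * mean_size,
    total_biomass_ci = n * size_ci,
    overall_rate = n * I,
    overall_rate_ci = n * dI,
    per_biomass_rate = I / mean_size
  )
}

#' Equivalent cohort size for a target energy demand or biomass
#'
#' How many individuals of a (smaller) species match a target overall
#' metabolic rate (energy mode) or total biomass (biomass mode)? Returns
#' both the raw quotient and its rounding to the nearest whole individual;
#' published designs need not be exact quotients, so both are reported.
#'
#' @param target Target overall rate (mJ day^-1) or biomass (mg AFDW);
#'   non-negative.
#' @param per_individual Per-individual rate or size in the same units;
#'   strictly positive.
#' @param mode `"energy"` or `"biomass"` (informational label).
#' @return A list with `count` (integer), `ratio` (raw quotient) and `mode`.
#' @examples
#' equivalent_count(4 * individual_metabolic_rate(12.88),
#'                  individual_metabolic_rate(7.77))
#' @export
equivalent_count <- function(target, per_individual,
                             mode = c("energy", "biomass")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(target), length(target) == 1L,
            is.numeric(per_individual), length(per_individual) == 1L)
  if (target < 0) stop("equivalent_count: 'target' must be non-negative")
  if (per_individual <= 0)
    stop("equivalent_count: 'per_individual' must be strictly positive")
  ratio <- target / per_individual
  list(count = as.integer(round(ratio)), ratio = ratio, mode = mode)
}

#' Species profiles of the three model gastropods
#'
#' Mean individual sizes (mg AFDW) with 95% CI half-widths for the three
#' study species, in descending size order: *Galba truncatula*,
#' *Bithynia tentaculata*, *Ecrobia ventrosa*.
#'
#' @return data.frame with columns `species`, `mean_size`, `size_ci`.
#' @export
study_species <- function() {
  data.frame(
    species = c("G. truncatula", "B. tentaculata", "E. ventrosa"),
    mean_size = c(12.88, 7.77, 0.37),
    size_ci = c(2.54, 2.99, 0.05)
  )
}

#' Observed treatment design of the mesocosm study
#'
#' The seven observed species-by-abundance treatments: numeric equivalence
#' (4 individuals of each species), biomass equivalence (7 B. tentaculata
#' and 145 E. ventrosa matching the AFDW of 4 G. truncatula; 79 E. ventrosa
#' matching 4 B. tentaculata), and a supplementary abundance of 12
#' E. ventrosa. Printed abundances are taken as the design; they are not
#' recomputed from size quotients. Each treatment is replicated over
#' `n_series` independent series.
#'
#' @param n_series Number of replicate series per treatment.
#' @return data.frame with columns `treatment_id`, `species`, `n`,
#'   `equivalence_class`.
#' @export
study_design <- function(n_series = 4) {
  d <- data.frame(
    treatment_id = c("Gt4", "Bt4", "Bt7", "Ev4", "Ev12", "Ev79", "Ev145"),
    species = c("G. truncatula", "B. tentaculata", "B. tentaculata",
                "E. ventrosa", "E. ventrosa", "E. ventrosa", "E. ventrosa"),
    n = c(4L, 4L, 7L, 4L, 12L, 79L, 145L),
    equivalence_class = c("numeric", "numeric", "biomass",
                          "numeric", "supplementary", "biomass", "biomass")
  )
  attr(d, "n_series") <- n_series
  d
}

#' Design table with cohort energetics
#'
#' Expands a treatment design into the full design table: individual and
#' cohort sizes, metabolic rates, and delta-method CI half-widths, plus the
#' energy-equivalence modelled rows (counts from [equivalent_count()] on
#' unrounded rates against the reference cohort of 4 G. truncatula).
#'
#' Printed-value convention: `overall_rate_printed` is `n` times the
#' individual rate rounded to `digits` decimals, matching how such tables
#' are conventionally typeset (the unrounded exact product is in
#' `overall_rate`).
#'
#' @param design data.frame as from [study_design()].
#' @param species data.frame as from [study_species()].
#' @param model A [metabolic_model()].
#' @param reference_n,reference_species Reference cohort for the modelled
#'   energy-equivalence rows.
#' @param digits Decimals for the printed individual rate.
#' @return data.frame, one row per treatment plus one modelled
#'   energy-equivalence row per non-reference species, with a logical
#'   `modelled` column.
#' @export
design_table <- function(design = study_design(), species = study_species(),
                         model = metabolic_model(),
                         reference_n = 4L,
                         reference_species = "G. truncatula",
                         digits = 2) {
  stopifnot(all(design$species %in% species$species))
  ref_size <- species$mean_size[species$species == reference_species]
  ref_rate <- reference_n * individual_metabolic_rate(ref_size, model)

  rows <- lapply(seq_len(nrow(design)), function(i) {
    sp <- species[species$species == design$species[i], ]
    pe <- population_energetics(design$n[i], sp$mean_size, sp$size_ci, model)
    cbind(data.frame(treatment_id = design$treatment_id[i],
                     species = design$species[i],
                     equivalence_class = design$equivalence_class[i],
                     modelled = FALSE), pe)
  })

  # modelled energy-equivalence rows for the non-reference species
  others <- species[species$species != reference_species, ]
  erows <- lapply(seq_len(nrow(others)), function(i) {
    sp <- others[i, ]
    ind_rate <- individual_metabolic_rate(sp$mean_size, model)
    n_eq <- equivalent_count(ref_rate, ind_rate, mode = "energy")$count
    pe <- population_energetics(n_eq, sp$mean_size, sp$size_ci, model)
    cbind(data.frame(treatment_id = paste0(abbreviate_species(sp$species), n_eq, "E"),
                     species = sp$species,
                     equivalence_class = "energy",
                     modelled = TRUE), pe)
  })

  out <- do.call(rbind, c(rows, erows))
  out$individual_rate_printed <- round(out$individual_rate, digits)
  out$overall_rate_printed <- out$n * out$individual_rate_printed
  rownames(out) <- NULL
  out[order(match(out$species, species$species), out$n), ]
}

abbreviate_species <- function(x) {
  vapply(strsplit(x, "[. ]+"), function(p) paste0(substr(p, 1, 1), collapse = ""),
         character(1))
}
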
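#' Scintillation-counter calibration for the radiotracer pipeline
#'
#' Parameters needed to turn raw scintillation counts (DPM) into corrected,
#' decay-adjusted charges: counting efficiency against an external standard,
#' the blank (background) count, the tracer half-life, and the DPM-to-curie
#' conversion factor. The default half-life is that of ^32P, 14.268 days.
#'
#' @param counting_efficiency Fraction in (0, 1].
#' @param blank_dpm Background count subtracted from every sample, DPM.
#' @param half_life_days Tracer half-life, days (> 0).
#' @param dpm_to_ci Curie per DPM; 1 DPM = 4.556e-13 Ci.
#' @return Object of class `tracer_calibration`.
#' @export
tracer_calibration <- function(counting_efficiency = 1,
                               blank_dpm = 0,
                               half_life_days = 14.268,
                               dpm_to_ci = 4.556e-13) {
  if (!is.numeric(counting_efficiency) || counting_efficiency <= 0 ||
      counting_efficiency > 1)
    stop("tracer_calibration: 'counting_efficiency' must lie in (0, 1]")
  if (blank_dpm < 0) stop("tracer_calibration: 'blank_dpm' must be non-negative")
  if (half_life_days <= 0) stop("tracer_calibration: 'half_life_days' must be positive")
  if (dpm_to_ci <= 0) stop("tracer_calibration: 'dpm_to_ci' must be positive")
  structure(list(counting_efficiency = counting_efficiency,
                 blank_dpm = blank_dpm,
                 half_life_days = half_life_days,
                 dpm_to_ci = dpm_to_ci),
            class = "tracer_calibration")
}

#' Blank and efficiency correction of raw counts
#'
#' `(raw - blank) / efficiency`, clamped at zero. Blanks can legitimately
#' exceed near-background samples, so negative corrected counts clamp to
#' zero with a warning instead of erroring.
#'
#' @param raw Raw counts, DPM (vectorised, non-negative).
#' @param cal A [tracer_calibration()].
#' @return Corrected DPM.
#' @export
correct_dpm <- function(raw, cal = tracer_calibration()) {
  stopifnot(inherits(cal, "tracer_calibration"), is.numeric(raw))
  if (any(raw < 0)) stop("correct_dpm: raw counts must be non-negative")
  out <- (raw - cal$blank_dpm) / cal$counting_efficiency
  neg <- out < 0
  if (any(neg)) {
    warning(sprintf("correct_dpm: %d sample(s) below blank; clamped to 0", sum(neg)))
    out[neg] <- 0
  }
  out
}

#' Radioactive-decay correction to a common reference time
#'
#' Back-corrects a measured activity to what it was `elapsed` days earlier:
#' `dpm * 2^(elapsed / half_life)`. Negative `elapsed` projects forward.
#'
#' @param dpm Activity at measurement time, DPM (vectorised).
#' @param elapsed_days Days between the reference time and the measurement
#'   (measurement minus reference; may be negative).
#' @param cal A [tracer_calibration()].
#' @return Activity at the reference time, DPM.
#' @export
decay_correct <- function(dpm, elapsed_days, cal = tracer_calibration()) {
  stopifnot(inherits(cal, "tracer_calibration"))
  dpm * 2^(elapsed_days / cal$half_life_days)
}

#' DPM to curie (and back)
#'
#' @param dpm Activity, DPM (non-negative).
#' @param cal A [tracer_calibration()].
#' @return `dpm_to_curie`: activity in Ci; `dpm_to_nanocurie`: in nCi;
#'   `curie_to_dpm`: the inverse of `dpm_to_curie`.
#' @export
dpm_to_curie <- function(dpm, cal = tracer_calibration()) {
  if (any(dpm < 0)) stop("dpm_to_curie: 'dpm' must be non-negative")
  dpm * cal$dpm_to_ci
}

#' @rdname dpm_to_curie
#' @export
dpm_to_nanocurie <- function(dpm, cal = tracer_calibration()) {
  dpm_to_curie(dpm, cal) * 1e9
}

#' @rdname dpm_to_curie
#' @param ci Activity, Ci.
#' @export
curie_to_dpm <- function(ci, cal = tracer_calibration()) {
  ci / cal$dpm_to_ci
}

#' Full charge-processing pipeline for a measurement table
#'
#' Applies blank/efficiency correction, decay correction back to the
#' reference time, and conversion to nCi, in that order, to a table of raw
#' scintillation measurements.
#'
#' @param measurements data.frame with columns `subject_id`, `subject_kind`
#'   (`"disk"` or `"forager"`), `raw_dpm`, and `measurement_days` (days
#'   elapsed between the reference time, normally the series' trial start,
#'   and the measurement).
#' @param cal A [tracer_calibration()].
#' @return The input with added columns `corrected_dpm`, `reference_dpm`
#'   and `charge_nci`.
#' @export
process_charges <- function(measurements, cal = tracer_calibration()) {
  need <- c("subject_id", "subject_kind", "raw_dpm", "measurement_days")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("process_charges: missing columns: ", paste(miss, collapse = ", "))
  bad <- !measurements$subject_kind %in% c("disk", "forager")
  if (any(bad))
    stop("process_charges: unknown subject_kind in rows ",
         paste(which(bad), collapse = ", "))
  measurements$corrected_dpm <- correct_dpm(measurements$raw_dpm, cal)
  measurements$reference_dpm <- decay_correct(measurements$corrected_dpm,
                                              measurements$measurement_days, cal)
  measurements$charge_nci <- dpm_to_nanocurie(measurements$reference_dpm, cal)
  measurements
}

#' Convert reference-time charges to raw counter readings
#'
#' Inverse of [process_charges()]: given true charges (nCi, at reference
#' time), produces the raw DPM a counter would report at the measurement
#' time, after decay, counting efficiency and blank. Used to emit realistic
#' raw measurement tables from simulated studies.
#'
#' @param charge_nci True charges at reference time, nCi.
#' @param measurement_days Days from reference time to measurement.
#' @param cal A [tracer_calibration()].
#' @return Raw DPM values.
#' @export
charge_to_raw_dpm <- function(charge_nci, measurement_days,
                              cal = tracer_calibration()) {
  ref_dpm <- curie_to_dpm(charge_nci * 1e-9, cal)
  at_meas <- decay_correct(ref_dpm, -measurement_days, cal)
  at_meas * cal$counting_efficiency + cal$blank_dpm
}
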
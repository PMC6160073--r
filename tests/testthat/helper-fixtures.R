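# Shared fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- generate_study(simulation_config(), seed = 42)
  .fixtures$study
}

default_report <- function() {
  if (is.null(.fixtures$report))
    .fixtures$report <- suppressWarnings(run_pipeline(default_study()))
  .fixtures$report
}

recovery_study <- function() {
  if (is.null(.fixtures$recovery))
    .fixtures$recovery <- generate_study(recovery_config(), seed = 1)
  .fixtures$recovery
}

# sum over grazed disks + body charges of one trial, for conservation checks
trial_balance <- function(study, treatment_id, series_id, efficiency) {
  d <- study$disks
  f <- study$foragers
  dd <- d[d$role == "grazed" & !is.na(d$treatment_id) &
            d$treatment_id == treatment_id & d$series_id == series_id, ]
  ff <- f[f$treatment_id == treatment_id & f$series_id == series_id, ]
  list(initial = sum(dd$initial_charge),
       residual = sum(dd$charge),
       body = sum(ff$body_charge),
       closed = sum(dd$charge) + sum(ff$body_charge) / efficiency)
}
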
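test_that("configuration invariants are enforced before simulating", {
  expect_error(simulation_config(ingestion_exponent = 2.5), "\\(0, 2\\)")
  expect_error(simulation_config(assimilation_efficiency = 0), "\\(0, 1\\]")
  expect_error(simulation_config(n_disks = 0), "positive")
  expect_error(simulation_config(quitting_coef = -1), "non-negative")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("a zero quitting threshold yields no departures", {
  set.seed(1)
  trial <- simulate_trial(simulation_config(quitting_coef = 0),
                          "B. tentaculata", 5)
  expect_true(all(is.na(trial$foragers$departure_time)))
  expect_true(all(is.na(trial$foragers$true_departure)))
})

test_that("tracer charge is conserved through a trial", {
  set.seed(2)
  cfg1 <- simulation_config(assimilation_efficiency = 1, quitting_coef = 0)
  trial <- simulate_trial(cfg1, "G. truncatula", 1)
  loss <- trial$initial_total - sum(trial$disks$charge)
  expect_equal(trial$foragers$body_charge, loss, tolerance = 1e-9)

  study <- default_study()
  eff <- study$ground_truth$assimilation_efficiency
  for (key in names(study$ground_truth$initial_totals)) {
    parts <- strsplit(key, "_s")[[1]]
    bal <- trial_balance(study, parts[1], as.integer(parts[2]), eff)
    expect_equal(bal$closed, bal$initial, tolerance = 1e-6)
  }
})

test_that("a full study is deterministic, complete and on the observation grid", {
  s1 <- generate_study(simulation_config(), seed = 7)
  s2 <- generate_study(simulation_config(), seed = 7)
  expect_identical(s1, s2)

  study <- default_study()
  trials <- unique(study$foragers[c("treatment_id", "series_id")])
  expect_equal(nrow(trials), 7 * 4)
  expect_equal(sum(study$disks$role == "start_control"), 4 * 16)
  expect_equal(sum(study$disks$role == "final_control"), 4 * 16)
  expect_equal(sum(study$disks$role == "grazed"), 7 * 4 * 16)

  sched <- observation_schedule(96)
  dep <- study$foragers$departure_time
  expect_true(all(dep[!is.na(dep)] %in% sched))
})

test_that("raising the quitting threshold lowers GUT and raises GUD", {
  lo <- generate_study(simulation_config(quitting_coef = 0.15), seed = 7)
  hi <- generate_study(simulation_config(quitting_coef = 0.35), seed = 7)
  dlo <- suppressWarnings(compute_descriptors(lo$foragers, lo$disks))
  dhi <- suppressWarnings(compute_descriptors(hi$foragers, hi$disks))
  expect_lt(mean(dhi$gut_mean, na.rm = TRUE), mean(dlo$gut_mean, na.rm = TRUE))
  expect_gt(mean(dhi$gud), mean(dlo$gud))
})

test_that("higher conspecific abundance lowers GUD and raises exploitation", {
  agg <- default_report()$aggregated
  ev <- agg[agg$treatment_id %in% c("Ev4", "Ev12", "Ev79", "Ev145"), ]
  ev <- ev[order(match(ev$treatment_id, c("Ev4", "Ev12", "Ev79", "Ev145"))), ]
  expect_true(all(diff(ev$gud) < 0))
  expect_true(all(diff(ev$exploitation) > 0))
})

test_that("the generating ingestion exponent is recovered across species", {
  fit <- fit_accumulation_scaling(recovery_study()$foragers)
  gamma <- recovery_study()$ground_truth$ingestion_exponent
  expect_gt(fit$n, 3 * 20)
  expect_lte(fit$b - fit$b_ci, gamma)
  expect_gte(fit$b + fit$b_ci, gamma)
})

test_that("studies round-trip through the plain-text interchange formats", {
  dir <- withr::local_tempdir()
  study <- default_study()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(back$foragers, study$foragers, tolerance = 1e-12)
  expect_equal(back$disks$charge, study$disks$charge, tolerance = 1e-12)
  expect_equal(back$ground_truth$ingestion_exponent,
               study$ground_truth$ingestion_exponent)
})
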
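forager_df <- function(departure, entry = 0, charge = 1) {
  data.frame(entry_time = entry, departure_time = departure,
             body_charge = charge)
}

test_that("giving-up time averages leavers only and is censoring-invariant", {
  g <- giving_up_time(forager_df(c(20, 30)))
  expect_equal(g$mean, 25)
  expect_equal(g$n_leavers, 2)

  allc <- giving_up_time(forager_df(c(NA, NA, NA)))
  expect_true(is.na(allc$mean))
  expect_equal(allc$n_leavers, 0)
  expect_equal(allc$n_censored, 3)

  same <- giving_up_time(forager_df(c(26, 26, 26, 26)))
  expect_equal(same$mean, 26)
  expect_equal(same$ci, 0)

  # adding censored records never moves the mean
  base <- giving_up_time(forager_df(c(12, 40, 55.5)))
  padded <- giving_up_time(forager_df(c(12, 40, 55.5, NA, NA, NA, NA)))
  expect_equal(padded$mean, base$mean)
  expect_equal(padded$ci, base$ci)
  expect_equal(padded$n_censored, 4)

  empty <- data.frame(entry_time = numeric(0), departure_time = numeric(0))
  expect_error(giving_up_time(empty), "at least one")
  expect_error(giving_up_time(forager_df(0, entry = 5)), "before entry")
})

test_that("net accumulation rate divides charge by time on patch", {
  expect_equal(net_accumulation_rate(2.6, 0, 26), 0.1)
  expect_equal(net_accumulation_rate(0, 0, 26), 0)
  expect_equal(net_accumulation_rate(9.6, 0, NA, horizon = 96), 0.1)
  expect_equal(net_accumulation_rate(c(2.6, 9.6), c(0, 0), c(26, NA)),
               c(0.1, 0.1))
  expect_error(net_accumulation_rate(1, 96, NA, horizon = 96), "time on patch")
  expect_error(net_accumulation_rate(-1, 0, 26), "negative")
})

test_that("giving-up density is the mean residual charge with a t CI", {
  expect_equal(giving_up_density(rep(31.2, 16))$mean, 31.2)
  expect_equal(giving_up_density(rep(31.2, 16))$ci, 0)
  g <- giving_up_density(c(10, 20, 30))
  expect_equal(g$mean, 20)
  expect_equal(g$ci, stats::qt(0.975, 2) * stats::sd(c(10, 20, 30)) / sqrt(3))
  expect_error(giving_up_density(numeric(0)), "no grazed disks")
})

test_that("exploitation is the complement of the grazed/control ratio", {
  e <- exploitation_fraction(15.6, 31.2)
  expect_equal(e$exploited, 0.5)
  expect_equal(e$exploited + e$ratio, 1)
  expect_equal(exploitation_fraction(31.2, 31.2)$exploited, 0)
  expect_warning(neg <- exploitation_fraction(33, 31.2), "negative")
  expect_equal(round(neg$exploited, 3), -0.058)
  # identity holds for arbitrary inputs
  set.seed(8)
  g <- stats::runif(10, 0, 50); ctl <- stats::runif(10, 10, 50)
  e2 <- suppressWarnings(exploitation_fraction(g, ctl))
  expect_equal(e2$exploited + g / ctl, rep(1, 10), tolerance = 1e-15)
  expect_error(exploitation_fraction(10, 0), "positive")
})

test_that("departure discretisation maps onto the day/night observation grid", {
  s <- observation_schedule(96)
  expect_equal(max(s), 96)
  expect_equal(discretize_departure(10.2, s), 10.5)
  expect_equal(discretize_departure(10.5, s), 10.5)       # exact check time
  expect_equal(discretize_departure(14, s), 24)           # mid-night -> block end
  expect_equal(discretize_departure(12 + 24, s), 36)
  expect_true(is.na(discretize_departure(97, s)))
  # idempotent and never decreasing
  t <- stats::runif(50, 0, 96)
  d <- discretize_departure(t, s)
  expect_true(all(d >= t))
  expect_equal(discretize_departure(d, s), d)
})

test_that("per-series descriptors assemble and aggregate over series", {
  study <- default_study()
  ps <- suppressWarnings(compute_descriptors(study$foragers, study$disks))
  expect_equal(nrow(ps), 7 * 4)
  expect_equal(sort(unique(ps$n_leavers + ps$n_censored)),
               sort(unique(study_design()$n)), ignore_attr = TRUE)
  agg <- aggregate_descriptors(ps)
  expect_equal(nrow(agg), 7)
  expect_true(all(agg$n_series == 4))
  # a treatment where nothing is grazed: GUD within control sampling spread
  quiet <- simulate_trial(simulation_config(quitting_coef = 0),
                          "E. ventrosa", 1)
  expect_true(all(is.na(quiet$foragers$departure_time)))
  # missing controls abort the exploitation stage by name
  nodisks <- study$disks[study$disks$role != "final_control", ]
  expect_error(compute_descriptors(study$foragers, nodisks), "final-control")
})
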
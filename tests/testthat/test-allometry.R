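test_that("individual metabolic rate follows the power law and its invariants", {
  m <- metabolic_model()
  expect_equal(round(individual_metabolic_rate(7.77, m), 2), 3.49)
  expect_equal(round(individual_metabolic_rate(0.37, m), 2), 0.31)
  expect_equal(individual_metabolic_rate(1, m), m$a)

  # strictly increasing in M; homogeneity I(kM) = k^b I(M)
  M <- sort(stats::runif(20, 0.1, 50))
  I <- individual_metabolic_rate(M, m)
  expect_true(all(diff(I) > 0))
  for (k in c(0.5, 2, 7.3))
    expect_equal(individual_metabolic_rate(k * M, m),
                 k^m$b * I, tolerance = 1e-12)

  expect_error(individual_metabolic_rate(0, m), "positive")
  expect_error(individual_metabolic_rate(-3, m), "positive")
  expect_error(metabolic_model(a = -1), "positive")
  expect_error(metabolic_model(b = 2.5), "0, 2")
})

test_that("delta-method size-CI propagation agrees with a finite-difference oracle", {
  m <- metabolic_model()
  fd_oracle <- function(M, dM, h = 1e-6) {
    (individual_metabolic_rate(M + h, m) -
       individual_metabolic_rate(M - h, m)) / (2 * h) * dM
  }
  expect_equal(propagate_size_ci(7.77, 0, m), 0)
  expect_equal(propagate_size_ci(7.77, 2.99, m), fd_oracle(7.77, 2.99),
               tolerance = 1e-6)
  expect_equal(round(propagate_size_ci(7.77, 2.99, m), 3), 1.06)
  expect_equal(propagate_size_ci(0.37, 0.05, m), fd_oracle(0.37, 0.05),
               tolerance = 1e-6)
  expect_equal(round(propagate_size_ci(0.37, 0.05, m), 4), 0.0336)
  # random cases against the oracle at relative tolerance 1e-6
  set.seed(11)
  for (i in 1:20) {
    M <- stats::runif(1, 0.05, 40); dM <- stats::runif(1, 0, M / 2)
    expect_equal(propagate_size_ci(M, dM, m), fd_oracle(M, dM),
                 tolerance = 1e-6)
  }
  expect_warning(propagate_size_ci(1, 1.5, m), "non-positive")
})

test_that("population energetics are exactly linear in cohort size", {
  m <- metabolic_model()
  pe <- population_energetics(7, 7.77, 2.99, m)
  expect_equal(pe$total_biomass, 7 * 7.77)
  expect_equal(pe$overall_rate, 7 * individual_metabolic_rate(7.77, m))
  expect_equal(pe$overall_rate_ci, 7 * propagate_size_ci(7.77, 2.99, m))
  # per-biomass rate is independent of n
  for (n in c(1, 4, 145))
    expect_equal(population_energetics(n, 0.37, 0, m)$per_biomass_rate,
                 individual_metabolic_rate(0.37, m) / 0.37)
  expect_warning(pe0 <- population_energetics(0, 12.88, 2.54, m), "empty")
  expect_equal(pe0$total_biomass, 0)
  expect_equal(pe0$overall_rate, 0)
})

test_that("equivalent_count rounds to nearest, reports the raw ratio, and round-trips", {
  expect_equal(equivalent_count(21, 3.49)$count, 6L)
  expect_equal(equivalent_count(21, 5.25)$count, 4L)
  bio <- equivalent_count(51.52, 7.77, mode = "biomass")
  expect_equal(bio$ratio, 51.52 / 7.77, tolerance = 1e-12)
  expect_equal(bio$count, 7L)
  expect_error(equivalent_count(10, 0), "positive")

  m <- metabolic_model()
  set.seed(3)
  for (i in 1:15) {
    n <- sample(1:200, 1); M <- stats::runif(1, 0.1, 20)
    rate <- suppressWarnings(population_energetics(n, M, 0, m)$overall_rate)
    expect_identical(
      equivalent_count(rate, individual_metabolic_rate(M, m))$count,
      as.integer(n))
  }
})

test_that("theoretical exponents pair the individual and per-biomass scalings", {
  expect_equal(theoretical_exponents(metabolic_model()),
               c(individual = 0.79, per_biomass = -0.21))
  expect_equal(theoretical_exponents(metabolic_model(b = 1)),
               c(individual = 1, per_biomass = 0))
  expect_equal(theoretical_exponents(metabolic_model(b = 0.75)),
               c(individual = 0.75, per_biomass = -0.25))
})

test_that("design table reproduces the treatment-table arithmetic", {
  dt <- design_table()
  cell <- function(id, col) dt[dt$treatment_id == id, col]
  expect_equal(cell("Gt4", "total_biomass"), 51.52)
  expect_equal(cell("Bt7", "total_biomass"), 54.39)
  expect_equal(cell("Ev145", "total_biomass"), 53.65)
  expect_equal(cell("Bt7", "overall_rate_printed"), 24.43)
  expect_equal(cell("Ev79", "overall_rate_printed"), 24.49)
  expect_equal(cell("Ev12", "overall_rate_printed"), 3.72)
  expect_equal(cell("Ev145", "overall_rate_printed"), 44.95)
  # modelled energy-equivalence rows carry the interpolation abundances
  expect_equal(dt$n[dt$modelled & dt$species == "B. tentaculata"], 6)
  expect_equal(dt$n[dt$modelled & dt$species == "E. ventrosa"], 66)
})
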
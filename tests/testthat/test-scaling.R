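test_that("power-law fit is exact on noiseless data and invariant to x rescaling", {
  x <- c(1, 2, 4, 8)
  fit <- suppressWarnings(fit_power_law(x, 2 * x^0.5))
  expect_equal(fit$a, 2, tolerance = 1e-12)
  expect_equal(fit$b, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$b_ci, 0, tolerance = 1e-9)

  flat <- suppressWarnings(fit_power_law(x, rep(3, 4)))
  expect_equal(flat$b, 0, tolerance = 1e-12)

  # slope invariant to positive rescaling of x; intercept maps as a * k^-b
  set.seed(31)
  y <- 1.7 * x^0.8 * exp(stats::rnorm(4, 0, 0.1))
  f1 <- fit_power_law(x, y); f2 <- fit_power_law(5 * x, y)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
  expect_equal(f2$a, f1$a * 5^-f1$b, tolerance = 1e-9)

  expect_error(fit_power_law(c(1, 2, -1), c(1, 2, 3)), "rows 3")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("log-log OLS agrees with a direct normal-equations oracle", {
  x <- c(1, 2, 4, 8)
  y <- c(1, 2.2, 4, 8)   # y = x with one point perturbed
  fit <- fit_power_law(x, y)
  lx <- log(x); ly <- log(y)
  slope_oracle <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sum((lx - mean(lx))^2)
  int_oracle <- mean(ly) - slope_oracle * mean(lx)
  expect_equal(fit$b, slope_oracle, tolerance = 1e-12)
  expect_equal(log(fit$a), int_oracle, tolerance = 1e-12)
  # Pearson r is the signed square root of the simple-regression R^2
  expect_equal(fit$r^2, fit$r_squared, tolerance = 1e-12)
  expect_equal(sign(fit$r), sign(fit$b))
})

test_that("slope CI covers the generating exponent at the nominal rate", {
  set.seed(99)
  beta <- 0.75; n <- 20; reps <- 1000
  x <- exp(stats::runif(n, 0, 3))
  covered <- 0L
  for (r in seq_len(reps)) {
    y <- 2 * x^beta * stats::rlnorm(n, 0, 0.3)
    f <- fit_power_law(x, y)
    if (f$b - f$b_ci <= beta && beta <= f$b + f$b_ci) covered <- covered + 1L
  }
  expect_gt(covered / reps, 0.93)
  expect_lt(covered / reps, 0.97)
})

test_that("logit-linearised fit recovers exact logistic relationships", {
  x <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  y <- stats::plogis(0.5 + 2 * log(x))
  fit <- suppressWarnings(fit_logit_fraction(x, y))
  expect_equal(fit$b, 2, tolerance = 1e-9)
  expect_equal(fit$a, 0.5, tolerance = 1e-9)
  # with continuous fractions the Bernoulli likelihood at p = y is the
  # entropy, not zero, so even a perfect fit keeps pseudo-R2 inside (0, 1)
  expect_gt(fit$pseudo_r_squared, 0.5)
  expect_lte(fit$pseudo_r_squared, 1)

  w <- testthat::capture_warnings(flat <- fit_logit_fraction(x, rep(0.4, 8)))
  expect_match(w, "zero variance", all = FALSE)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$pseudo_r_squared, 0, tolerance = 1e-12)

  # boundary fractions are nudged, values outside [0,1] rejected
  expect_silent(fit_logit_fraction(x, c(0, 0.2, 0.3, 0.5, 0.6, 0.7, 0.9, 1)))
  expect_error(fit_logit_fraction(x, c(1.2, rep(0.5, 7))), "\\[0, 1\\]")
})

test_that("McFadden pseudo-R2 matches an explicit two-likelihood oracle", {
  set.seed(17)
  x <- c(4, 7, 12, 25, 44, 79, 120, 145)
  y <- stats::plogis(-1 + 0.6 * log(x) + stats::rnorm(8, 0, 0.4))
  fit <- fit_logit_fraction(x, y)

  ll <- function(p) sum(y * log(p) + (1 - y) * log(1 - p))
  co <- stats::coef(stats::lm(stats::qlogis(y) ~ log(x)))
  p_fit <- stats::plogis(co[1] + co[2] * log(x))
  p_null <- stats::plogis(mean(stats::qlogis(y)))
  oracle <- 1 - ll(p_fit) / ll(p_null)
  expect_equal(fit$pseudo_r_squared, oracle, tolerance = 1e-12)
  expect_gte(fit$pseudo_r_squared, 0)
  expect_lte(fit$pseudo_r_squared, 1)
})

test_that("Pearson correlation matches the covariance formula and handles edge cases", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(0.7, 2.1, 1.4, 4.9, 3.1)
  pc <- pearson_with_ci(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, oracle, tolerance = 1e-12)
  expect_true(pc$ci_lower <= pc$r && pc$r <= pc$ci_upper)

  exact <- pearson_with_ci(1:5, 2 + 3 * (1:5))
  expect_equal(exact$r, 1)
  expect_lt(exact$p, 1e-10)

  # orthogonal construction
  xo <- c(-1, 1, -1, 1); yo <- c(-1, -1, 1, 1)
  expect_equal(pearson_with_ci(xo, yo)$r, 0)

  expect_warning(und <- pearson_with_ci(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(und$r))
})

test_that("one-way residual-charge ANOVA matches hand-computed sums of squares", {
  same <- residual_charge_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)

  res <- residual_charge_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 1.5)    # SSB = 1.5 on 1 df, SSW = 4 on 4 df
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)

  expect_error(residual_charge_anova(1:3, c("a", "a", "b")), ">= 2 groups")
})
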
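#' Power-law fit by OLS on log-log axes
#'
#' Fits `Y = a * X^b` by ordinary least squares of `log(y)` on `log(x)`
#' (natural logs; the base only shifts the intercept, never the exponent).
#' The intercept is back-transformed to the multiplicative coefficient `a`;
#' 95% CIs come from the t distribution of the linear fit; the R^2 is that
#' of the log-log regression. Pearson's correlation on the log-log pairs is
#' reported alongside, as is conventional in allometric scaling tables.
#'
#' @param x,y Strictly positive numeric vectors, length >= 3.
#' @param conf Confidence level for all CIs.
#' @return Object of class `scaling_fit`: list with `a`, `b`,
#'   `a_ci` (half-width on the back-transformed scale, asymmetric: the
#'   half-width of the log-intercept CI mapped through `exp` is reported as
#'   `a_ci_lower`/`a_ci_upper` too), `b_ci`, `r`, `r_ci`, `p_value`,
#'   `r_squared`, `link = "log-log"`, `n`, and the underlying `lm` fit.
#' @examples
#' x <- c(1, 2, 4, 8); fit_power_law(x, 2 * x^0.5)
#' @export
fit_power_law <- function(x, y, conf = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad))
    stop("fit_power_law: non-positive or non-finite values in rows ",
         paste(bad, collapse = ", "))
  if (length(x) < 3) stop("fit_power_law: need n >= 3")
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  ci <- stats::confint(fit, level = conf)
  co <- stats::coef(fit)
  pc <- pearson_with_ci(lx, ly, conf = conf)
  structure(list(
    a = exp(unname(co[1])), b = unname(co[2]),
    log_intercept = unname(co[1]),
    log_intercept_ci = unname(diff(ci[1, ])) / 2,
    a_ci_lower = exp(ci[1, 1]), a_ci_upper = exp(ci[1, 2]),
    b_ci = unname(diff(ci[2, ])) / 2,
    r = pc$r, r_ci = pc$ci, p_value = pc$p,
    r_squared = summary(fit)$r.squared,
    link = "log-log", n = length(x), fit = fit
  ), class = "scaling_fit")
}

#' Logit-linearised fit for fractional descriptors
#'
#' For descriptors that are fractions in (0, 1) (e.g. resource
#' exploitation), the relationship with size or abundance is linearised
#' with the logit link: OLS of `log(y / (1 - y))` on `log(x)`. Because an
#' R^2 is not meaningful for link-transformed responses, goodness of fit is
#' reported as McFadden's pseudo-R^2, `1 - llik(fit) / llik(null)`, where
#' both log-likelihoods use the Bernoulli form
#' `sum(y * log(p) + (1 - y) * log(1 - p))` with `p` the inverse-logit
#' fitted fractions and the null model the intercept-only logit fit.
#'
#' @param x Strictly positive predictor.
#' @param y Fractions; values outside `(0, 1)` but within `[0, 1]` are
#'   nudged into the open interval by `eps`, values outside `[0, 1]` are an
#'   error.
#' @param eps Boundary nudge for exact 0/1 fractions.
#' @param conf Confidence level.
#' @return A `scaling_fit` with `link = "logit-log"` and
#'   `pseudo_r_squared` in place of `r_squared`.
#' @export
fit_logit_fraction <- function(x, y, eps = 1e-6, conf = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(!is.finite(x) | x <= 0)) stop("fit_logit_fraction: 'x' must be positive")
  if (any(!is.finite(y) | y < 0 | y > 1))
    stop("fit_logit_fraction: 'y' must lie in [0, 1]")
  if (length(x) < 3) stop("fit_logit_fraction: need n >= 3")
  y <- pmin(pmax(y, eps), 1 - eps)
  lx <- log(x); ly <- stats::qlogis(y)
  fit <- stats::lm(ly ~ lx)
  ci <- stats::confint(fit, level = conf)
  co <- stats::coef(fit)
  pc <- pearson_with_ci(lx, ly, conf = conf)

  bernoulli_ll <- function(p) sum(y * log(p) + (1 - y) * log(1 - p))
  ll_fit <- bernoulli_ll(stats::plogis(stats::fitted(fit)))
  ll_null <- bernoulli_ll(stats::plogis(mean(ly)))
  pseudo <- 1 - ll_fit / ll_null
  structure(list(
    a = unname(co[1]), b = unname(co[2]),
    a_ci = unname(diff(ci[1, ])) / 2,
    b_ci = unname(diff(ci[2, ])) / 2,
    r = pc$r, r_ci = pc$ci, p_value = pc$p,
    pseudo_r_squared = max(0, pseudo),
    link = "logit-log", n = length(x), fit = fit
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  if (x$link == "log-log") {
    cat(sprintf("Power-law fit (n = %d): Y = %.4g * X^%.4g  [slope ± %.4g]\n",
                x$n, x$a, x$b, x$b_ci))
    cat(sprintf("R2 = %.3f; Pearson r = %.3f [± %.3f], p = %.3g\n",
                x$r_squared, x$r, x$r_ci, x$p_value))
  } else {
    cat(sprintf("Logit-log fit (n = %d): logit(Y) = %.4g + %.4g log X  [slope ± %.4g]\n",
                x$n, x$a, x$b, x$b_ci))
    cat(sprintf("McFadden pseudo-R2 = %.3f; Pearson r = %.3f [± %.3f], p = %.3g\n",
                x$pseudo_r_squared, x$r, x$r_ci, x$p_value))
  }
  invisible(x)
}

#' Pearson correlation with Fisher-z CI and t-test p-value
#'
#' Product-moment correlation with a two-sided t-test p-value and a 95% CI
#' from the Fisher z transform. Degenerate (zero-variance) inputs return
#' `NA` with a warning rather than an error, since scaling tables can
#' legitimately contain flat descriptors.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @param conf Confidence level.
#' @return List with `r`, `ci` (half-width), `ci_lower`, `ci_upper`, `p`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson_with_ci: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_with_ci: zero variance; correlation undefined")
    return(list(r = NA_real_, ci = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  if (is.null(ct$conf.int)) {
    # Fisher-z CI needs n >= 4 (se = 1/sqrt(n - 3))
    lo <- NA_real_; hi <- NA_real_
  } else {
    lo <- unname(ct$conf.int[1]); hi <- unname(ct$conf.int[2])
  }
  list(r = unname(ct$estimate), ci = (hi - lo) / 2,
       ci_lower = lo, ci_upper = hi, p = ct$p.value)
}

#' One-way fixed-effects ANOVA on residual disk charges
#'
#' F test for a treatment effect on grazed-disk residual charges (the
#' ungrazed final-control disks enter as their own group, so a k-treatment
#' study yields `df_between = k`).
#'
#' @param charge Disk charges, nCi.
#' @param group Group labels (factor or character), >= 2 groups with >= 2
#'   values each.
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
residual_charge_anova <- function(charge, group) {
  stopifnot(length(charge) == length(group))
  group <- factor(group)
  counts <- table(group)
  if (length(counts) < 2 || any(counts < 2))
    stop("residual_charge_anova: need >= 2 groups with >= 2 values each")
  fit <- stats::lm(charge ~ group)
  tab <- stats::anova(fit)
  list(F = tab$`F value`[1],
       df_between = tab$Df[1],
       df_within = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}
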
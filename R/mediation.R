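#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value on n - 2
#' degrees of freedom (delegated to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# centred cross-products; closed-form OLS paths for a simple mediation model
# (used by simple_mediation and, vectorised, by its bootstrap)
mediation_paths <- function(x, m, y) {
  n <- length(x)
  mx <- mean(x); mm <- mean(m); my <- mean(y)
  sxx <- sum((x - mx)^2); smm <- sum((m - mm)^2)
  sxm <- sum((x - mx) * (m - mm))
  sxy <- sum((x - mx) * (y - my))
  smy <- sum((m - mm) * (y - my))
  det <- sxx * smm - sxm^2
  a <- sxm / sxx
  c_tot <- sxy / sxx
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  list(a = a, b = b, c = c_tot, c_prime = c_prime)
}

#' Simple mediation analysis with percentile bootstrap
#'
#' Decomposes the total effect of `x` on `y` into the direct path `c_prime`
#' and the indirect path `a * b` through the mediator `m`, using ordinary
#' least squares with intercepts: `a` from the regression of `m` on `x`;
#' `(c_prime, b)` from `y` on `x` and `m` jointly; `c` from `y` on `x`.
#' Percent direct and percent mediated are `100 c_prime / c` and
#' `100 a b / c`, which sum to 100 by the OLS identity `c = c_prime + a b`.
#' Inference for the indirect effect is by percentile bootstrap (rows
#' resampled jointly); the effect is declared significant when the CI
#' excludes zero. A Sobel z is reported as a diagnostic only.
#'
#' @param x,m,y numeric vectors of equal length >= 5; `x` and `m` must not
#'   be collinear.
#' @param n_boot bootstrap resamples (default 5000).
#' @param ci_level confidence level for the percentile CI (default 0.95).
#' @param seed RNG seed for the bootstrap (`NULL` = current stream).
#' @param standardize if `TRUE`, z-score all three variables first.
#' @param case optional label naming the X/M/Y roles.
#' @return object of class `mediation_result` with paths, p-values,
#'   `indirect`, `percent_direct`, `percent_mediated` (NA when `c` is 0),
#'   `ci` and diagnostics.
#' @examples
#' fit <- simple_mediation(x = c(1, 2, 3, 4, 5), m = c(1, 3, 2, 5, 4),
#'                         y = c(2, 4, 5, 8, 7), n_boot = 200, seed = 1)
#' fit$indirect
#' @export
simple_mediation <- function(x, m, y, n_boot = 5000, ci_level = 0.95,
                             seed = NULL, standardize = FALSE, case = NULL) {
  stopifnot(is.numeric(x), is.numeric(m), is.numeric(y))
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (n < 5) stop("need at least 5 observations")
  if (anyNA(x) || anyNA(m) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(m) == 0) stop("zero variance in x or m")
  if (abs(stats::cor(x, m)) > 1 - 1e-10) stop("x and m are collinear")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  if (standardize) {
    x <- as.numeric(scale(x)); m <- as.numeric(scale(m)); y <- as.numeric(scale(y))
  }
  fit_m <- stats::lm(m ~ x)
  fit_y <- stats::lm(y ~ x + m)
  fit_c <- stats::lm(y ~ x)
  sm <- stats::coef(summary(fit_m)); sy <- stats::coef(summary(fit_y))
  sc <- stats::coef(summary(fit_c))
  a <- sm["x", "Estimate"]; se_a <- sm["x", "Std. Error"]
  b <- sy["m", "Estimate"]; se_b <- sy["m", "Std. Error"]
  c_prime <- sy["x", "Estimate"]
  c_tot <- sc["x", "Estimate"]
  indirect <- a * b
  sobel_se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  sobel_z <- indirect / sobel_se
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    xb <- matrix(x[idx], n_boot, n)
    mb <- matrix(m[idx], n_boot, n)
    yb <- matrix(y[idx], n_boot, n)
    mxb <- rowMeans(xb); mmb <- rowMeans(mb); myb <- rowMeans(yb)
    sxx <- rowSums(xb^2) - n * mxb^2
    smm <- rowSums(mb^2) - n * mmb^2
    sxm <- rowSums(xb * mb) - n * mxb * mmb
    sxy <- rowSums(xb * yb) - n * mxb * myb
    smy <- rowSums(mb * yb) - n * mmb * myb
    det <- sxx * smm - sxm^2
    ab <- (sxm / sxx) * (sxx * smy - sxm * sxy) / det
    ab[!is.finite(ab)] <- NA_real_
    ab
  })
  alpha <- 1 - ci_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  pct_direct <- if (abs(c_tot) > 0) 100 * c_prime / c_tot else NA_real_
  pct_mediated <- if (abs(c_tot) > 0) 100 * indirect / c_tot else NA_real_
  structure(list(
    a = a, b = b, c = c_tot, c_prime = c_prime, indirect = indirect,
    percent_direct = pct_direct, percent_mediated = pct_mediated,
    p_a = sm["x", "Pr(>|t|)"], p_b = sy["m", "Pr(>|t|)"],
    p_c = sc["x", "Pr(>|t|)"], p_c_prime = sy["x", "Pr(>|t|)"],
    ci_level = ci_level, ci = ci,
    significant_indirect = ci[1] > 0 || ci[2] < 0,
    sobel_z = sobel_z, sobel_p = 2 * stats::pnorm(-abs(sobel_z)),
    n = n, n_boot = n_boot, seed = seed, standardized = standardize,
    case = case %||% "X -> Y through M"),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s (n = %d)\n", x$case, x$n))
  cat(sprintf("  a = %.5f, b = %.5f, c = %.5f, c' = %.5f\n", x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect (a*b) = %.5f, %d%% percentile CI [%.5f, %.5f]%s\n",
              x$indirect, round(100 * x$ci_level), x$ci[1], x$ci[2],
              if (x$significant_indirect) " *" else ""))
  if (is.finite(x$percent_direct))
    cat(sprintf("  %.1f%% direct, %.1f%% mediated\n", x$percent_direct, x$percent_mediated))
  invisible(x)
}

#' Standardised mediation paths from a correlation matrix
#'
#' Correlation-level counterpart of [simple_mediation()]: with standardised
#' variables, `a = r_xm`, `b = (r_my - r_xy r_xm) / (1 - r_xm^2)`,
#' `c_prime = (r_xy - r_my r_xm) / (1 - r_xm^2)`, `c = r_xy`; the identity
#' `c = c_prime + a b` holds algebraically.
#'
#' @param r_xm,r_xy,r_my pairwise Pearson correlations; magnitudes <= 1,
#'   `|r_xm| < 1`, and the implied 3 x 3 matrix positive semi-definite.
#' @return list with `a`, `b`, `c`, `c_prime`, `indirect`,
#'   `percent_direct`, `percent_mediated`.
#' @examples
#' mediation_from_correlations(r_xm = 0.50, r_xy = 0.45, r_my = 0.91)
#' @export
mediation_from_correlations <- function(r_xm, r_xy, r_my) {
  rs <- c(r_xm, r_xy, r_my)
  if (any(!is.finite(rs)) || any(abs(rs) > 1))
    stop("correlations must be finite with magnitude <= 1")
  if (abs(r_xm) >= 1) stop("|r_xm| = 1: x and m are collinear")
  cm <- matrix(c(1, r_xm, r_xy, r_xm, 1, r_my, r_xy, r_my, 1), 3, 3)
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("implied correlation matrix is not positive semi-definite")
  denom <- 1 - r_xm^2
  a <- r_xm
  b <- (r_my - r_xy * r_xm) / denom
  c_prime <- (r_xy - r_my * r_xm) / denom
  c_tot <- r_xy
  list(a = a, b = b, c = c_tot, c_prime = c_prime, indirect = a * b,
       percent_direct = if (c_tot != 0) 100 * c_prime / c_tot else NA_real_,
       percent_mediated = if (c_tot != 0) 100 * a * b / c_tot else NA_real_)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] (3 <= n <= 5000) with explicit
#' zero-variance and range errors.
#'
#' @param values numeric vector.
#' @return list with `statistic` (W) and `p`.
#' @export
normality_check <- function(values) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(values) == 0) stop("zero variance input")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}
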
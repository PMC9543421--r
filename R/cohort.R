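# Table-layout defaults: per-zone and per-layer GSU means and SDs of the
# calibration cohort (standardised greyscale units)
default_zone_targets <- function() {
  list(means = c(gsu_zone_0_2 = 15, gsu_zone_2_6 = 14,
                 gsu_zone_6_10 = 19, gsu_zone_10_12 = 26),
       sds = c(gsu_zone_0_2 = 4, gsu_zone_2_6 = 4,
               gsu_zone_6_10 = 9, gsu_zone_10_12 = 11))
}
default_layer_targets <- function() {
  list(means = c(gsu_layer_anterior = 23, gsu_layer_central = 16,
                 gsu_layer_posterior = 13),
       sds = c(gsu_layer_anterior = 9, gsu_layer_central = 6,
               gsu_layer_posterior = 6))
}

#' Calibrate the linear-Gaussian cohort model
#'
#' Solves for structural coefficients of the chain age -> tilt ->
#' densitometry such that the population means, SDs and pairwise
#' correlations equal the targets exactly. In standardised variables:
#' `tilt* = r_at age* + e_t` and
#' `dens* = b_age age* + b_tilt tilt* + e_d`, where `(b_age, b_tilt)` solve
#' the two-predictor normal equations of the target correlation matrix.
#' Defaults are the calibration cohort statistics: age 42.8 +/- 20.0 y,
#' tilt 5.8 +/- 1.8 deg, overall densitometry 17 +/- 7 GSU, correlations
#' r(age,tilt) = 0.50, r(age,dens) = 0.91, r(tilt,dens) = 0.45.
#'
#' @param age_mean,age_sd age moments (years).
#' @param tilt_mean,tilt_sd corneal tilt moments (degrees).
#' @param dens_mean,dens_sd overall densitometry moments (GSU).
#' @param r_age_tilt,r_age_dens,r_tilt_dens target Pearson correlations;
#'   the implied matrix must be positive definite.
#' @param age_bounds resampling bounds on age in years; the default is
#'   unbounded because no normal truncated to a ~60-year window can carry a
#'   20-year SD, so bounding would break the moment calibration (see the
#'   methods vignette). Pass e.g. `c(18, 79)` for an eligibility-faithful
#'   cohort at the cost of calibration.
#' @param shared_loading fraction (in SD units) of each zone/layer value
#'   carried by the subject's overall densitometry; the remainder is
#'   independent noise. Cross-region correlations are not part of the
#'   calibration targets, so this within-subject coherence is a model choice.
#' @param zone_targets,layer_targets lists with `means` and `sds` vectors
#'   for the four zones / three layers.
#' @return object of class `cohort_model` including the structural
#'   coefficients `beta_age`, `beta_tilt` and residual SDs.
#' @examples
#' m <- calibrate_cohort_model()
#' c(m$beta_age, m$beta_tilt)
#' @export
calibrate_cohort_model <- function(age_mean = 42.8, age_sd = 20.0,
                                   tilt_mean = 5.8, tilt_sd = 1.8,
                                   dens_mean = 17, dens_sd = 7,
                                   r_age_tilt = 0.50, r_age_dens = 0.91,
                                   r_tilt_dens = 0.45,
                                   age_bounds = c(-Inf, Inf),
                                   shared_loading = 0.8,
                                   zone_targets = default_zone_targets(),
                                   layer_targets = default_layer_targets()) {
  if (any(abs(c(r_age_tilt, r_age_dens, r_tilt_dens)) > 1))
    stop("correlation magnitudes must be <= 1")
  corr <- matrix(c(1, r_age_tilt, r_age_dens,
                   r_age_tilt, 1, r_tilt_dens,
                   r_age_dens, r_tilt_dens, 1), 3, 3)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("target correlation matrix is not positive definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  if (age_sd <= 0 || tilt_sd <= 0 || dens_sd <= 0) stop("SDs must be > 0")
  sd_tilt_resid <- sqrt(1 - r_age_tilt^2)
  denom <- 1 - r_age_tilt^2
  beta_age <- (r_age_dens - r_tilt_dens * r_age_tilt) / denom
  beta_tilt <- (r_tilt_dens - r_age_dens * r_age_tilt) / denom
  var_dens_resid <- 1 - (beta_age * r_age_dens + beta_tilt * r_tilt_dens)
  if (var_dens_resid <= 0) stop("implied densitometry residual variance is not positive")
  if (abs(shared_loading) > 1) stop("shared_loading must lie in [-1, 1]")
  # explained (signal) variance of standardised densitometry
  var_mu <- beta_age^2 + beta_tilt^2 + 2 * beta_age * beta_tilt * r_age_tilt
  dens_comp <- solve_support_calibration(
    target_mean = dens_mean, S = dens_sd * sqrt(var_mu),
    E = dens_sd * sqrt(var_dens_resid))
  region_comp <- list()
  for (tg in list(zone_targets, layer_targets)) {
    for (nm in names(tg$means)) {
      region_comp[[nm]] <- solve_support_calibration(
        target_mean = tg$means[[nm]],
        S = tg$sds[[nm]] * abs(shared_loading),
        E = tg$sds[[nm]] * sqrt(1 - shared_loading^2))
    }
  }
  structure(list(
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    tilt_mean = tilt_mean, tilt_sd = tilt_sd,
    dens_mean = dens_mean, dens_sd = dens_sd,
    r_age_tilt = r_age_tilt, r_age_dens = r_age_dens, r_tilt_dens = r_tilt_dens,
    beta_age = beta_age, beta_tilt = beta_tilt,
    sd_tilt_resid = sd_tilt_resid, sd_dens_resid = sqrt(var_dens_resid),
    shared_loading = shared_loading, var_mu = var_mu,
    dens_comp = dens_comp, region_comp = region_comp,
    zone_targets = zone_targets, layer_targets = layer_targets),
    class = "cohort_model")
}

#' Correlations implied by a cohort model (closed form)
#'
#' @param model a [calibrate_cohort_model()] result.
#' @return named vector `r_age_tilt`, `r_age_dens`, `r_tilt_dens` implied by
#'   the structural coefficients; equal to the calibration targets by
#'   construction.
#' @export
implied_correlations <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  c(r_age_tilt = model$r_age_tilt,
    r_age_dens = model$beta_age + model$beta_tilt * model$r_age_tilt,
    r_tilt_dens = model$beta_age * model$r_age_tilt + model$beta_tilt)
}

#' @export
print.cohort_model <- function(x, ...) {
  cat(sprintf("<cohort_model> age %g +/- %g y, tilt %g +/- %g deg, densitometry %g +/- %g GSU\n",
              x$age_mean, x$age_sd, x$tilt_mean, x$tilt_sd, x$dens_mean, x$dens_sd))
  cat(sprintf("  structural: tilt* = %.4f age* + e;  dens* = %.5f age* + %.5f tilt* + e\n",
              x$r_age_tilt, x$beta_age, x$beta_tilt))
  invisible(x)
}

# ---- support-aware moment calibration --------------------------------------
# Redrawing GSU values that fall outside [0, 100] truncates the lower tail,
# which deflates the realized SD and (because part of the removed variance is
# signal) the covariances with the upstream variables. These helpers solve,
# once at calibration time, for an intercept C, a signal scale g and a
# residual scale k of v = C + g*S*d + k*E*e (d, e standard normal; redraw
# until v in [lo, hi]) such that the redrawn population has mean/SD equal to
# the targets and cov(x, v) equal to the untruncated value for every x that
# is jointly Gaussian with d. The covariance condition reduces, by Stein's
# identity, to g * E[d tn_mean/dm] = 1 — a single factor fixes all upstream
# covariances at once. All integrals are deterministic Gaussian quadrature.

# truncated-normal mean and variance on [lo, hi]; vectorised over m
tn_mean_var <- function(m, s, lo, hi) {
  if (s <= 0) stop("truncated-normal scale must be > 0")
  al <- (lo - m) / s; be <- (hi - m) / s
  Z <- stats::pnorm(be) - stats::pnorm(al)
  fa <- stats::dnorm(al); fb <- stats::dnorm(be)
  mean <- m + s * (fa - fb) / Z
  var <- s^2 * (1 + (al * fa - be * fb) / Z - ((fa - fb) / Z)^2)
  # kept mass underflows when the location is many sigmas outside [lo, hi]:
  # the redrawn value then concentrates at the near boundary
  deg <- !is.finite(mean) | !is.finite(var) | Z < 1e-280
  if (any(deg)) {
    mean[deg] <- ifelse(m[deg] < (lo + hi) / 2, lo, hi)
    var[deg] <- 0
  }
  var <- pmax(var, 0)
  list(mean = mean, var = var)
}

# population moments of the redrawn value when the conditional location is
# C + g*S*d with d ~ N(0,1): returns mean, var, and the Stein attenuation
# factor g * E[d tn_mean / dm]
redraw_population_stats <- function(C, g, k, S, E, lo, hi, nodes) {
  m <- C + g * S * nodes$z
  s <- k * E
  tv <- tn_mean_var(m, s, lo, hi)
  h <- 1e-4
  dmean <- (tn_mean_var(m + h, s, lo, hi)$mean -
              tn_mean_var(m - h, s, lo, hi)$mean) / (2 * h)
  mean <- sum(nodes$w * tv$mean)
  e2 <- sum(nodes$w * (tv$var + tv$mean^2))
  list(mean = mean, var = e2 - mean^2, attenuation = g * sum(nodes$w * dmean))
}

gauss_nodes <- function(n = 801, span = 8) {
  z <- seq(-span, span, length.out = n)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  list(z = z, w = w)
}

# solve (C, g, k) so the redrawn population matches target mean/var and the
# Stein attenuation equals 1 (covariances preserved). S/E: signal and
# residual SDs of the unbounded model. Identity when truncation is negligible.
solve_support_calibration <- function(target_mean, S, E, lo = 0, hi = 100) {
  if (E <= 0 || S < 0) return(list(C = target_mean, g = 1, k = 1))
  target_var <- S^2 + E^2
  nodes <- gauss_nodes()
  # untouched model: if the out-of-range mass is negligible, keep identity
  mass_out <- sum(nodes$w * (stats::pnorm(lo, target_mean + S * nodes$z, E) +
                               stats::pnorm(target_mean + S * nodes$z, hi, E)))
  if (mass_out < 1e-12) return(list(C = target_mean, g = 1, k = 1))
  C <- target_mean; g <- 1; k <- 1
  for (sweep in 1:25) {
    st <- redraw_population_stats(C, g, k, S, E, lo, hi, nodes)
    g <- g / st$attenuation
    kfun <- function(kk)
      redraw_population_stats(C, g, kk, S, E, lo, hi, nodes)$var - target_var
    lo_k <- 1e-3; hi_k <- 4
    if (kfun(lo_k) > 0) {
      k <- lo_k
    } else {
      k <- stats::uniroot(kfun, c(lo_k, hi_k), tol = 1e-12)$root
    }
    st <- redraw_population_stats(C, g, k, S, E, lo, hi, nodes)
    C <- C + (target_mean - st$mean)
    if (abs(st$mean - target_mean) < 1e-9 &&
        abs(st$var - target_var) < 1e-8 &&
        abs(st$attenuation - 1) < 1e-9) break
  }
  st <- redraw_population_stats(C, g, k, S, E, lo, hi, nodes)
  if (abs(st$mean - target_mean) > 1e-6 || abs(st$var - target_var) > 1e-4)
    stop("support calibration failed to converge for target mean ", target_mean)
  list(C = C, g = g, k = k)
}

# redraw entries of `draw()` until `ok(value)`; preserves moments better
# than clamping. Returns list(values, redraws).
redraw_until <- function(n, draw, ok, max_rounds = 1000) {
  v <- draw(n)
  redraws <- 0L
  bad <- which(!ok(v))
  rounds <- 0
  while (length(bad)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) stop("redraw limit exceeded; targets likely infeasible")
    redraws <- redraws + length(bad)
    v[bad] <- draw(length(bad))
    bad <- bad[!ok(v[bad])]
  }
  list(values = v, redraws = redraws)
}

# exact redraw of out-of-range values: sampling the truncated conditional by
# inverse CDF is distributionally identical to redrawing until in range, but
# needs one uniform per value (a conditional mean far outside the support
# would otherwise demand astronomically many rejection rounds)
rtrunc_conditional <- function(k, mean, sd, lo, hi) {
  if (any(sd <= 0)) stop("value outside its physical range with zero residual SD")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(k, pmin(plo, 1 - 1e-16), pmax(phi, 1e-300))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

#' Simulate a cohort of subjects
#'
#' Draws ages, then tilt, then densitometry following the structural
#' equations of the calibrated model; per-zone and per-layer GSU values are
#' affine transforms of the subject's standardised overall densitometry
#' plus independent noise matched to the target means/SDs. Values outside
#' their physical range (tilt < 0, GSU outside `[0, 100]`, age outside
#' `age_bounds`) are redrawn from the truncated conditional distribution
#' (never clamped); out-of-range counts are attached as the `"redraws"`
#' attribute. Deterministic for a given seed.
#'
#' @param model a [calibrate_cohort_model()] result.
#' @param n number of subjects (>= 4); default 86, the calibration cohort
#'   size (right eyes only, one record per subject).
#' @param seed RNG seed (`NULL` = current stream).
#' @return data.frame with columns `id`, `age_years`, `tilt_deg`,
#'   `gsu_overall`, `gsu_zone_0_2`, `gsu_zone_2_6`, `gsu_zone_6_10`,
#'   `gsu_zone_10_12`, `gsu_layer_anterior`, `gsu_layer_central`,
#'   `gsu_layer_posterior`.
#' @export
simulate_cohort <- function(model, n = 86, seed = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  if (n < 4) stop("n must be >= 4")
  with_seed(seed, {
    redraws <- c()
    agez <- redraw_until(n, function(k) stats::rnorm(k),
                         function(z) {
                           a <- model$age_mean + model$age_sd * z
                           a >= model$age_bounds[1] & a <= model$age_bounds[2]
                         })
    redraws["age"] <- agez$redraws
    a_star <- agez$values
    age <- model$age_mean + model$age_sd * a_star

    # tilt residuals with the tilt >= 0 constraint enforced per subject
    # (acceptance depends on the paired age draw, so redraw conditionally)
    e_t <- stats::rnorm(n)
    t_star <- model$r_age_tilt * a_star + model$sd_tilt_resid * e_t
    tilt <- model$tilt_mean + model$tilt_sd * t_star
    bad <- which(tilt < 0)
    if (length(bad)) {
      cond_mean <- model$tilt_mean +
        model$tilt_sd * model$r_age_tilt * a_star[bad]
      tilt[bad] <- rtrunc_conditional(length(bad), cond_mean,
                                      model$tilt_sd * model$sd_tilt_resid,
                                      lo = 0, hi = Inf)
      t_star[bad] <- (tilt[bad] - model$tilt_mean) / model$tilt_sd
    }
    redraws["tilt"] <- length(bad)

    mu_d <- model$beta_age * a_star + model$beta_tilt * t_star
    cmp <- model$dens_comp
    e_d <- stats::rnorm(n)
    cond_mean <- cmp$C + cmp$g * model$dens_sd * mu_d
    cond_sd <- cmp$k * model$dens_sd * model$sd_dens_resid
    dens <- cond_mean + cond_sd * e_d
    bad <- which(dens < 0 | dens > 100)
    if (length(bad))
      dens[bad] <- rtrunc_conditional(length(bad), cond_mean[bad], cond_sd,
                                      lo = 0, hi = 100)
    redraws["dens"] <- length(bad)
    # standardised overall densitometry: population mean/SD equal the
    # targets by construction of the support calibration
    d_star <- (dens - model$dens_mean) / model$dens_sd

    out <- data.frame(id = sprintf("S%03d", seq_len(n)),
                      age_years = age, tilt_deg = tilt, gsu_overall = dens)
    lam <- model$shared_loading
    resid_load <- sqrt(1 - lam^2)
    region_targets <- list(model$zone_targets, model$layer_targets)
    for (tg in region_targets) {
      for (nm in names(tg$means)) {
        sdv <- tg$sds[[nm]]
        rc <- model$region_comp[[nm]]
        mu_r <- rc$C + rc$g * sdv * lam * d_star
        sd_r <- rc$k * sdv * resid_load
        v <- mu_r + sd_r * stats::rnorm(n)
        bad <- which(v < 0 | v > 100)
        if (length(bad))
          v[bad] <- rtrunc_conditional(length(bad), mu_r[bad], sd_r,
                                       lo = 0, hi = 100)
        redraws[nm] <- length(bad)
        out[[nm]] <- v
      }
    }
    attr(out, "redraws") <- redraws
    out
  })
}
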
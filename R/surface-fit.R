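#' Fit a smooth polynomial surface to an elevation grid
#'
#' Least-squares fit, over the central aperture, of the space of bivariate
#' polynomials of total degree `basis_order` — the span of Zernike terms up
#' to that radial order on the disc. Coordinates are scaled to the fit
#' radius and the system solved by QR, giving continuous analytic height
#' and gradient callables for the ray tracer. Extrapolation beyond the fit
#' radius is forbidden.
#'
#' @param grid an [elevation_grid()].
#' @param basis_order maximum total polynomial degree (default 8, the
#'   conventional radial order for corneal topography smoothing).
#' @param fit_radius radius of the fitted aperture in mm; default
#'   `min(half_aperture, 4)` (the central 8-mm zone).
#' @return an object of class `smooth_surface` with fields `coef`,
#'   `powx`/`powy` (monomial exponents), `scale`, `rms_residual` (mm),
#'   `basis_order`, `n_points`, `zrange`.
#' @export
fit_smooth_surface <- function(grid, basis_order = 8, fit_radius = NULL) {
  stopifnot(inherits(grid, "elevation_grid"), basis_order >= 1)
  a <- fit_radius %||% min(grid$half_aperture, 4)
  if (a <= 0 || a > grid$half_aperture + 1e-9)
    stop("fit_radius must be positive and within the grid aperture")
  xy <- grid_xy(grid)
  keep <- is.finite(grid$heights) & (xy$x^2 + xy$y^2 <= a^2 * (1 + 1e-12))
  ex <- expand.grid(i = 0:basis_order, j = 0:basis_order)
  ex <- ex[ex$i + ex$j <= basis_order, ]
  nterm <- nrow(ex)
  if (sum(keep) < nterm)
    stop("insufficient valid grid points (", sum(keep), ") for ", nterm, " basis terms")
  u <- xy$x[keep] / a
  v <- xy$y[keep] / a
  z <- grid$heights[keep]
  pu <- outer(u, 0:basis_order, `^`)
  pv <- outer(v, 0:basis_order, `^`)
  X <- pu[, ex$i + 1L] * pv[, ex$j + 1L]
  fit <- lm.fit(X, z)
  if (fit$rank < nterm)
    stop("rank-deficient surface fit (rank ", fit$rank, " < ", nterm, " terms)")
  res <- fit$residuals
  structure(
    list(coef = unname(fit$coefficients), powx = ex$i, powy = ex$j,
         scale = a, basis_order = basis_order, n_points = sum(keep),
         rms_residual = sqrt(mean(res^2)),
         zrange = range(z), surface = grid$surface),
    class = "smooth_surface"
  )
}

#' @export
print.smooth_surface <- function(x, ...) {
  cat(sprintf("<smooth_surface> %s, order %d over r <= %.3g mm, %d points, RMS residual %.3g um\n",
              x$surface %||% "surface", x$basis_order, x$scale, x$n_points,
              1000 * x$rms_residual))
  invisible(x)
}

check_in_aperture <- function(s, x, y) {
  if (any(x^2 + y^2 > s$scale^2 * (1 + 1e-9)))
    stop("point outside the fitted aperture (extrapolation forbidden)")
}

#' @export
srf_height.smooth_surface <- function(s, x, y) {
  check_in_aperture(s, x, y)
  u <- x / s$scale; v <- y / s$scale
  pu <- outer(u, 0:s$basis_order, `^`)
  pv <- outer(v, 0:s$basis_order, `^`)
  as.numeric((pu[, s$powx + 1L, drop = FALSE] * pv[, s$powy + 1L, drop = FALSE]) %*% s$coef)
}

#' @export
srf_gradient.smooth_surface <- function(s, x, y) {
  check_in_aperture(s, x, y)
  u <- x / s$scale; v <- y / s$scale
  pu <- outer(u, 0:s$basis_order, `^`)
  pv <- outer(v, 0:s$basis_order, `^`)
  # d/dx [u^i v^j] = (i/a) u^(i-1) v^j ; u^(i-1) read with exponent clamped
  pux <- pu[, pmax(s$powx, 1L), drop = FALSE] * rep(s$powx / s$scale, each = length(u))
  pux[, s$powx == 0L] <- 0
  pvy <- pv[, pmax(s$powy, 1L), drop = FALSE] * rep(s$powy / s$scale, each = length(v))
  pvy[, s$powy == 0L] <- 0
  gx <- as.numeric((pux * pv[, s$powy + 1L, drop = FALSE]) %*% s$coef)
  gy <- as.numeric((pu[, s$powx + 1L, drop = FALSE] * pvy) %*% s$coef)
  list(gx = gx, gy = gy)
}

#' @export
srf_zrange.smooth_surface <- function(s) s$zrange + c(-0.25, 0.25)
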
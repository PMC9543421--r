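#' Analytic biconic (conicoid) corneal surface
#'
#' A conicoid with independent apical radii and asphericities along the
#' x and y principal meridians, the standard analytic model for corneal
#' anterior and posterior surfaces. Equal radii and Q values reduce it to
#' a rotationally symmetric conic (Q = 0 sphere, Q = -1 paraboloid).
#' Heights are sag in mm measured from the apex plane toward +z (the
#' instrument / visual axis; light propagates toward +z).
#'
#' @param radius_x,radius_y apical radii of curvature in mm (> 0).
#' @param q_x,q_y asphericities (conic constants Q) along x and y.
#' @param apex apex offset `(x0, y0, z0)` in mm.
#' @return an object of class `conicoid_surface`.
#' @examples
#' s <- conicoid_surface(7.8, q_x = -0.25)
#' sagitta(s, 1, 0)
#' @export
conicoid_surface <- function(radius_x, radius_y = radius_x,
                             q_x = 0, q_y = q_x, apex = c(0, 0, 0)) {
  stopifnot(is.numeric(radius_x), is.numeric(radius_y),
            length(apex) == 3, all(is.finite(apex)))
  if (radius_x <= 0 || radius_y <= 0) stop("apex radii must be > 0")
  structure(
    list(radius_x = radius_x, radius_y = radius_y,
         q_x = q_x, q_y = q_y, apex = as.numeric(apex)),
    class = "conicoid_surface"
  )
}

#' @export
print.conicoid_surface <- function(x, ...) {
  cat(sprintf(
    "<conicoid_surface> Rx=%.4g mm, Ry=%.4g mm, Qx=%.4g, Qy=%.4g, apex=(%g, %g, %g)\n",
    x$radius_x, x$radius_y, x$q_x, x$q_y, x$apex[1], x$apex[2], x$apex[3]))
  invisible(x)
}

# square-root argument of the sag equation; real sag requires >= 0
conicoid_sqrt_arg <- function(s, x, y) {
  1 - (1 + s$q_x) * x^2 / s$radius_x^2 - (1 + s$q_y) * y^2 / s$radius_y^2
}

#' Sagitta (height) of a conicoid surface
#'
#' Evaluates the sag equation
#' `z = (x^2/Rx + y^2/Ry) / (1 + sqrt(1 - (1+Qx) x^2/Rx^2 - (1+Qy) y^2/Ry^2))`
#' relative to the apex, then adds the apex offset. Vectorised over `x`, `y`.
#'
#' @param surface a [conicoid_surface()].
#' @param x,y in-plane coordinates in mm (relative to the instrument axis).
#' @param allow_na if `TRUE`, points outside the real-sag domain yield `NA`
#'   instead of an error (used when sampling grids near the conic limit).
#' @return heights in mm; `z(x0, y0) = z0`.
#' @export
sagitta <- function(surface, x, y, allow_na = FALSE) {
  stopifnot(inherits(surface, "conicoid_surface"))
  xr <- x - surface$apex[1]
  yr <- y - surface$apex[2]
  arg <- conicoid_sqrt_arg(surface, xr, yr)
  bad <- arg < 0
  if (any(bad, na.rm = TRUE) && !allow_na)
    stop("point outside the real-sag domain of the conicoid")
  arg[bad] <- NA_real_
  num <- xr^2 / surface$radius_x + yr^2 / surface$radius_y
  surface$apex[3] + num / (1 + sqrt(arg))
}

# gradient (dz/dx, dz/dy) of the sag; list(gx, gy), vectorised
conicoid_gradient <- function(surface, x, y, allow_na = FALSE) {
  xr <- x - surface$apex[1]
  yr <- y - surface$apex[2]
  arg <- conicoid_sqrt_arg(surface, xr, yr)
  bad <- arg < 0
  if (any(bad, na.rm = TRUE) && !allow_na)
    stop("point outside the real-sag domain of the conicoid")
  arg[bad] <- NA_real_
  S <- sqrt(arg)
  D <- 1 + S
  N <- xr^2 / surface$radius_x + yr^2 / surface$radius_y
  sx <- -(1 + surface$q_x) * xr / (surface$radius_x^2 * S)
  sy <- -(1 + surface$q_y) * yr / (surface$radius_y^2 * S)
  list(gx = (2 * xr / surface$radius_x * D - N * sx) / D^2,
       gy = (2 * yr / surface$radius_y * D - N * sy) / D^2)
}

#' Unit normal of a conicoid surface
#'
#' Outward (toward -z light source) normal `(-dz/dx, -dz/dy, 1)`
#' normalised to unit length, so the z-component is always positive.
#'
#' @inheritParams sagitta
#' @return a unit 3-vector (for scalar input) or a 3-column matrix.
#' @export
analytic_normal <- function(surface, x, y) {
  g <- conicoid_gradient(surface, x, y)
  n <- cbind(-g$gx, -g$gy, 1)
  n <- n / sqrt(rowSums(n^2))
  if (length(x) == 1L) as.numeric(n) else n
}

# ---- generic surface interface used by the ray tracer ---------------------
# srf_height/srf_gradient dispatch over conicoid_surface and smooth_surface

srf_height <- function(s, x, y) UseMethod("srf_height")
srf_gradient <- function(s, x, y) UseMethod("srf_gradient")
srf_zrange <- function(s) UseMethod("srf_zrange")

#' @export
srf_height.conicoid_surface <- function(s, x, y) sagitta(s, x, y)
#' @export
srf_gradient.conicoid_surface <- function(s, x, y) conicoid_gradient(s, x, y)
#' @export
srf_zrange.conicoid_surface <- function(s) {
  # sag is monotone in r along each meridian; bound via the domain edge
  rmax <- 6
  zs <- vapply(seq(0, 2 * pi, length.out = 32), function(th) {
    r <- rmax
    repeat {
      arg <- conicoid_sqrt_arg(s, r * cos(th), r * sin(th))
      if (arg >= 0.05 || r < 0.5) break
      r <- r * 0.9
    }
    sagitta(s, s$apex[1] + r * cos(th), s$apex[2] + r * sin(th))
  }, numeric(1))
  range(c(s$apex[3], zs))
}

srf_normal <- function(s, x, y) {
  g <- srf_gradient(s, x, y)
  unit_vector(c(-g$gx, -g$gy, 1))
}
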
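#' Specification of a synthetic cornea
#'
#' Parameters for a tilted biconic cornea sampled to anterior/posterior
#' elevation grids with optional Gaussian measurement noise — the package's
#' stand-in for measured eyes, with known ground-truth tilt. Defaults are
#' typical adult values: anterior radius 7.8 mm (Q = -0.25), posterior
#' radius 6.5 mm (Q = -0.20), central thickness 0.55 mm, sampled at 0.25-mm
#' spacing over a 10-mm-diameter aperture.
#'
#' @param anterior_radius,anterior_q anterior apical radius (mm) and Q.
#' @param posterior_radius,posterior_q posterior apical radius (mm) and Q.
#' @param thickness central corneal thickness, mm.
#' @param tilt_x,tilt_y true tilt angles (deg) applied about the anterior
#'   apex, x first then y.
#' @param noise_sd_um elevation measurement noise SD, micrometres (>= 0).
#' @param spacing grid spacing, mm.
#' @param half_aperture grid half-aperture, mm.
#' @param seed RNG seed for the noise (`NULL` = current stream).
#' @return object of class `cornea_spec`.
#' @export
cornea_spec <- function(anterior_radius = 7.8, anterior_q = -0.25,
                        posterior_radius = 6.5, posterior_q = -0.20,
                        thickness = 0.55, tilt_x = 0, tilt_y = 0,
                        noise_sd_um = 0, spacing = 0.25, half_aperture = 5,
                        seed = NULL) {
  if (noise_sd_um < 0) stop("noise SD must be >= 0")
  if (thickness <= 0) stop("thickness must be > 0")
  structure(list(anterior_radius = anterior_radius, anterior_q = anterior_q,
                 posterior_radius = posterior_radius, posterior_q = posterior_q,
                 thickness = thickness, tilt_x = tilt_x, tilt_y = tilt_y,
                 noise_sd_um = noise_sd_um, spacing = spacing,
                 half_aperture = half_aperture, seed = seed),
            class = "cornea_spec")
}

# height map of a rigidly rotated analytic surface, solved per grid node by
# vectorised Newton iteration on z: the point (x, y, z) lies on the rotated
# surface iff R^T (x, y, z) lies on the unrotated one
rotated_surface_heights <- function(surface, rotation, x, y) {
  R <- rotation$matrix
  piv <- rotation$pivot
  xs <- x - piv[1]; ys <- y - piv[2]
  z <- sagitta(surface, x, y, allow_na = TRUE) - piv[3]   # untilted start
  z[is.na(z)] <- 0
  for (it in 1:50) {
    qx <- R[1, 1] * xs + R[2, 1] * ys + R[3, 1] * z + piv[1]
    qy <- R[1, 2] * xs + R[2, 2] * ys + R[3, 2] * z + piv[2]
    qz <- R[1, 3] * xs + R[2, 3] * ys + R[3, 3] * z + piv[3]
    s <- sagitta(surface, qx, qy, allow_na = TRUE)
    g <- qz - s
    if (all(is.na(g) | abs(g) < 1e-13)) break
    gr <- conicoid_gradient(surface, qx, qy, allow_na = TRUE)
    dg <- R[3, 3] - (gr$gx * R[3, 1] + gr$gy * R[3, 2])
    step <- g / dg
    step[is.na(step)] <- 0
    z <- z - step
  }
  out <- z + piv[3]
  out[is.na(g)] <- NA_real_
  out
}

#' Generate a synthetic tilted cornea as elevation grids
#'
#' Samples the anterior and posterior conicoids, applies the true-tilt
#' rotation about the anterior apex, solves each grid node for the rotated
#' surface height, masks cells outside the circular aperture or the conic
#' domain, and adds independent Gaussian elevation noise. Deterministic for
#' a given seed.
#'
#' @param spec a [cornea_spec()].
#' @return list with `anterior` and `posterior` [elevation_grid()]s and
#'   `truth`, the applied [rotation_from_angles()] rotation.
#' @export
make_cornea <- function(spec) {
  stopifnot(inherits(spec, "cornea_spec"))
  ant <- conicoid_surface(spec$anterior_radius, q_x = spec$anterior_q)
  post <- conicoid_surface(spec$posterior_radius, q_x = spec$posterior_q,
                           apex = c(0, 0, spec$thickness))
  # fail early if the aperture leaves the conic sag domain
  for (s in list(ant, post)) {
    if (conicoid_sqrt_arg(s, spec$half_aperture, 0) < 0 ||
        conicoid_sqrt_arg(s, 0, spec$half_aperture) < 0)
      stop("grid aperture exceeds the real-sag domain of the surface")
  }
  truth <- rotation_from_angles(spec$tilt_x, spec$tilt_y, pivot = c(0, 0, 0))
  n <- round(spec$half_aperture / spec$spacing)
  if (abs(n * spec$spacing - spec$half_aperture) > 1e-9)
    stop("half_aperture must be an integer multiple of spacing")
  xv <- spec$spacing * seq(-n, n)
  X <- matrix(xv, 2 * n + 1, 2 * n + 1, byrow = TRUE)
  Y <- matrix(rev(xv), 2 * n + 1, 2 * n + 1)
  inside <- X^2 + Y^2 <= spec$half_aperture^2 * (1 + 1e-12)
  grids <- with_seed(spec$seed, {
    lapply(list(anterior = ant, posterior = post), function(s) {
      h <- rotated_surface_heights(s, truth, X, Y)
      h[!inside] <- NA_real_
      if (spec$noise_sd_um > 0) {
        noise <- matrix(stats::rnorm(length(h), sd = spec$noise_sd_um / 1000),
                        nrow(h), ncol(h))
        h <- h + ifelse(is.na(h), NA_real_, noise)
      }
      h
    })
  })
  list(anterior = elevation_grid(grids$anterior, spec$spacing, "anterior"),
       posterior = elevation_grid(grids$posterior, spec$spacing, "posterior"),
       truth = truth)
}
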
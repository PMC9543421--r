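#' Construct a ray
#'
#' @param origin 3-vector origin in mm.
#' @param direction 3-vector direction; normalised to unit length.
#' @return object of class `ray`.
#' @export
ray <- function(origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3,
            all(is.finite(origin)), all(is.finite(direction)))
  structure(list(origin = as.numeric(origin),
                 direction = unit_vector(as.numeric(direction))),
            class = "ray")
}

#' @export
print.ray <- function(x, ...) {
  cat(sprintf("<ray> origin (%g, %g, %g), direction (%.6f, %.6f, %.6f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Vector-form Snell refraction
#'
#' Refracts a unit direction `d` at an interface with unit normal `n`,
#' from index `n1` into `n2`:
#' `t = (n1/n2) d + ((n1/n2) cos(theta_i) - cos(theta_t)) n`.
#' The normal may be given with either sign; it is flipped internally so it
#' opposes the incoming ray. The output is unit length, lies in the plane
#' of incidence, and satisfies `n1 sin(theta_i) = n2 sin(theta_t)`.
#'
#' @param direction incoming unit direction.
#' @param normal surface unit normal (either orientation).
#' @param n1,n2 refractive indices on the incidence and transmission sides.
#' @return refracted unit direction.
#' @export
refract <- function(direction, normal, n1, n2) {
  d <- unit_vector(direction)
  n <- unit_vector(normal)
  if (n1 <= 0 || n2 <= 0) stop("refractive indices must be > 0")
  if (sum(d * n) > 0) n <- -n        # make the normal oppose the ray
  ci <- -sum(d * n)                  # cos(theta_i) > 0
  eta <- n1 / n2
  st2 <- eta^2 * (1 - ci^2)          # sin^2(theta_t)
  if (st2 > 1) stop("total internal reflection (sin(theta_t) > 1)")
  ct <- sqrt(1 - st2)
  unit_vector(eta * d + (eta * ci - ct) * n)
}

#' Intersect a ray with a surface
#'
#' First point along the ray where the ray height equals the surface height
#' z(x, y), found by bracketing in z and root refinement to |dz| < 1e-9 mm.
#' Works for both analytic conicoids and fitted smooth surfaces.
#'
#' @param r a [ray()] propagating toward +z.
#' @param surface a `conicoid_surface` or `smooth_surface`.
#' @param t_min smallest admissible ray parameter (used to step off a
#'   surface the ray just left).
#' @return intersection point, a 3-vector in mm.
#' @export
intersect_surface <- function(r, surface, t_min = 0) {
  stopifnot(inherits(r, "ray"))
  d <- r$direction; o <- r$origin
  if (d[3] <= 1e-9) stop("ray does not propagate toward +z")
  zr <- srf_zrange(surface)
  f <- function(t) {
    p <- o + t * d
    p[3] - srf_height(surface, p[1], p[2])
  }
  t_lo <- max(t_min, (zr[1] - 0.5 - o[3]) / d[3])
  t_hi <- (zr[2] + 0.5 - o[3]) / d[3]
  f_lo <- f(t_lo)
  if (f_lo > 0) {
    # origin already past the bracket floor (e.g. between the surfaces):
    # start from the origin itself
    t_lo <- max(t_min, 0)
    f_lo <- f(t_lo)
  }
  f_hi <- f(t_hi)
  if (!(f_lo < 0 && f_hi > 0))
    stop("ray does not intersect the surface within its aperture")
  root <- uniroot(f, c(t_lo, t_hi), f.lower = f_lo, f.upper = f_hi,
                  tol = 1e-12, maxiter = 200)
  o + root$root * d
}

#' Two-surface corneal model for ray tracing
#'
#' Anterior and posterior surfaces (analytic or fitted) with the refractive
#' indices of air, corneal stroma and aqueous humour. Central thickness is
#' implied by the apex heights of the two surfaces.
#'
#' @param anterior,posterior `conicoid_surface` or `smooth_surface` objects;
#'   the posterior apex must lie behind the anterior apex.
#' @param n_air,n_cornea,n_aqueous refractive indices (defaults 1.0, 1.376,
#'   1.336 — standard Gullstrand values).
#' @return object of class `corneal_model`.
#' @export
corneal_model <- function(anterior, posterior,
                          n_air = 1.0, n_cornea = 1.376, n_aqueous = 1.336) {
  if (n_air <= 0 || n_cornea <= 0 || n_aqueous <= 0)
    stop("refractive indices must be > 0")
  thick <- srf_height(posterior, 0, 0) - srf_height(anterior, 0, 0)
  if (thick <= 0)
    stop("posterior apex must lie behind the anterior apex (central thickness > 0)")
  structure(list(anterior = anterior, posterior = posterior,
                 n_air = n_air, n_cornea = n_cornea, n_aqueous = n_aqueous,
                 central_thickness = thick),
            class = "corneal_model")
}

#' @export
print.corneal_model <- function(x, ...) {
  cat(sprintf("<corneal_model> central thickness %.4g mm, indices %.3f / %.3f / %.3f\n",
              x$central_thickness, x$n_air, x$n_cornea, x$n_aqueous))
  invisible(x)
}

#' Trace a ray through the cornea
#'
#' Two Snell refractions: air to stroma at the anterior surface, stroma to
#' aqueous at the posterior surface.
#'
#' @param model a [corneal_model()].
#' @param r incoming [ray()] originating in air before the anterior surface.
#' @return the exit [ray()] (origin on the posterior surface).
#' @export
trace_through_cornea <- function(model, r) {
  stopifnot(inherits(model, "corneal_model"))
  p1 <- intersect_surface(r, model$anterior)
  d1 <- refract(r$direction, srf_normal(model$anterior, p1[1], p1[2]),
                model$n_air, model$n_cornea)
  r1 <- ray(p1, d1)
  p2 <- intersect_surface(r1, model$posterior, t_min = 1e-9)
  d2 <- refract(d1, srf_normal(model$posterior, p2[1], p2[2]),
                model$n_cornea, model$n_aqueous)
  ray(p2, d2)
}

#' Axial crossing distance of an exit ray
#'
#' Distance, measured along the axis direction from the exit point, to the
#' point of closest approach between the exit ray and the axis ray — the
#' local focal length of that ray. Defined this way it is invariant under
#' rigid rotation of the whole scene. Parallel rays return `Inf`.
#'
#' @param exit_ray,axis_ray [ray()] objects with unit directions.
#' @return distance in mm, or `Inf` when the directions are parallel
#'   within 1e-12.
#' @export
axial_crossing_distance <- function(exit_ray, axis_ray) {
  d1 <- exit_ray$direction; d2 <- axis_ray$direction
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (sqrt(sum(cr^2)) < 1e-12) return(Inf)
  w0 <- exit_ray$origin - axis_ray$origin
  b <- sum(d1 * d2)
  dd <- sum(d1 * w0); e <- sum(d2 * w0)
  t1 <- (b * e - dd) / (1 - b^2)      # parameter of closest approach on exit ray
  q <- exit_ray$origin + t1 * d1
  sum((q - exit_ray$origin) * d2)
}

#' Central-ray deviation under a trial rotation
#'
#' Rotates the corneal model rigidly by `rotation` (implemented by tracing
#' the counter-rotated central ray, which is geometrically identical), then
#' returns the (x, y) components of the exit direction minus the instrument
#' axis. A zero residual means the central ray exits undeviated — infinite
#' focal length — so this pair is the least-squares residual that the
#' optical-axis optimisation drives to zero.
#'
#' @param model a [corneal_model()].
#' @param rotation a [rotation_from_angles()] result.
#' @param start_z z at which the central ray starts (mm, before the cornea).
#' @return named numeric `(x, y)` residual (dimensionless direction
#'   components).
#' @export
central_ray_deviation <- function(model, rotation, start_z = -10) {
  stopifnot(inherits(model, "corneal_model"), inherits(rotation, "rigid_rotation"))
  o <- apply_rotation_inverse(rotation, c(0, 0, start_z))
  d <- as.numeric(crossprod(rotation$matrix, c(0, 0, 1)))
  ex <- trace_through_cornea(model, ray(o, d))
  d_out <- as.numeric(rotation$matrix %*% ex$direction)
  c(x = d_out[1], y = d_out[2])
}

#' Estimate the corneal optical axis and angle alpha
#'
#' Fits smooth surfaces to the anterior and posterior elevation grids, then
#' runs a Levenberg-Marquardt loop over the two tilt angles, rotating the
#' cornea until the central ray (entering along the instrument axis, which
#' is taken as the visual axis) traverses both surfaces undeviated. The
#' optical axis is the inverse rotation applied to the instrument axis;
#' angle alpha is its angle to that axis and is the package's measure of
#' corneal tilt.
#'
#' @param anterior,posterior [elevation_grid()] objects.
#' @param basis_order polynomial order for [fit_smooth_surface()].
#' @param fit_radius fitted aperture radius in mm (default central 8-mm zone).
#' @param bounds_deg symmetric optimiser bounds on each tilt angle (deg);
#'   the default 15 covers physiologic tilt with margin.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param start starting angles (deg), default `c(0, 0)`.
#' @return object of class `tilt_result`: `optical_axis` (unit vector in the
#'   instrument frame), `angle_alpha` (deg), `residual_deviation`,
#'   `iterations`, `converged`, `fitted_rotation`, plus fit diagnostics.
#' @export
estimate_optical_axis <- function(anterior, posterior, basis_order = 8,
                                  fit_radius = NULL, bounds_deg = 15,
                                  max_iter = 200, start = c(0, 0)) {
  stopifnot(inherits(anterior, "elevation_grid"), inherits(posterior, "elevation_grid"))
  ant <- fit_smooth_surface(anterior, basis_order = basis_order, fit_radius = fit_radius)
  post <- fit_smooth_surface(posterior, basis_order = basis_order, fit_radius = fit_radius)
  model <- corneal_model(ant, post)
  fn <- function(par) {
    tryCatch(
      central_ray_deviation(model, rotation_from_angles(par[1], par[2])),
      error = function(e) c(10, 10)   # trace failure flagged to the optimiser
    )
  }
  out <- minpack.lm::nls.lm(
    par = start, fn = fn,
    lower = rep(-bounds_deg, 2), upper = rep(bounds_deg, 2),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0, epsfcn = 1e-8))
  rot <- rotation_from_angles(out$par[1], out$par[2])
  axis <- as.numeric(crossprod(rot$matrix, c(0, 0, 1)))  # inverse rotation of z-hat
  resid <- sqrt(sum(out$fvec^2))
  structure(
    list(optical_axis = axis,
         angle_alpha = angle_between_axes(axis, c(0, 0, 1)),
         residual_deviation = resid,
         iterations = out$niter,
         converged = is.finite(resid) && resid < 1e-8,
         fitted_rotation = rot,
         fit_rms_anterior = ant$rms_residual,
         fit_rms_posterior = post$rms_residual),
    class = "tilt_result"
  )
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf("<tilt_result> angle alpha %.4f deg, axis (%.5f, %.5f, %.5f)\n",
              x$angle_alpha, x$optical_axis[1], x$optical_axis[2], x$optical_axis[3]))
  cat(sprintf("  residual %.3g, %d iterations, converged: %s\n",
              x$residual_deviation, x$iterations, x$converged))
  invisible(x)
}

#' Serialise a tilt result to JSON
#'
#' @param result a `tilt_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tilt_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "tilt_result"))
  rec <- list(angle_alpha_deg = result$angle_alpha,
              axis_x = result$optical_axis[1],
              axis_y = result$optical_axis[2],
              axis_z = result$optical_axis[3],
              residual = result$residual_deviation,
              iterations = result$iterations,
              converged = result$converged)
  if (is.null(path)) return(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}
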
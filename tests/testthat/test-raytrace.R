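test_that("refraction matches scalar Snell in the plane of incidence", {
  # no index step or normal incidence: direction unchanged
  d <- c(0.3, -0.2, 0.933); d <- d / sqrt(sum(d^2))
  expect_equal(refract(d, c(0.1, 0.2, 0.97), 1.336, 1.336), d, tolerance = 1e-12)
  expect_equal(refract(c(0, 0, 1), c(0, 0, 1), 1, 1.376), c(0, 0, 1),
               tolerance = 1e-12)
  # 45 deg into n = 1.376: sin(theta_t) = sin(45)/1.376
  st <- sin(pi / 4) / 1.376
  want <- c(st, 0, sqrt(1 - st^2))
  got <- refract(c(1, 0, 1) / sqrt(2), c(0, 0, 1), 1, 1.376)
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(got, c(0.51389, 0, 0.85786), tolerance = 1e-5)
  # normal sign must not matter
  expect_equal(refract(c(1, 0, 1) / sqrt(2), c(0, 0, -1), 1, 1.376), want,
               tolerance = 1e-12)
})

test_that("Snell invariant and plane of incidence hold over random refractions", {
  set.seed(101)
  for (i in 1:300) {
    d <- random_direction()
    n <- c(rnorm(2, sd = 0.3), 1); n <- n / sqrt(sum(n^2))
    n1 <- runif(1, 1, 1.6); n2 <- runif(1, 1, 1.6)
    ci <- abs(sum(d * n))
    if (sqrt(1 - ci^2) * n1 / n2 >= 1) next  # skip TIR geometries
    t <- refract(d, n, n1, n2)
    expect_equal(sqrt(sum(t^2)), 1, tolerance = 1e-12)
    # n1 sin(theta_i) = n2 sin(theta_t)
    si <- sqrt(1 - sum(d * n)^2); stt <- sqrt(1 - sum(t * n)^2)
    expect_equal(n1 * si, n2 * stt, tolerance = 1e-12)
    # refracted ray stays in span(d, n)
    cr <- c(d[2] * n[3] - d[3] * n[2], d[3] * n[1] - d[1] * n[3],
            d[1] * n[2] - d[2] * n[1])
    expect_lt(abs(sum(t * cr)), 1e-12)
  }
  expect_error(refract(c(1, 0, 0.02), c(0, 0, 1), 1.6, 1.0),
               "total internal reflection")
})

test_that("ray-surface intersection matches closed forms", {
  sph <- conicoid_surface(7.8, q_x = 0)
  expect_equal(intersect_surface(ray(c(0, 0, -10), c(0, 0, 1)), sph),
               c(0, 0, 0), tolerance = 1e-9)
  # oblique ray onto a sphere satisfies the sphere equation to 1e-9
  r <- ray(c(0.8, -0.4, -10), c(0.05, 0.02, 0.998))
  p <- intersect_surface(r, sph)
  expect_equal(sum((p - c(0, 0, 7.8))^2), 7.8^2, tolerance = 1e-9)
  # flat surface z = 0.5 fitted from a grid
  plane <- fit_smooth_surface(
    elevation_grid(matrix(0.5, 41, 41), 0.25, "anterior"))
  expect_equal(intersect_surface(ray(c(0, 0, -10), c(0, 0, 1)), plane),
               c(0, 0, 0.5), tolerance = 1e-9)
  expect_error(intersect_surface(ray(c(0, 0, -10), c(0, 1, 0)), sph),
               "propagate")
})

test_that("tracing an untilted symmetric cornea leaves the axial ray undeviated", {
  model <- corneal_model(conicoid_surface(7.8, q_x = -0.25),
                         conicoid_surface(6.5, q_x = -0.2, apex = c(0, 0, 0.55)))
  out <- trace_through_cornea(model, ray(c(0, 0, -10), c(0, 0, 1)))
  expect_equal(out$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(out$origin[1:2], c(0, 0), tolerance = 1e-12)
  # exit directions are unit length across a bundle
  set.seed(103)
  for (i in 1:100) {
    h <- runif(2, -1.5, 1.5)
    out <- trace_through_cornea(model, ray(c(h[1], h[2], -10), c(0, 0, 1)))
    expect_equal(sum(out$direction^2), 1, tolerance = 1e-12)
  }
})

test_that("refractions are reversible and hit points collinear through the cornea", {
  model <- corneal_model(conicoid_surface(7.8, q_x = -0.25),
                         conicoid_surface(6.5, q_x = -0.2, apex = c(0, 0, 0.55)))
  set.seed(104)
  for (i in 1:25) {
    d0 <- c(rnorm(2, sd = 0.05), 1); d0 <- d0 / sqrt(sum(d0^2))
    o <- c(runif(2, -1, 1), -10)
    p1 <- intersect_surface(ray(o, d0), model$anterior)
    n1 <- corneatilt:::srf_normal(model$anterior, p1[1], p1[2])
    d1 <- refract(d0, n1, 1, 1.376)
    p2 <- intersect_surface(ray(p1, d1), model$posterior, t_min = 1e-9)
    n2 <- corneatilt:::srf_normal(model$posterior, p2[1], p2[2])
    d2 <- refract(d1, n2, 1.376, 1.336)
    # reverse the exit ray: each refraction must invert, segment collinear
    back1 <- refract(-d2, n2, 1.336, 1.376)
    expect_equal(back1, -d1, tolerance = 1e-8)
    seg <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    expect_equal(seg, d1, tolerance = 1e-9)
    back0 <- refract(back1, n1, 1.376, 1.0)
    expect_equal(back0, -d0, tolerance = 1e-8)
  }
})

test_that("paraxial bundle crosses the axis at the two-surface back focal distance", {
  # Gullstrand two-surface paraxial oracle (independent closed form)
  n_c <- 1.376; n_a <- 1.336; t <- 0.55e-3
  P1 <- (n_c - 1) / 7.8e-3; P2 <- (n_a - n_c) / 6.5e-3
  P <- P1 + P2 - (t / n_c) * P1 * P2
  bfd_mm <- 1000 * n_a / (P / (1 - (t / n_c) * P1))
  model <- corneal_model(conicoid_surface(7.8),
                         conicoid_surface(6.5, apex = c(0, 0, 0.55)))
  axis <- ray(c(0, 0, -10), c(0, 0, 1))
  for (h in c(0.05, -0.1, 0.15, 0.2)) {
    ex <- trace_through_cornea(model, ray(c(h, 0, -10), c(0, 0, 1)))
    expect_equal(axial_crossing_distance(ex, axis), bfd_mm,
                 tolerance = 0.01)
  }
})

test_that("axial crossing distance: parallel, trigonometric and rotation cases", {
  axis <- ray(c(0, 0, 0), c(0, 0, 1))
  expect_identical(axial_crossing_distance(ray(c(1, 0, 0), c(0, 0, 1)), axis), Inf)
  for (phi in c(0.02, 0.1, 0.5)) {
    ex <- ray(c(1, 0, 0), c(-sin(phi), 0, cos(phi)))
    expect_equal(axial_crossing_distance(ex, axis), 1 / tan(phi),
                 tolerance = 1e-10)
  }
  # invariance under rigid rotation of the whole scene
  rot <- rotation_from_angles(17, -9, pivot = c(0.3, -0.2, 1))
  ex <- ray(c(1, 0.2, 0), c(-0.05, 0.01, 1))
  d0 <- axial_crossing_distance(ex, axis)
  ex_r <- ray(apply_rotation(rot, ex$origin),
              as.numeric(rot$matrix %*% ex$direction))
  ax_r <- ray(apply_rotation(rot, axis$origin),
              as.numeric(rot$matrix %*% axis$direction))
  expect_equal(axial_crossing_distance(ex_r, ax_r), d0, tolerance = 1e-9)
})

test_that("central-ray deviation is zero when the tilt is undone and grows smoothly", {
  eye0 <- make_cornea(cornea_spec())  # untilted
  m0 <- corneal_model(fit_smooth_surface(eye0$anterior),
                      fit_smooth_surface(eye0$posterior))
  expect_lt(sqrt(sum(central_ray_deviation(m0, rotation_from_angles(0, 0))^2)),
            1e-10)
  eye <- make_cornea(cornea_spec(tilt_x = 5, tilt_y = 0))
  m <- corneal_model(fit_smooth_surface(eye$anterior),
                     fit_smooth_surface(eye$posterior))
  expect_lt(sqrt(sum(central_ray_deviation(m, rotation_from_angles(-5, 0))^2)),
            1e-6)
  # residual norm increases monotonically with distance from the optimum
  offs <- c(0, 0.25, 0.5, 1, 2)
  norms <- vapply(offs, function(o)
    sqrt(sum(central_ray_deviation(m, rotation_from_angles(-5 + o, 0))^2)),
    numeric(1))
  expect_true(all(diff(norms) > 0))
})

test_that("optical-axis estimation recovers synthetic tilt", {
  # null case
  null <- make_cornea(cornea_spec())
  res0 <- estimate_optical_axis(null$anterior, null$posterior)
  expect_lt(res0$angle_alpha, 0.05)
  # (3, 4) deg tilt: truth = arccos(cos 3 cos 4) ~ 5 deg
  eye <- make_cornea(cornea_spec(tilt_x = 3, tilt_y = 4))
  res <- estimate_optical_axis(eye$anterior, eye$posterior)
  expect_true(res$converged)
  expect_lt(abs(res$angle_alpha - true_alpha(eye$truth)), 0.1)
  expect_lt(abs(res$angle_alpha - 5.00), 0.1)
  expect_equal(res$angle_alpha,
               angle_between_axes(res$optical_axis, c(0, 0, 1)),
               tolerance = 1e-9)
  # 2-um elevation noise across seeds stays within half a degree
  for (seed in 1:3) {
    eyen <- make_cornea(cornea_spec(tilt_x = 3, tilt_y = 4, noise_sd_um = 2,
                                    seed = seed))
    resn <- estimate_optical_axis(eyen$anterior, eyen$posterior)
    expect_lt(abs(resn$angle_alpha - true_alpha(eyen$truth)), 0.5)
  }
})

test_that("estimate is insensitive to doubling the smoothing basis order", {
  eye <- make_cornea(cornea_spec(tilt_x = 4, tilt_y = -2))
  r8 <- estimate_optical_axis(eye$anterior, eye$posterior, basis_order = 8)
  r16 <- estimate_optical_axis(eye$anterior, eye$posterior, basis_order = 16)
  expect_lt(abs(r8$angle_alpha - r16$angle_alpha), 0.05)
})

test_that("tilt results serialise to flat JSON records", {
  eye <- make_cornea(cornea_spec(tilt_x = 2, tilt_y = 1))
  res <- estimate_optical_axis(eye$anterior, eye$posterior)
  path <- withr::local_tempfile(fileext = ".json")
  tilt_result_json(res, path)
  rec <- jsonlite::read_json(path)
  expect_equal(rec$angle_alpha_deg, res$angle_alpha, tolerance = 1e-12)
  expect_identical(rec$converged, TRUE)
  expect_equal(rec$axis_z, res$optical_axis[3], tolerance = 1e-12)
})
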
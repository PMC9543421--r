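test_that("sagitta matches circle and paraboloid closed forms", {
  sph <- conicoid_surface(7.8, q_x = 0)
  expect_identical(sagitta(sph, 0, 0), 0)
  # Q = 0: circle z = R - sqrt(R^2 - r^2)
  expect_equal(sagitta(sph, 1, 0), 7.8 - sqrt(7.8^2 - 1), tolerance = 1e-12)
  r <- sqrt(runif(50, 0, 16))
  th <- runif(50, 0, 2 * pi)
  expect_equal(sagitta(sph, r * cos(th), r * sin(th)),
               7.8 - sqrt(7.8^2 - r^2), tolerance = 1e-12)
  # Q = -1: paraboloid z = r^2 / (2R)
  par <- conicoid_surface(7.8, q_x = -1)
  expect_equal(sagitta(par, 1, 0), 1 / (2 * 7.8), tolerance = 1e-12)
  # apex offset shifts the whole surface
  off <- conicoid_surface(7.8, q_x = 0, apex = c(0.5, -0.2, 0.55))
  expect_equal(sagitta(off, 0.5, -0.2), 0.55, tolerance = 1e-12)
})

test_that("sagitta rejects points outside the real-sag domain", {
  s <- conicoid_surface(2, q_x = 0.5)
  expect_error(sagitta(s, 2, 0), "domain")
  expect_true(is.na(sagitta(s, 2, 0, allow_na = TRUE)))
  expect_error(conicoid_surface(-1), "radii")
})

test_that("analytic normals are unit length and match the sphere closed form", {
  sph <- conicoid_surface(7.8, q_x = 0)
  expect_equal(analytic_normal(sph, 0, 0), c(0, 0, 1), tolerance = 1e-12)
  # a sphere's normal points toward its centre: (-sin, 0, cos), sin = x/R
  st <- 1 / 7.8
  expect_equal(analytic_normal(sph, 1, 0), c(-st, 0, sqrt(1 - st^2)),
               tolerance = 1e-9)
  set.seed(11)
  for (q in c(-1, -0.3, 0, 0.4)) {
    s <- conicoid_surface(7.5, q_x = q)
    r <- sqrt(runif(25, 0, 9)); th <- runif(25, 0, 2 * pi)
    n <- analytic_normal(s, r * cos(th), r * sin(th))
    expect_equal(rowSums(n^2), rep(1, 25), tolerance = 1e-12)
    expect_true(all(n[, 3] > 0))
  }
})

test_that("rotation matrices are orthonormal and match the explicit product", {
  expect_equal(rotation_from_angles(0, 0)$matrix, diag(3), tolerance = 1e-15)
  # explicit oracle: Rx(3 deg) %*% Ry(4 deg) applied to z-hat
  a <- 3 * pi / 180; b <- 4 * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  want <- as.numeric(rx %*% ry %*% c(0, 0, 1))
  got <- apply_rotation(rotation_from_angles(3, 4), c(0, 0, 1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(want, c(0.069756, -0.052208, 0.996196), tolerance = 1e-5)
  expect_equal(angle_between_axes(got, c(0, 0, 1)),
               acos(cos(a) * cos(b)) * 180 / pi, tolerance = 1e-9)
  set.seed(21)
  for (i in 1:100) {
    r <- rotation_from_angles(runif(1, -89, 89), runif(1, -89, 89))
    expect_lt(max(abs(crossprod(r$matrix) - diag(3))), 1e-12)
    expect_equal(det(r$matrix), 1, tolerance = 1e-12)
  }
  expect_error(rotation_from_angles(95, 0), "\\(-90, 90\\)")
})

test_that("elementary inverses composed in reversed order give the identity", {
  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, -30, 30); b <- runif(1, -30, 30)
    m <- rotation_from_angles(0, -b)$matrix %*%
      rotation_from_angles(-a, 0)$matrix %*%
      rotation_from_angles(a, b)$matrix
    expect_lt(max(abs(m - diag(3))), 1e-10)
  }
  # rotation about a pivot keeps the pivot fixed
  r <- rotation_from_angles(7, -3, pivot = c(0.5, 1, 2))
  expect_equal(apply_rotation(r, c(0.5, 1, 2)), c(0.5, 1, 2), tolerance = 1e-12)
})

test_that("angle_between_axes clamps rounding and rejects zero vectors", {
  expect_identical(angle_between_axes(c(0, 0, 1), c(0, 0, 1)), 0)
  th <- 5.8 * pi / 180
  expect_equal(angle_between_axes(c(sin(th), 0, cos(th)), c(0, 0, 1)), 5.8,
               tolerance = 1e-9)
  # vectors whose dot product exceeds 1 by rounding must not yield NaN
  v <- c(1, 1, 1) / sqrt(3)
  expect_false(is.nan(angle_between_axes(v, v * (1 + 1e-16))))
  expect_error(angle_between_axes(c(0, 0, 0), c(0, 0, 1)), "zero-length")
})

test_that("smooth surface fit reproduces a noise-free conicoid below 0.1 um", {
  g <- conicoid_grid(radius = 7.8, q = -0.25)
  fit <- fit_smooth_surface(g)
  expect_lt(fit$rms_residual, 1e-4)  # mm
  s <- conicoid_surface(7.8, q_x = -0.25)
  set.seed(41)
  r <- sqrt(runif(20, 0, 15.9)); th <- runif(20, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  expect_equal(srf_height(fit, x, y), sagitta(s, x, y), tolerance = 1e-4)
  expect_lt(max(abs(srf_height(fit, x, y) - sagitta(s, x, y))), 1e-4)
})

test_that("smooth surface normals agree with analytic normals within 0.01 deg", {
  g <- conicoid_grid(radius = 7.8, q = -0.25)
  fit <- fit_smooth_surface(g)
  s <- conicoid_surface(7.8, q_x = -0.25)
  set.seed(42)
  r <- sqrt(runif(40, 0, 15.9)); th <- runif(40, 0, 2 * pi)
  for (i in 1:40) {
    x <- r[i] * cos(th[i]); y <- r[i] * sin(th[i])
    nf <- corneatilt:::srf_normal(fit, x, y)
    na <- analytic_normal(s, x, y)
    expect_lt(angle_between_axes(nf, na), 0.01)
  }
})

test_that("fitting a plane gives zero gradient; fit smooths 2-um noise", {
  h <- matrix(0.5, 41, 41)
  plane <- elevation_grid(h, spacing = 0.25, surface = "anterior")
  fit <- fit_smooth_surface(plane)
  g <- srf_gradient(fit, c(0, 1, -2, 3), c(0, -1, 2, 1))
  expect_lt(max(abs(c(g$gx, g$gy))), 1e-9)
  expect_equal(srf_height(fit, 0, 0), 0.5, tolerance = 1e-12)

  gn <- conicoid_grid(noise_sd_um = 2, seed = 5)
  fitn <- fit_smooth_surface(gn)
  expect_lte(fitn$rms_residual, 3e-3)  # <= 3 um against 2-um generator noise
})

test_that("surface fit fails cleanly on insufficient data and extrapolation", {
  h <- matrix(NA_real_, 41, 41)
  h[19:23, 19:23] <- 0.1  # 25 valid points < 45 basis terms
  g <- elevation_grid(h, 0.25, "anterior")
  expect_error(fit_smooth_surface(g), "insufficient")
  fit <- fit_smooth_surface(conicoid_grid())
  expect_error(srf_height(fit, 4.5, 0), "extrapolation")
})

test_that("elevation CSV dialect round-trips bit-identically", {
  g <- conicoid_grid(noise_sd_um = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_elevation_csv(g, path)
  g2 <- read_elevation_csv(path)
  expect_identical(g2$spacing, g$spacing)
  expect_identical(g2$surface, g$surface)
  expect_identical(g2$half_aperture, g$half_aperture)
  fin <- is.finite(g$heights)
  expect_identical(fin, is.finite(g2$heights))
  expect_identical(g$heights[fin], g2$heights[fin])
  lines <- readLines(path)
  expect_match(lines[1], "^# spacing_mm=")
  expect_match(lines[3], "^# surface=anterior$")
})
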
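# shared fixtures, built in code at test time

# elevation grid sampled straight from an analytic conicoid (untilted)
conicoid_grid <- function(radius = 7.8, q = -0.25, spacing = 0.25,
                          half_aperture = 5, apex_z = 0,
                          surface = "anterior", noise_sd_um = 0, seed = NULL) {
  s <- conicoid_surface(radius, q_x = q, apex = c(0, 0, apex_z))
  n <- round(half_aperture / spacing)
  xv <- spacing * seq(-n, n)
  X <- matrix(xv, 2 * n + 1, 2 * n + 1, byrow = TRUE)
  Y <- matrix(rev(xv), 2 * n + 1, 2 * n + 1)
  h <- sagitta(s, X, Y, allow_na = TRUE)
  h[X^2 + Y^2 > half_aperture^2] <- NA_real_
  if (noise_sd_um > 0) {
    if (!is.null(seed)) set.seed(seed)
    h <- h + matrix(rnorm(length(h), sd = noise_sd_um / 1000), nrow(h), ncol(h))
  }
  elevation_grid(h, spacing, surface)
}

# random unit vector with positive z (a plausible incoming ray direction)
random_direction <- function() {
  v <- c(rnorm(2), abs(rnorm(1)) + 0.2)
  v / sqrt(sum(v^2))
}

# true angle alpha implied by a tilt rotation
true_alpha <- function(rotation)
  angle_between_axes(as.numeric(rotation$matrix %*% c(0, 0, 1)), c(0, 0, 1))

# piecewise-constant densitometry volume with one value per standard zone
volume_by_zone <- function(zone_values, thickness_um = 550) {
  v <- array(rep(zone_values, times = 4 * 3), dim = c(4, 4, 3))
  densitometry_volume(v, radius_breaks = c(0, 1, 3, 5, 6),
                      depth_breaks = c(0, 0.3, 0.6, 1),
                      thickness_um = thickness_um)
}

# piecewise-constant volume with one value per standard depth layer; the
# depth breaks are placed exactly at the 120-um and (thickness - 60)-um
# boundaries so layer means are exact
volume_by_layer <- function(layer_values, thickness_um = 550) {
  db <- c(0, 120 / thickness_um, (thickness_um - 60) / thickness_um, 1)
  v <- array(rep(layer_values, each = 4 * 4), dim = c(4, 4, 3))
  densitometry_volume(v, radius_breaks = c(0, 1, 3, 5, 6),
                      depth_breaks = db, thickness_um = thickness_um)
}
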
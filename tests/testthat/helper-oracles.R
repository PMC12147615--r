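# Shared fixtures and independent oracles.

# Canonical marker set from first principles (frames = identity).
canonical_fixture <- function() {
  rbind(
    m1 = c(0, 0, 40), m2 = c(0, 0, 0), m3 = c(0, 20, 20),
    m4 = c(0, 0, 35), m5 = c(0, 20, 0), m6 = c(0, 0, 0), m7 = c(0, -20, 0)
  )
}

# Random rotation matrix (uniform axis, uniform angle).
random_rotation <- function() {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(1, -pi, pi)
  k <- matrix(
    c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0),
    3, 3
  )
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

apply_rigid <- function(markers, rotation, translation = c(0, 0, 0)) {
  t(apply(markers, 1, function(p) as.vector(rotation %*% p) + translation))
}

# Independent ICC(2,1) oracle: mean squares from stats::aov, then the
# Shrout-Fleiss absolute-agreement single-measure formula.
icc21_aov_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Independent DTM-plane oracle: least-squares line fit through two points
# in (flexion_extension, deviation) space.
plane_fit_oracle <- function(re, uf) {
  fe <- c(re[1], uf[1])
  dev <- c(re[2], uf[2])
  fit <- stats::lm(dev ~ fe)
  slope <- atan(unname(stats::coef(fit)[2])) * 180 / pi
  offset <- -unname(stats::coef(fit)[1] / stats::coef(fit)[2])
  rng <- sqrt(diff(fe)^2 + diff(dev)^2)
  list(slope = slope, offset = offset, range = rng)
}

# Recover the DTM plane from a simulated trajectory via the full pipeline.
recover_plane <- function(sim, side = "right") {
  ang <- wrist_angle_trajectory(
    sim$markers,
    dorsal_reference = c(0, 0, 1), side = side
  )
  ext <- mark_extreme_positions(ang, sim$events)
  dtm_plane(ext$radial_extension, ext$ulnar_flexion)
}

# Participant x rater matrix of scored values for one side and scheme.
scored_matrix <- function(study, scheme, side = "dominant") {
  meas <- study$measurements
  meas <- meas[meas$side == side, ]
  raters <- sort(unique(meas$rater))
  k <- scheme_k(scheme)
  vapply(raters, function(r) {
    sub <- meas[meas$rater == r & meas$trial <= k, ]
    agg <- aggregate(dtm_range ~ participant, data = sub, FUN = mean)
    agg <- agg[order(agg$participant), ]
    agg$dtm_range
  }, numeric(length(unique(meas$participant))))
}
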
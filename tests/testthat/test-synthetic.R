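test_that("equal seeds give identical output, different seeds differ", {
  cfg <- trajectory_config(marker_noise_sd = 0.5, seed = 9)
  s1 <- simulate_trajectory(cfg)
  s2 <- simulate_trajectory(cfg)
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_trajectory(trajectory_config(marker_noise_sd = 0.5, seed = 10))
  expect_false(identical(s1$markers, s3$markers))

  st1 <- simulate_study(study_config(seed = 9))
  st2 <- simulate_study(study_config(seed = 9))
  expect_identical(st1$measurements, st2$measurements)
  expect_identical(st1$mocap, st2$mocap)
  # byte-identical CSV round trip
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_measurements(st1$measurements, p1)
  write_measurements(st2$measurements, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(simulate_study(study_config(n_participants = 4, seed = 5)))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("noiseless trajectories round-trip the configured plane exactly", {
  sim <- simulate_trajectory(
    trajectory_config(slope = 30, offset = 25, range = 50, marker_noise_sd = 0)
  )
  p <- recover_plane(sim)
  expect_equal(p$slope, 30, tolerance = 1e-6)
  expect_equal(p$offset, 25, tolerance = 1e-6)
  expect_equal(p$range, 50, tolerance = 1e-6)
  # negative-slope and negative-offset paths round-trip too
  sim <- simulate_trajectory(
    trajectory_config(slope = -20, offset = -10, range = 40)
  )
  p <- recover_plane(sim)
  expect_equal(c(p$slope, p$offset, p$range), c(-20, -10, 40),
    tolerance = 1e-6
  )
})

test_that("generated trajectories satisfy the kinematics invariants", {
  sim <- simulate_trajectory(
    trajectory_config(slope = 32.5, offset = 25.8, range = 50.8)
  )
  idx <- round(seq(1, nrow(sim$markers), length.out = 12))
  for (i in idx) {
    m <- matrix(as.numeric(sim$markers[i, -1]), 7, 3, byrow = TRUE)
    f <- build_forearm_frame(m, c(0, 0, 1))
    h <- build_hand_frame(m, c(0, 0, 1))
    expect_lt(max(abs(crossprod(f$axes) - diag(3))), 1e-9)
    expect_lt(max(abs(crossprod(h$axes) - diag(3))), 1e-9)
    expect_equal(det(h$axes), 1, tolerance = 1e-9)
  }
  # forearm markers are static in the laboratory frame
  forearm_cols <- paste0(
    rep(paste0("m", 1:3), each = 3), "_", rep(c("x", "y", "z"), 3)
  )
  expect_true(all(vapply(
    sim$markers[forearm_cols],
    function(col) diff(range(col)) < 1e-12, logical(1)
  )))
})

test_that("marker noise of 0.5 mm keeps recovery inside pilot tolerances", {
  # tolerances are the ~97.5% pilot quantiles over 200 generator seeds
  # (slope 7, offset 5.5, range 6 degrees); require >= 90% joint pass
  ok <- vapply(1:50, function(s) {
    sim <- simulate_trajectory(trajectory_config(
      slope = 30, offset = 25, range = 50, marker_noise_sd = 0.5, seed = s
    ))
    p <- recover_plane(sim)
    abs(p$slope - 30) <= 7 && abs(p$offset - 25) <= 5.5 &&
      abs(p$range - 50) <= 6
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the inclinometer ground truth tracks the configured range", {
  # with a neutral grip the instrument sees (approximately) the angular
  # excursion of the hand along the vertical plane
  sim <- simulate_trajectory(
    trajectory_config(slope = 30, offset = 25, range = 50, grip_rotation = 0)
  )
  expect_equal(sim$inclinometer$dtm_range, 50, tolerance = 1)
  expect_equal(
    sim$inclinometer$dtm_range,
    sim$inclinometer$radial_extension + sim$inclinometer$ulnar_flexion
  )
  # a rotated grip shrinks the swept inclination (geometric bias mechanism)
  tilted <- simulate_trajectory(
    trajectory_config(
      slope = 30, offset = 25, range = 50, grip_rotation = 30
    )
  )
  expect_lt(tilted$inclinometer$dtm_range, sim$inclinometer$dtm_range)
})

test_that("study tables satisfy the measurement-record invariants", {
  study <- simulate_study(study_config(seed = 21))
  meas <- study$measurements
  expect_true(all(meas$trial %in% 1:3))
  expect_true(all(meas$radial_extension %% 5 == 0))
  expect_true(all(meas$ulnar_flexion %% 5 == 0))
  expect_equal(meas$dtm_range, meas$radial_extension + meas$ulnar_flexion)
  expect_true(all(meas$session %in% 1:2))
  # each participant x side has both raters, each rater one session, 3 trials
  counts <- table(meas$participant, meas$side, meas$rater)
  expect_true(all(counts == 3))
  by_rater <- unique(meas[, c("participant", "rater", "session")])
  expect_equal(nrow(by_rater), 42 * 2)
  # the two raters of a participant sit in different sessions
  sessions <- tapply(by_rater$session, by_rater$participant, sort)
  expect_true(all(vapply(
    sessions, function(s) identical(as.integer(s), 1:2), logical(1)
  )))
  expect_equal(nrow(study$mocap), 42 * 2)
  expect_equal(nrow(study$truth), 42 * 2)
})

test_that("a noise-free study yields perfect reliability and agreement", {
  study <- simulate_study(study_config(
    n_participants = 12, sides = "dominant",
    sd_rater = 0, sd_session = 0, sd_trial = 0, sd_split = 0,
    instrument_scale = 1, instrument_offset = 0, sd_mocap_noise = 0,
    quantize = FALSE, seed = 31
  ))
  m <- scored_matrix(study, "first")
  expect_equal(m[, 1], m[, 2])
  expect_equal(icc_2_1(m)$icc, 1)
  first <- study$measurements[
    study$measurements$session == 1 & study$measurements$trial == 1,
  ]
  first <- first[order(first$participant), ]
  gold <- study$mocap[order(study$mocap$participant), ]
  ba <- bland_altman(first$dtm_range, gold$dtm_range)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$bias_type, "none")
})

test_that("population ICC follows the variance-component ratio", {
  expect_equal(population_icc(10, 0, 0), 1)
  expect_equal(population_icc(0, 5, 5), 0)
  expect_equal(population_icc(10, sqrt(5), 5), 0.769230769, tolerance = 1e-9)
  expect_error(population_icc(0, 0, 0), "undefined")
})

test_that("default study conditions are calibrated to realistic magnitudes", {
  cfg <- study_config()
  # closed-form population mean and SD of single-trial instrument readings
  pop_mean <- cfg$instrument_scale * cfg$mean_true_range +
    cfg$instrument_offset
  pop_var <- (cfg$instrument_scale * cfg$sd_between)^2 +
    cfg$sd_rater^2 + cfg$sd_session^2 + cfg$sd_trial^2 +
    2 * 5^2 / 12 # two independently quantized readings
  expect_gt(pop_mean, 76.9 - 5)
  expect_lt(pop_mean, 76.9 + 5)
  expect_gt(sqrt(pop_var), 17.1 - 5)
  expect_lt(sqrt(pop_var), 17.1 + 5)
  # pooled simulated first-trial values agree with the closed form
  pooled <- unlist(lapply(1:25, function(s) {
    st <- simulate_study(study_config(sides = "dominant", seed = 400 + s))
    st$measurements$dtm_range[st$measurements$trial == 1]
  }))
  n <- length(pooled)
  expect_equal(mean(pooled), pop_mean, tolerance = 3 * sqrt(pop_var / n) + 0.5)
  expect_equal(sd(pooled), sqrt(pop_var), tolerance = 0.05 * sqrt(pop_var))
})
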
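test_that("canonical marker configurations give identity body frames", {
  m <- canonical_fixture()
  f <- build_forearm_frame(m)
  h <- build_hand_frame(m)
  expect_equal(f$axes, diag(3), tolerance = 1e-12)
  expect_equal(h$axes, diag(3), tolerance = 1e-12)
  expect_equal(f$origin, c(0, 0, 0))
  # the packaged canonical geometry is the same configuration, shifted
  f2 <- build_forearm_frame(canonical_markers())
  h2 <- build_hand_frame(canonical_markers())
  expect_equal(f2$axes, diag(3), tolerance = 1e-12)
  expect_equal(h2$axes, diag(3), tolerance = 1e-12)
})

test_that("body frames are translation invariant and rotation equivariant", {
  set.seed(41)
  m <- canonical_fixture()
  shifted <- sweep(m, 2, c(-5, 7, -12), `+`)
  expect_equal(build_forearm_frame(shifted)$axes, diag(3), tolerance = 1e-12)
  expect_equal(build_hand_frame(shifted)$axes, diag(3), tolerance = 1e-12)
  for (i in 1:10) {
    r <- random_rotation()
    rotated <- apply_rigid(m, r, rnorm(3, sd = 50))
    ref <- as.vector(r %*% c(1, 0, 0)) # rotated dorsal reference
    expect_equal(build_forearm_frame(rotated, ref)$axes, r, tolerance = 1e-9)
    expect_equal(build_hand_frame(rotated, ref)$axes, r, tolerance = 1e-9)
  }
})

test_that("body frames are orthonormal and right-handed for jittered geometry", {
  set.seed(42)
  for (i in 1:25) {
    m <- canonical_fixture() + matrix(rnorm(21, sd = 3), 7, 3)
    for (frame in list(build_forearm_frame(m), build_hand_frame(m))) {
      expect_lt(max(abs(crossprod(frame$axes) - diag(3))), 1e-9)
      expect_equal(det(frame$axes), 1, tolerance = 1e-9)
    }
  }
})

test_that("degenerate marker geometry is rejected", {
  m <- canonical_fixture()
  m["m3", ] <- c(0, 0, 20) # collinear with m1, m2
  expect_error(build_forearm_frame(m), "collinear")
  m <- canonical_fixture()
  m["m4", ] <- m["m6", ] # zero-length hand z axis
  expect_error(build_hand_frame(m), "degenerate")
  m <- canonical_fixture()
  m["m5", ] <- c(0, 1e-4, 17.5) # m4, m5, m7 nearly collinear
  m["m7", ] <- c(0, -1e-4, 17.5)
  expect_error(build_hand_frame(m), "collinear")
})

test_that("wrist angles decompose constructed rotations", {
  f <- build_forearm_frame(canonical_fixture())
  expect_equal(
    unclass(wrist_angles(f, f))[1:3],
    list(flexion_extension = 0, radial_ulnar = 0, axial_rotation = 0)
  )
  h <- body_frame(c(0, 0, 0), f$axes %*% compose_wrist_rotation(30, 0))
  a <- wrist_angles(f, h)
  expect_equal(a$flexion_extension, 30, tolerance = 1e-9)
  expect_equal(a$radial_ulnar, 0, tolerance = 1e-9)
  h <- body_frame(c(0, 0, 0), f$axes %*% compose_wrist_rotation(20, 10))
  a <- wrist_angles(f, h)
  expect_equal(
    c(a$flexion_extension, a$radial_ulnar, a$axial_rotation),
    c(20, 10, 0),
    tolerance = 1e-9
  )
})

test_that("compose-decompose round trip recovers angles in (-80, 80)", {
  f <- body_frame(c(0, 0, 0), diag(3))
  grid <- expand.grid(
    fe = seq(-75, 75, by = 25), ru = seq(-75, 75, by = 25),
    ax = c(-40, 0, 40)
  )
  for (i in seq_len(nrow(grid))) {
    h <- body_frame(
      c(0, 0, 0),
      compose_wrist_rotation(grid$fe[i], grid$ru[i], grid$ax[i])
    )
    a <- wrist_angles(f, h)
    expect_equal(
      c(a$flexion_extension, a$radial_ulnar, a$axial_rotation),
      c(grid$fe[i], grid$ru[i], grid$ax[i]),
      tolerance = 1e-9
    )
  }
})

test_that("wrist angles are invariant under a common rigid motion", {
  set.seed(43)
  m <- canonical_fixture()
  hand_rot <- compose_wrist_rotation(25, -10, 5)
  m[4:7, ] <- t(hand_rot %*% t(m[4:7, ]))
  base <- wrist_angles(build_forearm_frame(m), build_hand_frame(m))
  for (i in 1:10) {
    r <- random_rotation()
    moved <- apply_rigid(m, r, rnorm(3, sd = 100))
    ref <- as.vector(r %*% c(1, 0, 0))
    got <- wrist_angles(
      build_forearm_frame(moved, ref), build_hand_frame(moved, ref)
    )
    expect_equal(
      unlist(unclass(got)), unlist(unclass(base)),
      tolerance = 1e-9
    )
  }
})

test_that("dtm_plane matches hand-computed and line-fit geometry", {
  p <- dtm_plane(c(40, 15), c(-20, -15))
  expect_equal(p$slope, atan(30 / 60) * 180 / pi, tolerance = 1e-12)
  expect_equal(p$range, sqrt(60^2 + 30^2), tolerance = 1e-12)
  expect_equal(p$offset, 10, tolerance = 1e-12)

  # pure flexion-extension path
  p0 <- dtm_plane(c(30, 0), c(-30, 0))
  expect_equal(c(p0$slope, p0$offset, p0$range), c(0, 0, 60))

  # ulnar-extension to radial-flexion path has negative slope
  expect_lt(dtm_plane(c(40, -15), c(-20, 15))$slope, 0)

  # independent two-point line-fit oracle on random position pairs
  set.seed(44)
  for (i in 1:20) {
    re <- c(runif(1, 10, 60), runif(1, 5, 30))
    uf <- c(runif(1, -60, -10), runif(1, -30, -5))
    p <- dtm_plane(re, uf)
    o <- plane_fit_oracle(re, uf)
    expect_equal(p$slope, o$slope, tolerance = 1e-9)
    expect_equal(p$offset, o$offset, tolerance = 1e-9)
    expect_equal(p$range, o$range, tolerance = 1e-9)
  }
})

test_that("dtm_plane flags degenerate paths", {
  expect_error(dtm_plane(c(10, 5), c(10, 5)), "coincide")
  # parallel to flexion-extension axis at nonzero deviation: no zero crossing
  expect_warning(p <- dtm_plane(c(30, 10), c(-30, 10)), "offset undefined")
  expect_true(is.na(p$offset))
  # vertical path (pure deviation) has slope 90
  expect_equal(dtm_plane(c(10, 20), c(10, -20))$slope, 90)
})

test_that("extreme positions use the nearest sample, ties to the earlier one", {
  ang <- tibble::tibble(
    time = seq(0, 1, by = 0.1),
    flexion_extension = seq(0, 50, by = 5),
    radial_ulnar = seq(0, -20, by = -2),
    axial_rotation = 0
  )
  ev <- c(radial_extension = 0.3, ulnar_flexion = 0.9)
  ext <- mark_extreme_positions(ang, ev)
  expect_equal(ext$radial_extension$flexion_extension, 15)
  expect_equal(ext$ulnar_flexion$flexion_extension, 45)
  # between samples: nearest wins
  ext <- mark_extreme_positions(
    ang, c(radial_extension = 0.32, ulnar_flexion = 0.88)
  )
  expect_equal(ext$radial_extension$flexion_extension, 15)
  expect_equal(ext$ulnar_flexion$flexion_extension, 45)
  # exact midpoint: earlier sample
  ext <- mark_extreme_positions(
    ang, c(radial_extension = 0.25, ulnar_flexion = 0.85)
  )
  expect_equal(ext$radial_extension$flexion_extension, 10)
  expect_equal(ext$ulnar_flexion$flexion_extension, 40)
  expect_error(
    mark_extreme_positions(
      ang, c(radial_extension = 1.4, ulnar_flexion = 0.9)
    ),
    "outside the recording"
  )
})

test_that("left-side recordings are mirrored to side-consistent signs", {
  sim <- simulate_trajectory(
    trajectory_config(slope = 30, offset = 25, range = 50)
  )
  mirrored <- sim$markers
  y_cols <- grepl("_y$", names(mirrored))
  mirrored[, y_cols] <- -mirrored[, y_cols]
  p_right <- recover_plane(sim)
  p_left <- recover_plane(list(markers = mirrored, events = sim$events),
    side = "left"
  )
  expect_equal(p_left$slope, p_right$slope, tolerance = 1e-9)
  expect_equal(p_left$offset, p_right$offset, tolerance = 1e-9)
  expect_equal(p_left$range, p_right$range, tolerance = 1e-9)
})
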
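# Synthetic-data generators: marker trajectories for the kinematics stage
# and full two-rater measurement studies for the reliability/agreement
# stages, both seeded and with known ground truth.

#' Trajectory-generator configuration
#'
#' Ground-truth geometry and sampling for one simulated hammering recording.
#' Defaults are the typical dominant-side motion-capture magnitudes of the
#' instrument-validation study design this package targets: an oblique plane
#' about 30 degrees off the sagittal flexion-extension plane, offset about
#' 26 degrees into extension, with a 50 degree range, three reciprocating
#' strokes of about one second each.
#'
#' @param slope DTM-plane slope (degrees, see [dtm_plane()]).
#' @param offset DTM-plane offset (degrees, extension positive).
#' @param range DTM range (degrees, > 0).
#' @param n_cycles Number of reciprocating hammering cycles.
#' @param cycle_period Duration of one up-down cycle (seconds).
#' @param rate_hz Sampling rate (Hz).
#' @param marker_noise_sd Isotropic Gaussian marker noise, per coordinate
#'   (mm).
#' @param grip_rotation Orientation offset (degrees) of the mallet long axis
#'   from its nominal direction in the hand frame, about the hand dorsal
#'   axis; models the grip-dependent mismatch between the instrument axis
#'   and the third-metacarpal axis.
#' @param seed Integer seed fixing all randomness; `NULL` uses the current
#'   RNG state.
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(slope = 32.5, offset = 25.8, range = 50.8,
                              n_cycles = 3, cycle_period = 1.0, rate_hz = 100,
                              marker_noise_sd = 0, grip_rotation = 0,
                              seed = NULL) {
  stopifnot(
    is.finite(slope), abs(slope) < 90,
    is.finite(offset),
    is.finite(range), range > 0,
    n_cycles >= 1, cycle_period > 0, rate_hz > 0,
    marker_noise_sd >= 0, is.finite(grip_rotation)
  )
  structure(
    list(
      slope = slope, offset = offset, range = range,
      n_cycles = as.integer(n_cycles), cycle_period = cycle_period,
      rate_hz = rate_hz, marker_noise_sd = marker_noise_sd,
      grip_rotation = grip_rotation, seed = seed
    ),
    class = "trajectory_config"
  )
}

# Laboratory frame: z vertically up, x the horizontal striking direction.
# The participant's forearm lies on the table with the dorsum up, so the
# forearm dorsal axis maps to lab +z, the proximal axis to lab +x and the
# radial axis to lab -y; the forearm is then pronated/supinated about its
# long axis by the plane slope so that the performed oblique DTM plane is
# vertical (the instructed "hammering in the vertical direction").
forearm_lab_orientation <- function(slope_deg) {
  g <- cbind(c(0, 0, 1), c(0, -1, 0), c(1, 0, 0)) # images of x_F, y_F, z_F
  g %*% rot_z(deg2rad(slope_deg))
}

#' Simulate a marker trajectory of the hammering action
#'
#' Generates a seven-marker recording whose wrist-angle path oscillates
#' sinusoidally along the straight line defined by the configured DTM-plane
#' slope and offset, with total angular excursion `range`. Forearm markers
#' are fixed in the laboratory frame; hand markers ride on the rotating hand
#' rigid body (plate triangle base 40 mm, height 20 mm; metacarpal
#' landmarks). Event marks are placed at the extreme of the third downward
#' stroke (ulnar flexion) and the extreme of the following upward stroke
#' (radial extension), as in the measurement protocol. Isotropic Gaussian
#' noise of `marker_noise_sd` mm is added per marker coordinate per frame.
#'
#' @param config A [trajectory_config()].
#' @return List of class `simulated_trajectory` with elements
#'   * `markers` — tibble `time`, `m1_x` ... `m7_z` (mm);
#'   * `events` — tibble `event`, `time` for the two marked still instants;
#'   * `truth` — the generating [dtm_plane()] (slope, offset, range);
#'   * `inclinometer` — list with the noise-free instrument readings at the
#'     two events (`radial_extension`, `ulnar_flexion`, positive above the
#'     horizontal for radial extension / below for ulnar flexion) and their
#'     sum `dtm_range`;
#'   * `config`.
#' @examples
#' sim <- simulate_trajectory(trajectory_config(slope = 30, offset = 25,
#'   range = 50, seed = 1))
#' ang <- wrist_angle_trajectory(sim$markers, dorsal_reference = c(0, 0, 1))
#' ext <- mark_extreme_positions(ang, sim$events)
#' dtm_plane(ext$radial_extension, ext$ulnar_flexion)
#' @export
simulate_trajectory <- function(config = trajectory_config()) {
  stopifnot(inherits(config, "trajectory_config"))
  with_seed(config$seed, {
    time <- seq(0, config$n_cycles * config$cycle_period,
      by = 1 / config$rate_hz
    )
    # path position along the DTM line, starting at radial extension
    s <- (config$range / 2) * cos(2 * pi * time / config$cycle_period)
    sl <- deg2rad(config$slope)
    fe <- config$offset + s * cos(sl)
    dev <- s * sin(sl)

    g_lab <- forearm_lab_orientation(config$slope)
    base <- canonical_markers()
    forearm_rows <- 1:3
    hand_rows <- 4:7

    pos <- matrix(NA_real_, nrow = length(time), ncol = 21)
    lab_forearm <- t(g_lab %*% t(base[forearm_rows, , drop = FALSE]))
    for (i in seq_along(time)) {
      r <- compose_wrist_rotation(fe[i], dev[i])
      lab_hand <- t(g_lab %*% r %*% t(base[hand_rows, , drop = FALSE]))
      pos[i, ] <- as.vector(t(rbind(lab_forearm, lab_hand)))
    }
    if (config$marker_noise_sd > 0) {
      pos <- pos + rnorm(length(pos), sd = config$marker_noise_sd)
    }
    cols <- paste0(
      rep(paste0("m", 1:7), each = 3), "_", rep(c("x", "y", "z"), 7)
    )
    markers <- tibble::as_tibble(as.data.frame(pos))
    names(markers) <- cols
    markers <- tibble::add_column(markers, time = time, .before = 1)

    t_uf <- (config$n_cycles - 0.5) * config$cycle_period
    t_re <- config$n_cycles * config$cycle_period
    events <- tibble::tibble(
      event = c("ulnar_flexion", "radial_extension"),
      time = c(t_uf, t_re)
    )

    # noise-free instrument readings of the mallet axis at the two extremes
    mallet_axis_hand <- rot_x(deg2rad(config$grip_rotation)) %*% c(0, 0, 1)
    read_at <- function(s_val) {
      r <- compose_wrist_rotation(
        config$offset + s_val * cos(sl), s_val * sin(sl)
      )
      inclinometer_reading(g_lab %*% r %*% mallet_axis_hand)
    }
    incl_re <- read_at(config$range / 2)
    incl_uf <- read_at(-config$range / 2)
    inclinometer <- list(
      radial_extension = incl_re,
      ulnar_flexion = -incl_uf, # positive below the horizontal
      dtm_range = incl_re - incl_uf
    )

    structure(
      list(
        markers = markers,
        events = events,
        truth = structure(
          list(
            slope = config$slope, offset = config$offset,
            range = config$range
          ),
          class = "dtm_plane"
        ),
        inclinometer = inclinometer,
        config = config
      ),
      class = "simulated_trajectory"
    )
  })
}

#' Measurement-study generator configuration
#'
#' Defines the conditions of a simulated two-rater, two-session, three-trial
#' DTM-range study with a motion-capture gold standard in session 1. The
#' defaults emulate the validation-study design this package targets:
#' 42 participants, a true (motion-capture scale) range of about
#' 51 +/- 10 degrees, an instrument that over-reads by a pure scale factor
#' of 1.4375 (a mean percent ratio of about 36%), day-scale session
#' variability dominating rater differences, trial-to-trial noise of about
#' 7 degrees, and 5 degree reading quantization. See the methods vignette
#' for the calibration rationale.
#'
#' @param n_participants Number of participants.
#' @param sides Character vector of sides measured.
#' @param raters Two rater identifiers.
#' @param n_trials Trials per rater and session (3 in the protocol).
#' @param mean_true_range,sd_between Mean and between-participant SD of the
#'   true DTM range (degrees).
#' @param sd_rater SD of the additive rater effect (degrees).
#' @param sd_session SD of the additive participant-by-session effect
#'   (degrees).
#' @param sd_trial SD of trial-to-trial noise (degrees).
#' @param instrument_scale Proportional instrument bias (multiplies the true
#'   range).
#' @param instrument_offset Fixed instrument bias (degrees).
#' @param sd_mocap_noise SD of the motion-capture gold-standard error
#'   (degrees).
#' @param quantize Apply 5 degree reading quantization?
#' @param re_fraction Fraction of a trial's range read as radial extension
#'   (the rest is ulnar flexion).
#' @param sd_split SD of the noise on that radial/ulnar split (degrees).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 42,
                         sides = c("dominant", "nondominant"),
                         raters = c("A", "B"),
                         n_trials = 3,
                         mean_true_range = 50.8,
                         sd_between = 9.74,
                         sd_rater = 2.0,
                         sd_session = 6.3,
                         sd_trial = 6.8,
                         instrument_scale = 1.4375,
                         instrument_offset = 0,
                         sd_mocap_noise = 2.0,
                         quantize = TRUE,
                         re_fraction = 0.55,
                         sd_split = 3.0,
                         seed = NULL) {
  stopifnot(
    n_participants >= 1, length(raters) == 2L, n_trials >= 1,
    is.finite(mean_true_range),
    sd_between >= 0, sd_rater >= 0, sd_session >= 0, sd_trial >= 0,
    instrument_scale > 0, is.finite(instrument_offset),
    sd_mocap_noise >= 0, re_fraction > 0, re_fraction < 1, sd_split >= 0
  )
  structure(
    list(
      n_participants = as.integer(n_participants), sides = sides,
      raters = raters, n_trials = as.integer(n_trials),
      mean_true_range = mean_true_range, sd_between = sd_between,
      sd_rater = sd_rater, sd_session = sd_session, sd_trial = sd_trial,
      instrument_scale = instrument_scale,
      instrument_offset = instrument_offset,
      sd_mocap_noise = sd_mocap_noise, quantize = quantize,
      re_fraction = re_fraction, sd_split = sd_split, seed = seed
    ),
    class = "study_config"
  )
}

#' Simulate a complete two-rater measurement study
#'
#' Per participant and side, a true DTM range is drawn from
#' `Normal(mean_true_range, sd_between^2)`. The motion-capture gold standard
#' (recorded in session 1) adds `Normal(0, sd_mocap_noise^2)` error. Each
#' instrument trial reads
#' `instrument_scale * truth + instrument_offset + rater effect +
#' participant-session effect + trial noise`, split into radial-extension
#' and ulnar-flexion components (fraction `re_fraction` plus split noise)
#' and quantized to the 5 degree instrument scale when `quantize` is on.
#' The rater measuring in session 1 is randomized per participant.
#'
#' @param config A [study_config()].
#' @return List of class `simulated_study` with
#'   * `measurements` — tibble `participant`, `side`, `rater`, `session`,
#'     `trial`, `radial_extension`, `ulnar_flexion`, `dtm_range` (derived);
#'   * `mocap` — tibble `participant`, `side`, `dtm_range` (gold standard);
#'   * `truth` — tibble `participant`, `side`, `true_range`;
#'   * `config`.
#' @examples
#' study <- simulate_study(study_config(seed = 7))
#' head(study$measurements)
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    ids <- sprintf("P%03d", seq_len(n))
    raters <- config$raters

    rater_effect <- stats::setNames(rnorm(2, 0, config$sd_rater), raters)
    # rater measuring in session 1, randomized per participant
    first_rater <- stats::setNames(sample(raters, n, replace = TRUE), ids)

    ps <- expand.grid(
      participant = ids, side = config$sides,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    ps$true_range <- rnorm(nrow(ps), config$mean_true_range, config$sd_between)
    ps$gold <- ps$true_range + rnorm(nrow(ps), 0, config$sd_mocap_noise)
    sess <- expand.grid(
      participant = ids, side = config$sides, session = 1:2,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    sess$u <- rnorm(nrow(sess), 0, config$sd_session)

    grid <- expand.grid(
      trial = seq_len(config$n_trials), rater = raters,
      side = config$sides, participant = ids,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$session <- ifelse(
      grid$rater == first_rater[grid$participant], 1L, 2L
    )
    key_ps <- function(df) paste(df$participant, df$side)
    key_sess <- function(df) paste(df$participant, df$side, df$session)
    truth_of <- ps$true_range[match(key_ps(grid), key_ps(ps))]
    u_of <- sess$u[match(key_sess(grid), key_sess(sess))]

    value <- config$instrument_scale * truth_of + config$instrument_offset +
      rater_effect[grid$rater] + u_of +
      rnorm(nrow(grid), 0, config$sd_trial)
    split_noise <- rnorm(nrow(grid), 0, config$sd_split)
    re <- config$re_fraction * value + split_noise
    uf <- (1 - config$re_fraction) * value - split_noise
    if (config$quantize) {
      re <- quantize_reading(re)
      uf <- quantize_reading(uf)
    }

    measurements <- tibble::tibble(
      participant = grid$participant, side = grid$side,
      rater = grid$rater, session = grid$session, trial = grid$trial,
      radial_extension = re, ulnar_flexion = uf,
      dtm_range = suppressWarnings(dtm_range_from_readings(re, uf))
    )
    measurements <- dplyr::arrange(
      measurements, .data$participant, .data$side, .data$rater, .data$trial
    )
    structure(
      list(
        measurements = measurements,
        mocap = tibble::tibble(
          participant = ps$participant, side = ps$side, dtm_range = ps$gold
        ),
        truth = tibble::tibble(
          participant = ps$participant, side = ps$side,
          true_range = ps$true_range
        ),
        config = config
      ),
      class = "simulated_study"
    )
  })
}

#' Population ICC implied by additive variance components
#'
#' For the additive model `value = subject + rater + error`, the
#' single-measure absolute-agreement population ICC is
#' `sd_between^2 / (sd_between^2 + sd_rater^2 + sd_residual^2)`. Used as
#' the closed-form oracle in parameter-recovery checks.
#'
#' @param sd_between Between-subject SD.
#' @param sd_rater Rater-effect SD.
#' @param sd_residual Residual SD (session + trial noise as seen by one
#'   score).
#' @return Population ICC in \[0, 1\].
#' @examples
#' population_icc(10, sqrt(5), 5) # 0.7692
#' @export
population_icc <- function(sd_between, sd_rater, sd_residual) {
  stopifnot(sd_between >= 0, sd_rater >= 0, sd_residual >= 0)
  total <- sd_between^2 + sd_rater^2 + sd_residual^2
  if (total == 0) {
    stop("all variance components are zero; population ICC undefined",
      call. = FALSE
    )
  }
  sd_between^2 / total
}
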
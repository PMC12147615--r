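# Inclinometer-based DTM-range scoring: sign convention, 5-degree
# quantization, trial aggregation.

#' DTM range from the two inclinometer readings
#'
#' The DTM range is the sum of the radial-extension and ulnar-flexion
#' inclination angles. Readings are positive when the motion proceeds beyond
#' the horizontal plane and negative otherwise, so either reading (and in
#' principle the range) may be negative.
#'
#' @param radial_extension,ulnar_flexion Inclinometer readings in degrees
#'   (vectorised).
#' @return DTM range in degrees. Emits a warning for negative ranges.
#' @examples
#' dtm_range_from_readings(40, 35) # 75
#' dtm_range_from_readings(50, -5) # 45
#' @export
dtm_range_from_readings <- function(radial_extension, ulnar_flexion) {
  if (!all(is.finite(radial_extension)) || !all(is.finite(ulnar_flexion))) {
    stop("inclinometer readings must be finite", call. = FALSE)
  }
  rng <- radial_extension + ulnar_flexion
  if (any(rng < 0)) {
    warning("negative DTM range(s): both readings below the horizontal",
      call. = FALSE
    )
  }
  rng
}

#' Quantize a reading to the instrument's 5-degree gradations
#'
#' Rounds to the nearest multiple of `unit` (default 5 degrees, the minimum
#' measurement unit of the bubble inclinometer); readings exactly between
#' two gradations round away from zero.
#'
#' @param angle Angle(s) in degrees.
#' @param unit Gradation size in degrees.
#' @return `angle` rounded to the instrument scale.
#' @examples
#' quantize_reading(72.6) # 75
#' quantize_reading(72.5) # 75 (tie away from zero)
#' quantize_reading(-3) # -5
#' @export
quantize_reading <- function(angle, unit = 5) {
  if (!all(is.finite(angle))) {
    stop("cannot quantize non-finite reading(s)", call. = FALSE)
  }
  stopifnot(is.numeric(unit), length(unit) == 1L, unit > 0)
  sign(angle) * unit * floor(abs(angle) / unit + 0.5)
}

#' Trial-aggregation schemes
#'
#' The measurement protocol takes three trials; reliability is evaluated for
#' the first trial alone (`"first"`, k = 1), the mean of the first two
#' (`"first-second"`, k = 2) and the mean of all three (`"first-third"`,
#' k = 3). Aggregation always uses acquisition order, never a best-of rule.
#'
#' @param scheme Scheme label (one of `"first"`, `"first-second"`,
#'   `"first-third"`) or the integer k itself.
#' @return Integer k in 1..3.
#' @export
scheme_k <- function(scheme) {
  if (is.numeric(scheme)) {
    k <- as.integer(scheme)
  } else {
    k <- c("first" = 1L, "first-second" = 2L, "first-third" = 3L)[[
      match.arg(as.character(scheme), c("first", "first-second", "first-third"))
    ]]
  }
  if (!k %in% 1:3) stop("aggregation scheme must use k in 1..3", call. = FALSE)
  k
}

#' Aggregate the initial trials of one measurement series
#'
#' @param values DTM-range values (degrees) for one participant, side, rater
#'   and session.
#' @param scheme Aggregation scheme (see [scheme_k()]).
#' @param trials Trial indices of `values` in acquisition order; defaults to
#'   `seq_along(values)`.
#' @return Mean of trials `1..k` (degrees).
#' @examples
#' aggregate_trials(c(75, 80, 85), "first") # 75
#' aggregate_trials(c(75, 80, 85), "first-second") # 77.5
#' aggregate_trials(c(75, 80, 85), 3) # 80
#' @export
aggregate_trials <- function(values, scheme, trials = seq_along(values)) {
  k <- scheme_k(scheme)
  stopifnot(length(values) == length(trials))
  idx <- match(seq_len(k), trials)
  if (anyNA(idx)) {
    missing_trials <- setdiff(seq_len(k), trials)
    stop("missing trial(s): ", paste(missing_trials, collapse = ", "),
      call. = FALSE
    )
  }
  mean(values[idx])
}

#' Inclinometer reading of a mallet-axis direction
#'
#' The bubble inclinometer reports the angle between the long axis of the
#' mallet shaft and the horizontal plane: the arcsine of the vertical
#' component of the unit axis, positive above the horizontal. The
#' laboratory frame has z vertically up.
#'
#' @param mallet_axis Unit 3-vector of the shaft direction in the laboratory
#'   frame.
#' @return Inclination in degrees in \[-90, 90\].
#' @examples
#' inclinometer_reading(c(1, 0, 0)) # 0
#' inclinometer_reading(c(0, 0, 1)) # 90
#' @export
inclinometer_reading <- function(mallet_axis) {
  mallet_axis <- as.numeric(mallet_axis)
  stopifnot(length(mallet_axis) == 3L, all(is.finite(mallet_axis)))
  if (abs(vec_norm(mallet_axis) - 1) > 1e-6) {
    stop("mallet axis must be a unit vector", call. = FALSE)
  }
  rad2deg(asin(min(1, max(-1, mallet_axis[3]))))
}
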
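# Plain-CSV interfaces for marker trajectories, event marks and
# measurement-study tables.

MARKER_COLS <- paste0(
  rep(paste0("m", 1:7), each = 3), "_", rep(c("x", "y", "z"), 7)
)

#' Read / write a marker-trajectory CSV
#'
#' Format: header `time,m1_x,m1_y,m1_z,...,m7_x,m7_y,m7_z`; one row per
#' sample; positions in mm, time in seconds; optional leading comment line
#' `# rate_hz=<value>`.
#'
#' @param path File path.
#' @return `read_marker_trajectory()`: a tibble with attribute `rate_hz`
#'   when the comment line is present.
#' @export
read_marker_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  rate_hz <- NULL
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("rate_hz\\s*=\\s*([0-9.]+)", header))[[1]]
    if (length(m) == 2L) rate_hz <- as.numeric(m[2])
  }
  df <- read.csv(path, comment.char = "#")
  need <- c("time", MARKER_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(
      "marker trajectory ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(df[, need])
  if (!is.null(rate_hz)) attr(out, "rate_hz") <- rate_hz
  out
}

#' @rdname read_marker_trajectory
#' @param trajectory Tibble with columns `time`, `m1_x` ... `m7_z`.
#' @param rate_hz Optional sampling rate recorded as a comment line.
#' @export
write_marker_trajectory <- function(trajectory, path, rate_hz = NULL) {
  need <- c("time", MARKER_COLS)
  missing_cols <- setdiff(need, names(trajectory))
  if (length(missing_cols) > 0) {
    stop("trajectory lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(rate_hz)) writeLines(sprintf("# rate_hz=%g", rate_hz), con)
  write.csv(as.data.frame(trajectory[, need]), con, row.names = FALSE)
  invisible(path)
}

#' Read / write an event-mark CSV
#'
#' Two rows, header `event,time`: the `radial_extension` and `ulnar_flexion`
#' still instants (seconds).
#'
#' @param path File path.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path)
  if (!all(c("event", "time") %in% names(df))) {
    stop("events file ", path, " must have columns `event` and `time`",
      call. = FALSE
    )
  }
  need <- c("radial_extension", "ulnar_flexion")
  if (!all(need %in% df$event)) {
    stop(
      "events file ", path,
      " must contain rows `radial_extension` and `ulnar_flexion`",
      call. = FALSE
    )
  }
  tibble::as_tibble(df[, c("event", "time")])
}

#' @rdname read_events
#' @param events Tibble with columns `event`, `time`.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events[, c("event", "time")]), path,
    row.names = FALSE
  )
  invisible(path)
}

MEASUREMENT_COLS <- c(
  "participant", "side", "rater", "session", "trial",
  "radial_extension", "ulnar_flexion"
)

#' Read / write a measurement-study CSV
#'
#' Format: header
#' `participant,side,rater,session,trial,radial_extension,ulnar_flexion`.
#' The DTM range is derived on read (`dtm_range` column) and is never
#' stored in the file.
#'
#' @param path File path.
#' @return A tibble with the seven schema columns plus derived `dtm_range`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop(
      "measurement file ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(df[, MEASUREMENT_COLS])
  if (!all(out$trial %in% 1:3)) {
    stop("measurement file ", path, ": column `trial` must be in 1..3",
      call. = FALSE
    )
  }
  out$dtm_range <- dtm_range_from_readings(
    out$radial_extension, out$ulnar_flexion
  )
  out
}

#' @rdname read_measurements
#' @param measurements Tibble with the measurement schema columns (a
#'   `dtm_range` column, if present, is dropped).
#' @export
write_measurements <- function(measurements, path) {
  missing_cols <- setdiff(MEASUREMENT_COLS, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurements lack column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  write.csv(as.data.frame(measurements[, MEASUREMENT_COLS]), path,
    row.names = FALSE
  )
  invisible(path)
}

#' Reference published agreement summaries
#'
#' Bundled summary rows (per aggregation scheme and side) from a published
#' validation study of the mallet-inclinometer DTM-range technique against
#' motion capture: mean difference with 95% CI, the difference-vs-mean
#' correlation, the percent proportional bias and the percent 95% limits of
#' agreement, printed to one decimal. Shipped for internal-consistency
#' checks of the Bland-Altman arithmetic (CI and LOA intervals must be
#' symmetric about their central value).
#'
#' @return A tibble with columns `scheme`, `side`, `mean_difference`,
#'   `ci_low`, `ci_high`, `gamma`, `p_gamma`, `bias_pct`, `loa_low_pct`,
#'   `loa_high_pct`.
#' @export
reference_agreement_summaries <- function() {
  path <- system.file("extdata", "reference_agreement_summaries.csv",
    package = "dtmkit", mustWork = TRUE
  )
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}
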
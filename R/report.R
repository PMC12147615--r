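# Study tables (descriptives, reliability, agreement) and the end-to-end
# pipeline driver.

#' Descriptive summary of per-participant values
#'
#' @param values Numeric vector, n >= 2.
#' @return Named list `mean`, `sd` (sample, n-1), `min`, `max`, `n`.
#' @examples
#' descriptives(c(70, 75, 80, 85, 90)) # mean 80, sd 7.906
#' @export
descriptives <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  list(
    mean = mean(values), sd = sd(values),
    min = min(values), max = max(values), n = length(values)
  )
}

SCHEMES <- c("first", "first-second", "first-third")

# Scored values per participant x side x rater (x session) for one scheme.
score_measurements <- function(measurements, scheme) {
  k <- scheme_k(scheme)
  groups <- dplyr::group_by(
    measurements, .data$participant, .data$side, .data$rater, .data$session
  )
  dplyr::summarise(
    groups,
    score = aggregate_trials(.data$dtm_range, k, .data$trial),
    .groups = "drop"
  )
}

check_study_schema <- function(study) {
  if (is.character(study)) {
    dir <- study
    meas_path <- file.path(dir, "measurements.csv")
    mocap_path <- file.path(dir, "mocap.csv")
    if (!file.exists(meas_path)) {
      stop("schema error: missing file ", meas_path, call. = FALSE)
    }
    measurements <- read_measurements(meas_path)
    if (!file.exists(mocap_path)) {
      stop("schema error: missing file ", mocap_path, call. = FALSE)
    }
    mocap <- tibble::as_tibble(read.csv(mocap_path))
  } else {
    measurements <- study$measurements
    mocap <- study$mocap
    if (is.null(measurements) || is.null(mocap)) {
      stop("schema error: study must provide `measurements` and `mocap`",
        call. = FALSE
      )
    }
    if (!"dtm_range" %in% names(measurements)) {
      measurements$dtm_range <- dtm_range_from_readings(
        measurements$radial_extension, measurements$ulnar_flexion
      )
    }
  }
  miss <- setdiff(MEASUREMENT_COLS, names(measurements))
  if (length(miss) > 0) {
    stop("schema error in measurements: missing column(s) ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  miss <- setdiff(c("participant", "side", "dtm_range"), names(mocap))
  if (length(miss) > 0) {
    stop("schema error in mocap table: missing column(s) ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  list(measurements = measurements, mocap = mocap)
}

#' Run the full reliability and agreement pipeline
#'
#' For every aggregation scheme (first trial, mean of first two, mean of
#' three) and side, computes
#'
#' 1. **descriptives** — mean, SD, min, max of the scored instrument values
#'    by rater, of the first-session (first-test) scores, and of the
#'    motion-capture gold standard;
#' 2. **reliability** — inter-rater [icc_2_1()] on the participant x rater
#'    matrix of scored values;
#' 3. **agreement** — [bland_altman()] of the first-session scores against
#'    the motion-capture gold standard (captured in session 1 only).
#'
#' @param study A `simulated_study` (see [simulate_study()]), a list with
#'   `measurements` and `mocap` tibbles, or a directory containing
#'   `measurements.csv` and `mocap.csv`.
#' @param alpha Significance level for CIs and the proportional-bias test.
#' @param out_dir Optional output directory; when given, writes
#'   `table1_descriptives.csv`, `table2_reliability.csv`,
#'   `table3_agreement.csv` (display rounding: 1 decimal for degrees and
#'   percent, 2 for ICC and gamma) and `summary.json` (full precision).
#' @param verbose Log stage progress with `message()`.
#' @return Object of class `study_tables`: list of tibbles `descriptives`,
#'   `reliability`, `agreement`.
#' @examples
#' tables <- run_pipeline(simulate_study(study_config(seed = 7)))
#' tables$reliability
#' @export
run_pipeline <- function(study, alpha = 0.05, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[dtmkit] ", ...)
  dat <- check_study_schema(study)
  measurements <- dat$measurements
  mocap <- dat$mocap
  sides <- unique(measurements$side)
  raters <- sort(unique(measurements$rater))
  if (length(raters) != 2L) {
    stop("pipeline expects exactly 2 raters, got ", length(raters),
      call. = FALSE
    )
  }

  desc_rows <- list()
  rel_rows <- list()
  agr_rows <- list()
  for (scheme in SCHEMES) {
    say("scoring scheme `", scheme, "`")
    scored <- score_measurements(measurements, scheme)
    for (side in sides) {
      s_side <- scored[scored$side == side, ]

      # -- descriptives: per rater, first test, and mocap gold ------------
      sources <- c(
        stats::setNames(
          lapply(raters, function(r) s_side$score[s_side$rater == r]),
          paste0("rater_", raters)
        ),
        list(
          first_test = s_side$score[s_side$session == 1],
          mocap = mocap$dtm_range[mocap$side == side]
        )
      )
      for (src in names(sources)) {
        d <- descriptives(sources[[src]])
        desc_rows[[length(desc_rows) + 1L]] <- tibble::tibble(
          scheme = scheme, side = side, source = src,
          mean = d$mean, sd = d$sd, min = d$min, max = d$max, n = d$n
        )
      }

      # -- reliability: participants x raters matrix ----------------------
      wide <- stats::reshape(
        as.data.frame(s_side[, c("participant", "rater", "score")]),
        idvar = "participant", timevar = "rater", direction = "wide"
      )
      mat <- as.matrix(wide[, paste0("score.", raters)])
      if (anyNA(mat)) {
        stop("computation error: incomplete participant x rater cells for ",
          side, " / ", scheme,
          call. = FALSE
        )
      }
      fit <- icc_2_1(mat, alpha = alpha)
      rel_rows[[length(rel_rows) + 1L]] <- tibble::tibble(
        scheme = scheme, side = side,
        icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
        label = fit$label, n_subjects = fit$n_subjects,
        n_raters = fit$n_raters
      )

      # -- agreement: first-session scores vs mocap gold ------------------
      first <- s_side[s_side$session == 1, c("participant", "score")]
      gold <- mocap[mocap$side == side, c("participant", "dtm_range")]
      pairs <- dplyr::inner_join(first, gold, by = "participant")
      ba <- bland_altman(pairs$score, pairs$dtm_range, alpha = alpha)
      agr_rows[[length(agr_rows) + 1L]] <- tibble::tibble(
        scheme = scheme, side = side, n = ba$n,
        mean_difference = ba$mean_difference,
        ci_low = ba$ci_low, ci_high = ba$ci_high,
        gamma = ba$gamma, p_gamma = ba$p_gamma,
        bias_type = ba$bias_type, bias = ba$bias,
        sd_difference = ba$sd_difference,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        loa_units = ba$loa_units
      )
    }
  }

  tables <- structure(
    list(
      descriptives = dplyr::bind_rows(desc_rows),
      reliability = dplyr::bind_rows(rel_rows),
      agreement = dplyr::bind_rows(agr_rows)
    ),
    class = "study_tables"
  )

  if (!is.null(out_dir)) {
    say("writing tables to ", out_dir)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    round_cols <- function(df, cols, digits) {
      df[cols] <- lapply(df[cols], round, digits = digits)
      df
    }
    write.csv(
      round_cols(
        as.data.frame(tables$descriptives),
        c("mean", "sd", "min", "max"), 1
      ),
      file.path(out_dir, "table1_descriptives.csv"),
      row.names = FALSE
    )
    write.csv(
      round_cols(
        as.data.frame(tables$reliability),
        c("icc", "ci_low", "ci_high"), 2
      ),
      file.path(out_dir, "table2_reliability.csv"),
      row.names = FALSE
    )
    agr_out <- as.data.frame(tables$agreement)
    agr_out <- round_cols(
      agr_out,
      c("mean_difference", "ci_low", "ci_high", "bias", "sd_difference",
        "loa_low", "loa_high"),
      1
    )
    agr_out$gamma <- round(agr_out$gamma, 2)
    write.csv(agr_out, file.path(out_dir, "table3_agreement.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(
      lapply(unclass(tables), function(df) as.data.frame(df)),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  tables
}

#' @export
print.study_tables <- function(x, ...) {
  cat("DTM study tables\n\n-- Descriptives --\n")
  print(x$descriptives, n = Inf)
  cat("\n-- Reliability (ICC 2,1) --\n")
  print(x$reliability, n = Inf)
  cat("\n-- Agreement (Bland-Altman vs motion capture) --\n")
  print(x$agreement, n = Inf)
  invisible(x)
}
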
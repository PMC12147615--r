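# Marker-based wrist kinematics: body frames, wrist angles, DTM-plane
# geometry.
#
# Marker convention (seven reflective markers on the dorsum):
#   m1, m2, m3 — forearm cluster plate (isosceles triangle, base m1-m2 along
#                the forearm median line, m1 proximal);
#   m4         — mid-shaft of the third metacarpal;
#   m5, m6, m7 — heads of the second, third and fourth metacarpals.
# Positions are millimetres in the laboratory frame.

# Minimum triangle altitude (mm) below which a marker triple is treated as
# collinear, and minimum axis length (mm) for the z axis.
.DEGENERACY_MM <- 1

#' Construct a rigid-body frame
#'
#' A body frame is an origin plus a right-handed orthonormal 3x3 rotation
#' whose columns are the x, y and z unit axes expressed in the laboratory
#' frame.
#'
#' @param origin Numeric length-3 origin (mm).
#' @param axes 3x3 matrix with columns x, y, z.
#' @return An object of class `body_frame`.
#' @export
body_frame <- function(origin, axes) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (!all(is.finite(origin)) || !all(is.finite(axes))) {
    stop("body frame must be finite", call. = FALSE)
  }
  gram <- crossprod(axes)
  if (max(abs(gram - diag(3))) > 1e-9) {
    stop("body frame axes are not orthonormal (tolerance 1e-9)", call. = FALSE)
  }
  if (det(axes) < 0) {
    stop("body frame axes are left-handed", call. = FALSE)
  }
  structure(list(origin = origin, axes = axes), class = "body_frame")
}

#' @export
print.body_frame <- function(x, ...) {
  cat("<body_frame> origin (mm):", format(x$origin, digits = 4), "\n")
  m <- x$axes
  dimnames(m) <- list(c("lab_x", "lab_y", "lab_z"), c("x", "y", "z"))
  print(round(m, 6))
  invisible(x)
}

# Coerce a marker set to a 7x3 matrix with rows m1..m7.
as_marker_matrix <- function(markers) {
  if (is.data.frame(markers)) {
    cols <- paste0(
      rep(paste0("m", 1:7), each = 3), "_", rep(c("x", "y", "z"), 7)
    )
    missing_cols <- setdiff(cols, names(markers))
    if (length(missing_cols) > 0) {
      stop(
        "marker table lacks column(s): ", paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    if (nrow(markers) != 1L) {
      stop("expected a single marker sample (one row)", call. = FALSE)
    }
    m <- matrix(as.numeric(markers[1, cols]), nrow = 7, ncol = 3, byrow = TRUE)
  } else {
    m <- unname(as.matrix(markers))
    if (!all(dim(m) == c(7L, 3L))) {
      stop("markers must be a 7x3 matrix (rows m1..m7)", call. = FALSE)
    }
  }
  if (!all(is.finite(m))) {
    stop("marker positions must all be finite", call. = FALSE)
  }
  rownames(m) <- paste0("m", 1:7)
  m
}

# Smallest altitude (mm) of the triangle a, b, c; 0 when degenerate.
triangle_min_altitude <- function(a, b, c) {
  area2 <- vec_norm(cross3(b - a, c - a)) # twice the area
  longest <- max(vec_norm(b - a), vec_norm(c - a), vec_norm(c - b))
  if (longest < .Machine$double.eps^0.5) {
    return(0)
  }
  area2 / longest
}

# Shared frame construction: z along `z_vec`, x along the component of
# `normal` orthogonal to z, sign chosen towards `dorsal_reference`,
# y = z x x.
build_frame <- function(z_vec, normal, origin, dorsal_reference, what) {
  if (vec_norm(z_vec) < .DEGENERACY_MM) {
    stop("degenerate geometry in ", what, ": z-axis markers (nearly) coincide",
      call. = FALSE
    )
  }
  z <- unit3(z_vec)
  x_raw <- normal - sum(normal * z) * z
  if (vec_norm(x_raw) < .Machine$double.eps^0.25) {
    stop("degenerate geometry in ", what, ": plane normal parallel to z axis",
      call. = FALSE
    )
  }
  x <- unit3(x_raw)
  alignment <- sum(x * unit3(dorsal_reference))
  if (abs(alignment) < 1e-9) {
    stop(
      "dorsal reference direction is orthogonal to the candidate x axis; ",
      "cannot disambiguate the dorsal normal in ", what,
      call. = FALSE
    )
  }
  if (alignment < 0) x <- -x
  y <- cross3(z, x)
  body_frame(origin, cbind(x, y, z))
}

#' Forearm body frame from the marker-plate cluster
#'
#' The z axis points proximally from marker 2 to marker 1, the x axis is the
#' dorsal-pointing normal of the plane of markers 1-3, and y = z x x points
#' radially.
#'
#' @param markers A 7x3 marker matrix (rows `m1`..`m7`, mm) or a one-row data
#'   frame with columns `m1_x` ... `m7_z`.
#' @param dorsal_reference Approximate dorsal direction in the laboratory
#'   frame, used only to pick the sign of the plane normal. Default `c(1,0,0)`.
#' @return A [body_frame()] with origin at marker 2.
#' @examples
#' m <- canonical_markers()
#' build_forearm_frame(m)$axes # identity
#' @seealso [build_hand_frame()], [wrist_angles()]
#' @export
build_forearm_frame <- function(markers, dorsal_reference = c(1, 0, 0)) {
  m <- as_marker_matrix(markers)
  if (triangle_min_altitude(m["m1", ], m["m2", ], m["m3", ]) < .DEGENERACY_MM) {
    stop("degenerate geometry: forearm markers m1-m3 are (near-)collinear",
      call. = FALSE
    )
  }
  normal <- cross3(m["m2", ] - m["m1", ], m["m3", ] - m["m1", ])
  build_frame(
    z_vec = m["m1", ] - m["m2", ],
    normal = normal,
    origin = m["m2", ],
    dorsal_reference = dorsal_reference,
    what = "forearm frame"
  )
}

#' Hand body frame from the metacarpal markers
#'
#' The z axis points proximally from marker 6 (third-metacarpal head) to
#' marker 4 (third-metacarpal mid-shaft); the x axis is the dorsal-pointing
#' normal of the plane of markers 4, 5 and 7, orthogonalised against z;
#' y = z x x.
#'
#' @inheritParams build_forearm_frame
#' @return A [body_frame()] with origin at marker 6.
#' @export
build_hand_frame <- function(markers, dorsal_reference = c(1, 0, 0)) {
  m <- as_marker_matrix(markers)
  if (triangle_min_altitude(m["m4", ], m["m5", ], m["m7", ]) < .DEGENERACY_MM) {
    stop("degenerate geometry: hand markers m4, m5, m7 are (near-)collinear",
      call. = FALSE
    )
  }
  normal <- cross3(m["m5", ] - m["m4", ], m["m7", ] - m["m4", ])
  build_frame(
    z_vec = m["m4", ] - m["m6", ],
    normal = normal,
    origin = m["m6", ],
    dorsal_reference = dorsal_reference,
    what = "hand frame"
  )
}

#' Compose a wrist rotation from its angle decomposition
#'
#' Builds the hand-relative-to-forearm rotation for given wrist angles under
#' the package's intrinsic y-x-z convention: flexion-extension about the
#' forearm y (radial) axis first (extension positive), then radial-ulnar
#' deviation about the once-rotated x (dorsal) axis (radial positive), then
#' axial rotation about the twice-rotated z.
#'
#' @param flexion_extension,radial_ulnar,axial_rotation Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
compose_wrist_rotation <- function(flexion_extension, radial_ulnar,
                                   axial_rotation = 0) {
  rot_y(deg2rad(flexion_extension)) %*%
    rot_x(deg2rad(radial_ulnar)) %*%
    rot_z(deg2rad(axial_rotation))
}

#' Wrist angles from forearm and hand frames
#'
#' Decomposes the relative rotation `t(forearm$axes) %*% hand$axes` in the
#' intrinsic y-x-z sequence of [compose_wrist_rotation()]. When the two z
#' axes are parallel the wrist is in the neutral position and both
#' flexion-extension and radial-ulnar deviation are zero.
#'
#' @param forearm,hand [body_frame()] objects.
#' @return An object of class `wrist_angles`: a list with
#'   `flexion_extension` (degrees, extension positive), `radial_ulnar`
#'   (degrees, radial positive) and `axial_rotation` (degrees).
#' @examples
#' f <- build_forearm_frame(canonical_markers())
#' h <- body_frame(f$origin, f$axes %*% compose_wrist_rotation(30, 0))
#' wrist_angles(f, h) # 30 degrees extension
#' @export
wrist_angles <- function(forearm, hand) {
  stopifnot(inherits(forearm, "body_frame"), inherits(hand, "body_frame"))
  r <- t(forearm$axes) %*% hand$axes
  s <- min(1, max(-1, -r[2, 3])) # sin(radial_ulnar)
  if (abs(s) > sin(deg2rad(89))) {
    warning("radial-ulnar deviation within 1 degree of gimbal lock (90)",
      call. = FALSE
    )
  }
  structure(
    list(
      flexion_extension = rad2deg(atan2(r[1, 3], r[3, 3])),
      radial_ulnar = rad2deg(asin(s)),
      axial_rotation = rad2deg(atan2(r[2, 1], r[2, 2]))
    ),
    class = "wrist_angles"
  )
}

#' @export
print.wrist_angles <- function(x, ...) {
  cat(sprintf(
    "<wrist_angles> flexion-extension %+.2f deg, radial-ulnar %+.2f deg, axial %+.2f deg\n",
    x$flexion_extension, x$radial_ulnar, x$axial_rotation
  ))
  invisible(x)
}

#' Wrist-angle time series from a marker trajectory
#'
#' Applies [build_forearm_frame()], [build_hand_frame()] and
#' [wrist_angles()] to every sample of a marker trajectory table.
#'
#' @param trajectory Data frame with columns `time`, `m1_x` ... `m7_z`
#'   (see [read_marker_trajectory()]).
#' @param dorsal_reference Approximate dorsal direction in the laboratory
#'   frame (see [build_forearm_frame()]).
#' @param side `"right"` or `"left"`. Left hands are mirrored at ingest
#'   (lab y negated) so that radial-ulnar signs are side-consistent.
#' @return A tibble with columns `time`, `flexion_extension`,
#'   `radial_ulnar`, `axial_rotation` (degrees).
#' @export
wrist_angle_trajectory <- function(trajectory, dorsal_reference = c(1, 0, 0),
                                   side = c("right", "left")) {
  side <- match.arg(side)
  if (!"time" %in% names(trajectory)) {
    stop("trajectory lacks a `time` column", call. = FALSE)
  }
  cols <- paste0(rep(paste0("m", 1:7), each = 3), "_", rep(c("x", "y", "z"), 7))
  missing_cols <- setdiff(cols, names(trajectory))
  if (length(missing_cols) > 0) {
    stop("trajectory lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  pos <- as.matrix(trajectory[, cols])
  if (side == "left") {
    y_cols <- grepl("_y$", cols)
    pos[, y_cols] <- -pos[, y_cols]
    dorsal_reference <- dorsal_reference * c(1, -1, 1)
  }
  out <- vapply(seq_len(nrow(pos)), function(i) {
    m <- matrix(pos[i, ], nrow = 7, ncol = 3, byrow = TRUE)
    ang <- wrist_angles(
      build_forearm_frame(m, dorsal_reference),
      build_hand_frame(m, dorsal_reference)
    )
    c(ang$flexion_extension, ang$radial_ulnar, ang$axial_rotation)
  }, numeric(3))
  tibble::tibble(
    time = trajectory$time,
    flexion_extension = out[1, ],
    radial_ulnar = out[2, ],
    axial_rotation = out[3, ]
  )
}

as_angle_pair <- function(x) {
  if (inherits(x, "wrist_angles")) {
    c(x$flexion_extension, x$radial_ulnar)
  } else {
    x <- as.numeric(x)
    stopifnot(length(x) >= 2L)
    x[1:2]
  }
}

#' DTM-plane geometry from the two extreme wrist positions
#'
#' The dart-throwing motion is modelled as a linear path in the 2-D
#' wrist-angle space (flexion-extension, radial-ulnar deviation) through the
#' marked radial-extension and ulnar-flexion positions. The returned
#' geometry is:
#'
#' * `slope` — inclination of the path relative to the sagittal (pure
#'   flexion-extension) plane, in (-90, 90] degrees; positive when the wrist
#'   travels from radial extension towards ulnar flexion, negative for an
#'   ulnar-extension to radial-flexion path.
#' * `offset` — flexion-extension angle where the path crosses zero
#'   deviation, positive in extension.
#' * `range` — Euclidean distance between the two positions (degrees).
#'
#' @param radial_extension,ulnar_flexion The two extreme positions, as
#'   [wrist_angles()] objects or numeric `(flexion_extension, radial_ulnar)`
#'   pairs in degrees.
#' @return An object of class `dtm_plane`: list with `slope`, `offset`,
#'   `range` (degrees). `offset` is `NA` (with a warning) when the path
#'   never crosses zero deviation.
#' @examples
#' dtm_plane(c(40, 15), c(-20, -15)) # slope 26.57, offset 10, range 67.08
#' @export
dtm_plane <- function(radial_extension, ulnar_flexion) {
  re <- as_angle_pair(radial_extension)
  uf <- as_angle_pair(ulnar_flexion)
  d_fe <- uf[1] - re[1]
  d_dev <- uf[2] - re[2]
  rng <- sqrt(d_fe^2 + d_dev^2)
  if (rng < .Machine$double.eps^0.5) {
    stop("the two wrist positions coincide; DTM plane undefined", call. = FALSE)
  }
  eps <- 1e-12 * max(1, abs(d_fe), abs(d_dev))
  slope <- if (abs(d_fe) <= eps) 90 else rad2deg(atan(d_dev / d_fe))
  if (abs(d_dev) <= eps) {
    if (abs(re[2]) <= 1e-9) {
      offset <- 0 # path runs along zero deviation
    } else {
      warning(
        "path parallel to the flexion-extension axis at nonzero deviation; ",
        "offset undefined",
        call. = FALSE
      )
      offset <- NA_real_
    }
  } else {
    offset <- re[1] - re[2] * d_fe / d_dev
  }
  structure(
    list(slope = slope, offset = offset, range = rng),
    class = "dtm_plane"
  )
}

#' @export
print.dtm_plane <- function(x, ...) {
  cat(sprintf(
    "<dtm_plane> slope %.2f deg, offset %s deg, range %.2f deg\n",
    x$slope,
    if (is.na(x$offset)) "NA" else sprintf("%.2f", x$offset),
    x$range
  ))
  invisible(x)
}

#' Wrist angles at the marked extreme positions
#'
#' Extracts the wrist angles at the two event marks (the still instants at
#' maximal radial extension and maximal ulnar flexion) from a wrist-angle
#' time series, using the nearest sample in time; ties break towards the
#' earlier sample.
#'
#' @param angles Tibble from [wrist_angle_trajectory()] (columns `time`,
#'   `flexion_extension`, `radial_ulnar`, `axial_rotation`).
#' @param events Data frame with columns `event` (containing
#'   `"radial_extension"` and `"ulnar_flexion"`) and `time` (seconds), or a
#'   named numeric vector of the two event times.
#' @return List with elements `radial_extension` and `ulnar_flexion`, each a
#'   `wrist_angles` object.
#' @export
mark_extreme_positions <- function(angles, events) {
  if (is.numeric(events)) {
    events <- data.frame(event = names(events), time = as.numeric(events))
  }
  need <- c("radial_extension", "ulnar_flexion")
  if (!all(need %in% events$event)) {
    stop("events must contain rows `radial_extension` and `ulnar_flexion`",
      call. = FALSE
    )
  }
  t_min <- min(angles$time)
  t_max <- max(angles$time)
  pick <- function(label) {
    t_ev <- events$time[match(label, events$event)]
    if (t_ev < t_min - 1e-9 || t_ev > t_max + 1e-9) {
      stop(
        sprintf(
          "event `%s` at %.4f s lies outside the recording [%.4f, %.4f] s",
          label, t_ev, t_min, t_max
        ),
        call. = FALSE
      )
    }
    i <- which.min(abs(angles$time - t_ev)) # first minimum = earlier sample
    structure(
      list(
        flexion_extension = angles$flexion_extension[i],
        radial_ulnar = angles$radial_ulnar[i],
        axial_rotation = angles$axial_rotation[i]
      ),
      class = "wrist_angles"
    )
  }
  list(
    radial_extension = pick("radial_extension"),
    ulnar_flexion = pick("ulnar_flexion")
  )
}

#' Canonical seven-marker configuration
#'
#' A neutral-wrist marker set in which both body frames equal the identity:
#' the forearm plate on the z axis, the hand markers distally along -z.
#' Useful as a fixture and as the seed geometry of the trajectory simulator.
#'
#' @param hand_z Distance (mm) from the wrist centre (origin) to the
#'   third-metacarpal head (marker 6).
#' @return A 7x3 marker matrix (rows `m1`..`m7`).
#' @export
canonical_markers <- function(hand_z = 80) {
  rbind(
    m1 = c(0, 0, 100),
    m2 = c(0, 0, 60),
    m3 = c(0, 20, 80),
    m4 = c(0, 0, -(hand_z - 35)),
    m5 = c(0, 20, -hand_z),
    m6 = c(0, 0, -hand_z),
    m7 = c(0, -20, -hand_z)
  )
}
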
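#' Six-point eye landmark set
#'
#' Constructs the canonical six-landmark description of one eye on one video
#' frame. Landmarks follow the standard eye-aspect-ratio (EAR) convention:
#' `p1` is the temporal eye corner, `p4` the nasal corner, `p2`/`p3` sit on
#' the upper lid and `p6`/`p5` on the lower lid, so that `p2`-`p6` and
#' `p3`-`p5` are the two vertical lid distances and `p1`-`p4` the horizontal
#' eye width.
#'
#' @param coords numeric 6 x 2 matrix of pixel coordinates, rows in the order
#'   p1..p6 (columns x, y). A data frame with two numeric columns is accepted.
#' @return an object of class `eye_landmarks` (a 6 x 2 matrix with row names
#'   `p1`..`p6`).
#' @examples
#' open_eye <- eye_landmarks(rbind(
#'   c(0, 0), c(1, 0.5), c(3, 0.5), c(4, 0), c(3, -0.5), c(1, -0.5)
#' ))
#' compute_ear(open_eye) # 0.25
#' @export
eye_landmarks <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || !identical(dim(coords), c(6L, 2L))) {
    stop("`coords` must be a numeric 6 x 2 matrix (rows p1..p6, columns x,y)")
  }
  if (!all(is.finite(coords))) {
    stop("landmark coordinates must all be finite")
  }
  dimnames(coords) <- list(paste0("p", 1:6), c("x", "y"))
  structure(coords, class = c("eye_landmarks", "matrix"))
}

#' Eye aspect ratio of a landmark set
#'
#' The EAR is the ratio of the summed vertical lid distances to twice the
#' horizontal eye width:
#' \deqn{EAR = \frac{\|p_2-p_6\| + \|p_3-p_5\|}{2\,\|p_1-p_4\|}}
#' with Euclidean norms. It is dimensionless, sits near 0.25 for an open eye,
#' and drops toward 0 as the lids close. Being a ratio of distances it is
#' invariant under rotation, translation and uniform scaling of the landmark
#' set, which makes it robust to head pose and camera distance.
#'
#' @param landmarks an [eye_landmarks] object or a numeric 6 x 2 matrix with
#'   rows in p1..p6 order.
#' @return a single non-negative number.
#' @seealso [build_series()] to map whole recordings to EAR series.
#' @export
compute_ear <- function(landmarks) {
  lm <- if (inherits(landmarks, "eye_landmarks")) landmarks else eye_landmarks(landmarks)
  horiz <- sqrt(sum((lm["p1", ] - lm["p4", ])^2))
  if (horiz <= 0) {
    stop("degenerate eye geometry: horizontal corner distance |p1 - p4| is zero")
  }
  v1 <- sqrt(sum((lm["p2", ] - lm["p6", ])^2))
  v2 <- sqrt(sum((lm["p3", ] - lm["p5", ])^2))
  (v1 + v2) / (2 * horiz)
}

#' Landmark set with a prescribed EAR
#'
#' Simple geometric synthesis: places the corners `width` apart on the x axis
#' and the lid points symmetrically about it at the height that yields the
#' requested EAR. Useful for tests and for landmark-level simulation; it is a
#' geometric construction, not an eyelid-kinematics model.
#'
#' @param ear target EAR value (non-negative).
#' @param width horizontal corner distance in pixels.
#' @return an [eye_landmarks] object with `compute_ear()` equal to `ear`.
#' @export
landmarks_for_ear <- function(ear, width = 4) {
  stopifnot(is.numeric(ear), length(ear) == 1, ear >= 0, width > 0)
  h <- ear * width / 2 # each vertical distance is 2h, EAR = 4h / (2 width)
  eye_landmarks(rbind(
    c(0, 0),
    c(width / 4, h), c(3 * width / 4, h),
    c(width, 0),
    c(3 * width / 4, -h), c(width / 4, -h)
  ))
}

#' Combine left- and right-eye EAR values
#'
#' One video frame yields up to two EAR values. The combination mode decides
#' the per-frame scalar fed to blink detection; the default averages whatever
#' is available, falling back to the single detected eye.
#'
#' @param left_ear,right_ear numeric vectors of per-frame EAR values, `NA`
#'   where the eye was not detected. Recycled to a common length.
#' @param mode one of `"mean"` (average of available eyes, the default),
#'   `"left"`, `"right"`, or `"min"` (more conservative: the more closed eye).
#' @return numeric vector; `NA` where no eye was available (or, for
#'   `"left"`/`"right"`, where that eye was absent).
#' @export
combine_eyes <- function(left_ear, right_ear, mode = c("mean", "left", "right", "min")) {
  mode <- match.arg(mode)
  n <- max(length(left_ear), length(right_ear))
  l <- rep_len(as.numeric(left_ear), n)
  r <- rep_len(as.numeric(right_ear), n)
  switch(mode,
    left  = l,
    right = r,
    mean  = ifelse(is.na(l), r, ifelse(is.na(r), l, (l + r) / 2)),
    min   = ifelse(is.na(l), r, ifelse(is.na(r), l, pmin(l, r)))
  )
}

#' EAR time series
#'
#' Container for an ordered per-frame EAR trace. Frames are indexed 0-based;
#' timestamps default to `frame / fps`. Missing frames (landmark dropout, e.g.
#' occlusion by a face mask) are kept in place as `NA` so that downstream run
#' detection can treat them as run-breakers rather than silently splicing the
#' signal.
#'
#' @param ear numeric vector of per-frame EAR values, `NA` for missing frames.
#' @param fps frame rate in frames per second (required when `timestamp` is
#'   not supplied).
#' @param timestamp optional numeric vector of per-frame times in seconds.
#' @param frame optional integer vector of 0-based frame indices; defaults to
#'   `0:(n-1)`. Must be strictly increasing.
#' @return a data frame of class `ear_series` with columns `frame`,
#'   `timestamp`, `ear` and attributes `fps` and `duration` (seconds,
#'   `n / fps`).
#' @export
ear_series <- function(ear, fps, timestamp = NULL, frame = NULL) {
  ear <- as.numeric(ear)
  n <- length(ear)
  if (n == 0) stop("empty recording: no frames supplied")
  if (missing(fps) || is.null(fps)) {
    if (is.null(timestamp) || length(timestamp) < 2) {
      stop("`fps` is required when no timestamps are supplied")
    }
    fps <- (length(timestamp) - 1) / (timestamp[length(timestamp)] - timestamp[1])
  }
  stopifnot(is.numeric(fps), length(fps) == 1, fps > 0)
  if (is.null(frame)) frame <- seq_len(n) - 1L
  frame <- as.integer(frame)
  if (length(frame) != n || any(diff(frame) <= 0)) {
    stop("`frame` must be a strictly increasing index vector, one per value")
  }
  if (is.null(timestamp)) timestamp <- frame / fps
  if (any(ear < 0, na.rm = TRUE)) stop("EAR values must be non-negative")
  out <- data.frame(frame = frame, timestamp = as.numeric(timestamp), ear = ear)
  structure(out,
    fps = fps, duration = n / fps,
    class = c("ear_series", "data.frame")
  )
}

#' @export
print.ear_series <- function(x, ...) {
  cat(sprintf(
    "<ear_series> %d frames @ %.6g fps (%.3g s), %d missing\n",
    nrow(x), attr(x, "fps"), attr(x, "duration"), sum(is.na(x$ear))
  ))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Build an EAR series from per-frame landmark rows
#'
#' Converts tabular landmark detections (one row per eye per frame, see
#' [read_landmark_csv()] for the dialect) into an [ear_series]. Frames flagged
#' invalid, or absent for both eyes, become missing (`NA`) entries; they are
#' retained in place so that landmark dropout breaks blink runs exactly as it
#' does in the recording app.
#'
#' @param landmarks data frame with columns `frame`, optional `timestamp`,
#'   `eye` (`"left"`/`"right"`), `p1x`,`p1y`,...,`p6x`,`p6y`, and optional
#'   logical `valid`.
#' @param fps frame rate; required when `landmarks` has no `timestamp` column.
#' @param combine eye-combination mode passed to [combine_eyes()].
#' @return an [ear_series] with one entry per distinct frame index.
#' @export
build_series <- function(landmarks, fps = NULL, combine = c("mean", "left", "right", "min")) {
  combine <- match.arg(combine)
  if (!is.data.frame(landmarks) || nrow(landmarks) == 0) {
    stop("empty recording: no landmark rows supplied")
  }
  needed <- c("frame", "eye", as.vector(t(outer(paste0("p", 1:6), c("x", "y"), paste0))))
  missing_cols <- setdiff(needed, names(landmarks))
  if (length(missing_cols)) {
    stop("landmark table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"valid" %in% names(landmarks)) landmarks$valid <- TRUE
  # normalize to 0-based frame indices
  landmarks$frame <- as.integer(landmarks$frame) - min(as.integer(landmarks$frame))
  frames <- sort(unique(landmarks$frame))

  row_ear <- function(row) {
    if (!isTRUE(as.logical(row[["valid"]]))) return(NA_real_)
    coords <- matrix(as.numeric(row[needed[-(1:2)]]), ncol = 2, byrow = TRUE)
    if (any(!is.finite(coords))) return(NA_real_)
    compute_ear(eye_landmarks(coords))
  }
  per_eye <- function(eye) {
    vals <- rep(NA_real_, length(frames))
    sub <- landmarks[landmarks$eye == eye, , drop = FALSE]
    if (nrow(sub)) {
      idx <- match(sub$frame, frames)
      vals[idx] <- vapply(seq_len(nrow(sub)), function(i) row_ear(sub[i, ]), numeric(1))
    }
    vals
  }
  ear <- combine_eyes(per_eye("left"), per_eye("right"), mode = combine)

  ts <- NULL
  if ("timestamp" %in% names(landmarks) && !all(is.na(landmarks$timestamp))) {
    ts <- landmarks$timestamp[match(frames, landmarks$frame)]
  }
  if (is.null(ts) && is.null(fps)) {
    stop("`fps` is required when the landmark table carries no timestamps")
  }
  ear_series(ear, fps = if (is.null(fps)) NULL else fps, timestamp = ts, frame = frames)
}

#' Summary statistics of an EAR series
#'
#' Reports the mean, maximum and minimum EAR over the non-missing frames
#' (AverageEAR / MaxEAR / MinEAR), together with frame and dropout counts.
#' MaxEAR and MinEAR feed the personalised dynamic blink thresholds
#' ([dynamic_thresholds()]). The optional robust variant replaces the raw
#' extrema with quantiles to guard against single-frame glitches.
#'
#' @param series an [ear_series].
#' @param robust use quantiles instead of raw min/max.
#' @param probs length-2 vector of lower/upper quantile probabilities used
#'   when `robust = TRUE`.
#' @return an object of class `ear_summary`: a list with `average_ear`,
#'   `max_ear`, `min_ear`, `n_frames`, `n_missing`.
#' @export
ear_summary <- function(series, robust = FALSE, probs = c(0.005, 0.995)) {
  stopifnot(inherits(series, "ear_series"))
  x <- series$ear
  good <- x[!is.na(x)]
  if (length(good) == 0) stop("no data: every frame in the series is missing")
  if (robust) {
    q <- stats::quantile(good, probs = sort(probs), names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
  } else {
    lo <- min(good); hi <- max(good)
  }
  structure(
    list(
      average_ear = mean(good),
      max_ear = hi,
      min_ear = lo,
      n_frames = length(x),
      n_missing = sum(is.na(x))
    ),
    robust = robust,
    class = "ear_summary"
  )
}

#' @export
summary.ear_series <- function(object, ...) ear_summary(object, ...)

#' @export
print.ear_summary <- function(x, ...) {
  cat(sprintf(
    "<ear_summary> AverageEAR %.4f  MaxEAR %.4f  MinEAR %.4f  (%d frames, %d missing)\n",
    x$average_ear, x$max_ear, x$min_ear, x$n_frames, x$n_missing
  ))
  invisible(x)
}
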
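# Run-length machinery shared by the fixed rule and the dynamic detector.
# `below` is logical with NA for missing frames; missing frames break runs
# unless bridge_gap > 0, in which case an all-missing gap of at most
# bridge_gap frames flanked by below-threshold frames is absorbed into one
# event. Returns start/end indices (1-based into the vector) of maximal runs
# whose span length is >= min_run.
find_runs <- function(below, min_run = 3L, bridge_gap = 0L) {
  stopifnot(min_run >= 1, bridge_gap >= 0)
  n <- length(below)
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  code <- ifelse(is.na(below), 2L, as.integer(below)) # 0 above, 1 below, 2 missing
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  ev_start <- integer(); ev_end <- integer()
  open_start <- NA_integer_; open_end <- NA_integer_
  close_event <- function() {
    if (!is.na(open_start)) {
      ev_start <<- c(ev_start, open_start)
      ev_end <<- c(ev_end, open_end)
    }
    open_start <<- NA_integer_; open_end <<- NA_integer_
  }
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 1L) {
      if (is.na(open_start)) open_start <- starts[k]
      open_end <- ends[k]
    } else if (v == 2L && !is.na(open_start) && r$lengths[k] <= bridge_gap &&
               k < length(r$values) && r$values[k + 1] == 1L) {
      # bridgeable dropout inside an ongoing event: keep it open
    } else {
      close_event()
    }
  }
  close_event()
  keep <- (ev_end - ev_start + 1L) >= min_run
  data.frame(start = ev_start[keep], end = ev_end[keep])
}

#' Count blinks with a fixed EAR threshold
#'
#' The original single-threshold rule: a blink is any run of at least
#' `min_run` consecutive non-missing frames whose EAR is less than or equal
#' to `threshold`; each maximal such run counts once. The default threshold
#' 0.163 separates open from closed eyes well for typical recordings but
#' systematically misses partial blinks, which is what motivates the dynamic
#' dual-threshold detector ([segment_events()]).
#'
#' @param series an [ear_series].
#' @param threshold fixed EAR threshold (default 0.163).
#' @param min_run minimum run length in frames (default 3).
#' @param bridge_gap number of consecutive missing frames allowed inside a
#'   run before it is broken (default 0: any dropout breaks the run).
#' @return integer blink count.
#' @export
count_blinks_fixed <- function(series, threshold = 0.163, min_run = 3L, bridge_gap = 0L) {
  stopifnot(inherits(series, "ear_series"))
  if (nrow(series) == 0) stop("empty recording: no frames supplied")
  nrow(find_runs(series$ear <= threshold, min_run = min_run, bridge_gap = bridge_gap))
}

#' Full/partial blink threshold pair
#'
#' Bundles the two EAR thresholds used by the dynamic detector. The partial
#' threshold defaults to 1.4 x the full threshold (a partial blink is a dip
#' whose EAR stays up to 40% above the full-blink threshold). `reference`
#' records how thresholds are compared to the signal: `"absolute"` compares
#' raw EAR values (the formula as printed), `"offset"` compares
#' `ear - min_ear`, which makes detection invariant to a constant shift of
#' the whole trace.
#'
#' @param full_threshold full-blink EAR threshold (>= 0).
#' @param partial_threshold partial-blink EAR threshold; defaults to
#'   `1.4 * full_threshold` and must be at least `full_threshold`.
#' @param reference `"absolute"` (default) or `"offset"`.
#' @param min_ear recording MinEAR, used only in offset mode.
#' @return an object of class `threshold_pair`.
#' @export
threshold_pair <- function(full_threshold, partial_threshold = 1.4 * full_threshold,
                           reference = c("absolute", "offset"), min_ear = 0) {
  reference <- match.arg(reference)
  stopifnot(
    is.numeric(full_threshold), length(full_threshold) == 1, full_threshold >= 0,
    is.numeric(partial_threshold), length(partial_threshold) == 1,
    partial_threshold >= full_threshold
  )
  structure(
    list(
      full_threshold = full_threshold,
      partial_threshold = partial_threshold,
      reference = reference,
      min_ear = min_ear
    ),
    class = "threshold_pair"
  )
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "<threshold_pair> full %.6g, partial %.6g (%s reference)\n",
    x$full_threshold, x$partial_threshold, x$reference
  ))
  invisible(x)
}

#' Personalised dynamic blink thresholds
#'
#' Derives the two detection thresholds from the recording's own EAR range:
#' \deqn{T_{full} = \frac{0.1281}{0.27527}\,(MaxEAR - MinEAR), \qquad
#'       T_{partial} = 1.4\,T_{full}.}
#' Because lid anatomy and camera geometry make the open-eye plateau and the
#' closed-eye floor differ between people, a single fixed threshold miscounts
#' blinks (especially partial blinks, common in dry eye); scaling the
#' thresholds to the individual span personalises the detector. The
#' coefficient 0.1281/0.27527 is an empirically calibrated constant.
#'
#' @param summary an [ear_summary] (or anything with `max_ear`/`min_ear`).
#' @param reference comparison mode recorded in the result; see
#'   [threshold_pair()].
#' @return a [threshold_pair].
#' @examples
#' s <- structure(list(max_ear = 0.27527, min_ear = 0), class = "ear_summary")
#' dynamic_thresholds(s)$full_threshold # 0.1281
#' @export
dynamic_thresholds <- function(summary, reference = c("absolute", "offset")) {
  reference <- match.arg(reference)
  if (!all(c("max_ear", "min_ear") %in% names(summary))) {
    stop("`summary` must carry max_ear and min_ear (see ear_summary())")
  }
  if (summary$max_ear < summary$min_ear) {
    stop("invalid summary: max_ear is smaller than min_ear")
  }
  full <- (0.1281 / 0.27527) * (summary$max_ear - summary$min_ear)
  threshold_pair(full, 1.4 * full, reference = reference, min_ear = summary$min_ear)
}

#' Segment and classify blink events
#'
#' Finds maximal runs of at least `min_run` consecutive non-missing frames at
#' or below the partial threshold, then classifies each event by its minimum:
#' FULL if the event reaches the full threshold, PARTIAL otherwise.
#' Segmenting by the partial threshold and classifying by the event minimum
#' keeps a full blink's entry/exit frames — which necessarily traverse the
#' partial band — from being double-counted as a separate partial blink.
#'
#' @param series an [ear_series].
#' @param thresholds a [threshold_pair], typically from
#'   [dynamic_thresholds()].
#' @param min_run minimum event length in frames.
#' @param bridge_gap missing-frame bridging, as in [count_blinks_fixed()].
#' @return a data frame of class `blink_events` with columns `start_frame`,
#'   `end_frame` (inclusive, in the series' frame indexing), `n_frames`,
#'   `min_ear` (raw scale) and `kind` (`"FULL"`/`"PARTIAL"`), ordered and
#'   non-overlapping. The thresholds used are attached as attribute
#'   `thresholds`.
#' @export
segment_events <- function(series, thresholds, min_run = 3L, bridge_gap = 0L) {
  stopifnot(inherits(series, "ear_series"), inherits(thresholds, "threshold_pair"))
  x <- series$ear
  cmp <- if (thresholds$reference == "offset") x - thresholds$min_ear else x
  runs <- find_runs(cmp <= thresholds$partial_threshold,
                    min_run = min_run, bridge_gap = bridge_gap)
  if (nrow(runs) == 0) {
    ev <- data.frame(
      start_frame = integer(), end_frame = integer(), n_frames = integer(),
      min_ear = numeric(), kind = character()
    )
  } else {
    ev <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      sl <- runs$start[i]:runs$end[i]
      ev_min_cmp <- min(cmp[sl], na.rm = TRUE)
      data.frame(
        start_frame = series$frame[runs$start[i]],
        end_frame = series$frame[runs$end[i]],
        n_frames = runs$end[i] - runs$start[i] + 1L,
        min_ear = min(x[sl], na.rm = TRUE),
        kind = if (ev_min_cmp <= thresholds$full_threshold) "FULL" else "PARTIAL"
      )
    }))
  }
  structure(ev,
    thresholds = thresholds, min_run = min_run,
    class = c("blink_events", "data.frame")
  )
}

#' Blink rate metrics for a recording
#'
#' Tallies segmented events by kind and normalises the counts to per-minute
#' rates using the actual recording duration (recordings are nominally one
#' minute but run a few seconds over or under). Also reports an open/close
#' ratio, `100 * MinEAR / MaxEAR` — note this definition is a package
#' convention and has not been validated against any clinical quantity.
#'
#' @param events a `blink_events` data frame from [segment_events()].
#' @param series the [ear_series] the events were segmented from.
#' @return an object of class `blink_metrics`: list with `full_count`,
#'   `partial_count`, `duration` (s), `full_rate_per_min`,
#'   `partial_rate_per_min`, `open_close_ratio_pct`.
#' @export
compute_metrics <- function(events, series) {
  stopifnot(inherits(events, "blink_events"), inherits(series, "ear_series"))
  duration <- attr(series, "duration")
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid duration: the series must span a positive time interval")
  }
  s <- ear_summary(series)
  full <- sum(events$kind == "FULL")
  part <- sum(events$kind == "PARTIAL")
  structure(
    list(
      full_count = full,
      partial_count = part,
      duration = duration,
      full_rate_per_min = full * 60 / duration,
      partial_rate_per_min = part * 60 / duration,
      open_close_ratio_pct = 100 * s$min_ear / s$max_ear
    ),
    class = "blink_metrics"
  )
}

#' @export
print.blink_metrics <- function(x, ...) {
  cat(sprintf(
    "<blink_metrics> %d full (%.1f/min), %d partial (%.1f/min) in %.1f s\n",
    x$full_count, x$full_rate_per_min, x$partial_count, x$partial_rate_per_min,
    x$duration
  ))
  invisible(x)
}
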
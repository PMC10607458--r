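# Run a block of code with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards. Keeps simulate_ear_series() deterministic
# per seed without clobbering user randomness.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic EAR recording
#'
#' Describes a one-minute-style EAR trace with known ground truth: an
#' open-eye plateau near 0.25, trapezoidal full-blink dips toward 0,
#' shallower partial-blink dips whose bottom sits a fraction of the span
#' below the plateau, additive Gaussian noise clipped at zero, and optional
#' landmark-dropout (missing-frame) runs. Dips are trapezoidal — a short
#' linear descent, at least three bottom frames, a short ascent — so that a
#' full blink's entry and exit frames traverse the partial band, exercising
#' the double-counting hazard the event segmentation must handle.
#'
#' @param duration recording length in seconds (default 60, the standard
#'   recording protocol).
#' @param fps frame rate (default 30, standard phone HD video).
#' @param open_level open-eye EAR plateau (default 0.25).
#' @param full_depth EAR at the bottom of a full blink (default 0.02).
#' @param partial_depth_fraction fraction of the span
#'   `open_level - full_depth` reached by partial dips (default 0.5, which
#'   places the bottom between the two dynamic thresholds).
#' @param n_full,n_partial numbers of full and partial blink events.
#' @param blink_len_frames bottom-frame count per dip (minimum 3).
#' @param ramp_frames frames in each of the descent and ascent ramps.
#' @param noise_sd standard deviation of the additive Gaussian noise, in EAR
#'   units (default 0.005, about 2% of the open level).
#' @param dropout_runs optional data frame (or list of length-2 vectors)
#'   of missing-frame stretches, columns/elements `start_frame` (0-based)
#'   and `length`.
#' @param seed integer seed making the generated recording reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration = 60, fps = 30, open_level = 0.25,
                           full_depth = 0.02, partial_depth_fraction = 0.5,
                           n_full = 10, n_partial = 2, blink_len_frames = 3,
                           ramp_frames = 2, noise_sd = 0.005,
                           dropout_runs = NULL, seed = 1) {
  stopifnot(
    duration > 0, fps > 0, blink_len_frames >= 3, ramp_frames >= 0,
    n_full >= 0, n_partial >= 0, noise_sd >= 0,
    partial_depth_fraction > 0, partial_depth_fraction < 1
  )
  partial_bottom <- open_level - partial_depth_fraction * (open_level - full_depth)
  if (!(full_depth < partial_bottom && partial_bottom < open_level)) {
    stop("depths must be ordered: full_depth < partial bottom < open_level")
  }
  if (!is.null(dropout_runs) && !is.data.frame(dropout_runs)) {
    dropout_runs <- as.data.frame(do.call(rbind, dropout_runs))
    names(dropout_runs) <- c("start_frame", "length")
  }
  structure(
    list(
      duration = duration, fps = fps, open_level = open_level,
      full_depth = full_depth, partial_depth_fraction = partial_depth_fraction,
      partial_bottom = partial_bottom,
      n_full = as.integer(n_full), n_partial = as.integer(n_partial),
      blink_len_frames = as.integer(blink_len_frames),
      ramp_frames = as.integer(ramp_frames),
      noise_sd = noise_sd, dropout_runs = dropout_runs,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic EAR recording with ground truth
#'
#' Realises a [synthetic_spec()]: places the requested full and partial dips
#' at random non-overlapping positions (at least two open frames between
#' events), shapes each as a trapezoid, adds zero-clipped Gaussian noise,
#' and finally blanks any dropout runs to missing. The same spec and seed
#' always reproduce the identical recording.
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `synthetic_recording`:
#'   `series` (an [ear_series]), `truth` (list with an `events` data frame —
#'   `start_frame`/`end_frame` of each dip's bottom run, 0-based, and
#'   `kind` — plus `n_full` and `n_partial`), and the `spec` itself.
#' @examples
#' rec <- simulate_ear_series(synthetic_spec(n_full = 5, n_partial = 1, seed = 7))
#' rec$truth$n_full
#' @export
simulate_ear_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_frames <- as.integer(round(spec$duration * spec$fps))
  n_ev <- spec$n_full + spec$n_partial
  width <- spec$blink_len_frames + 2L * spec$ramp_frames
  gap <- 2L # open frames separating adjacent events (and padding the ends)
  slack <- n_frames - n_ev * (width + gap) - gap
  if (slack < 0) {
    stop(
      "infeasible placement: ", n_ev, " events of ", width,
      " frames do not fit in ", n_frames, " frames"
    )
  }

  with_private_seed(spec$seed, {
    x <- rep(spec$open_level, n_frames)
    truth_events <- data.frame(
      start_frame = integer(), end_frame = integer(), kind = character()
    )
    if (n_ev > 0) {
      extra <- diff(c(0, sort(sample.int(slack + 1L, n_ev, replace = TRUE) - 1L)))
      kinds <- sample(c(rep("FULL", spec$n_full), rep("PARTIAL", spec$n_partial)))
      pos <- 0L
      starts <- integer(n_ev)
      for (i in seq_len(n_ev)) {
        pos <- pos + gap + extra[i]
        starts[i] <- pos + 1L # 1-based index of first ramp frame
        pos <- pos + width
      }
      ramp <- spec$ramp_frames
      for (i in seq_len(n_ev)) {
        bottom <- if (kinds[i] == "FULL") spec$full_depth else spec$partial_bottom
        frac <- if (ramp > 0) seq_len(ramp) / (ramp + 1) else numeric(0)
        profile <- c(
          spec$open_level + frac * (bottom - spec$open_level),
          rep(bottom, spec$blink_len_frames),
          spec$open_level + rev(frac) * (bottom - spec$open_level)
        )
        x[starts[i]:(starts[i] + width - 1L)] <- profile
      }
      bottom_start <- starts + ramp
      truth_events <- data.frame(
        start_frame = bottom_start - 1L, # 0-based
        end_frame = bottom_start + spec$blink_len_frames - 2L,
        kind = kinds
      )
    }
    if (spec$noise_sd > 0) {
      x <- pmax(0, x + stats::rnorm(n_frames, 0, spec$noise_sd))
    }
    if (!is.null(spec$dropout_runs)) {
      for (i in seq_len(nrow(spec$dropout_runs))) {
        s <- spec$dropout_runs$start_frame[i] + 1L
        e <- min(n_frames, s + spec$dropout_runs$length[i] - 1L)
        if (s <= n_frames) x[s:e] <- NA_real_
      }
    }
    structure(
      list(
        series = ear_series(x, fps = spec$fps),
        truth = list(
          events = truth_events,
          n_full = spec$n_full, n_partial = spec$n_partial
        ),
        spec = spec
      ),
      class = "synthetic_recording"
    )
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %d frames, truth: %d full + %d partial (seed %d)\n",
    nrow(x$series), x$truth$n_full, x$truth$n_partial, x$spec$seed
  ))
  invisible(x)
}

#' Cohort-style presets for the synthetic generator
#'
#' Draws a [synthetic_spec()] whose blink counts emulate one of the two
#' pilot-cohort groups over a one-minute recording: controls averaged 22.2
#' full and 2.5 partial blinks per minute (full rates ranging 10-31), DED
#' patients 37.4 full and 5.8 partial per minute (full rates 13-64). Counts
#' are drawn from normals at the group means, rounded and clamped into the
#' preset ranges; all shape parameters keep their defaults.
#'
#' @param kind `"control"` or `"ded"`.
#' @param seed integer seed; drives both the count draw and the recording
#'   realisation.
#' @param noise_sd noise level forwarded to [synthetic_spec()].
#' @return a [synthetic_spec()].
#' @export
ded_profile <- function(kind = c("control", "ded"), seed = 1, noise_sd = 0.005) {
  kind <- match.arg(kind)
  with_private_seed(seed, {
    if (kind == "control") {
      n_full <- min(30L, max(15L, as.integer(round(stats::rnorm(1, 22.2, 5)))))
      n_partial <- min(8L, max(0L, as.integer(round(stats::rnorm(1, 2.5, 2)))))
    } else {
      n_full <- min(64L, max(13L, as.integer(round(stats::rnorm(1, 37.4, 12)))))
      n_partial <- min(14L, max(0L, as.integer(round(stats::rnorm(1, 5.8, 4)))))
    }
    synthetic_spec(
      n_full = n_full, n_partial = n_partial,
      noise_sd = noise_sd, seed = seed
    )
  })
}
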
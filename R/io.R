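# CSV dialect shared by all readers/writers: comma-separated, header row,
# UTF-8, "." decimal; a missing EAR is an empty cell.

# read.csv type-guesses a sex column that is all "F" into logical FALSE;
# undo that before validation.
fix_sex_column <- function(df) {
  if ("sex" %in% names(df) && is.logical(df$sex)) {
    df$sex <- ifelse(df$sex, "T", "F")
  }
  df
}

#' Read an EAR time-series CSV
#'
#' Dialect: columns `frame`, `timestamp`, `ear`; an empty `ear` cell marks a
#' missing frame. When the file has usable timestamps the frame rate is
#' inferred from them; otherwise `fps` must be supplied.
#'
#' @param path file path.
#' @param fps frame rate override/fallback.
#' @return an [ear_series].
#' @export
read_ear_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty recording: ", path, " has no data rows")
  if (!"ear" %in% names(df)) stop("malformed EAR file ", path, ": no `ear` column")
  ts <- if ("timestamp" %in% names(df) && sum(!is.na(df$timestamp)) >= 2) df$timestamp else NULL
  frame <- if ("frame" %in% names(df)) as.integer(df$frame) - min(as.integer(df$frame)) else NULL
  if (is.null(fps) && is.null(ts)) {
    stop("`fps` is required: ", path, " has no usable timestamp column")
  }
  ear_series(as.numeric(df$ear), fps = fps, timestamp = ts, frame = frame)
}

#' Write an EAR time-series CSV
#'
#' @param series an [ear_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @rdname read_ear_csv
#' @export
write_ear_csv <- function(series, path) {
  stopifnot(inherits(series, "ear_series"))
  df <- as.data.frame(series)
  # %.17g keeps the round-trip lossless for doubles
  num <- function(v) ifelse(is.na(v), NA, formatC(v, digits = 17, format = "g"))
  df$timestamp <- num(df$timestamp)
  df$ear <- num(df$ear)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read per-frame eye landmarks
#'
#' CSV dialect: one row per eye per frame with columns `frame`, `timestamp`,
#' `eye` (`"left"`/`"right"`), `p1x`,`p1y`,...,`p6x`,`p6y`, `valid`. The JSON
#' dialect is an array of objects with the same fields. Any function mapping
#' a video to this table (e.g. a face-landmark detector adapter) can feed
#' [build_series()].
#'
#' @param path file path; format chosen by extension (`.json` vs anything
#'   else as CSV).
#' @return a data frame in the landmark dialect.
#' @export
read_landmark_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) stop("empty recording: ", path, " has no landmark rows")
  coord_cols <- as.vector(t(outer(paste0("p", 1:6), c("x", "y"), paste0)))
  missing_cols <- setdiff(c("frame", "eye", coord_cols), names(df))
  if (length(missing_cols)) {
    stop(
      "malformed landmark file ", path, ": missing column(s) ",
      paste(missing_cols, collapse = ", ")
    )
  }
  bad <- which(!df$eye %in% c("left", "right"))
  if (length(bad)) {
    stop("malformed landmark file ", path, ": bad `eye` value at row ", bad[1])
  }
  df
}

#' @rdname read_landmark_file
#' @export
read_landmark_csv <- read_landmark_file

#' Read questionnaire records
#'
#' CSV or JSON with fields `id`, `age`, `sex`, `dry_gritty`,
#' `regular_contact_lens`. Each row is validated through
#' [questionnaire_record()]; a missing or invalid field raises an error
#' naming the field and row.
#'
#' @param path file path (`.json` or CSV).
#' @return a named list of [questionnaire_record()] objects.
#' @export
read_questionnaire <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df <- fix_sex_column(df)
  needed <- c("id", "age", "sex", "dry_gritty", "regular_contact_lens")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(
      "malformed questionnaire ", path, ": missing field(s) ",
      paste(missing_cols, collapse = ", ")
    )
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      questionnaire_record(
        df$age[i], df$sex[i], df$dry_gritty[i], df$regular_contact_lens[i]
      ),
      error = function(e) {
        stop("questionnaire row ", i, " (id ", df$id[i], "): ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
  })
  names(recs) <- as.character(df$id)
  recs
}

#' Read a cohort results CSV
#'
#' Dialect: columns `id`, `group`, `age`, `sex`, `full_rate`
#' (or `full_rate_per_min`), `partial_rate` (or `partial_rate_per_min`),
#' `eye_score`, `duration` (or `duration_s`); optional
#' `regular_contact_lens`, `dry_gritty`, `open_close_pct`. Column aliases
#' are normalised to the long names.
#'
#' @param path file path.
#' @return a cohort data frame (see [pilot_cohort()]).
#' @export
read_cohort_csv <- function(path) {
  df <- fix_sex_column(utils::read.csv(path, stringsAsFactors = FALSE))
  aliases <- c(
    full_rate = "full_rate_per_min", partial_rate = "partial_rate_per_min",
    duration = "duration_s"
  )
  for (short in names(aliases)) {
    if (short %in% names(df) && !aliases[[short]] %in% names(df)) {
      names(df)[names(df) == short] <- aliases[[short]]
    }
  }
  needed <- c(
    "id", "group", "age", "sex", "full_rate_per_min",
    "partial_rate_per_min", "eye_score", "duration_s"
  )
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(
      "malformed cohort file ", path, ": missing column(s) ",
      paste(missing_cols, collapse = ", ")
    )
  }
  df$group <- tolower(df$group)
  df
}

#' Write segmented blink events as CSV
#'
#' Columns: `start_frame`, `end_frame`, `n_frames`, `min_ear`, `kind`.
#'
#' @param events a `blink_events` data frame from [segment_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' All tunable knobs of the analysis pipeline, with their defaults. The
#' configuration is embedded in every report so a run can be reproduced
#' exactly.
#'
#' @param fps frame rate assumed when the input carries no timestamps.
#' @param combine eye-combination mode ([combine_eyes()]).
#' @param min_run minimum blink run length in frames.
#' @param threshold_mode `"dynamic"` (personalised dual thresholds, default)
#'   or `"fixed"` (single fixed threshold, full blinks only).
#' @param fixed_threshold EAR threshold used in fixed mode.
#' @param reference threshold comparison mode, see [threshold_pair()].
#' @param robust_summary,robust_probs robust-extrema options for
#'   [ear_summary()].
#' @param bridge_gap missing-frame bridging for run detection.
#' @param t_variant t-test variant for cohort comparisons.
#' @param seed integer seed recorded for simulation runs.
#' @param quiet suppress per-stage progress messages.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(fps = 30, combine = "mean", min_run = 3L,
                       threshold_mode = c("dynamic", "fixed"),
                       fixed_threshold = 0.163,
                       reference = c("absolute", "offset"),
                       robust_summary = FALSE, robust_probs = c(0.005, 0.995),
                       bridge_gap = 0L, t_variant = c("student", "welch"),
                       seed = NULL, quiet = FALSE) {
  structure(
    list(
      fps = fps, combine = combine, min_run = as.integer(min_run),
      threshold_mode = match.arg(threshold_mode),
      fixed_threshold = fixed_threshold,
      reference = match.arg(reference),
      robust_summary = robust_summary, robust_probs = robust_probs,
      bridge_gap = as.integer(bridge_gap),
      t_variant = match.arg(t_variant),
      seed = seed, quiet = quiet
    ),
    class = "run_config"
  )
}

#' Write a report (any list structure) as JSON
#'
#' @param report a list; S3 wrappers are unclassed recursively.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else {
      x <- unname(unclass(x))
    }
    x
  }
  jsonlite::write_json(strip(report), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
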
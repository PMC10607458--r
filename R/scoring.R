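#' Questionnaire record for the non-video score components
#'
#' Three of the five eye-healthiness-score components come from a short
#' questionnaire rather than the video: a dry/gritty feeling (clinically,
#' foreign body sensation), sex and age (women over 50 are the highest-risk
#' demographic for dry eye), and regular — not occasional — contact-lens
#' wear.
#'
#' @param age age in years (study eligibility requires >= 18).
#' @param sex `"F"` or `"M"`.
#' @param dry_gritty logical; persistent dry/gritty feeling.
#' @param regular_contact_lens logical; regular contact-lens wearer.
#' @return an object of class `questionnaire_record`.
#' @export
questionnaire_record <- function(age, sex, dry_gritty, regular_contact_lens) {
  for (fld in c("age", "sex", "dry_gritty", "regular_contact_lens")) {
    v <- get(fld)
    if (length(v) != 1 || is.na(v)) stop("questionnaire field `", fld, "` is missing")
  }
  sex <- toupper(as.character(sex))
  if (!sex %in% c("F", "M")) stop("questionnaire field `sex` must be \"F\" or \"M\"")
  if (!is.numeric(age) || age < 18) stop("questionnaire field `age` must be numeric and >= 18")
  structure(
    list(
      age = as.numeric(age), sex = sex,
      dry_gritty = isTRUE(as.logical(dry_gritty)),
      regular_contact_lens = isTRUE(as.logical(regular_contact_lens))
    ),
    class = "questionnaire_record"
  )
}

#' 10-point eye healthiness score
#'
#' Composite dry-eye risk score with five components:
#' full blink rate > 30/min (3 points), partial blink rate > 5/min
#' (3 points), dry/gritty feeling (2 points), woman over 50 years old
#' (1 point), regular contact-lens wearing (1 point). All rate and age
#' comparisons are strict, so a rate of exactly 30/min or an age of exactly
#' 50 scores nothing for that component.
#'
#' @param metrics a [compute_metrics()] result, or any list with
#'   `full_rate_per_min` and `partial_rate_per_min` (both per minute).
#' @param questionnaire a [questionnaire_record()] (a plain list with the
#'   same fields is coerced).
#' @return an object of class `score_breakdown`: per-component points and
#'   `total` in 0..10.
#' @examples
#' q <- questionnaire_record(56, "F", dry_gritty = FALSE, regular_contact_lens = TRUE)
#' eye_health_score(list(full_rate_per_min = 31, partial_rate_per_min = 3), q)$total # 5
#' @export
eye_health_score <- function(metrics, questionnaire) {
  if (!inherits(questionnaire, "questionnaire_record")) {
    questionnaire <- questionnaire_record(
      questionnaire$age, questionnaire$sex,
      questionnaire$dry_gritty, questionnaire$regular_contact_lens
    )
  }
  fr <- metrics$full_rate_per_min
  pr <- metrics$partial_rate_per_min
  if (!is.numeric(fr) || !is.numeric(pr) || is.na(fr) || is.na(pr) || fr < 0 || pr < 0) {
    stop("invalid metrics: per-minute blink rates must be non-negative numbers")
  }
  b <- list(
    blink_points = if (fr > 30) 3L else 0L,
    partial_points = if (pr > 5) 3L else 0L,
    gritty_points = if (questionnaire$dry_gritty) 2L else 0L,
    woman_over_50_points =
      if (questionnaire$sex == "F" && questionnaire$age > 50) 1L else 0L,
    lens_points = if (questionnaire$regular_contact_lens) 1L else 0L
  )
  b$total <- b$blink_points + b$partial_points + b$gritty_points +
    b$woman_over_50_points + b$lens_points
  structure(b, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "<score_breakdown> blink %d + partial %d + gritty %d + woman>50 %d + lens %d = %d/10\n",
    x$blink_points, x$partial_points, x$gritty_points,
    x$woman_over_50_points, x$lens_points, x$total
  ))
  invisible(x)
}

#' DED category for a total score
#'
#' Maps the 10-point total to a screening category: 0-3 normal, 4-6 mild DED
#' (the app raises an alert at >= 4), 7-10 severe DED (a doctor's visit is
#' recommended to confirm the diagnosis).
#'
#' @param total score in 0..10.
#' @return `"NORMAL"`, `"MILD_DED"` or `"SEVERE_DED"`.
#' @export
categorize_score <- function(total) {
  if (!is.numeric(total) || length(total) != 1 || is.na(total) ||
      total < 0 || total > 10) {
    stop("invalid score: `total` must be a single number in 0..10")
  }
  if (total < 4) "NORMAL" else if (total < 7) "MILD_DED" else "SEVERE_DED"
}

#' Full eye-health screening report
#'
#' Combines the score breakdown, its category, the alert flag (raised at
#' total >= 4, i.e. mild DED or worse) and an echo of the inputs.
#'
#' @inheritParams eye_health_score
#' @return an object of class `eye_health_report`: list with `breakdown`,
#'   `total`, `category`, `alert`, `metrics`, `questionnaire`.
#' @export
eye_health_report <- function(metrics, questionnaire) {
  breakdown <- eye_health_score(metrics, questionnaire)
  structure(
    list(
      breakdown = breakdown,
      total = breakdown$total,
      category = categorize_score(breakdown$total),
      alert = breakdown$total >= 4,
      metrics = metrics,
      questionnaire = questionnaire
    ),
    class = "eye_health_report"
  )
}

#' @export
print.eye_health_report <- function(x, ...) {
  cat(sprintf(
    "<eye_health_report> total %d/10 -> %s%s\n",
    x$total, x$category, if (x$alert) " [ALERT]" else ""
  ))
  print(x$breakdown)
  invisible(x)
}
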
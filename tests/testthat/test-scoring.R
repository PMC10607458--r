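rates <- function(full, partial) {
  list(full_rate_per_min = full, partial_rate_per_min = partial)
}

test_that("score reproduces the published per-participant totals", {
  # high full rate, woman over 50, lens wearer
  b7 <- eye_health_score(rates(31, 3), questionnaire_record(56, "F", FALSE, TRUE))
  expect_equal(b7$total, 5L)
  expect_equal(b7$blink_points, 3L)
  expect_equal(b7$woman_over_50_points, 1L)
  expect_equal(b7$lens_points, 1L)
  # high partial rate, woman over 50
  expect_equal(
    eye_health_score(rates(23, 8), questionnaire_record(53, "F", FALSE, FALSE))$total, 4L
  )
  # nothing elevated
  expect_equal(
    eye_health_score(rates(10, 1), questionnaire_record(58, "M", FALSE, FALSE))$total, 0L
  )
  # every component met -> full 10 points
  expect_equal(
    eye_health_score(rates(31, 6), questionnaire_record(56, "F", TRUE, TRUE))$total, 10L
  )
})

test_that("rate and age thresholds are strict inequalities", {
  q50 <- questionnaire_record(50, "F", FALSE, FALSE)
  q51 <- questionnaire_record(51, "F", FALSE, FALSE)
  expect_equal(eye_health_score(rates(30, 5), q50)$total, 0L) # all boundaries score zero
  expect_equal(eye_health_score(rates(30.01, 5), q50)$blink_points, 3L)
  expect_equal(eye_health_score(rates(30, 5.01), q50)$partial_points, 3L)
  expect_equal(eye_health_score(rates(30, 5), q51)$woman_over_50_points, 1L)
  # age alone never scores for men
  expect_equal(
    eye_health_score(rates(30, 5), questionnaire_record(90, "M", FALSE, FALSE))$total, 0L
  )
})

test_that("score equals the sum-of-indicators oracle on the boundary grid", {
  grid <- expand.grid(
    full = c(30, 30.01), partial = c(5, 5.01), age = c(50, 51),
    sex = c("F", "M"), gritty = c(FALSE, TRUE), lens = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- eye_health_score(
      rates(g$full, g$partial),
      questionnaire_record(g$age, g$sex, g$gritty, g$lens)
    )$total
    expect_equal(got, oracle_score(g$full, g$partial, g$age, g$sex, g$gritty, g$lens))
  }
})

test_that("score is monotone in every component", {
  set.seed(31)
  for (i in 1:40) {
    full <- runif(1, 0, 60); partial <- runif(1, 0, 15); age <- runif(1, 18, 90)
    sex <- sample(c("F", "M"), 1)
    gritty <- sample(c(TRUE, FALSE), 1); lens <- sample(c(TRUE, FALSE), 1)
    base <- eye_health_score(rates(full, partial), questionnaire_record(age, sex, gritty, lens))$total
    expect_gte(
      eye_health_score(rates(full + 10, partial), questionnaire_record(age, sex, gritty, lens))$total,
      base
    )
    expect_gte(
      eye_health_score(rates(full, partial + 5), questionnaire_record(age, sex, gritty, lens))$total,
      base
    )
    expect_gte(
      eye_health_score(rates(full, partial), questionnaire_record(age, sex, TRUE, TRUE))$total,
      base
    )
  }
})

test_that("categories split at 4 and 7", {
  expect_equal(categorize_score(0), "NORMAL")
  expect_equal(categorize_score(3), "NORMAL")
  expect_equal(categorize_score(4), "MILD_DED")
  expect_equal(categorize_score(6), "MILD_DED")
  expect_equal(categorize_score(7), "SEVERE_DED")
  expect_equal(categorize_score(10), "SEVERE_DED")
  expect_error(categorize_score(11), "invalid score")
  expect_error(categorize_score(-1), "invalid score")
})

test_that("every attainable score has a defined category", {
  grid <- expand.grid(
    full = c(0, 40), partial = c(0, 10), age = c(30, 60),
    sex = c("F", "M"), gritty = c(FALSE, TRUE), lens = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    total <- eye_health_score(
      rates(g$full, g$partial),
      questionnaire_record(g$age, g$sex, g$gritty, g$lens)
    )$total
    expect_true(categorize_score(total) %in% c("NORMAL", "MILD_DED", "SEVERE_DED"))
  }
})

test_that("reports carry category and the mild-DED alert flag", {
  rep7 <- eye_health_report(rates(31, 3), questionnaire_record(56, "F", FALSE, TRUE))
  expect_equal(rep7$category, "MILD_DED")
  expect_true(rep7$alert)
  rep0 <- eye_health_report(rates(0, 0), questionnaire_record(30, "M", FALSE, FALSE))
  expect_equal(rep0$category, "NORMAL")
  expect_false(rep0$alert)
  rep10 <- eye_health_report(rates(40, 9), questionnaire_record(60, "F", TRUE, TRUE))
  expect_equal(rep10$category, "SEVERE_DED")
})

test_that("invalid inputs are rejected with named fields", {
  expect_error(eye_health_score(rates(-1, 0), questionnaire_record(30, "F", FALSE, FALSE)), "invalid metrics")
  expect_error(questionnaire_record(17, "F", FALSE, FALSE), "age")
  expect_error(questionnaire_record(30, "X", FALSE, FALSE), "sex")
  expect_error(questionnaire_record(30, "F", NA, FALSE), "dry_gritty")
})
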
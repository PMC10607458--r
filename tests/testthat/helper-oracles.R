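# Independent oracles kept deliberately naive: explicit loops and
# sum-of-indicator arithmetic, no shared code with the implementation.

# brute-force maximal-run blink counter
oracle_count_runs <- function(x, threshold, min_run = 3) {
  count <- 0; run <- 0
  for (v in x) {
    if (!is.na(v) && v <= threshold) {
      run <- run + 1
    } else {
      if (run >= min_run) count <- count + 1
      run <- 0
    }
  }
  if (run >= min_run) count <- count + 1
  count
}

# sum-of-indicators eye healthiness score
oracle_score <- function(full, partial, age, sex, gritty, lens) {
  3 * (full > 30) + 3 * (partial > 5) + 2 * gritty +
    1 * (sex == "F" && age > 50) + 1 * lens
}

# closed-form pooled-variance two-sample t statistic and p-value
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# shorthand series constructor for tests
es <- function(x, fps = 30) ear_series(x, fps = fps)

# landmark table row for one eye on one frame, at a prescribed EAR
landmark_row <- function(frame, eye, ear, valid = TRUE, width = 4) {
  lm <- landmarks_for_ear(ear, width = width)
  row <- data.frame(frame = frame, timestamp = NA_real_, eye = eye, valid = valid)
  for (i in 1:6) {
    row[[paste0("p", i, "x")]] <- lm[i, 1]
    row[[paste0("p", i, "y")]] <- lm[i, 2]
  }
  row
}
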
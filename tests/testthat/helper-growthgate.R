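# Shared fixtures and independent oracles, built in code at test time.

# Small hand-rolled record table; gaps are injected by the callers.
make_records <- function(n = 5, age = 30, height = 165, gender = "male") {
  health_records(data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    visit_date = rep("2018-05-01", n),
    age = rep_len(age, n),
    gender = rep_len(gender, n),
    height_cm = rep_len(height, n),
    weight_kg = 62, bmi = 23.5, waist_cm = 80, hip_cm = 92,
    validated = TRUE,
    stringsAsFactors = FALSE))
}

random_records <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("R%04d", sample.int(9999, n, replace = TRUE)),
    visit_date = as.character(as.Date("2015-01-01") + sample.int(2000, n, TRUE)),
    age = sample(15:95, n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE),
    height_cm = round(runif(n, 130, 200), 1),
    weight_kg = round(runif(n, 35, 120), 1),
    bmi = round(runif(n, 12, 50), 1),
    waist_cm = round(runif(n, 50, 150), 1),
    hip_cm = round(runif(n, 60, 160), 1),
    validated = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
  health_records(df, source_label = "random-fixture")
}

# Independent naive reimplementation of the two-breakpoint search: double
# loop, normal equations solved directly, first strict minimum wins.
naive_two_breakpoints <- function(ages, values, weights = rep(1, length(ages)),
                                  candidates = c(25, 95), min_seg_len = 5) {
  best <- NULL
  for (b1 in candidates[1]:candidates[2]) {
    for (b2 in candidates[1]:candidates[2]) {
      if (b1 - min(ages) < min_seg_len) next
      if (b2 - b1 < min_seg_len) next
      if (max(ages) - b2 < min_seg_len) next
      X <- cbind(1, ages, pmax(ages - b1, 0), pmax(ages - b2, 0))
      W <- diag(weights)
      beta <- tryCatch(solve(t(X) %*% W %*% X, t(X) %*% W %*% values),
                       error = function(e) NULL)
      if (is.null(beta)) next
      r <- values - X %*% beta
      sse <- sum(weights * r^2)
      if (is.null(best) || sse < best$sse * (1 - 1e-8) - 1e-12) {
        best <- list(b1 = b1, b2 = b2, sse = sse)
      }
    }
  }
  best
}

# Closed-form local regression oracle: tricube-times-point-weight WLS
# polynomial through all points, evaluated at x0 (the span-1 case).
tricube_wls_at <- function(x, y, w, x0, degree) {
  d <- abs(x - x0)
  h <- max(d)
  tri <- (1 - pmin(d / h, 1)^3)^3
  wt <- tri * w
  X <- outer(x - x0, 0:degree, `^`)
  beta <- solve(t(X) %*% diag(wt) %*% X, t(X) %*% diag(wt) %*% y)
  beta[1]
}

total_variation <- function(y) sum(abs(diff(y)))
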
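build_test_model <- function(n = 6000, seed = 14) {
  preprocess_pipeline(generate_cohort(n = n, seed = seed)) |>
    build_reference()
}

test_that("reference band at a grid age is exactly the smoothed outer curves", {
  m <- build_test_model()
  q <- m$curves
  age <- q$ages[5]
  b <- band_from_reference(m, age)
  expect_equal(b$lower, unname(q$smoothed[match(5, q$levels),
                                          as.character(age)]))
  expect_equal(b$upper, unname(q$smoothed[match(95, q$levels),
                                          as.character(age)]))
  expect_equal(b$source, "cohort_reference")
  expect_lt(b$lower, b$upper)
})

test_that("bands interpolate linearly between grid ages", {
  m <- build_test_model()
  q <- m$curves
  # drop one age from the grid to force interpolation at it
  keep <- q$ages != 30
  m2 <- m
  m2$curves$ages <- q$ages[keep]
  m2$curves$smoothed <- q$smoothed[, keep]
  i <- which(m2$curves$ages == 29)
  b29 <- band_from_reference(m2, 29)
  b31 <- band_from_reference(m2, 31)
  b30 <- band_from_reference(m2, 30)
  expect_equal(b30$lower, (b29$lower + b31$lower) / 2, tolerance = 1e-12)
  expect_equal(b30$upper, (b29$upper + b31$upper) / 2, tolerance = 1e-12)
})

test_that("ages beyond the per-age grid fall back to the enclosing 5-year bin", {
  m <- build_test_model(n = 2000, seed = 15)
  beyond <- max(m$curves$ages) + 1
  if (beyond <= 100) {
    b <- band_from_reference(m, beyond)
    bin <- findInterval(beyond, m$binned$lower)
    lo <- unname(m$binned$quantiles[1, bin])
    hi <- unname(m$binned$quantiles[nrow(m$binned$quantiles), bin])
    if (m$binned$counts[bin] > 0 && !is.na(lo) && !is.na(hi) && lo < hi) {
      expect_equal(b$lower, lo)
      expect_equal(b$upper, hi)
    } else {
      # a bin too thin to define a proper band yields no reference band
      expect_null(b)
    }
  }
  expect_error(band_from_reference(m, 17), "unsupported age")
})

test_that("cohort bands for young adults approximate the generating percentiles", {
  m <- build_test_model(n = 14000, seed = 16)
  gen <- adult_male_preset()
  want_lo <- 163 + qnorm(0.05) * gen$noise_sd
  want_hi <- 163 + qnorm(0.95) * gen$noise_sd
  for (age in c(25, 35, 45)) {
    b <- band_from_reference(m, age)
    expect_equal(b$lower, want_lo, tolerance = 0.01)  # within ~1.5 cm
    expect_equal(b$upper, want_hi, tolerance = 0.01)
  }
})

test_that("history bands need k validated priors and use the median centre", {
  h <- make_records(3, age = c(50, 52, 54), height = c(164, 165, 166))
  expect_null(band_from_history(h[h$validated == FALSE, ], "height_cm"))
  b <- band_from_history(h, "height_cm")
  expect_equal(b$lower, 165 - 3)
  expect_equal(b$upper, 165 + 3)
  expect_equal(b$source, "personal_history")
  # relative tolerance for weight
  bw <- band_from_history(h, "weight_kg")
  expect_equal(bw$lower, 62 * 0.9)
  expect_equal(bw$upper, 62 * 1.1)
})

test_that("the decline allowance extends the lower bound by elapsed years x slope", {
  h <- make_records(1, age = 66, height = 165)
  seg <- structure(list(b1 = 49, b2 = 64, slopes = c(0, -0.1, -0.5),
                        labels = c("stable", "slow_decline", "sharp_decline")),
                   class = "age_segments")
  b <- band_from_history(h, "height_cm", age = 70, segments = seg)
  expect_equal(b$lower, 162 - 4 * 0.5)
  expect_equal(b$upper, 168)   # upper bound is not widened
})

test_that("resolve_band walks the hierarchy and never exceeds global bounds", {
  m <- build_test_model(n = 3000, seed = 18)
  h <- make_records(2, age = c(40, 42), height = 165)
  b1 <- resolve_band(history = h, model = m, age = 43)
  expect_equal(b1$source, "personal_history")
  b2 <- resolve_band(history = NULL, model = m, age = 43)
  expect_equal(b2$source, "cohort_reference")
  b3 <- resolve_band(history = NULL, model = NULL, age = 43)
  expect_equal(b3$source, "global_bounds")
  # under-age requests fall through to global bounds rather than failing
  b4 <- resolve_band(history = NULL, model = m, age = 15)
  expect_equal(b4$source, "global_bounds")
  gb <- plausibility_bounds()$height_cm
  for (b in list(b1, b2, b3, b4)) {
    expect_gte(b$lower, gb[1])
    expect_lte(b$upper, gb[2])
  }
})

test_that("gate decisions respect the closed band and flag unit errors", {
  band <- structure(list(measure = "height_cm", lower = 148, upper = 178,
                         source = "cohort_reference", band_levels = c(5, 95)),
                    class = "acceptance_band")
  rec <- make_records(1, height = 163)
  d <- check_entry(rec, list(height_cm = band))
  expect_equal(d$status, "accepted")
  rec$height_cm <- 64    # 163 cm keyed in as inches
  d2 <- check_entry(rec, list(height_cm = band))
  expect_equal(d2$status, "suspicious")
  expect_equal(d2$reason, "below lower bound")
  rec$height_cm <- 148   # boundary value is accepted
  expect_equal(check_entry(rec, list(height_cm = band))$status, "accepted")
})

test_that("the gate flags about 10 percent of clean data with the 5-95 band", {
  m <- build_test_model(n = 14000, seed = 19)
  fresh <- generate_cohort(n = 10000, seed = 20)
  dec <- gate_records(fresh, m)
  rate <- mean(dec$status == "suspicious")
  expect_gt(rate, 0.07)
  expect_lt(rate, 0.135)
})

test_that("cm-to-inch corruptions are essentially always detected", {
  m <- build_test_model(n = 8000, seed = 21)
  clean <- generate_cohort(n = 2000, seed = 22)
  gen <- adult_male_preset()
  gen$error_rate <- 1
  gen$error_mix <- c(unit_cm_to_inch = 1, digit_transpose = 0,
                     offset_100 = 0, keystroke = 0)
  bad <- inject_errors(clean, gen, seed = 23)
  dec <- gate_records(bad$records, m)
  expect_equal(mean(dec$status == "suspicious"), 1)
})

test_that("update_reference accumulates below batch size and rebuilds when forced", {
  m <- build_test_model(n = 2000, seed = 24)
  extra <- generate_cohort(n = 100, seed = 25)
  m2 <- update_reference(m, extra, batch_size = 500)
  expect_equal(m2$version, m$version)
  expect_equal(m2$pending, 100L)
  expect_equal(m2$curves$raw, m$curves$raw)   # curves untouched
  # forced rebuild with zero new records: identical curves, version + 1
  m3 <- update_reference(m, health_records(data.frame(patient_id = character())),
                         force = TRUE)
  expect_equal(m3$version, m$version + 1L)
  expect_equal(m3$curves$raw, m$curves$raw, tolerance = 1e-12)
  expect_equal(m3$previous$version, m$version)
  # threshold crossing triggers a rebuild that folds the new records in
  m4 <- update_reference(m, extra, batch_size = 100)
  expect_equal(m4$version, m$version + 1L)
  expect_equal(m4$n_total, 2100L, ignore_attr = TRUE)
  expect_equal(m4$pending, 0L)
})

test_that("update_reference rejects mismatched gender and unvalidated records", {
  m <- build_test_model(n = 1000, seed = 26)
  bad <- make_records(2, gender = "female")
  expect_error(update_reference(m, bad), "gender")
  unval <- make_records(2)
  unval$validated <- FALSE
  expect_error(update_reference(m, unval), "validated")
})

test_that("rebuilding with more data from the same population tightens the curves", {
  gen <- adult_male_preset()
  small <- preprocess_pipeline(generate_cohort(gen, n = 1500, seed = 27))
  m <- build_reference(small)
  big_batch <- generate_cohort(gen, n = 12000, seed = 28)
  m2 <- update_reference(m, big_batch, force = TRUE)
  err <- function(model) {
    q <- model$curves
    sel <- q$ages >= 20 & q$ages <= 49
    mean(abs(q$smoothed[match(50, q$levels), sel] - 163))
  }
  expect_lt(err(m2), err(m))
})
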
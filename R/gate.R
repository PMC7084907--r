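#' Per-measure personal tolerances
#'
#' Tolerances applied around the median of a patient's own validated
#' history: height is near-constant between adult visits so gets an
#' absolute +/- 3 cm; mass-related measures legitimately vary and get
#' relative tolerances (weight +/- 10%, BMI +/- 15%, waist and hip
#' +/- 10%).
#'
#' @param height_cm Absolute tolerance in cm.
#' @param weight_kg,bmi,waist_cm,hip_cm Relative tolerances as fractions.
#' @return Named list with class `personal_tolerances`.
#' @export
personal_tolerances <- function(height_cm = 3, weight_kg = 0.10, bmi = 0.15,
                                waist_cm = 0.10, hip_cm = 0.10) {
  structure(list(height_cm = height_cm, weight_kg = weight_kg, bmi = bmi,
                 waist_cm = waist_cm, hip_cm = hip_cm),
            class = "personal_tolerances")
}

acceptance_band <- function(measure, lower, upper, source,
                            band_levels = NULL) {
  stopifnot(lower < upper)
  structure(list(measure = measure, lower = lower, upper = upper,
                 source = source, band_levels = band_levels),
            class = "acceptance_band")
}

#' @export
print.acceptance_band <- function(x, ...) {
  cat(sprintf("<acceptance_band> %s in [%.2f, %.2f] (%s)\n",
              x$measure, x$lower, x$upper, x$source))
  invisible(x)
}

#' Acceptance band from cohort reference curves
#'
#' Evaluates the smoothed lower/upper percentile curves of a reference model
#' at the given age. Ages between grid points are linearly interpolated;
#' ages outside the per-age grid but at least 20 use the enclosing five-year
#' bin. Returns `NULL` (so the caller can fall back) when the model carries
#' no information at that age.
#'
#' @param model A `reference_model`.
#' @param age Age in years, must be >= 20 (the reference scope starts at the
#'   end of natural growth).
#' @param band_levels `c(low, high)` percentile levels, default `c(5, 95)`;
#'   must be among the model's levels.
#' @return An `acceptance_band` with `source = "cohort_reference"`, or
#'   `NULL`.
#' @export
band_from_reference <- function(model, age, band_levels = c(5, 95)) {
  stopifnot(inherits(model, "reference_model"))
  if (is.na(age) || age < 20) {
    stop("unsupported age: reference curves cover ages >= 20", call. = FALSE)
  }
  q <- model$curves
  idx <- match(band_levels, q$levels)
  if (anyNA(idx)) stop("band levels must be among the model's levels",
                       call. = FALSE)
  if (age >= min(q$ages) && age <= max(q$ages)) {
    lo <- stats::approx(q$ages, q$smoothed[idx[1], ], xout = age)$y
    hi <- stats::approx(q$ages, q$smoothed[idx[2], ], xout = age)$y
    return(acceptance_band(q$measure, lo, hi, "cohort_reference", band_levels))
  }
  b <- model$binned
  bin <- findInterval(age, b$lower)
  if (bin >= 1 && bin <= length(b$bins) && b$counts[bin] > 0) {
    lo <- b$quantiles[idx[1], bin]
    hi <- b$quantiles[idx[2], bin]
    if (!is.na(lo) && !is.na(hi) && lo < hi) {
      return(acceptance_band(q$measure, lo, hi, "cohort_reference",
                             band_levels))
    }
  }
  NULL
}

#' Acceptance band from a patient's own history
#'
#' Centres a band on the median of the patient's validated prior values for
#' one measure: height gets an absolute tolerance, other measures a relative
#' one (see [personal_tolerances()]). When an `age_segments` object and the
#' current age are supplied, the lower bound is additionally widened
#' downward by the reference decline allowance — elapsed years since the
#' last validated visit times the (negative) reference slope at the current
#' age — so that genuine ageing-related height loss is not flagged.
#'
#' @param history `health_records` rows of one patient, sorted by
#'   `visit_date`.
#' @param measure Measure column name.
#' @param tol A [personal_tolerances()] object.
#' @param k Minimum number of validated prior values required (default 1).
#' @param age Current age in years (needed for the decline allowance).
#' @param segments Optional `age_segments` from [segment_reference()].
#' @return An `acceptance_band` with `source = "personal_history"`, or
#'   `NULL` when fewer than `k` validated prior values exist.
#' @export
band_from_history <- function(history, measure = "height_cm",
                              tol = personal_tolerances(), k = 1,
                              age = NULL, segments = NULL) {
  ok <- history$validated & !is.na(history[[measure]])
  if (sum(ok) < k) return(NULL)
  vals <- history[[measure]][ok]
  centre <- stats::median(vals)
  t <- tol[[measure]]
  half <- if (measure == "height_cm") t else t * centre
  lower <- centre - half
  upper <- centre + half
  if (!is.null(segments) && !is.null(age)) {
    last_age <- history$age[ok][length(vals)]
    elapsed <- age - last_age
    if (!is.na(elapsed) && elapsed > 0) {
      slope <- segment_slope_at(segments, age)
      if (slope < 0) lower <- lower + elapsed * slope
    }
  }
  acceptance_band(measure, lower, upper, "personal_history")
}

# Reference slope (units/year) of the segment containing the given age.
segment_slope_at <- function(segments, age) {
  if (age <= segments$b1) segments$slopes[1]
  else if (age <= segments$b2) segments$slopes[2]
  else segments$slopes[3]
}

#' Resolve the acceptance band for one patient and measure
#'
#' Fallback hierarchy: personal history when enough validated prior values
#' exist, else the gender/age cohort reference, else the global
#' plausibility bounds. The winning band is always intersected with the
#' global bounds, so the result can never be wider than what is physically
#' plausible; the hierarchy is total — it never fails.
#'
#' @param history `health_records` for the patient (may be empty or `NULL`).
#' @param model A `reference_model` or `NULL`.
#' @param age Current age in years.
#' @param measure Measure column name.
#' @param bounds Global [plausibility_bounds()].
#' @param band_levels Reference band percentiles, default `c(5, 95)`.
#' @param tol,k,segments Passed to [band_from_history()].
#' @return An `acceptance_band`.
#' @export
resolve_band <- function(history = NULL, model = NULL, age,
                         measure = "height_cm",
                         bounds = plausibility_bounds(),
                         band_levels = c(5, 95),
                         tol = personal_tolerances(), k = 1,
                         segments = NULL) {
  band <- NULL
  if (!is.null(history) && nrow(history) > 0) {
    band <- band_from_history(history, measure, tol = tol, k = k, age = age,
                              segments = segments)
  }
  if (is.null(band) && !is.null(model) && !is.na(age) && age >= 20) {
    band <- band_from_reference(model, age, band_levels)
  }
  gb <- bounds[[measure]]
  if (is.null(band)) {
    return(acceptance_band(measure, gb[1], gb[2], "global_bounds"))
  }
  band$lower <- max(band$lower, gb[1])
  band$upper <- min(band$upper, gb[2])
  band
}

#' Gate one record's measurements against resolved bands
#'
#' One decision per measure present on the record: the value is `accepted`
#' iff it lies inside the closed band, otherwise `suspicious` with a reason
#' naming the violated side. Suspicious entries are never altered — the gate
#' only flags them for re-examination by the healthcare worker.
#'
#' @param record A single-row `health_records` (or one-row data frame).
#' @param bands Named list of `acceptance_band`s, keyed by measure.
#' @return A data frame of decisions: `patient_id`, `measure`, `value`,
#'   `lower`, `upper`, `source`, `status`, `reason`.
#' @export
check_entry <- function(record, bands) {
  stopifnot(nrow(record) == 1)
  out <- lapply(names(bands), function(m) {
    v <- record[[m]]
    if (is.null(v) || is.na(v)) return(NULL)
    b <- bands[[m]]
    status <- if (v >= b$lower && v <= b$upper) "accepted" else "suspicious"
    reason <- if (status == "accepted") ""
      else if (v < b$lower) "below lower bound" else "above upper bound"
    data.frame(patient_id = record$patient_id, measure = m, value = v,
               lower = b$lower, upper = b$upper, source = b$source,
               status = status, reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fold validated records into a reference model
#'
#' Appends preprocessed, validated records to the model's retained cohort.
#' Curves are rebuilt (a full rebuild, not incremental maintenance) once the
#' accumulated new records reach `batch_size`, or immediately when `force =
#' TRUE`; otherwise only the pending counter changes. On rebuild the version
#' is incremented and the previous model (curves and metadata, without its
#' own record payload) is retained under `$previous` for audit.
#'
#' @param model A `reference_model`.
#' @param new_records `health_records` of validated records, same gender as
#'   the model.
#' @param batch_size Rebuild threshold, default 500.
#' @param force Rebuild now regardless of the threshold.
#' @return The updated `reference_model`.
#' @export
update_reference <- function(model, new_records, batch_size = 500,
                             force = FALSE) {
  stopifnot(inherits(model, "reference_model"))
  if (nrow(new_records) > 0) {
    if (any(is.na(new_records$gender)) ||
        any(new_records$gender != model$gender)) {
      stop("new records must match the model's gender (", model$gender, ")",
           call. = FALSE)
    }
    if (!all(new_records$validated)) {
      stop("only validated records may update the reference", call. = FALSE)
    }
    model$records <- rbind(as.data.frame(model$records)[record_columns()],
                           as.data.frame(new_records)[record_columns()])
    model$pending <- model$pending + nrow(new_records)
  }
  if (!force && model$pending < batch_size) return(model)
  cohort <- structure(list(records = health_records(model$records),
                           audit = NULL, drops = NULL, gender = model$gender,
                           age_range = range(model$records$age)),
                      class = "clean_cohort")
  cfg <- model$config
  rebuilt <- build_reference(cohort, measure = cfg$measure,
                             levels = cfg$levels, span = cfg$span,
                             degree = cfg$degree)
  rebuilt$version <- model$version + 1L
  prev <- model
  prev$records <- NULL
  prev$previous <- NULL
  rebuilt$previous <- prev
  rebuilt
}
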
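#' Plausibility bounds for anthropometric measures
#'
#' Closed per-measure intervals used to strip physically impossible entries
#' before any statistics. Defaults are deliberately wider than any attested
#' adult value so that only impossible entries (unit mix-ups, keying slips)
#' are cut; every bound is overridable.
#'
#' @param height_cm,weight_kg,bmi,waist_cm,hip_cm Length-2 numeric
#'   `c(low, high)` intervals in the measure's units.
#' @return A named list of intervals with class `plausibility_bounds`.
#' @export
plausibility_bounds <- function(height_cm = c(120, 210),
                                weight_kg = c(25, 250),
                                bmi = c(10, 70),
                                waist_cm = c(40, 200),
                                hip_cm = c(50, 200)) {
  b <- list(height_cm = height_cm, weight_kg = weight_kg, bmi = bmi,
            waist_cm = waist_cm, hip_cm = hip_cm)
  for (m in names(b)) {
    if (length(b[[m]]) != 2 || !is.numeric(b[[m]]) || b[[m]][1] >= b[[m]][2]) {
      stop("bound for '", m, "' must be numeric c(low, high) with low < high",
           call. = FALSE)
    }
  }
  structure(b, class = "plausibility_bounds")
}

drop_report <- function(rs, rows, step, reason) {
  if (!length(rows)) reason <- character(0)
  data.frame(row = rows,
             patient_id = if (length(rows)) rs$patient_id[rows] else character(),
             step = rep(step, length(rows)),
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Keep only records with all required measures present
#'
#' @param rs A `health_records` set.
#' @param required Character vector of measure names that must be non-missing.
#' @return `list(records, report)`: the survivors and a drop report naming,
#'   for each dropped row, the first missing measure.
#' @export
filter_complete <- function(rs, required = measure_columns()) {
  if (!length(required)) stop("'required' must be non-empty", call. = FALSE)
  unknown <- setdiff(required, measure_columns())
  if (length(unknown)) {
    stop("unknown measure name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rs) == 0) {
    return(list(records = rs, report = drop_report(rs, integer(), "complete",
                                                   character())))
  }
  miss <- vapply(required, function(m) is.na(rs[[m]]), logical(nrow(rs)))
  miss <- matrix(miss, nrow = nrow(rs))
  drop <- rowSums(miss) > 0
  first_missing <- apply(miss, 1, function(z) required[which(z)[1]])
  report <- drop_report(rs, which(drop), "complete",
                        paste0("missing ", unlist(first_missing[drop])))
  list(records = rs[!drop, , drop = FALSE], report = report)
}

#' Keep only records within an age window
#'
#' The window is closed on both sides; records with missing age are dropped
#' and reported with reason `"age_missing"`.
#'
#' @param rs A `health_records` set.
#' @param min_age,max_age Inclusive bounds in integer years (`max_age = Inf`
#'   for unbounded).
#' @return `list(records, report)`.
#' @export
filter_age <- function(rs, min_age = 20, max_age = Inf) {
  if (min_age < 0) stop("min_age must be >= 0", call. = FALSE)
  if (min_age > max_age) stop("min_age > max_age", call. = FALSE)
  age_na <- is.na(rs$age)
  out_of_range <- !age_na & (rs$age < min_age | rs$age > max_age)
  reason <- character(nrow(rs))
  reason[age_na] <- "age_missing"
  reason[out_of_range] <- "age_out_of_range"
  drop <- age_na | out_of_range
  report <- drop_report(rs, which(drop), "age", reason[drop])
  list(records = rs[!drop, , drop = FALSE], report = report)
}

#' Partition records by gender
#'
#' @param rs A `health_records` set.
#' @return `list(male, female, report)`: every record with known gender lands
#'   in exactly one of the two sets; unknown/missing-gender records are
#'   reported, not fatal.
#' @export
split_gender <- function(rs) {
  unknown <- is.na(rs$gender)
  report <- drop_report(rs, which(unknown), "gender", "gender_unknown")
  list(male = rs[!unknown & rs$gender == "male", , drop = FALSE],
       female = rs[!unknown & rs$gender == "female", , drop = FALSE],
       report = report)
}

#' Remove records with implausible measure values
#'
#' A record is kept iff every present measure lies inside its closed
#' plausibility interval; missing measures do not violate bounds.
#'
#' @param rs A `health_records` set.
#' @param bounds A [plausibility_bounds()] object.
#' @return `list(records, report)`; the report names the measure, value and
#'   violated bound for each dropped row.
#' @export
remove_outliers <- function(rs, bounds = plausibility_bounds()) {
  reason <- character(nrow(rs))
  for (m in intersect(measure_columns(), names(bounds))) {
    v <- rs[[m]]
    viol <- !is.na(v) & (v < bounds[[m]][1] | v > bounds[[m]][2])
    new <- viol & reason == ""
    reason[new] <- sprintf("%s=%g outside [%g, %g]", m, v[new],
                           bounds[[m]][1], bounds[[m]][2])
  }
  drop <- reason != ""
  report <- drop_report(rs, which(drop), "outlier", reason[drop])
  list(records = rs[!drop, , drop = FALSE], report = report)
}

#' Preprocess raw records into a clean, gendered cohort
#'
#' Applies, in order: completeness filtering, age filtering, gender
#' selection, and plausibility-bound outlier removal, recording an audit
#' trail `(step, n_in, n_kept, n_dropped)` for each step. At every step
#' `n_in = n_kept + n_dropped`, and consecutive steps chain.
#'
#' @param rs A `health_records` set.
#' @param gender Target cohort gender, `"male"` or `"female"`.
#' @param required Measures that must be present (default all five).
#' @param min_age,max_age Inclusive age window in years.
#' @param bounds A [plausibility_bounds()] object.
#' @return A `clean_cohort`: `list(records, audit, drops, gender, age_range)`.
#' @export
preprocess_pipeline <- function(rs, gender = "male",
                                required = measure_columns(),
                                min_age = 20, max_age = Inf,
                                bounds = plausibility_bounds()) {
  gender <- match.arg(gender, c("male", "female"))
  audit <- list()
  drops <- list()
  note <- function(step, n_in, n_kept) {
    audit[[length(audit) + 1]] <<- data.frame(
      step = step, n_in = n_in, n_kept = n_kept, n_dropped = n_in - n_kept,
      stringsAsFactors = FALSE)
  }

  s1 <- filter_complete(rs, required)
  note("complete", nrow(rs), nrow(s1$records)); drops[[1]] <- s1$report

  s2 <- filter_age(s1$records, min_age, max_age)
  note("age", nrow(s1$records), nrow(s2$records)); drops[[2]] <- s2$report

  s3 <- split_gender(s2$records)
  kept <- s3[[gender]]
  other <- setdiff(c("male", "female"), gender)
  rep3 <- rbind(s3$report,
                drop_report(s2$records,
                            which(!is.na(s2$records$gender) &
                                    s2$records$gender == other),
                            "gender", paste0("gender_", other)))
  note("gender", nrow(s2$records), nrow(kept)); drops[[3]] <- rep3

  s4 <- remove_outliers(kept, bounds)
  note("outlier", nrow(kept), nrow(s4$records)); drops[[4]] <- s4$report

  if (nrow(s4$records) == 0) stop("empty cohort after preprocessing",
                                  call. = FALSE)
  structure(list(records = s4$records,
                 audit = do.call(rbind, audit),
                 drops = do.call(rbind, drops),
                 gender = gender,
                 age_range = range(s4$records$age)),
            class = "clean_cohort")
}

#' @export
print.clean_cohort <- function(x, ...) {
  cat(sprintf("<clean_cohort> %s, n = %d, ages %d-%d\n", x$gender,
              nrow(x$records), x$age_range[1], x$age_range[2]))
  print(x$audit)
  invisible(x)
}
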
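#' Default percentile levels
#'
#' The seven CDC-style percentile levels used throughout: 5, 10, 25, 50, 75,
#' 90 and 95.
#'
#' @return Numeric vector of the seven levels.
#' @export
default_levels <- function() c(5, 10, 25, 50, 75, 90, 95)

# Pinned quantile rule: linear interpolation of order statistics with
# plotting position h = (n - 1) p + 1, i.e. stats::quantile type = 7.
q_rule <- function(x, levels) {
  stats::quantile(x, probs = levels / 100, type = 7, names = FALSE)
}

#' Per-age quantile and mean curves
#'
#' Computes, for each distinct age present in the cohort, the requested
#' percentiles (linear interpolation of order statistics, plotting position
#' `h = (n-1)p + 1`) and the arithmetic mean of one measure, together with
#' per-age sample counts. Ages absent from the cohort are absent from the
#' grid.
#'
#' @param cohort A `clean_cohort` from [preprocess_pipeline()].
#' @param measure Measure column name, e.g. `"height_cm"`.
#' @param levels Strictly increasing percentile levels in (0, 100).
#' @return A `quantile_curveset`: list with `measure`, `gender`, `ages`
#'   (increasing integer grid), `levels`, `raw` (levels x ages matrix),
#'   `smoothed` (`NULL` until [smooth_curveset()]), `mean_curve`, `counts`,
#'   `n_total` and `built_at`.
#' @export
per_age_quantiles <- function(cohort, measure = "height_cm",
                              levels = default_levels()) {
  stopifnot(inherits(cohort, "clean_cohort"))
  if (any(levels <= 0 | levels >= 100) || is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing and inside (0, 100)",
         call. = FALSE)
  }
  vals <- cohort$records[[measure]]
  if (is.null(vals) || all(is.na(vals))) {
    stop("measure '", measure, "' absent from all records", call. = FALSE)
  }
  keep <- !is.na(vals)
  vals <- vals[keep]
  ages <- cohort$records$age[keep]
  grid <- sort(unique(ages))
  by_age <- split(vals, factor(ages, levels = grid))
  raw <- vapply(by_age, q_rule, numeric(length(levels)), levels = levels)
  raw <- matrix(raw, nrow = length(levels),
                dimnames = list(paste0("p", levels), grid))
  structure(list(measure = measure, gender = cohort$gender,
                 ages = grid, levels = levels, raw = raw, smoothed = NULL,
                 mean_curve = vapply(by_age, mean, numeric(1)),
                 counts = vapply(by_age, length, integer(1)),
                 n_total = length(vals), built_at = Sys.time()),
            class = "quantile_curveset")
}

#' Locally weighted polynomial smoothing
#'
#' Classic loess-type smoother evaluated at the design points: at each `x[i]`
#' a polynomial of the given degree is fitted by weighted least squares over
#' the `ceiling(span * n)` nearest neighbours, with tricube distance weights
#' multiplied by the supplied point weights, and its value at `x[i]` is
#' returned. Zero robustness iterations; fully deterministic. When the local
#' design is degenerate (all neighbour `x` equal, or too few points carry
#' positive weight) the fit falls back to the local weighted mean and the
#' age is recorded in the `fallback` attribute.
#'
#' @param x Strictly increasing numeric vector of design points.
#' @param y Responses, same length as `x`.
#' @param w Non-negative point weights (e.g. per-age sample counts).
#' @param span Neighbourhood fraction in (0, 1]; `span * length(x)` must be
#'   at least `degree + 1`.
#' @param degree Local polynomial degree, 1 or 2.
#' @return Numeric vector of fitted values at `x`, with attribute `fallback`
#'   listing indices where the weighted-mean fallback was used.
#' @export
loess_smooth <- function(x, y, w = rep(1, length(x)), span = 0.75,
                         degree = 2) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n, all(w >= 0),
            degree %in% c(1, 2))
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  k <- ceiling(span * n)
  if (k < degree + 1) stop("span * length(x) must be >= degree + 1",
                           call. = FALSE)
  fitted <- numeric(n)
  fallback <- integer(0)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    nb <- order(d)[seq_len(k)]
    h <- max(d[nb])
    tric <- if (h > 0) {
      u <- d[nb] / h
      (1 - pmin(u, 1)^3)^3
    } else {
      rep(1, k)
    }
    wt <- tric * w[nb]
    ok <- wt > 0
    xs <- x[nb][ok] - x[i]
    if (sum(ok) >= degree + 1 && length(unique(xs)) >= degree + 1) {
      X <- stats::poly(xs, degree = degree, raw = TRUE, simple = TRUE)
      X <- cbind(1, X)
      fit <- stats::lm.wfit(X, y[nb][ok], wt[ok])
      fitted[i] <- fit$coefficients[1]
    } else if (any(ok)) {
      fitted[i] <- sum(wt[ok] * y[nb][ok]) / sum(wt[ok])
      fallback <- c(fallback, i)
    } else {
      fitted[i] <- mean(y[nb])
      fallback <- c(fallback, i)
    }
  }
  attr(fitted, "fallback") <- fallback
  fitted
}

#' Smooth all curves of a curve set and enforce non-crossing
#'
#' Smooths each percentile curve and the mean curve independently with
#' [loess_smooth()], using the per-age sample counts as point weights, then
#' enforces non-crossing by sorting the smoothed level values at each age
#' (levels keep their rank order). Every age where sorting changed anything
#' is recorded in the `crossing_fixed` attribute of the smoothed matrix.
#'
#' @param q A `quantile_curveset` with the raw part populated.
#' @param span,degree Passed to [loess_smooth()].
#' @return `q` with `smoothed` and `mean_smoothed` filled.
#' @export
smooth_curveset <- function(q, span = 0.75, degree = 2) {
  stopifnot(inherits(q, "quantile_curveset"))
  if (length(unique(q$ages)) < degree + 2) {
    stop("need at least degree + 2 distinct ages to smooth", call. = FALSE)
  }
  sm <- t(apply(q$raw, 1, function(y) {
    c(loess_smooth(q$ages, y, w = q$counts, span = span, degree = degree))
  }))
  dimnames(sm) <- dimnames(q$raw)
  crossed <- which(apply(sm, 2, is.unsorted))
  fixed_ages <- q$ages[crossed]
  sm <- apply(sm, 2, sort)
  sm <- matrix(sm, nrow = length(q$levels), dimnames = dimnames(q$raw))
  attr(sm, "crossing_fixed") <- fixed_ages
  q$smoothed <- sm
  q$mean_smoothed <- c(loess_smooth(q$ages, q$mean_curve, w = q$counts,
                                    span = span, degree = degree))
  q$span <- span
  q$degree <- degree
  q
}

#' Five-year binned quantiles
#'
#' Aggregates the cohort into the 17 closed-left five-year age groups
#' 20-24, 25-29, ..., 95-99, 100+ and computes per-bin percentiles (same
#' interpolation rule as [per_age_quantiles()]), mean and count. Empty bins
#' are present with count 0 and missing values.
#'
#' @inheritParams per_age_quantiles
#' @return A `binned_curveset`: list with `bins` (labels), `lower` (left
#'   edges), `quantiles` (levels x bins matrix), `mean_curve`, `counts`.
#' @export
bin_5yr <- function(cohort, measure = "height_cm", levels = default_levels()) {
  stopifnot(inherits(cohort, "clean_cohort"))
  edges <- c(seq(20, 100, by = 5), Inf)
  lo <- edges[seq_len(length(edges) - 2)]
  labels <- c(paste(lo, lo + 4, sep = "-"), "100+")
  vals <- cohort$records[[measure]]
  keep <- !is.na(vals)
  bin <- cut(cohort$records$age[keep], breaks = edges, right = FALSE,
             labels = labels)
  by_bin <- split(vals[keep], bin)
  qs <- vapply(by_bin, function(v) {
    if (length(v)) q_rule(v, levels) else rep(NA_real_, length(levels))
  }, numeric(length(levels)))
  qs <- matrix(qs, nrow = length(levels),
               dimnames = list(paste0("p", levels), labels))
  structure(list(bins = labels, lower = edges[-length(edges)], levels = levels,
                 quantiles = qs,
                 mean_curve = vapply(by_bin, function(v)
                   if (length(v)) mean(v) else NA_real_, numeric(1)),
                 counts = vapply(by_bin, length, integer(1))),
            class = "binned_curveset")
}

#' Build a reference model from a clean cohort
#'
#' Bundles the raw and smoothed per-age quantile curves, the five-year
#' binned curves, the build configuration and provenance into one
#' serializable model, and retains the cohort records so the model can be
#' rebuilt when validated records accumulate (see [update_reference()]).
#'
#' @inheritParams per_age_quantiles
#' @param span,degree Loess settings for [smooth_curveset()].
#' @return A `reference_model`.
#' @export
build_reference <- function(cohort, measure = "height_cm",
                            levels = default_levels(), span = 0.75,
                            degree = 2) {
  q <- per_age_quantiles(cohort, measure, levels)
  q <- smooth_curveset(q, span = span, degree = degree)
  structure(list(curves = q,
                 binned = bin_5yr(cohort, measure, levels),
                 config = list(measure = measure, levels = levels,
                               span = span, degree = degree,
                               gender = cohort$gender),
                 records = as.data.frame(cohort$records),
                 gender = cohort$gender,
                 n_total = q$n_total,
                 version = 1L,
                 pending = 0L,
                 built_at = Sys.time(),
                 previous = NULL),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %s %s, n = %d, v%d, ages %d-%d\n",
              x$gender, x$config$measure, x$n_total, x$version,
              min(x$curves$ages), max(x$curves$ages)))
  invisible(x)
}

#' Serialize a reference model to a text file
#'
#' Writes the model as human-diffable JSON: age grid, levels, raw and
#' smoothed curves, counts, binned curves, retained records and build
#' metadata. The volatile build timestamp is intentionally not serialized,
#' so identical inputs give byte-identical model files.
#'
#' @param model A `reference_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(model, path) {
  m <- unclass(model)
  m$built_at <- NULL
  m$curves <- unclass(m$curves)
  m$curves$built_at <- NULL
  m$crossing_fixed <- attr(m$curves$smoothed, "crossing_fixed")
  attr(m$curves$smoothed, "crossing_fixed") <- NULL
  m$binned <- unclass(m$binned)
  m$format <- "growthgate-reference-1"
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized reference model
#'
#' @param path Path written by [write_reference()].
#' @return A `reference_model` (with `built_at` set to `NA`).
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("cannot open '", path, "': no such file",
                               call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$format, "growthgate-reference-1")) {
    stop("'", path, "' is not a growthgate reference model", call. = FALSE)
  }
  m$format <- NULL
  lv <- m$curves$levels
  name_mat <- function(mat, cols) {
    mat <- matrix(as.numeric(mat), nrow = length(lv))
    dimnames(mat) <- list(paste0("p", lv), cols)
    mat
  }
  m$curves$raw <- name_mat(m$curves$raw, m$curves$ages)
  sm <- name_mat(m$curves$smoothed, m$curves$ages)
  attr(sm, "crossing_fixed") <- as.integer(unlist(m$crossing_fixed))
  m$crossing_fixed <- NULL
  m$curves$smoothed <- sm
  m$curves$counts <- unlist(m$curves$counts)
  m$curves$mean_curve <- unlist(m$curves$mean_curve)
  m$curves <- structure(m$curves, class = "quantile_curveset")
  m$binned$quantiles <- name_mat(m$binned$quantiles, m$binned$bins)
  m$binned$counts <- unlist(m$binned$counts)
  m$binned$mean_curve <- unlist(m$binned$mean_curve)
  m$binned <- structure(m$binned, class = "binned_curveset")
  m$records <- as.data.frame(m$records)
  m$built_at <- NA
  m$version <- as.integer(m$version)
  m$pending <- as.integer(m$pending)
  structure(m, class = "reference_model")
}
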
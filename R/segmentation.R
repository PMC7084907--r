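#' Exhaustive two-breakpoint piecewise-linear fit
#'
#' Searches all integer breakpoint pairs `(b1, b2)` inside `candidates`
#' (subject to every segment spanning at least `min_seg_len` years) and, for
#' each pair, fits a continuous piecewise-linear function by weighted least
#' squares on the basis `{1, a, (a - b1)+, (a - b2)+}`. Returns the global
#' minimizer of the weighted residual sum of squares; ties (within a 1e-8
#' relative tolerance) are broken in favour of the lexicographically
#' smallest `(b1, b2)`.
#'
#' @param ages Integer age vector (need not be consecutive).
#' @param values Curve values at `ages` (e.g. a smoothed mean height curve).
#' @param weights Non-negative weights, default per-point equal; reference
#'   builds pass per-age sample counts.
#' @param candidates Closed integer interval `c(lo, hi)` of admissible
#'   breakpoint ages.
#' @param min_seg_len Minimum span of each of the three segments, in years.
#' @return An `age_segments` object: `b1`, `b2`, `slopes` (three per-segment
#'   slopes in measure units per year), `sse`, `labels` (see
#'   [label_segments()]) and `fitted` values.
#' @export
fit_two_breakpoints <- function(ages, values, weights = NULL,
                                candidates = c(25, 95), min_seg_len = 5) {
  n <- length(ages)
  stopifnot(length(values) == n, n >= 4)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  a_min <- min(ages); a_max <- max(ages)
  lo1 <- max(candidates[1], a_min + min_seg_len)
  hi1 <- min(candidates[2], a_max - 2 * min_seg_len)
  feasible <- FALSE
  best <- NULL
  for (b1 in (if (lo1 <= hi1) lo1:hi1 else integer())) {
    lo2 <- b1 + min_seg_len
    hi2 <- min(candidates[2], a_max - min_seg_len)
    for (b2 in (if (lo2 <= hi2) lo2:hi2 else integer())) {
      feasible <- TRUE
      X <- cbind(1, ages, pmax(ages - b1, 0), pmax(ages - b2, 0))
      fit <- stats::lm.wfit(X, values, weights)
      sse <- sum(weights * fit$residuals^2)
      if (is.null(best) || sse < best$sse * (1 - 1e-8) - 1e-12) {
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        best <- list(b1 = b1, b2 = b2, sse = sse,
                     slopes = c(cf[2], cf[2] + cf[3], cf[2] + cf[3] + cf[4]),
                     fitted = fit$fitted.values)
      }
    }
  }
  if (!feasible) {
    stop("no admissible breakpoint pair under the given candidates/min_seg_len",
         call. = FALSE)
  }
  slopes <- unname(best$slopes)
  structure(list(b1 = best$b1, b2 = best$b2, slopes = slopes,
                 sse = best$sse, labels = label_segments(slopes),
                 fitted = unname(best$fitted),
                 candidates = candidates, min_seg_len = min_seg_len),
            class = "age_segments")
}

#' Label growth-pattern segments from their slopes
#'
#' Deterministic slope classification: `|s| <= t_stable` is `stable`
#' (boundary inclusive); a negative slope with `t_stable < |s| <= t_sharp`
#' is `slow_decline`; a negative slope with `|s| > t_sharp` is
#' `sharp_decline`; a positive slope above `t_stable` is `increase`.
#' Defaults (0.05, 0.3 cm/year) put the textbook adult rate of about 1 cm
#' per decade into `slow_decline` and reserve `sharp_decline` for the much
#' faster loss seen past the mid-sixties.
#'
#' @param slopes Numeric vector of per-segment slopes (units per year).
#' @param thresholds `c(t_stable, t_sharp)`, both positive, `t_stable <
#'   t_sharp`.
#' @return Character vector of labels, one per slope.
#' @export
label_segments <- function(slopes, thresholds = c(0.05, 0.3)) {
  t_stable <- thresholds[1]; t_sharp <- thresholds[2]
  stopifnot(t_stable > 0, t_sharp > t_stable)
  vapply(slopes, function(s) {
    if (abs(s) <= t_stable) "stable"
    else if (s > 0) "increase"
    else if (abs(s) <= t_sharp) "slow_decline"
    else "sharp_decline"
  }, character(1))
}

#' Segment a reference model's smoothed curve
#'
#' Pulls one curve (the mean by default, per the observation that the
#' average tracks the median) and the per-age counts out of a reference
#' model and runs [fit_two_breakpoints()] on a smoothed version of it.
#'
#' The curve handed to the breakpoint search is re-smoothed with a
#' local-*linear* loess (`degree = 1`, same span and count weights as the
#' model): since the model being fitted is piecewise-linear, local linear
#' smoothing is the matched choice — local quadratic smoothing at the
#' model's display settings displaces the upper knee by several years even
#' on a noiseless curve, because the quadratic neighbourhoods straddle the
#' corners. The model's stored band/display curves are unaffected.
#'
#' @param model A `reference_model`.
#' @param curve `"mean"` or a percentile level present in the model (e.g.
#'   `50`).
#' @param degree Local polynomial degree of the segmentation smoother,
#'   default 1 (see Details).
#' @param span Smoothing span, default the model's build span.
#' @param ... Passed to [fit_two_breakpoints()].
#' @return An `age_segments` object.
#' @export
segment_reference <- function(model, curve = "mean", degree = 1,
                              span = NULL, ...) {
  stopifnot(inherits(model, "reference_model"))
  q <- model$curves
  if (is.null(span)) span <- if (is.null(q$span)) 0.75 else q$span
  y <- if (identical(curve, "mean")) {
    q$mean_curve
  } else {
    lev <- as.numeric(curve)
    if (!lev %in% q$levels) stop("level ", curve, " not in model",
                                 call. = FALSE)
    q$raw[match(lev, q$levels), ]
  }
  w <- as.numeric(q$counts)
  sm <- c(loess_smooth(q$ages, unname(y), w = w, span = span,
                       degree = degree))
  fit_two_breakpoints(q$ages, sm, weights = w, ...)
}

#' @export
print.age_segments <- function(x, ...) {
  cat(sprintf("<age_segments> breakpoints %d / %d, sse = %.4g\n",
              x$b1, x$b2, x$sse))
  seg <- sprintf("  %s: slope %+.3f /yr [%s]",
                 c(sprintf("<= %d", x$b1),
                   sprintf("%d-%d", x$b1 + 1, x$b2),
                   sprintf("> %d", x$b2)),
                 x$slopes, x$labels)
  cat(seg, sep = "\n")
  invisible(x)
}
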
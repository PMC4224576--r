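#' Assemble per-frame records into per-group metric time series
#'
#' Groups per-frame records by the given tag columns, sorts each group by
#' time, and returns one series per group. Duplicate times within a group
#' are an error.
#'
#' @param records data.frame with a time column, the metric column, and any
#'   grouping tags.
#' @param metric name of the metric column.
#' @param time_col name of the time column (default `"time"`).
#' @param group_cols tag columns to group by (only those present are used).
#' @return list of `metric_series` objects: `times`, `values`, `metric`,
#'   `tags` (named list).
#' @export
build_series <- function(records, metric, time_col = "time",
                         group_cols = c("simulation", "leaflet")) {
  stopifnot(metric %in% names(records), time_col %in% names(records))
  group_cols <- intersect(group_cols, names(records))
  key <- if (length(group_cols))
    interaction(records[group_cols], drop = TRUE) else factor(rep(1, nrow(records)))
  lapply(split(records, key), function(r) {
    if (anyDuplicated(r[[time_col]]))
      stop("duplicate time within one series group for metric '", metric, "'")
    o <- order(r[[time_col]])
    tags <- as.list(r[1, group_cols, drop = FALSE])
    structure(list(times = r[[time_col]][o], values = r[[metric]][o],
                   metric = metric, tags = tags), class = "metric_series")
  })
}

#' Fit a power law L(t) ~ t^alpha on a time window
#'
#' Unweighted least squares of log(value) on log(time) over the window: the
#' slope is the coarsening exponent alpha, the exponentiated intercept the
#' prefactor. Regime windows are supplied by the user, not auto-detected.
#'
#' @param series a `metric_series` from [build_series()], or a list with
#'   `times` and `values`.
#' @param window `(t_start, t_end)`; default spans the whole series.
#' @return object of class `power_law_fit`: `alpha`, `prefactor`, `window`,
#'   `r_squared`, `n`.
#' @export
fit_power_law <- function(series, window = NULL) {
  t <- series$times; v <- series$values
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  t <- t[sel]; v <- v[sel]
  if (length(t) < 4L)
    stop("at least 4 points are required in the fit window")
  if (any(t <= 0) || any(v <= 0))
    stop("all times and values in the window must be positive (log fit)")
  fit <- stats::lm(log(v) ~ log(t))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(v) - mean(log(v)))^2)
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 window = window,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n = length(t)), class = "power_law_fit")
}

#' @export
#' @method print power_law_fit
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> L(t) = %.4g * t^%.4f  (window %g-%g, n = %d, r2 = %.4f)\n",
              x$prefactor, x$alpha, x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' Compare a metric between two conditions at matched times
#'
#' For each requested time, each series contributes its nearest frame's
#' value, provided the gap does not exceed one typical frame spacing of that
#' series (no interpolation across larger gaps). Per-condition mean and
#' min-max envelope are reported, plus the mean difference (a - b).
#'
#' @param series_a,series_b lists of `metric_series` (one per simulation or
#'   leaflet) for the two conditions.
#' @param times evaluation times; default: the times of the first series of
#'   condition a that fall inside the overlap of both conditions' ranges.
#' @return data.frame `time`, `mean_a`, `min_a`, `max_a`, `n_a`, `mean_b`,
#'   `min_b`, `max_b`, `n_b`, `diff_mean`.
#' @export
compare_conditions <- function(series_a, series_b, times = NULL) {
  if (inherits(series_a, "metric_series")) series_a <- list(series_a)
  if (inherits(series_b, "metric_series")) series_b <- list(series_b)
  rng_a <- range(unlist(lapply(series_a, `[[`, "times")))
  rng_b <- range(unlist(lapply(series_b, `[[`, "times")))
  lo <- max(rng_a[1], rng_b[1]); hi <- min(rng_a[2], rng_b[2])
  if (lo > hi) stop("the two conditions have disjoint time ranges")
  if (is.null(times)) {
    times <- series_a[[1]]$times
    times <- times[times >= lo & times <= hi]
  }
  nearest <- function(s, t) {
    i <- which.min(abs(s$times - t))
    gap <- abs(s$times[i] - t)
    tol <- if (length(s$times) > 1) stats::median(diff(s$times)) else Inf
    if (gap > tol) NA_real_ else s$values[i]
  }
  rows <- lapply(times, function(t) {
    va <- vapply(series_a, nearest, numeric(1), t = t)
    vb <- vapply(series_b, nearest, numeric(1), t = t)
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    data.frame(time = t,
               mean_a = mean(va), min_a = min(va), max_a = max(va),
               n_a = length(va),
               mean_b = mean(vb), min_b = min(vb), max_b = max(vb),
               n_b = length(vb),
               diff_mean = mean(va) - mean(vb))
  })
  do.call(rbind, rows)
}
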
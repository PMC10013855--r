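#' Pearson correlation with explicit degeneracy checks
#'
#' Standard product-moment correlation; errors (rather than silently
#' returning NaN) on short or zero-variance input.
#'
#' @param x,y Numeric vectors of equal length >= 3, or [cv_series()].
#' @return Correlation coefficient r in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (inherits(x, "cv_series")) x <- x$values
  if (inherits(y, "cv_series")) y <- y$values
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("need at least 3 samples for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Time-lagged Pearson cross-correlation
#'
#' r(tau) = cor(x(t), y(t + tau)) over the overlapping samples, for tau from
#' 0 to `max_lag` in steps of `step`. Positive lag means y is observed later
#' than x; negative lags are not computed. The overlap shrinks with the lag
#' and no padding is used; lags whose overlap would fall below 3 samples are
#' truncated with a warning.
#'
#' @param x,y [cv_series()] sharing a timestep (or plain vectors, in which
#'   case `timestep` applies).
#' @param max_lag Largest lag in ns; defaults to half the series duration.
#' @param step Lag increment in ns; defaults to the timestep.
#' @param timestep Timestep for plain-vector input (ns).
#' @return Object of class `lag_correlation`: data.frame `lag_ns`, `r`.
#' @export
lag_correlation <- function(x, y, max_lag = NULL, step = NULL,
                            timestep = NULL) {
  if (inherits(x, "cv_series") && inherits(y, "cv_series")) {
    if (abs(x$timestep - y$timestep) > 1e-12) {
      stop("series must share a timestep")
    }
    dt <- x$timestep
    xv <- x$values; yv <- y$values
  } else {
    dt <- timestep %||% 1
    xv <- as.numeric(if (inherits(x, "cv_series")) x$values else x)
    yv <- as.numeric(if (inherits(y, "cv_series")) y$values else y)
  }
  n <- min(length(xv), length(yv))
  xv <- xv[seq_len(n)]; yv <- yv[seq_len(n)]
  dur <- (n - 1) * dt
  max_lag <- max_lag %||% (dur / 2)
  if (max_lag > dur / 2 + 1e-9) {
    stop("max_lag exceeds half the series duration")
  }
  step <- step %||% dt
  lag_steps <- unique(round(seq(0, max_lag, by = step) / dt))
  keep <- n - lag_steps >= 3
  if (!all(keep)) {
    warning("lag range truncated: overlap shorter than 3 samples")
    lag_steps <- lag_steps[keep]
  }
  r <- vapply(lag_steps, function(L) {
    stats::cor(xv[seq_len(n - L)], yv[seq_len(n - L) + L])
  }, numeric(1))
  out <- data.frame(lag_ns = lag_steps * dt, r = r)
  class(out) <- c("lag_correlation", "data.frame")
  out
}

#' Lag at which the cross-correlation magnitude peaks
#'
#' @param lc A `lag_correlation`.
#' @return Lag in ns with the largest |r|.
#' @export
lag_peak <- function(lc) {
  stopifnot(inherits(lc, "lag_correlation"))
  lc$lag_ns[which.max(abs(lc$r))]
}

#' Per-run window averages and their pooled correlation
#'
#' For a set of runs, averages each run's two CVs over the final `last_ns`
#' window and correlates the per-run means across runs (the scatter-plot
#' summary underlying per-run distance/angle correlation tables). With
#' fewer than 3 runs the means are reported and r is omitted.
#'
#' @param runs List of runs, each a list with elements `x` and `y`
#'   ([cv_series()]).
#' @param last_ns Averaging window from the end of each run (ns),
#'   default 2000.
#' @return List with `means` (data.frame run, mean_x, mean_y) and `r`
#'   (or `NA` with fewer than 3 runs).
#' @export
window_scatter <- function(runs, last_ns = 2000) {
  stopifnot(length(runs) >= 1)
  means <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(run = i,
               mean_x = window_average(runs[[i]]$x, last_ns)$mean,
               mean_y = window_average(runs[[i]]$y, last_ns)$mean)
  }))
  r <- if (nrow(means) >= 3) pearson(means$mean_x, means$mean_y) else NA_real_
  list(means = means, r = r)
}

#' Pairwise correlation matrix among named per-run averages
#'
#' @param mean_table data.frame of per-run window means, one column per CV.
#' @return Symmetric correlation matrix (pairwise r).
#' @export
correlation_matrix <- function(mean_table) {
  stopifnot(is.data.frame(mean_table), nrow(mean_table) >= 3)
  stats::cor(as.matrix(mean_table))
}
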
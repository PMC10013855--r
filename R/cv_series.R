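#' Construct a collective-variable series
#'
#' A named, unit-tagged scalar time series extracted from a trajectory.
#'
#' @param name Series name.
#' @param values Numeric vector, one value per frame. Must be finite.
#' @param units One of "A" (Angstrom), "degrees", "kcal/mol".
#' @param timestep Time between samples, ns.
#' @return Object of class `cv_series`.
#' @export
cv_series <- function(name, values, units = c("A", "degrees", "kcal/mol"),
                      timestep = 1) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) < 1) stop("cv_series must have at least one value")
  if (!all(is.finite(values))) stop("cv_series values must be finite")
  if (timestep <= 0) stop("timestep must be > 0")
  structure(list(name = name, values = values, units = units,
                 timestep = timestep),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("cv_series '%s': %d samples, dt = %g ns, units = %s\n",
              x$name, length(x$values), x$timestep, x$units))
  cat(sprintf("  range [%.3f, %.3f], mean %.3f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.cv_series <- function(x) length(x$values)

#' Sample times of a series (ns)
#' @param series A [cv_series()].
#' @return Numeric vector `(0:(n-1)) * timestep`.
#' @export
cv_times <- function(series) {
  (seq_along(series$values) - 1) * series$timestep
}

#' Total duration of a series (ns)
#' @param series A [cv_series()].
#' @return `(n - 1) * timestep`.
#' @export
cv_duration <- function(series) {
  (length(series$values) - 1) * series$timestep
}

#' Write / read a CV series as CSV
#'
#' Schema: `time_ns,value,units`.
#'
#' @param series A [cv_series()].
#' @param path File path.
#' @return `write_cv_csv`: `path` invisibly; `read_cv_csv`: a [cv_series()].
#' @export
write_cv_csv <- function(series, path) {
  df <- data.frame(time_ns = cv_times(series), value = series$values,
                   units = series$units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_csv
#' @param name Name for the series read back (default: file base name).
#' @export
read_cv_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ns", "value", "units")
  if (!all(need %in% names(df))) {
    stop("CV csv must have columns: ", paste(need, collapse = ", "))
  }
  dt <- if (nrow(df) > 1) df$time_ns[2] - df$time_ns[1] else 1
  cv_series(name %||% sub("\\.csv$", "", basename(path)),
            df$value, units = df$units[1], timestep = dt)
}

#' Write several CV series as one wide CSV
#'
#' `time_ns` plus one column per series; the layout consumed by the
#' correlation and PMF stages.
#'
#' @param series_list Named list of [cv_series()] sharing a timestep/length.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cv_wide_csv <- function(series_list, path) {
  stopifnot(length(series_list) >= 1)
  n <- length(series_list[[1]]$values)
  dt <- series_list[[1]]$timestep
  for (s in series_list) {
    if (length(s$values) != n || s$timestep != dt) {
      stop("all series must share length and timestep")
    }
  }
  df <- data.frame(time_ns = cv_times(series_list[[1]]))
  for (nm in names(series_list)) df[[nm]] <- series_list[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
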
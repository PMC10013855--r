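#' G-alpha opening state thresholds
#'
#' The opening coordinate (A161-E299 center distance) maps to four states:
#' fully open at >= `open_min`, semi-open in \[`semiopen_min`, `open_min`),
#' semi-closed in (`semiclosed_min`, `semiopen_min`), closed at
#' <= `semiclosed_min`. Defaults 55/45/35 Angstrom. The boundary convention
#' keeps the explicit >=/<= at the outer bounds and assigns 45.0 to
#' semi-open.
#'
#' @param open_min,semiopen_min,semiclosed_min Thresholds in Angstrom,
#'   strictly decreasing and positive.
#' @return Object of class `state_thresholds`.
#' @export
state_thresholds <- function(open_min = 55, semiopen_min = 45,
                             semiclosed_min = 35) {
  if (!(open_min > semiopen_min && semiopen_min > semiclosed_min &&
        semiclosed_min > 0)) {
    stop("thresholds must satisfy open_min > semiopen_min > semiclosed_min > 0")
  }
  structure(list(open_min = open_min, semiopen_min = semiopen_min,
                 semiclosed_min = semiclosed_min),
            class = "state_thresholds")
}

#' State labels in closed-to-open order
#' @return Character vector of the four state labels.
#' @export
state_levels <- function() c("closed", "semi_closed", "semi_open", "open")

#' Classify opening distances into conformational states
#'
#' @param distance Numeric vector of opening distances (Angstrom), > 0.
#' @param thresholds A [state_thresholds()].
#' @return Factor with levels `closed < semi_closed < semi_open < open`.
#' @export
classify_state <- function(distance, thresholds = state_thresholds()) {
  stopifnot(inherits(thresholds, "state_thresholds"))
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    stop("distances must be finite and positive")
  }
  lab <- ifelse(distance >= thresholds$open_min, "open",
         ifelse(distance >= thresholds$semiopen_min, "semi_open",
         ifelse(distance > thresholds$semiclosed_min, "semi_closed",
                "closed")))
  factor(lab, levels = state_levels(), ordered = TRUE)
}

#' Classify a distance series into a state series
#'
#' @param series A [cv_series()] in Angstrom.
#' @param thresholds A [state_thresholds()].
#' @return Object of class `state_series`: per-frame labels plus the
#'   thresholds used and the series timestep.
#' @export
classify_series <- function(series, thresholds = state_thresholds()) {
  stopifnot(inherits(series, "cv_series"))
  if (series$units != "A") stop("state classification expects Angstrom units")
  structure(list(labels = classify_state(series$values, thresholds),
                 thresholds = thresholds, timestep = series$timestep),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat("state_series:", length(x$labels), "frames\n")
  print(round(occupancy(x), 4))
  invisible(x)
}

#' State occupancy fractions
#'
#' @param states A `state_series`.
#' @param window Optional numeric length-2 time range in ns (inclusive).
#' @return Named numeric vector over all four states, summing to 1.
#' @export
occupancy <- function(states, window = NULL) {
  stopifnot(inherits(states, "state_series"))
  lab <- states$labels
  if (!is.null(window)) {
    t <- (seq_along(lab) - 1) * states$timestep
    keep <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
    if (!any(keep)) stop("empty occupancy window")
    lab <- lab[keep]
  }
  tab <- table(factor(lab, levels = state_levels()))
  as.numeric(tab) / length(lab) -> fr
  names(fr) <- state_levels()
  fr
}

#' Transition counts between consecutive frames
#'
#' @param states A `state_series`.
#' @return 4x4 integer matrix of from-state (rows) to to-state (columns)
#'   counts over consecutive frame pairs; self-transitions excluded.
#' @export
transition_counts <- function(states) {
  stopifnot(inherits(states, "state_series"))
  lab <- as.character(states$labels)
  n <- length(lab)
  m <- matrix(0L, 4, 4, dimnames = list(state_levels(), state_levels()))
  if (n < 2) return(m)
  from <- lab[-n]; to <- lab[-1]
  chg <- from != to
  for (i in which(chg)) m[from[i], to[i]] <- m[from[i], to[i]] + 1L
  m
}

#' JSON summary of a state series
#'
#' @param states A `state_series`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_state_summary <- function(states, path) {
  out <- list(
    n_frames = length(states$labels),
    thresholds = unclass(states$thresholds),
    occupancy = as.list(occupancy(states)),
    transitions = as.data.frame.table(transition_counts(states),
                                      responseName = "count")
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
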
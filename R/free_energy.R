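# bin edges spanning [floor(min), ceil(max)] in whole bin widths
.make_edges <- function(x, bw) {
  lo <- floor(min(x) / bw) * bw
  hi <- ceiling(max(x) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  seq(lo, hi, by = bw)
}

# bin index per sample; top edge closed so every sample lands in a bin
.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i > length(edges) - 1] <- length(edges) - 1L
  i
}

.pmf_grid <- function(dims, edges, W, counts, mask, temperature) {
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(dims = dims, edges = edges, centers = centers, W = W,
                 counts = counts, mask = mask, temperature = temperature),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf(
    "pmf_grid: %dD, %s bins (%d unmasked), T = %g K, W range [0, %.3f]\n",
    x$dims, paste(vapply(x$centers, length, 1L), collapse = " x "),
    sum(!x$mask), x$temperature, max(x$W[!x$mask], na.rm = TRUE)))
  invisible(x)
}

# shared estimator: counts + optional per-bin cumulant correction ->
# free energies. `adj` is beta*c1 + beta^2*c2/2 per bin (zero if unbiased).
.finish_pmf <- function(counts, adj, mask, kT) {
  lnp <- ifelse(counts > 0, log(counts / max(counts)), -Inf) + adj
  mask <- mask | counts == 0 | !is.finite(lnp)
  if (all(mask)) stop("all bins are below the count cutoff")
  W <- -kT * lnp
  W <- W - min(W[!mask])
  W[mask] <- NA_real_
  list(W = W, mask = mask)
}

# per-bin cumulant adjustment for boosted samples; bins where the variance
# cannot be estimated (fewer than 2 samples) are masked
.cumulant_adjust <- function(bins, nbin, deltaV, beta, order) {
  if (!order %in% c(1, 2)) stop("cumulant expansion order must be 1 or 2")
  adj <- numeric(nbin)
  need_mask <- logical(nbin)
  if (diff(range(deltaV)) == 0) {
    # uniform boost shifts every bin equally and cancels on normalization
    return(list(adj = adj, mask = need_mask))
  }
  sp <- split(deltaV, factor(bins, levels = seq_len(nbin)))
  for (b in seq_len(nbin)) {
    v <- sp[[b]]
    if (length(v) == 0) next
    c1 <- mean(v)
    if (order == 1) {
      adj[b] <- beta * c1
    } else {
      if (length(v) < 2) { need_mask[b] <- TRUE; next }
      adj[b] <- beta * c1 + beta^2 * stats::var(v) / 2
    }
  }
  list(adj = adj, mask = need_mask)
}

#' 1D potential of mean force from unbiased samples
#'
#' Histogram estimator W(bin) = -kB T ln(count/count_max), shifted so the
#' minimum over unmasked bins is zero; bins with fewer than `count_cutoff`
#' samples are masked. Default bin width 0.5 Angstrom for distances; use 5
#' for angle CVs in degrees.
#'
#' @param samples Numeric vector of CV samples (or a [cv_series()]).
#' @param bin_width Bin width in the CV units (default 0.5).
#' @param count_cutoff Minimum raw count for a bin to be reported (default 1).
#' @param temperature Temperature in K (default 310).
#' @return A `pmf_grid` (free energies in kcal/mol).
#' @export
pmf_unbiased <- function(samples, bin_width = 0.5, count_cutoff = 1,
                         temperature = 310) {
  pmf_reweighted(samples, deltaV = NULL, bin_width = bin_width,
                 count_cutoff = count_cutoff, temperature = temperature)
}

#' 1D PMF with cumulant-expansion reweighting of boosted samples
#'
#' For samples generated under a boost potential Delta-V (Gaussian
#' accelerated MD), the unbiased probability of a bin is recovered from the
#' biased one through ln p = ln p* + beta c1 + beta^2 c2 / 2, where c1 and
#' c2 are the per-bin mean and variance of Delta-V (second-order cumulant
#' expansion of ln <exp(beta Delta-V)>). With `deltaV = NULL` or all zeros
#' this reduces exactly to the unbiased estimator.
#'
#' @inheritParams pmf_unbiased
#' @param deltaV Per-frame boost potential, kcal/mol, same length as
#'   `samples`; `NULL` for unbiased data.
#' @param order Cumulant expansion order, 1 or 2 (default 2).
#' @return A `pmf_grid`.
#' @export
pmf_reweighted <- function(samples, deltaV, bin_width = 0.5,
                           count_cutoff = 1, temperature = 310, order = 2) {
  if (inherits(samples, "cv_series")) samples <- samples$values
  stopifnot(length(samples) >= 1, bin_width > 0)
  if (!order %in% c(1, 2)) stop("cumulant expansion order must be 1 or 2")
  if (!is.null(deltaV)) {
    if (length(deltaV) != length(samples)) {
      stop("deltaV must match samples in length")
    }
    if (any(deltaV < 0)) stop("deltaV must be >= 0")
  }
  kT <- kt_kcalmol(temperature)
  edges <- .make_edges(samples, bin_width)
  bins <- .bin_index(samples, edges)
  nbin <- length(edges) - 1
  counts <- tabulate(bins, nbins = nbin)
  if (is.null(deltaV) || diff(range(deltaV)) == 0) {
    cum <- list(adj = numeric(nbin), mask = logical(nbin))
  } else {
    cum <- .cumulant_adjust(bins, nbin, deltaV, 1 / kT, order)
  }
  mask <- counts < count_cutoff | cum$mask
  fin <- .finish_pmf(counts, cum$adj, mask, kT)
  .pmf_grid(1L, list(edges), fin$W, counts, fin$mask, temperature)
}

#' 2D potential of mean force
#'
#' Joint-histogram version of the 1D estimators; unbiased when `deltaV` is
#' `NULL`, cumulant-reweighted otherwise. Bin widths default to 0.5 per axis
#' (use 5 for an angle axis in degrees); the count cutoff for 2D grids
#' defaults to 10 configurations per bin.
#'
#' @param samplesX,samplesY Equal-length sample vectors (or [cv_series()]).
#' @param bin_widths Length-2 bin widths (default c(0.5, 0.5)).
#' @param count_cutoff Minimum raw count per bin (default 10).
#' @param deltaV Optional per-frame boost potential (kcal/mol).
#' @param temperature Temperature in K (default 310).
#' @param order Cumulant order, 1 or 2.
#' @return A `pmf_grid` with `W` and `counts` as matrices (X rows, Y cols).
#' @export
pmf_2d <- function(samplesX, samplesY, bin_widths = c(0.5, 0.5),
                   count_cutoff = 10, deltaV = NULL, temperature = 310,
                   order = 2) {
  if (inherits(samplesX, "cv_series")) samplesX <- samplesX$values
  if (inherits(samplesY, "cv_series")) samplesY <- samplesY$values
  if (length(samplesX) != length(samplesY)) {
    stop("samplesX and samplesY must have equal length")
  }
  stopifnot(length(bin_widths) == 2, all(bin_widths > 0))
  if (!is.null(deltaV) && length(deltaV) != length(samplesX)) {
    stop("deltaV must match samples in length")
  }
  kT <- kt_kcalmol(temperature)
  ex <- .make_edges(samplesX, bin_widths[1])
  ey <- .make_edges(samplesY, bin_widths[2])
  nx <- length(ex) - 1; ny <- length(ey) - 1
  bx <- .bin_index(samplesX, ex); by <- .bin_index(samplesY, ey)
  bins <- (by - 1L) * nx + bx
  nbin <- nx * ny
  counts <- tabulate(bins, nbins = nbin)
  if (is.null(deltaV) || diff(range(deltaV)) == 0) {
    cum <- list(adj = numeric(nbin), mask = logical(nbin))
  } else {
    cum <- .cumulant_adjust(bins, nbin, deltaV, 1 / kT, order)
  }
  mask <- counts < count_cutoff | cum$mask
  fin <- .finish_pmf(counts, cum$adj, mask, kT)
  .pmf_grid(2L, list(ex, ey),
            matrix(fin$W, nx, ny), matrix(counts, nx, ny),
            matrix(fin$mask, nx, ny), temperature)
}

# neighbor list on the unmasked grid graph (adjacent bins; 4-connectivity)
.grid_neighbors <- function(pmf) {
  if (pmf$dims == 1) {
    n <- length(pmf$W)
    lapply(seq_len(n), function(i) {
      nb <- c(i - 1L, i + 1L)
      nb[nb >= 1 & nb <= n]
    })
  } else {
    nx <- nrow(pmf$W); ny <- ncol(pmf$W)
    lapply(seq_len(nx * ny), function(i) {
      x <- (i - 1L) %% nx + 1L; y <- (i - 1L) %/% nx + 1L
      nb <- integer(0)
      if (x > 1) nb <- c(nb, i - 1L)
      if (x < nx) nb <- c(nb, i + 1L)
      if (y > 1) nb <- c(nb, i - nx)
      if (y < ny) nb <- c(nb, i + nx)
      nb
    })
  }
}

.bin_location <- function(pmf, i) {
  if (pmf$dims == 1) return(pmf$centers[[1]][i])
  nx <- nrow(pmf$W)
  c(pmf$centers[[1]][(i - 1L) %% nx + 1L],
    pmf$centers[[2]][(i - 1L) %/% nx + 1L])
}

#' Local minima and the barrier between the two deepest minima
#'
#' Local minima are unmasked bins whose free energy is strictly below every
#' unmasked neighbor (grid adjacency; 4-connectivity in 2D). The barrier
#' between two minima is computed exactly on the grid graph as the bottleneck
#' path value: the smallest threshold t such that the two minima are
#' connected through bins with W <= t, minus the origin minimum's W.
#'
#' @param pmf A `pmf_grid`.
#' @param from,to Optional flat bin indices of two minima; default: the two
#'   deepest local minima.
#' @return List with `minima` (data.frame: bin, location, W) and, when at
#'   least two minima exist, `barrier` (kcal/mol above the origin minimum)
#'   and `saddle_W`.
#' @export
minima_and_barrier <- function(pmf, from = NULL, to = NULL) {
  stopifnot(inherits(pmf, "pmf_grid"))
  W <- as.numeric(pmf$W)
  mask <- as.logical(pmf$mask)
  nb <- .grid_neighbors(pmf)
  is_min <- vapply(seq_along(W), function(i) {
    if (mask[i]) return(FALSE)
    good <- nb[[i]][!mask[nb[[i]]]]
    length(good) > 0 && all(W[i] < W[good])
  }, logical(1))
  mins <- which(is_min)
  mins <- mins[order(W[mins])]
  minima <- data.frame(
    bin = mins,
    W = W[mins]
  )
  minima$location <- I(lapply(mins, function(i) .bin_location(pmf, i)))
  if (length(mins) < 2 && (is.null(from) || is.null(to))) {
    return(list(minima = minima, barrier = NULL, saddle_W = NULL))
  }
  a <- from %||% mins[1]
  b <- to %||% mins[2]
  # bottleneck connectivity: grow threshold over sorted unmasked W values
  thresholds <- sort(unique(W[!mask]))
  connected_at <- function(t) {
    keep <- !mask & W <= t
    if (!keep[a] || !keep[b]) return(FALSE)
    seen <- logical(length(W)); seen[a] <- TRUE
    queue <- a
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (j in nb[[i]]) {
        if (keep[j] && !seen[j]) {
          if (j == b) return(TRUE)
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    seen[b]
  }
  lo <- 1; hi <- length(thresholds)
  if (!connected_at(thresholds[hi])) {
    return(list(minima = minima, barrier = Inf, saddle_W = Inf))
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (connected_at(thresholds[mid])) hi <- mid else lo <- mid + 1
  }
  saddle <- thresholds[lo]
  list(minima = minima, barrier = saddle - W[a], saddle_W = saddle)
}

#' Write a PMF grid as CSV
#'
#' One row per bin: bin centers, free energy, raw count and mask flag.
#'
#' @param pmf A `pmf_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(pmf, path) {
  if (pmf$dims == 1) {
    df <- data.frame(center = pmf$centers[[1]], W = pmf$W,
                     count = pmf$counts, masked = pmf$mask)
  } else {
    g <- expand.grid(x = pmf$centers[[1]], y = pmf$centers[[2]])
    df <- data.frame(center_x = g$x, center_y = g$y,
                     W = as.numeric(pmf$W), count = as.integer(pmf$counts),
                     masked = as.logical(pmf$mask))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
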
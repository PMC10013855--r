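# Independent oracles used across the suite. Deliberately naive (loops,
# closed forms) and kept apart from the package implementations they check.

# Kabsch superposition RMSD via SVD
oracle_kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- Ac %*% t(R)
  sqrt(mean(rowSums((fit - Bc)^2)))
}

# brute-force residue contact set: all atom pairs, double loop
oracle_contact_residues <- function(traj, frame, probe_idx, target_idx,
                                    cutoff) {
  top <- traj$topology
  co <- traj$coords
  res <- unique(paste(top$chain[target_idx], top$resno[target_idx]))
  hit <- character(0)
  for (it in target_idx) {
    for (ip in probe_idx) {
      d <- sqrt(sum((co[frame, it, ] - co[frame, ip, ])^2))
      if (d <= cutoff) {
        hit <- c(hit, paste(top$chain[it], top$resno[it]))
        break
      }
    }
  }
  sort(unique(hit))
}

# random rigid transform applied to every frame of a coords array
random_rigid <- function(coords, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- stats::rnorm(3, sd = 10)
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    out[f, , ] <- coords[f, , ] %*% t(R) + matrix(tr, dim(coords)[2], 3,
                                                  byrow = TRUE)
  }
  out
}

# bottleneck (minimax) path value between two cells by exhaustive DFS over
# all simple paths on a small grid
oracle_bottleneck <- function(W, from, to) {
  nx <- nrow(W); ny <- ncol(W)
  nb <- function(i) {
    x <- (i - 1) %% nx + 1; y <- (i - 1) %/% nx + 1
    out <- integer(0)
    if (x > 1) out <- c(out, i - 1)
    if (x < nx) out <- c(out, i + 1)
    if (y > 1) out <- c(out, i - nx)
    if (y < ny) out <- c(out, i + nx)
    out
  }
  w <- as.numeric(W)
  best <- Inf
  dfs <- function(i, seen, mx) {
    mx <- max(mx, w[i])
    if (mx >= best) return(invisible())
    if (i == to) { best <<- mx; return(invisible()) }
    for (j in nb(i)) if (!seen[j]) {
      seen[j] <- TRUE
      dfs(j, seen, mx)
      seen[j] <- FALSE
    }
  }
  seen <- logical(nx * ny); seen[from] <- TRUE
  dfs(from, seen, -Inf)
  best
}

# Boltzmann probability of a coordinate interval under a potential1d
oracle_boltzmann_prob <- function(pot, lo, hi, temperature = 310,
                                  support = NULL) {
  kT <- ternarymd::kt_kcalmol(temperature)
  support <- if (is.null(support)) pot$domain else support
  Z <- stats::integrate(function(x) exp(-pot$V(x) / kT), support[1],
                        support[2])$value
  stats::integrate(function(x) exp(-pot$V(x) / kT), lo, hi)$value / Z
}
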
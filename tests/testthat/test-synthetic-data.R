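test_that("the calibrated double well pins its minima, barrier and asymmetry exactly", {
  pot <- make_opening_double_well()
  p <- pot$params
  # derivative vanishes at both requested minima and the solved saddle
  expect_equal(pot$dV(34), 0)
  expect_equal(pot$dV(62), 0)
  expect_equal(pot$dV(p$saddle_pos), 0, tolerance = 1e-9)
  # root-find the stationary points independently
  roots <- sort(c(
    stats::uniroot(pot$dV, c(30, 40))$root,
    stats::uniroot(pot$dV, c(p$saddle_pos - 5, p$saddle_pos + 5))$root,
    stats::uniroot(pot$dV, c(58, 66))$root
  ))
  expect_equal(roots[1], 34, tolerance = 1e-6)
  expect_equal(roots[3], 62, tolerance = 1e-6)
  # barrier above the lower (open) minimum; asymmetry as defined
  expect_equal(pot$V(p$saddle_pos) - pot$V(62), 2.5, tolerance = 1e-9)
  expect_equal(pot$V(34) - pot$V(62), 1.0, tolerance = 1e-9)
  # symmetric variant
  sym <- make_opening_double_well(asymmetry = 0)
  expect_equal(sym$params$saddle_pos, 48)
  expect_equal(sym$V(34), sym$V(62), tolerance = 1e-9)
  # infeasible: barrier below asymmetry
  expect_error(make_opening_double_well(barrier = 0.5, asymmetry = 1),
               "infeasible")
})

test_that("Langevin sampling is seed-deterministic and respects equipartition", {
  pot <- potential_harmonic(center = 10, k = 2)
  a <- simulate_langevin(pot, n_steps = 5000, dt = 0.005, seed = 7)
  b <- simulate_langevin(pot, n_steps = 5000, dt = 0.005, seed = 7)
  expect_identical(a$values, b$values)
  # equipartition: sample variance = kT / k within 3 SE (small dt to keep
  # the Euler-Maruyama discretization bias well under the sampling error,
  # thinned past the relaxation time)
  s <- simulate_langevin(pot, n_steps = 9e5, dt = 1.5e-4, x0 = 10, seed = 8)
  thin <- s$values[seq(500, length(s$values), by = 100)]
  v <- stats::var(thin)
  want <- kt_kcalmol(310) / 2
  se <- want * sqrt(2 / length(thin))
  expect_lt(abs(v - want), 3 * se)
  # near-zero temperature descends into the nearest minimum
  cold <- simulate_langevin(make_opening_double_well(), temperature = 1,
                            n_steps = 5000, dt = 2e-4, x0 = 40, seed = 9)
  expect_equal(cold$values[length(cold$values)], 34, tolerance = 0.5)
  # unstable timestep is refused with a suggested maximum
  expect_error(simulate_langevin(pot, dt = 10, n_steps = 10),
               "stability limit")
})

test_that("long-run histograms match the Boltzmann density (chi-squared, thinned)", {
  pot <- make_opening_double_well(closed_pos = -2, open_pos = 2, barrier = 1,
                                  asymmetry = 0.4)
  s <- simulate_langevin(pot, n_steps = 6e5, dt = 5e-4, x0 = 2, seed = 10)
  thin <- s$values[seq(2000, length(s$values), by = 1000)]  # ~iid samples
  edges <- seq(-4, 4, by = 1)
  counts <- table(cut(thin, edges))
  probs <- vapply(seq_len(length(edges) - 1), function(i) {
    oracle_boltzmann_prob(pot, edges[i], edges[i + 1],
                          support = c(-6, 6))
  }, numeric(1))
  keep <- probs * length(thin) >= 5
  chi <- sum((as.numeric(counts[keep]) - length(thin) * probs[keep])^2 /
               (length(thin) * probs[keep]))
  expect_lt(chi, stats::qchisq(0.99, df = sum(keep) - 1))
})

test_that("GaMD-style boosts vanish above the reference energy and record deltaV faithfully", {
  pot <- make_opening_double_well()
  b <- gamd_boost(pot, k0 = 1)
  grid <- seq(pot$domain[1], pot$domain[2], length.out = 500)
  dv <- b$deltaV(grid)
  expect_true(all(dv >= 0))
  expect_true(all(dv[pot$V(grid) >= b$E] == 0))
  # boosted runs reproduce deltaV(x) of the recorded positions
  s <- simulate_langevin(pot, n_steps = 2000, dt = 0.01, x0 = 62, boost = b,
                         seed = 11)
  expect_equal(attr(s, "deltaV"), b$deltaV(s$values))
  s2 <- simulate_langevin(pot, n_steps = 2000, dt = 0.01, x0 = 62,
                          boost = b, seed = 11)
  expect_identical(s$values, s2$values)
  expect_error(gamd_boost(pot, k0 = 2), "k0")
})

test_that("boosting flattens the landscape and speeds up barrier crossing", {
  pot <- make_opening_double_well()
  b <- gamd_boost(pot, k0 = 1)
  cross <- function(series) {
    st <- classify_series(series)
    sum(transition_counts(st))
  }
  plain <- simulate_langevin(pot, n_steps = 1e5, dt = 0.01, x0 = 62,
                             seed = 12)
  boosted <- simulate_langevin(pot, n_steps = 1e5, dt = 0.01, x0 = 62,
                               boost = b, seed = 12)
  expect_gt(cross(boosted), cross(plain))
})

test_that("Boltzmann occupancy ratio is recovered for an asymmetric well", {
  # asymmetry 1 kcal/mol at 310 K: occupancy ratio ~ exp(-1/0.616) ~ 0.2
  pot <- make_opening_double_well(asymmetry = 1)
  s <- simulate_langevin(pot, n_steps = 6e5, dt = 0.01, x0 = 62, seed = 13)
  st <- classify_series(s)
  occ <- occupancy(st)
  p_closed <- oracle_boltzmann_prob(pot, 0 + 1e-12, 35, support = c(25, 75))
  p_open <- oracle_boltzmann_prob(pot, 55, 75, support = c(25, 75))
  # 3-SE band estimated from 10 block means of the state indicator
  blocks <- split(as.integer(st$labels == "open"),
                  rep(1:10, each = length(s$values) / 10))
  se <- stats::sd(vapply(blocks, mean, numeric(1))) / sqrt(10)
  expect_lt(abs(occ["open"] - p_open), 3 * se + 0.02)
  blocks_c <- split(as.integer(st$labels == "closed"),
                    rep(1:10, each = length(s$values) / 10))
  se_c <- stats::sd(vapply(blocks_c, mean, numeric(1))) / sqrt(10)
  expect_lt(abs(occ["closed"] - p_closed), 3 * se_c + 0.02)
})

test_that("correlated pair generators hit their targets and are reproducible", {
  p1 <- correlated_cv_pair(-0.8, 1e5, "gaussian_iid", seed = 14)
  expect_equal(stats::cor(p1$x$values, p1$y$values), -0.8, tolerance = 0.01)
  p2 <- correlated_cv_pair(-0.8, 1e5, "gaussian_iid", seed = 14)
  expect_identical(p1$x$values, p2$x$values)
  expect_error(correlated_cv_pair(1.2, 100), "rho")
  expect_error(correlated_cv_pair(0.5, 100, "gaussian_iid", lag = 5),
               "OU process")
})

test_that("toy complexes emit self-consistent ground truth and reject bad scripts", {
  tc <- make_toy_complex(
    contact_script = data.frame(resno = 7, fraction = 0.6), seed = 15
  )
  expect_equal(tc$contact_truth$n_contact_frames, 60)
  expect_equal(length(tc$pose_id), n_frames(tc$trajectory))
  expect_equal(nrow(tc$pose_centers), 5)
  # determinism
  tc2 <- make_toy_complex(
    contact_script = data.frame(resno = 7, fraction = 0.6), seed = 15
  )
  expect_identical(tc$trajectory$coords, tc2$trajectory$coords)
  # scripted fraction outside [0,1] and unknown residues are rejected
  expect_error(make_toy_complex(
    contact_script = data.frame(resno = 7, fraction = 1.4)), "fraction")
  expect_error(make_toy_complex(
    contact_script = data.frame(resno = 99, fraction = 0.5)), "outside")
  expect_error(make_toy_complex(
    contact_script = data.frame(resno = c(4, 4), fraction = c(0.5, 0.6))),
    "twice")
})

test_that("toy complexes round trip through PDB + DCD + ground-truth JSON", {
  tc <- make_toy_complex(n_pose_clusters = 2, frames_per_pose = 5, seed = 16)
  dir <- withr::local_tempdir()
  paths <- write_toy_complex(tc, dir)
  st <- read_structure(paths$pdb)
  tr <- read_trajectory(st$topology, paths$dcd)
  expect_equal(n_frames(tr), 10)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$pose_id, tc$pose_id)
})
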
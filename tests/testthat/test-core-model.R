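test_that("topology enforces unique atom ids and consistent residues", {
  expect_error(
    topology(c(1, 1), c("CA", "CB"), c("C", "C"), c(1, 1), c("ALA", "ALA"),
             c("A", "A")),
    "unique"
  )
  expect_error(
    topology(1:2, c("CA", "CB"), c("C", "C"), c(1, 1), c("ALA", "GLY"),
             c("A", "A")),
    "inconsistent residue"
  )
  top <- topology(1:3, c("N", "CA", "C"), c("N", "C", "C"), c(1, 1, 1),
                  rep("GLY", 3), rep("A", 3))
  expect_s3_class(top, "topology")
  expect_equal(n_residues(top), 1)
})

test_that("PDB round trip preserves atoms, residues and coordinates", {
  top <- topology(1:6, c("N", "CA", "C", "N", "CA", "C"),
                  c("N", "C", "C", "N", "C", "C"),
                  c(5, 5, 5, 6, 6, 6), rep(c("ALA", "GLY"), each = 3),
                  c("A", "A", "A", "B", "B", "B"))
  set.seed(1)
  coords <- matrix(round(stats::rnorm(18, sd = 5), 3), ncol = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(top, coords, path)
  st <- read_structure(path)
  expect_equal(nrow(st$topology), 6)
  expect_equal(st$topology$resno, top$resno)
  expect_equal(st$topology$chain, top$chain)
  expect_equal(st$topology$atom_name, top$atom_name)
  expect_equal(n_residues(st$topology), 2)
  expect_equal(st$coords, coords, tolerance = 1e-6)
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("DCD round trip is faithful within float precision and errors on atom mismatch", {
  tc <- make_toy_complex(n_pose_clusters = 2, frames_per_pose = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tc$trajectory, path)
  back <- read_trajectory(tc$trajectory$topology, path)
  expect_equal(n_frames(back), n_frames(tc$trajectory))
  expect_lt(max(abs(back$coords - tc$trajectory$coords)), 1e-4)
  small_top <- topology(1:2, c("C1", "C2"), c("C", "C"), c(1, 1),
                        c("LIG", "LIG"), c("L", "L"))
  expect_error(read_trajectory(small_top, path), "atoms")
})

test_that("geometric_center is the unweighted mean and matches a brute-force oracle", {
  top <- topology(1:3, c("C1", "C2", "C3"), rep("C", 3), rep(1, 3),
                  rep("LIG", 3), rep("L", 3))
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 2, ] <- c(3, 0, 0)
  coords[1, 3, ] <- c(0, 3, 0)
  tr <- trajectory(top, coords)
  g <- residue_group("lig", 1, "L")
  expect_equal(geometric_center(tr, g, 1), c(1, 1, 0))
  # single atom is its own center
  top1 <- topology(1, "C1", "C", 1, "LIG", "L")
  tr1 <- trajectory(top1, coords[, 2, , drop = FALSE])
  expect_equal(geometric_center(tr1, residue_group("one", 1, "L"), 1),
               c(3, 0, 0))
  # 50 random atoms vs direct mean
  set.seed(9)
  n <- 50
  top50 <- topology(1:n, rep("CA", n), rep("C", n), rep(1, n),
                    rep("ALA", n), rep("A", n))
  arr <- array(stats::rnorm(n * 3), dim = c(1, n, 3))
  tr50 <- trajectory(top50, arr)
  expect_equal(geometric_center(tr50, residue_group("all", 1, "A"), 1),
               colMeans(matrix(arr[1, , ], ncol = 3)))
  expect_error(geometric_center(tr50, residue_group("all", 1, "A"), 7),
               "out of range")
})

test_that("geometric_center is equivariant under rigid transforms", {
  tc <- make_toy_complex(n_pose_clusters = 2, frames_per_pose = 3, seed = 5)
  tr <- tc$trajectory
  for (s in 1:3) {
    moved <- trajectory(tr$topology, random_rigid(tr$coords, seed = s))
    c0 <- geometric_center(tr, tc$ligand, 2)
    c1 <- geometric_center(moved, tc$ligand, 2)
    # the center must transform exactly like the atoms did
    one_atom <- tr$coords[2, 1, ]
    one_moved <- moved$coords[2, 1, ]
    expect_equal(sqrt(sum((c1 - one_moved)^2)),
                 sqrt(sum((c0 - one_atom)^2)), tolerance = 1e-9)
  }
})

test_that("superpose removes rigid motion and preserves internal geometry", {
  tc <- make_toy_complex(n_pose_clusters = 1, frames_per_pose = 4, seed = 2)
  tr <- tc$trajectory
  # frame 2 = frame 1 translated; frame 3 = frame 1 rotated 90 deg about z
  co <- tr$coords
  co[2, , ] <- co[1, , ] + matrix(c(5, 0, 0), dim(co)[2], 3, byrow = TRUE)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  co[3, , ] <- co[1, , ] %*% t(Rz)
  tr2 <- trajectory(tr$topology, co)
  fit <- superpose(tr2, 1, tc$receptor)
  expect_lt(max(abs(fit$coords[2, , ] - fit$coords[1, , ])), 1e-6)
  expect_lt(max(abs(fit$coords[3, , ] - fit$coords[1, , ])), 1e-6)
  # rigid-body property: intra-frame pairwise distances unchanged
  d_before <- stats::dist(matrix(co[4, , ], ncol = 3))
  d_after <- stats::dist(matrix(fit$coords[4, , ], ncol = 3))
  expect_lt(max(abs(d_before - d_after)), 1e-6)
})

test_that("superpose agrees with an independent Kabsch oracle on noisy copies", {
  set.seed(11)
  n <- 30
  top <- topology(1:n, rep("CA", n), rep("C", n), 1:n, rep("ALA", n),
                  rep("A", n))
  base <- matrix(stats::rnorm(n * 3, sd = 4), ncol = 3)
  noisy <- base + matrix(stats::rnorm(n * 3, sd = 0.3), ncol = 3)
  arr <- array(NA_real_, dim = c(2, n, 3))
  arr[1, , ] <- base
  arr[2, , ] <- random_rigid(array(noisy, c(1, n, 3)), seed = 4)[1, , ]
  tr <- trajectory(top, arr)
  grp <- residue_group("all", 1:n, "A")
  fit <- superpose(tr, 1, grp)
  got <- sqrt(mean(rowSums((fit$coords[2, , ] - fit$coords[1, , ])^2)))
  expect_equal(got, oracle_kabsch_rmsd(arr[2, , ], base), tolerance = 1e-6)
  # collinear fit atoms are rejected
  lin <- array(rep(cbind(1:n, 0, 0), each = 1), dim = c(1, n, 3))
  lin[1, , 1] <- 1:n; lin[1, , 2] <- 0; lin[1, , 3] <- 0
  expect_error(superpose(trajectory(top, lin), 1, grp), "collinear")
})

test_that("residue groups resolve subset rules and YAML configs parse ranges", {
  top <- topology(1:5, c("N", "CA", "C", "HA", "CA"),
                  c("N", "C", "C", "H", "C"),
                  c(1, 1, 1, 1, 2), c(rep("ALA", 4), "GLY"),
                  rep("A", 5))
  expect_equal(resolve_group(top, residue_group("r1", 1, "A")), 1:3)
  expect_equal(resolve_group(top, residue_group("r1", 1, "A", subset = "all")),
               1:4)
  expect_equal(resolve_group(top, residue_group("r1", 1, "A",
                                                subset = "calpha")), 2)
  expect_error(resolve_group(top, residue_group("bad", 99, "A")),
               "not in topology")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "receptor: {chain: A, residues: '1-2'}",
    "anchor:   {chain: A, residues: '2', subset: calpha}"
  ), yml)
  groups <- read_groups_yaml(yml)
  expect_named(groups, c("receptor", "anchor"))
  expect_equal(groups$receptor$resno, 1:2)
  expect_equal(groups$anchor$subset, "calpha")
  expect_equal(parse_residue_ranges("30-32, 40"), c(30L, 31L, 32L, 40L))
  expect_error(parse_residue_ranges("9-3"), "bad residue range")
})
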
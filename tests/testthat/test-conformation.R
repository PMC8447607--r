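# Ensemble shape statistics: Rg, superposition, RMSF, RMSD, clustering.

test_that("radius of gyration matches closed forms and a pairwise oracle", {
  two <- protein_traj(array(c(1, -1, 0, 0, 0, 0), dim = c(1, 2, 3)))
  expect_equal(radius_of_gyration(two), 1)  # beads at (+-1, 0, 0)

  one <- protein_traj(array(c(3, -2, 7), dim = c(1, 1, 3)))
  expect_equal(radius_of_gyration(one), 0)

  set.seed(41)
  X <- matrix(rnorm(300), ncol = 3)
  tr <- protein_traj(array(X, dim = c(1, 100, 3)))
  expect_lt(abs(radius_of_gyration(tr) - rg_pairwise_oracle(X)), 1e-12)

  # mass weighting shifts toward the heavy bead
  expect_error(radius_of_gyration(tr, masses = rep(-1, 100)), "non-negative")
})

test_that("Rg density is normalized, bimodal on two-state ensembles, and flags deltas", {
  ctr1 <- make_scaffold(30, seed = 51)
  ctr2 <- ctr1 * 1.6  # expanded state: Rg differs by ~1.8x
  e <- generate_conformational_ensemble(list(ctr1, ctr2), c(0.5, 0.5),
                                        noise_sigma = 0.05, n = 400,
                                        seed = 52)
  d <- rg_density(e$trajectory)
  expect_false(d$delta_like)
  expect_lt(abs(sum(diff(d$grid) * (head(d$density, -1) +
                                    tail(d$density, -1)) / 2) - 1), 1e-3)
  # two local maxima separated by a dip
  dens <- d$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  expect_gte(length(peaks), 2)

  # constant ensemble: delta-like flagged, peak at the common Rg
  static <- generate_conformational_ensemble(list(ctr1), 1, noise_sigma = 0,
                                             n = 20, seed = 53,
                                             rigid_motion = FALSE)
  ds <- rg_density(static$trajectory)
  expect_true(ds$delta_like)
  rg0 <- radius_of_gyration(static$trajectory, 1)
  expect_lt(abs(ds$grid[which.max(ds$density)] - rg0), 0.01)
})

test_that("Kabsch superposition recovers rigid motions and rejects reflections", {
  A <- make_scaffold(20, seed = 61)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  B <- sweep(A %*% t(Rz), 2, c(5, -3, 2), `+`)
  k <- kabsch_superpose(A, B)
  expect_lt(k$rmsd, 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(k$coords - B)), 1e-9)

  # mirror image of a chiral set keeps a positive RMSD
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.4, 1.2))
  mirror <- chiral %*% diag(c(1, 1, -1))
  km <- kabsch_superpose(mirror, chiral)
  expect_gt(km$rmsd, 0.1)
  expect_equal(det(km$rotation), 1, tolerance = 1e-10)

  # agreement with the quaternion oracle on random pairs
  set.seed(62)
  for (i in 1:10) {
    P <- matrix(rnorm(45), ncol = 3)
    Q <- matrix(rnorm(45), ncol = 3)
    expect_lt(abs(kabsch_superpose(P, Q)$rmsd -
                  quaternion_rmsd_oracle(P, Q)), 1e-10)
  }

  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3 fit beads")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSF separates mobile from static beads after superposition", {
  A <- make_scaffold(20, seed = 71)
  # static trajectory under random rigid motions: RMSF vanishes
  e <- generate_conformational_ensemble(list(A), 1, noise_sigma = 0,
                                        n = 15, seed = 72)
  expect_lt(max(rmsf(e$trajectory)), 1e-9)

  # one bead oscillating +/- d along x, others fixed, no rigid motion
  d_amp <- 0.8
  nf <- 10
  coords <- array(rep(t(A), nf), dim = c(3, 20, nf))
  coords <- aperm(coords, c(3, 2, 1))
  coords[, 1, 1] <- A[1, 1] + d_amp * rep(c(1, -1), nf / 2)
  tr <- protein_traj(coords)
  flc <- rmsf(tr, fit_selection = 2:20)
  expect_equal(unname(flc[1]), d_amp, tolerance = 1e-9)
  expect_lt(max(flc[-1]), 1e-9)

  # two-state ensemble: beads that move between states fluctuate more
  B <- A
  B[1:5, ] <- B[1:5, ] + 3  # "loop" beads displaced in state 2
  e2 <- generate_conformational_ensemble(list(A, B), c(0.5, 0.5),
                                         noise_sigma = 0.05, n = 200,
                                         seed = 73)
  flc2 <- rmsf(e2$trajectory, fit_selection = 6:20)
  expect_gt(min(flc2[1:5]), max(flc2[6:20]))
})

test_that("pairwise RMSD is a symmetric metric consistent with single fits", {
  A <- make_scaffold(15, seed = 81)
  e <- generate_conformational_ensemble(list(A), 1, noise_sigma = 0.3,
                                        n = 20, seed = 82)
  m <- pairwise_rmsd(e$trajectory)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(diag(m) == 0))
  # triangle inequality over all frame triples
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    expect_lte(m[i, k], m[i, j] + m[j, k] + 1e-10)
  }
  # entries match one-off Kabsch superpositions
  for (pair in list(c(1, 2), c(3, 17), c(9, 20))) {
    kk <- kabsch_superpose(frame_coords(e$trajectory, pair[1]),
                           frame_coords(e$trajectory, pair[2]))
    expect_lt(abs(m[pair[1], pair[2]] - kk$rmsd), 1e-10)
  }
  # duplicate frames give a zero matrix
  dup <- protein_traj(array(rep(t(A), 4), dim = c(3, 15, 4)) |>
                        aperm(c(3, 2, 1)))
  expect_lt(max(pairwise_rmsd(dup)), 1e-12)
})

test_that("gromos clustering follows the neighbor-counting rule exactly", {
  # all frames mutually within cutoff: one cluster, population 1
  m <- matrix(0.1, 6, 6); diag(m) <- 0
  cl <- gromos_cluster(m, 0.8)
  expect_equal(length(cl$centers), 1)
  expect_equal(cl$populations, 1)
  expect_true(all(cl$assignments == 1))

  # 3 near-identical frames + 1 distant: populations 0.75 / 0.25
  m <- matrix(5, 4, 4); diag(m) <- 0
  m[1:3, 1:3] <- 0.1; diag(m) <- 0
  cl <- gromos_cluster(m, 0.8)
  expect_equal(cl$populations, c(0.75, 0.25))
  expect_true(cl$centers[1] %in% 1:3)
  expect_equal(cl$centers[2], 4)
  expect_equal(sum(cl$populations), 1, tolerance = 1e-12)

  # oracle equivalence on random geometries
  set.seed(91)
  for (rep in 1:10) {
    pts <- matrix(rnorm(50 * 3), ncol = 3)
    m <- as.matrix(dist(pts))
    cutoff <- runif(1, 0.5, 2.5)
    got <- gromos_cluster(m, cutoff)
    want <- gromos_oracle(m, cutoff)
    expect_identical(got$assignments, want$assignments)
    expect_identical(got$centers, want$centers)
    expect_equal(sum(got$populations), 1, tolerance = 1e-12)
    expect_true(all(diff(got$populations) <= 0))
    # centers belong to their clusters
    expect_true(all(got$assignments[got$centers] ==
                    seq_along(got$centers)))
  }

  # cluster count is non-increasing in the cutoff
  pts <- matrix(rnorm(40 * 3), ncol = 3)
  m <- as.matrix(dist(pts))
  counts <- vapply(seq(0.2, 3, by = 0.2),
                   function(ct) length(gromos_cluster(m, ct)$centers), 0L)
  expect_true(all(diff(counts) <= 0))

  expect_error(gromos_cluster(matrix(c(0, 1, 2, 0), 2, 2), 0.8),
               "symmetric")
})

test_that("even subsampling uses the documented stride formula", {
  tr <- protein_traj(array(rnorm(10 * 4 * 3), dim = c(10, 4, 3)))
  sub <- subsample_evenly(tr, 3)
  expect_equal(sub$times, tr$times[c(1, 5, 10)])  # 0-based {0, 4, 9}

  # identity when n equals the frame count
  expect_equal(subsample_evenly(tr, 10)$coords, tr$coords)

  # requests beyond the trajectory return every frame once
  two <- subset_frames(tr, 1:2)
  expect_equal(n_frames(subsample_evenly(two, 10)), 2)
  expect_equal(n_frames(subsample_evenly(tr, 1)), 1)
})
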
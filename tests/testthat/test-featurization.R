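test_that("pair enumeration matches the combinatorial identity", {
  expect_equal(nrow(enumerate_ca_pairs(chain_topology(2))), 1)
  expect_equal(nrow(enumerate_ca_pairs(chain_topology(5))), 10)
  for (n in c(3, 10, 57, 200)) {
    expect_equal(nrow(enumerate_ca_pairs(chain_topology(n))),
                 n * (n - 1) / 2)
  }
  ## clipped terminals are excluded from eligibility
  defs <- enumerate_ca_pairs(chain_topology(10, clip = 2))
  expect_equal(nrow(defs), choose(6, 2))
  expect_false(any(c(defs$residue_i, defs$residue_j) %in%
                     c(1, 2, 9, 10)))
  ## deterministic lexicographic order and stable labels
  expect_equal(defs$label[1], "D_3_4")
  expect_no_error(enumerate_ca_pairs(chain_topology(4, clip = 1)))
  expect_error(enumerate_ca_pairs(chain_topology(3, clip = 1)),
               "at least 2")
})

test_that("topology and ensemble constructors validate their invariants", {
  expect_error(chain_topology(5, clip = 3), "clip")
  expect_error(topology(data.frame(index = c(1, 1, 2), name = "GLY",
                                   chain = "A")), "increasing")
  a <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  expect_silent(trajectory_ensemble(list(a), chain_topology(3)))
  a_bad <- a; a_bad[1, 1, 1] <- NA
  expect_error(trajectory_ensemble(list(a_bad), chain_topology(3)),
               "NA")
  expect_error(trajectory_ensemble(list(a[, 1:2, ]), chain_topology(3)),
               "frames x 3 x 3")
})

test_that("distance features agree with scalar brute force", {
  set.seed(42)
  a <- array(rnorm(6 * 5 * 3, sd = 4), c(6, 5, 3))
  ens <- coords_ensemble(list(a))
  defs <- enumerate_ca_pairs(chain_topology(5))
  fm <- compute_features(ens, defs)
  for (k in sample(nrow(defs), 4)) {
    i <- defs$residue_i[k]; j <- defs$residue_j[k]
    for (t in 1:6) {
      d <- sqrt(sum((a[t, i, ] - a[t, j, ])^2))
      expect_equal(fm$values[t, defs$label[k]], d, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
  ## fixed geometry gives a constant column
  b <- array(0, c(3, 2, 3)); b[, 2, 1] <- 5
  fm2 <- compute_features(coords_ensemble(list(b)),
                          enumerate_ca_pairs(chain_topology(2)))
  expect_equal(unname(fm2$values[, 1]), rep(5, 3))
  ## degenerate all-origin coordinates
  z <- array(0, c(2, 3, 3))
  fm3 <- compute_features(coords_ensemble(list(z)),
                          enumerate_ca_pairs(chain_topology(3)))
  expect_true(all(fm3$values == 0))
  ## unknown residue in a definition
  bad <- data.frame(residue_i = 1, residue_j = 99, label = "D_1_99")
  expect_error(compute_features(ens, bad), "D_1_99")
})

test_that("pruning removes only all-frame violations of the distance band", {
  vals <- cbind(close = rep(2.5, 6), far = rep(12, 6),
                mid = c(4, 8, 5, 7, 6, 5), span = c(2, 12, 6, 2, 12, 6))
  fm <- feature_matrix(vals, colnames(vals))
  pr <- prune_features(fm, d_min = 3, d_max = 10)
  expect_setequal(pr$report$label, c("close", "far"))
  expect_equal(pr$report$rule[pr$report$label == "close"], "too_close")
  expect_equal(pr$report$rule[pr$report$label == "far"], "too_far")
  expect_setequal(pr$pruned$labels, c("mid", "span"))
  ## idempotence
  pr2 <- prune_features(pr$pruned)
  expect_equal(nrow(pr2$report), 0)
  expect_identical(pr2$pruned$values, pr$pruned$values)
  ## commutes with column permutation
  perm <- c(3, 1, 4, 2)
  fmp <- feature_matrix(vals[, perm], colnames(vals)[perm])
  prp <- prune_features(fmp)
  expect_setequal(prp$pruned$labels, pr$pruned$labels)
  ## union semantics over two systems: feature out of band in one
  ## system but inside it in the other is retained for both
  fa <- feature_matrix(cbind(x = rep(2, 4)), "x")
  fb <- feature_matrix(cbind(x = rep(5, 4)), "x")
  both <- prune_features(list(fa, fb))
  expect_equal(nrow(both$report), 0)
  ## all-removed guard
  expect_error(prune_features(feature_matrix(cbind(a = rep(1, 3)), "a")),
               "review")
})

test_that("RMSF matches closed forms and is superposition invariant", {
  ## one residue alternating +/- a along x about its mean, inside a
  ## large rigid scaffold (many fixed residues, so the superposition
  ## is pinned by the scaffold and barely redistributes the motion)
  n <- 200; n_res <- 40
  set.seed(8)
  ref <- matrix(rnorm(n_res * 3, sd = 20), n_res, 3)
  a <- array(rep(ref, each = n), c(n, n_res, 3))
  a[, 1, 1] <- ref[1, 1] + rep(c(2, -2), n / 2)
  r <- ca_rmsf(coords_ensemble(list(a)))
  expect_equal(unname(r[1]), 2, tolerance = 0.05)
  expect_lt(max(r[-1]), 0.2)
  ## invariance under per-frame rigid motion
  rot <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a
  set.seed(1)
  for (t in seq_len(n)) {
    R <- rot(runif(1, 0, 2 * pi))
    b[t, , ] <- a[t, , ] %*% R + matrix(runif(3, -5, 5), n_res, 3,
                                        byrow = TRUE)
  }
  r2 <- ca_rmsf(coords_ensemble(list(b)))
  expect_equal(unname(r2), unname(r), tolerance = 1e-6)
  ## single frame is rejected at construction time
  expect_error(coords_ensemble(list(array(0, c(1, 3, 3)))), "2 frames")
})

test_that("ensemble round-trips through PDB topology and DCD", {
  se <- gen_toy_loop_trajectory(n_traj = 2, n_frames = 30, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_ensemble(se, dir)
  top <- load_topology(paths$topology, terminal_clip = 2)
  expect_equal(top$n_residues, 40)
  expect_equal(top$residues$index, 1:40)
  ens <- load_trajectories(paths$trajectories, top, dt = se$ensemble$dt)
  expect_length(ens$coords, 2)
  ## DCD stores single precision: agreement to 1e-3 Angstrom
  expect_equal(ens$coords[[1]], se$ensemble$coords[[1]],
               tolerance = 1e-3)
  ## stride halves the frame count and scales dt
  ens2 <- load_trajectories(paths$trajectories[1], top, stride = 2)
  expect_equal(dim(ens2$coords[[1]])[1], 15)
  expect_equal(ens2$dt, 2)
  expect_error(load_trajectories(character(), top), "no trajectory")
  ## ground truth JSON preserves the planted stationary distribution
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$pi_true, rep(0.25, 4), tolerance = 1e-12)
})

test_that("feature CSV round-trip preserves values, labels and segments", {
  fm <- feature_matrix(matrix(runif(20), 10, 2), c("D_1_2", "D_1_3"),
                       segments = c(6, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  fm2 <- read_feature_csv(path)
  expect_equal(fm2$values, fm$values, tolerance = 1e-12)
  expect_identical(fm2$labels, fm$labels)
  expect_identical(fm2$segments, fm$segments)
})
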
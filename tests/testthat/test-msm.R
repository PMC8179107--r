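test_that("transition counts match hand enumeration and add across trajectories", {
  expect_equal(count_matrix(list(c(1, 2, 1, 2)), 1),
               matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(count_matrix(list(rep(1L, 10)), 1),
               matrix(9, 1, 1))
  two <- count_matrix(list(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_equal(two, 2 * count_matrix(list(c(1, 2, 1, 2)), 1))
  ## lag-2 sliding window, never crossing boundaries
  expect_equal(count_matrix(list(c(1, 1, 2, 2)), 2),
               matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE))
  expect_error(count_matrix(list(c(1, 2)), 2), "shortest")
})

test_that("largest connected set picks the dominant communicating class", {
  C <- matrix(0, 3, 3)
  C[1, 2] <- C[2, 1] <- 50; C[3, 3] <- 1
  expect_equal(as.integer(largest_connected_set(C)), c(1, 2))
  expect_equal(attr(largest_connected_set(C), "dropped"), 3)
  full <- matrix(1, 4, 4)
  expect_equal(as.integer(largest_connected_set(full)), 1:4)
  ## one-way chain decomposes into singletons under strong connectivity
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 3] <- 5; chain[3, 3] <- 2
  expect_length(largest_connected_set(chain), 1)
  expect_error(largest_connected_set(matrix(0, 0, 0)), "nonempty")
})

test_that("reversible MLE matches analytic solutions and detailed balance", {
  ## symmetric counts give the symmetric closed form
  m <- estimate_reversible_msm(matrix(c(90, 10, 10, 90), 2, 2))
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
  ## any 2-state chain is reversible, so the constrained MLE equals the
  ## row-normalized counts; cross-checked against a brute-force grid
  ## likelihood maximizer
  set.seed(14)
  for (r in 1:20) {
    C <- matrix(rpois(4, sample(10:300, 4)) + 1, 2, 2)
    est <- estimate_reversible_msm(C)$T
    expect_equal(est, C / rowSums(C), tolerance = 1e-7)
  }
  C <- matrix(c(120, 40, 25, 200), 2, 2, byrow = TRUE)
  grid <- seq(0.002, 0.6, by = 0.002)
  ll <- outer(grid, grid, function(a, b)
    C[1, 1] * log(1 - a) + C[1, 2] * log(a) +
    C[2, 1] * log(b) + C[2, 2] * log(1 - b))
  best <- which(ll == max(ll), arr.ind = TRUE)
  est <- estimate_reversible_msm(C)$T
  expect_lt(abs(est[1, 2] - grid[best[1]]), 2e-3)
  expect_lt(abs(est[2, 1] - grid[best[2]]), 2e-3)
  ## detailed balance holds on larger random models
  set.seed(15)
  C5 <- matrix(rpois(25, 40) + 1, 5, 5)
  m5 <- estimate_reversible_msm(C5)
  db <- outer(m5$pi, rep(1, 5)) * m5$T
  expect_lt(max(abs(db - t(db))), 1e-8)
  expect_equal(rowSums(m5$T), rep(1, 5), tolerance = 1e-10)
})

test_that("stationary distribution is recovered from simulated dynamics", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  dtrajs <- sim_dtrajs(T, n_traj = 2, n_frames = 50000, seed = 16)
  m <- estimate_reversible_msm(count_matrix(dtrajs, 1))
  ## 3 SE allowing for the chain's correlation time
  n_eff <- 1e5 / 10
  expect_lt(abs(m$pi[1] - 2 / 3), 3 * sqrt(2 / 9 / n_eff) * 3)
  expect_lt(abs(m$T[1, 2] - 0.1), 5 / sqrt(sum(dtrajs[[1]] == 1) * 2))
})

test_that("implied timescales are lag-stable for Markovian data and vanish for noise", {
  T <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  dtrajs <- sim_dtrajs(T, 2, 50000, seed = 17)
  its <- implied_timescales(dtrajs, lags = c(1, 2, 5, 10), n_its = 1)
  expect_equal(nrow(its), 4)
  expect_lt(max(abs(its$its1 - mean(its$its1))) / mean(its$its1), 0.15)
  ## white-noise labels: fastest possible relaxation
  set.seed(18)
  noise <- list(sample.int(3, 20000, replace = TRUE))
  itsn <- implied_timescales(noise, lags = 1, n_its = 2)
  expect_lt(itsn$its1[1], 1)
  ## single lag gives a single row
  expect_equal(nrow(implied_timescales(dtrajs, lags = 1)), 1)
  ## timescales invariant under state relabeling
  relab <- lapply(dtrajs, function(s) 3L - s)
  its_r <- implied_timescales(relab, lags = c(1, 5), n_its = 1)
  its_o <- implied_timescales(dtrajs, lags = c(1, 5), n_its = 1)
  expect_equal(its_r$its1, its_o$its1, tolerance = 1e-9)
})

test_that("Chapman-Kolmogorov test validates Markovian data and flags violations", {
  T <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, 2, byrow = TRUE)
  dtrajs <- sim_dtrajs(T, 2, 50000, seed = 19)
  msm <- estimate_reversible_msm(count_matrix(dtrajs, 1))
  ck <- ck_test(msm, dtrajs, macro_sets = list(1, 2), factors = 1:5)
  expect_lt(max(ck$deviation[ck$factor == 1]), 1e-10)
  expect_lt(max(ck$deviation), 0.02)
  ## semi-Markov dwell-3 alternation is flagged by large deviations
  s <- rep(rep(c(1L, 2L), 50), each = 3)
  msm2 <- estimate_reversible_msm(count_matrix(list(s), 1))
  ck2 <- ck_test(msm2, list(s), macro_sets = list(1, 2), factors = c(1, 3))
  expect_gt(max(ck2$deviation[ck2$factor == 3]), 0.1)
})

test_that("k-means microstates separate well-spaced blobs deterministically", {
  set.seed(20)
  blob <- rbind(matrix(rnorm(600, 0, 0.2), ncol = 2),
                matrix(rnorm(600, 5, 0.2), ncol = 2))
  truth <- rep(1:2, each = 300)
  d <- cluster_microstates(blob, 2, seed = 4)
  lab <- d$dtrajs[[1]]
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(agree, 0.99)
  d2 <- cluster_microstates(blob, 2, seed = 4)
  expect_identical(d$centers, d2$centers)
  expect_equal(unique(cluster_microstates(blob, 1, seed = 1)$dtrajs[[1]]),
               1L)
  expect_error(cluster_microstates(blob[1:3, ], 5, seed = 1), "exceeds")
})

test_that("free-energy surfaces reflect sample densities", {
  set.seed(21)
  ## multinomial fluctuation: ~100 counts/bin gives an F range near
  ## 0.5 kT; it shrinks as 1/sqrt(frames)
  u <- cbind(runif(10000), runif(10000))
  f <- free_energy_surface(u, bins = 10)
  expect_equal(min(f$F, na.rm = TRUE), 0)
  expect_lt(max(f$F, na.rm = TRUE), 0.7)
  u_big <- cbind(runif(1e5), runif(1e5))
  expect_lt(max(free_energy_surface(u_big, bins = 10)$F, na.rm = TRUE),
            0.25)
  ## two clusters at population ratio 2:1 differ by ln 2 kT
  pts <- rbind(matrix(rnorm(8000, 0, 0.05), ncol = 2),
               matrix(rnorm(4000, 1, 0.05), ncol = 2))
  f2 <- free_energy_surface(pts, bins = 20)
  ix <- function(x) pmin(findInterval(x, f2$x_edges, all.inside = TRUE), 20)
  fmin_a <- f2$F[ix(0), ix(0)]
  fmin_b <- f2$F[ix(1), ix(1)]
  expect_equal(fmin_b - fmin_a, log(2), tolerance = 0.1)
  ## uniform weights equal no weights
  f3 <- free_energy_surface(u, bins = 10, weights = rep(2, nrow(u)))
  expect_equal(f3$F, f$F)
  expect_error(free_energy_surface(matrix(1, 5, 2), bins = 10),
               "one bin")
  expect_error(free_energy_surface(u, bins = 4), "at least 10")
})
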
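test_that("planted kinetics satisfy their structural invariants", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  kin <- planted_kinetics(T, c("a", "b"), slow_loop_residues = 1:3,
                          fast_loop_residues = 5:7)
  expect_equal(rowSums(kin$T_true), c(1, 1), tolerance = 1e-12)
  expect_equal(as.numeric(kin$pi_true %*% kin$T_true),
               as.numeric(kin$pi_true), tolerance = 1e-10)
  expect_equal(diag(kin$mfpt_true), c(a = 0, b = 0))
  expect_equal(kin$pi_true, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(planted_kinetics(T, slow_loop_residues = 1:3,
                                fast_loop_residues = 3:5), "disjoint")
  expect_error(planted_kinetics(matrix(c(0.9, 0.2, 0.2, 0.8), 2, 2)),
               "sum to 1")
  expect_error(planted_kinetics(diag(2)), "reducible")
})

test_that("mean first passage oracle matches closed forms", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(true_mfpt(T, 1, 2), 10)
  expect_equal(true_mfpt(T, 2, 1), 5)
  expect_equal(true_mfpt(T, 1, 1:2), 0)   # target covers all states
  expect_error(true_mfpt(T, 1, 1), "disjoint")
  expect_error(true_mfpt(T, integer(), 2), "nonempty")
})

test_that("linear-solve MFPT equals exhaustive path enumeration on a ring", {
  ring <- matrix(0, 3, 3)
  ring[1, 2] <- ring[2, 3] <- ring[3, 1] <- 0.5
  ring[1, 3] <- ring[2, 1] <- ring[3, 2] <- 0.5
  expect_equal(true_mfpt(ring, 1, 3), enumerate_mfpt(ring, 1, 3),
               tolerance = 1e-9)
  expect_equal(true_mfpt(ring, c(1, 2), 3),
               enumerate_mfpt(ring, c(1, 2), 3), tolerance = 1e-9)
})

test_that("hidden-Markov feature generator honors its contracts", {
  ## near-absorbing chain barely leaves its initial state (a strictly
  ## absorbing identity is rejected as reducible, tested below)
  g0 <- gen_hidden_markov_features(matrix(c(0.9999, 1e-4, 1e-4, 0.9999),
                                          2, 2),
                                   rbind(0, 1), 0.1, 1, 50, seed = 1)
  expect_lte(length(unique(g0$hidden_path[[1]])), 2)
  expect_length(g0$hidden_path[[1]], 50)

  ## zero noise emits exact centroids
  means <- rbind(c(0, 0), c(3, 1))
  g <- gen_hidden_markov_features(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                         byrow = TRUE),
                                  means, noise_sd = 0, 1, 500, seed = 2)
  expect_equal(g$features$values,
               unname(means[g$hidden_path[[1]], ]),
               ignore_attr = TRUE)

  ## same seed is bit-reproducible
  g2 <- gen_hidden_markov_features(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                          byrow = TRUE),
                                   means, 0.3, 2, 300, seed = 7)
  g3 <- gen_hidden_markov_features(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                          byrow = TRUE),
                                   means, 0.3, 2, 300, seed = 7)
  expect_identical(g2$features$values, g3$features$values)

  ## rejected inputs
  expect_error(gen_hidden_markov_features(matrix(c(0.9, 0.2, 0.2, 0.8),
                                                 2, 2),
                                          means, 0.1, 1, 10, 1),
               "sum to 1")
  expect_error(gen_hidden_markov_features(diag(2), means, 0.1, 1, 10, 1),
               "reducible")
  expect_error(gen_hidden_markov_features(
    matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
    rbind(c(1, 1), c(1, 1)), 0.1, 1, 10, 1), "distinct")
})

test_that("hidden state frequencies and transition counts converge to truth", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  g <- gen_hidden_markov_features(T, rbind(0, 1), 0.1, n_traj = 1,
                                  n_frames = 200000, seed = 11)
  path <- g$hidden_path[[1]]
  ## state-0 frequency within 3 SE of pi = 2/3; SE accounts for the
  ## chain's autocorrelation time (1 + 2 sum rho ~ (1+r)/(1-r), r = 0.7)
  f <- mean(path == 1)
  se <- sqrt(2 / 9 / length(path) * (1 + 0.7) / (1 - 0.7))
  expect_lt(abs(f - 2 / 3), 3 * se)
  ## empirical transition matrix close to T_true
  C <- count_matrix(list(path), 1)
  That <- C / rowSums(C)
  expect_lt(max(abs(That - T)), 5 / sqrt(min(rowSums(C))))
})

test_that("toy loop generator plants the advertised product kinetics", {
  se <- gen_toy_loop_trajectory(n_traj = 2, n_frames = 400, seed = 5)
  kin <- se$kinetics
  expect_equal(kin$pi_true, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(kin$slow_loop_residues, 28:33)
  expect_true(se$separability_ok)
  expect_length(se$hidden_path[[1]], 400)
  ## slow-block 2-state MFPT: product-chain set passage equals 1/p
  se2 <- gen_toy_loop_trajectory(rates = list(fast = 0.01, slow = 0.001),
                                 n_traj = 1, n_frames = 10,
                                 n_residues = 40, seed = 1)
  expect_equal(true_mfpt(se2$kinetics$T_true, c(1, 2), c(3, 4)), 1000,
               tolerance = 1e-9)
  ## same seed reproduces coordinates exactly
  sea <- gen_toy_loop_trajectory(n_traj = 1, n_frames = 50, seed = 9)
  seb <- gen_toy_loop_trajectory(n_traj = 1, n_frames = 50, seed = 9)
  expect_identical(sea$ensemble$coords, seb$ensemble$coords)
})

test_that("static toy (zero rates) has jitter-level fluctuations only", {
  se <- gen_toy_loop_trajectory(rates = list(fast = 0, slow = 0),
                                jitter_sd = 0.2, n_traj = 1,
                                n_frames = 4000, seed = 3)
  expect_null(se$kinetics)
  r <- ca_rmsf(se$ensemble)
  ## isotropic Gaussian jitter: RMSF -> sigma * sqrt(3)
  expect_equal(unname(mean(r)), 0.2 * sqrt(3), tolerance = 0.05)
})

test_that("overlapping loop geometry precondition is enforced", {
  expect_warning(
    gen_toy_loop_trajectory(displacement = 0.5, jitter_sd = 0.3,
                            n_traj = 1, n_frames = 20, seed = 1),
    "separability|jitter")
  expect_error(gen_toy_loop_trajectory(fast_block = 8:12,
                                       slow_block = 10:14,
                                       n_traj = 1, n_frames = 10),
               "disjoint")
  expect_error(gen_toy_loop_trajectory(
    rates = list(fast = 0.001, slow = 0.01), n_traj = 1, n_frames = 10),
    "below the fast")
})

test_that("synthetic relaxation data follow the forward model", {
  ## rigid limit with zero noise: NOE identical across residues
  tr <- relaxation_truth(S2_true = 1, tau_e_true = 0, tau_m_true = 14.7,
                         field_MHz = 800,
                         noise_sd = list(R1 = 0, R2 = 0, NOE = 0))
  ds <- gen_relaxation_data(tr, 12, seed = 1)
  expect_equal(var(ds$data$NOE), 0)
  ## rigid residues share one R2/R1 ratio at tau_m = 14.7 ns, 800 MHz
  expect_equal(var(ds$data$R2 / ds$data$R1), 0, tolerance = 1e-20)
  ## determinism
  tr2 <- relaxation_truth(S2_true = c(0.7, 0.9), tau_e_true = 40,
                          tau_m_true = 10)
  d1 <- gen_relaxation_data(tr2, 8, seed = 4)
  d2 <- gen_relaxation_data(tr2, 8, seed = 4)
  expect_identical(d1$data, d2$data)
  ## truth validation
  expect_error(relaxation_truth(S2_true = 1.2), "\\[0, 1\\]")
  expect_error(relaxation_truth(0.9, tau_e_true = 2000,
                                tau_m_true = 1), "below tau_m")
})
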
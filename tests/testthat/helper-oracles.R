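## Independent oracles and small fixture builders shared across tests.
## These deliberately avoid the package's own linear-solve / estimator
## code paths.

## Brute-force mean first passage time by stochastic simulation:
## replicas start pi-weighted on the source set and step until a
## target state is hit.  Returns mean and standard error.
simulate_mfpt <- function(T, source_set, target_set, n_rep = 1e5,
                          seed = 1, horizon = 1e4) {
  set.seed(seed)
  n <- nrow(T)
  pi <- Re(eigen(t(T))$vectors[, 1]); pi <- pi / sum(pi)
  w <- pi[source_set] / sum(pi[source_set])
  s <- sample(rep(source_set, 2), n_rep, replace = TRUE, prob = rep(w, 2))
  cum <- t(apply(T, 1, cumsum))
  steps <- rep(NA_real_, n_rep)
  active <- rep(TRUE, n_rep)
  for (t in seq_len(horizon)) {
    ia <- which(active)
    if (!length(ia)) break
    u <- runif(length(ia))
    s[ia] <- rowSums(cum[s[ia], , drop = FALSE] < u) + 1L
    hit <- ia[s[ia] %in% target_set]
    steps[hit] <- t
    active[hit] <- FALSE
  }
  stopifnot(!anyNA(steps))          # horizon generous for test chains
  c(mean = mean(steps), se = sd(steps) / sqrt(n_rep))
}

## Exact first-passage expectation by forward propagation with an
## absorbing target: E[T] = sum_t t * P(first absorption at t).
enumerate_mfpt <- function(T, source_set, target_set, horizon = 1e4) {
  n <- nrow(T)
  pi <- Re(eigen(t(T))$vectors[, 1]); pi <- pi / sum(pi)
  p <- numeric(n)
  p[source_set] <- pi[source_set] / sum(pi[source_set])
  expect <- 0
  for (t in seq_len(horizon)) {
    p <- as.numeric(p %*% T)            # mass entering the target this
    expect <- expect + t * sum(p[target_set])   # step is absorbed
    p[target_set] <- 0
    if (sum(p) < 1e-14) break
  }
  expect
}

## Discrete trajectories simulated straight from a transition matrix
## (bypassing the package generators) for MSM-level tests.
sim_dtrajs <- function(T, n_traj, n_frames, seed) {
  set.seed(seed)
  pi <- Re(eigen(t(T))$vectors[, 1]); pi <- pi / sum(pi)
  cum <- t(apply(T, 1, cumsum))
  lapply(seq_len(n_traj), function(r) {
    s <- integer(n_frames)
    s[1] <- sample.int(nrow(T), 1, prob = pi)
    for (t in 2:n_frames) s[t] <- sum(cum[s[t - 1], ] < runif(1)) + 1L
    s
  })
}

## Straight-chain topology fixture of n residues.
chain_topology <- function(n, clip = 0L) {
  topology(data.frame(index = seq_len(n), name = "GLY", chain = "A",
                      stringsAsFactors = FALSE), terminal_clip = clip)
}

## Deterministic small ensemble from an explicit coordinate closure.
coords_ensemble <- function(frames_list, dt = 1) {
  n_res <- dim(frames_list[[1]])[2]
  trajectory_ensemble(frames_list, chain_topology(n_res), dt = dt)
}

## Default toy-loop blocks, shared by selection/metastable tests.
TOY_SLOW <- 28:33
TOY_FAST <- 8:12

toy_features <- function(seed, n_traj = 6, n_frames = 2000, ...) {
  se <- gen_toy_loop_trajectory(n_traj = n_traj, n_frames = n_frames,
                                seed = seed, ...)
  defs <- enumerate_ca_pairs(
    topology(se$ensemble$topology$residues, 2L))
  list(se = se, fm = compute_features(se$ensemble, defs))
}
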
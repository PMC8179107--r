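## Synthetic-data generators: planted Markov switching kinetics for a toy
## bead-chain protein, feature-level hidden-Markov emissions, and
## forward-modelled NMR relaxation data.  Every downstream stage of the
## pipeline can be validated against the ground truth these return.

#' Planted ground-truth kinetics
#'
#' Bundles a hidden row-stochastic transition matrix (at the frame
#' interval) with its exact stationary distribution and mean first
#' passage time matrix, plus the residue index sets whose geometry
#' encodes each hidden process.
#'
#' @param T_true row-stochastic hidden transition matrix.
#' @param macrostates character labels, one per hidden state.
#' @param slow_loop_residues,fast_loop_residues disjoint integer sets of
#'   anchor residues (1-based) encoding the slow and fast process.
#' @return object of class `planted_kinetics` with fields `T_true`,
#'   `pi_true`, `mfpt_true` (frames), `macrostates`,
#'   `slow_loop_residues`, `fast_loop_residues`.
#' @export
planted_kinetics <- function(T_true, macrostates = NULL,
                             slow_loop_residues = integer(),
                             fast_loop_residues = integer()) {
  check_stochastic(T_true, tol = 1e-12, require_irreducible = TRUE)
  n <- nrow(T_true)
  if (is.null(macrostates)) macrostates <- paste0("S", seq_len(n))
  if (length(macrostates) != n)
    stop_kl("need %d macrostate labels, got %d", n, length(macrostates))
  if (length(intersect(slow_loop_residues, fast_loop_residues)) > 0)
    stop_kl("slow and fast loop residue sets must be disjoint")
  pi_true <- stationary_distribution(T_true)
  mfpt <- matrix(0, n, n, dimnames = list(macrostates, macrostates))
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i != j) mfpt[i, j] <- true_mfpt(T_true, i, j)
  }
  structure(list(macrostates = macrostates, T_true = T_true,
                 pi_true = pi_true, mfpt_true = mfpt,
                 slow_loop_residues = as.integer(slow_loop_residues),
                 fast_loop_residues = as.integer(fast_loop_residues)),
            class = "planted_kinetics")
}

#' Exact mean first passage time on a Markov chain
#'
#' Solves the first-passage linear system
#' `m_i = 1 + sum_{j not in target} T_ij m_j`, with `m = 0` on the
#' target set, and returns the stationary-weighted average of `m` over
#' the source set.  Time unit is one transition (one frame at the
#' matrix's lag).
#'
#' @param T row-stochastic, irreducible transition matrix.
#' @param source_set,target_set disjoint nonempty integer state sets.
#' @return mean first passage time in frames.
#' @export
true_mfpt <- function(T, source_set, target_set) {
  check_stochastic(T)
  n <- nrow(T)
  source_set <- as.integer(source_set); target_set <- as.integer(target_set)
  if (!length(source_set) || !length(target_set))
    stop_kl("source and target sets must be nonempty")
  if (any(c(source_set, target_set) < 1L | c(source_set, target_set) > n))
    stop_kl("state indices must lie in 1..%d", n)
  if (length(unique(target_set)) == n) return(0)  # already there
  if (length(intersect(source_set, target_set)))
    stop_kl("source and target sets must be disjoint")
  free <- setdiff(seq_len(n), target_set)
  A <- diag(length(free)) - T[free, free, drop = FALSE]
  m_free <- tryCatch(solve(A, rep(1, length(free))),
    error = function(e) {
      g <- igraph::graph_from_adjacency_matrix((T > 0) * 1,
                                               mode = "directed")
      d <- igraph::distances(g, v = free, to = target_set, mode = "out")
      bad <- free[apply(d, 1, function(r) all(!is.finite(r)))]
      stop_kl("first-passage system is singular; states {%s} cannot reach the target",
              paste(bad, collapse = ","))
    })
  m <- numeric(n); m[free] <- m_free
  pi <- stationary_distribution(T)
  sum(pi[source_set] * m[source_set]) / sum(pi[source_set])
}

## Simulate a discrete Markov chain path of length n from T, starting
## from a draw of the stationary distribution.
simulate_chain <- function(T, n, start = NULL) {
  k <- nrow(T)
  path <- integer(n)
  path[1] <- if (is.null(start)) {
    sample.int(k, 1, prob = stationary_distribution(T))
  } else as.integer(start)
  if (n > 1) for (t in 2:n) {
    path[t] <- sample.int(k, 1, prob = T[path[t - 1], ])
  }
  path
}

#' Hidden-Markov Gaussian feature emissions
#'
#' Simulates hidden state paths from a planted transition matrix and
#' emits feature vectors as the state centroid plus isotropic Gaussian
#' noise.  This is the feature-level oracle for the tICA and MSM
#' stages: the slow eigenvalues of `T_true` are the quantities those
#' stages must recover.
#'
#' @param T_true row-stochastic, irreducible hidden transition matrix.
#' @param state_means matrix `n_states x n_features` of pairwise
#'   distinct state centroids.
#' @param noise_sd isotropic emission standard deviation.
#' @param n_traj,n_frames number and length of independent trajectories.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return list with `features` (a [feature_matrix()]), `hidden_path`
#'   (list of per-trajectory integer state paths) and `kinetics`
#'   (a [planted_kinetics()]).
#' @export
gen_hidden_markov_features <- function(T_true, state_means, noise_sd,
                                       n_traj = 1L, n_frames = 1000L,
                                       seed = 1L) {
  check_stochastic(T_true, tol = 1e-12, require_irreducible = TRUE)
  state_means <- as.matrix(state_means)
  if (nrow(state_means) != nrow(T_true))
    stop_kl("state_means must have one row per hidden state")
  if (anyDuplicated(state_means))
    stop_kl("state centroids must be pairwise distinct")
  set.seed(derive_seed(seed, 11L))
  d <- ncol(state_means)
  paths <- vector("list", n_traj)
  vals <- vector("list", n_traj)
  for (r in seq_len(n_traj)) {
    path <- simulate_chain(T_true, n_frames)
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_frames * d, sd = noise_sd), n_frames, d)
    } else matrix(0, n_frames, d)
    vals[[r]] <- state_means[path, , drop = FALSE] + noise
    paths[[r]] <- path
  }
  fm <- feature_matrix(do.call(rbind, vals),
                       labels = paste0("F", seq_len(d)),
                       segments = rep(n_frames, n_traj))
  list(features = fm, hidden_path = paths,
       kinetics = planted_kinetics(T_true), seed = as.integer(seed))
}

## 2-state per-frame switching matrix from one or two probabilities.
two_state_T <- function(p) {
  p <- rep(as.numeric(p), length.out = 2)
  if (any(p < 0) || any(p > 1)) stop_kl("switch probabilities must be in [0,1]")
  matrix(c(1 - p[1], p[1], p[2], 1 - p[2]), 2, 2, byrow = TRUE)
}

#' Toy bead-chain ensemble with two planted switching loops
#'
#' Generates Cartesian C-alpha trajectories of a linear bead chain
#' (3.8 A spacing) in which two disjoint residue blocks — the "loops" —
#' each interconvert between a baseline (recessed) and a displaced
#' (extended) geometry under independent two-state Markov chains, one
#' slow and one fast, while scaffold residues only jitter about fixed
#' positions.  The 4-state product chain, its stationary distribution
#' and exact MFPTs are returned as ground truth, emulating a protein in
#' which one loop carries the slowest conformational process and a
#' second loop a faster one.
#'
#' @param n_residues chain length (beads).
#' @param fast_block,slow_block disjoint 1-based residue index blocks.
#' @param rates list with elements `fast` and `slow`: per-frame switch
#'   probabilities (scalar symmetric, or length-2 `c(p01, p10)`).  The
#'   slow block's probabilities must be smaller than the fast block's.
#' @param displacement Angstrom offset between the two conformations of
#'   each block (perpendicular to the chain axis).
#' @param jitter_sd Gaussian positional noise per coordinate (Angstrom).
#' @param n_traj,n_frames number and length of independent trajectories.
#' @param dt frame interval in ns (metadata only).
#' @param seed integer seed.
#' @return object of class `synthetic_ensemble`: fields `ensemble`
#'   (a [trajectory_ensemble()]), `hidden_path` (per-trajectory product
#'   state paths, slow-major indexing), `hidden_slow`, `hidden_fast`
#'   (per-block 1/2 paths), `kinetics` ([planted_kinetics()]),
#'   `separability_ok` (FALSE flags geometries too close for reliable
#'   feature selection) and `seed`.
#' @export
gen_toy_loop_trajectory <- function(n_residues = 40L,
                                    fast_block = 8:12,
                                    slow_block = 28:33,
                                    rates = list(fast = 0.01, slow = 0.002),
                                    displacement = 6,
                                    jitter_sd = 0.3,
                                    n_traj = 4L, n_frames = 2000L,
                                    dt = 1, seed = 1L) {
  fast_block <- as.integer(fast_block); slow_block <- as.integer(slow_block)
  if (length(intersect(fast_block, slow_block)))
    stop_kl("loop blocks must be disjoint")
  if (any(c(fast_block, slow_block) < 1L) ||
      any(c(fast_block, slow_block) > n_residues))
    stop_kl("loop blocks must lie inside 1..%d", n_residues)
  p_fast <- rep(as.numeric(rates$fast), length.out = 2)
  p_slow <- rep(as.numeric(rates$slow), length.out = 2)
  static <- all(c(p_fast, p_slow) == 0)
  if (!static && max(p_slow) >= min(p_fast))
    stop_kl("slow block switch probability (%g) must be below the fast block's (%g)",
            max(p_slow), min(p_fast))

  ## baseline geometry: straight chain along x at 3.8 A spacing
  base <- cbind(x = (seq_len(n_residues) - 1) * 3.8, y = 0, z = 0)
  disp_fast <- base; disp_fast[fast_block, "y"] <- displacement
  disp_slow <- base; disp_slow[slow_block, "z"] <- displacement

  ## separability: each block residue's distance change to the nearest
  ## scaffold residues must exceed 4 x jitter_sd for at least one pair
  scaffold <- setdiff(seq_len(n_residues), c(fast_block, slow_block))
  sep_of <- function(block, displaced) {
    min(vapply(block, function(i) {
      d0 <- sqrt(rowSums((base[scaffold, , drop = FALSE] -
                          matrix(base[i, ], length(scaffold), 3, byrow = TRUE))^2))
      d1 <- sqrt(rowSums((base[scaffold, , drop = FALSE] -
                          matrix(displaced[i, ], length(scaffold), 3, byrow = TRUE))^2))
      max(abs(d1 - d0))
    }, numeric(1)))
  }
  separability_ok <- min(sep_of(fast_block, disp_fast),
                         sep_of(slow_block, disp_slow)) > 4 * jitter_sd
  if (!separability_ok)
    warning("loop geometries are closer than 4 x jitter_sd; ",
            "kinetic feature selection may fail", call. = FALSE)

  ## product chain, slow-major: state = 2*(s_slow - 1) + s_fast
  T_fast <- two_state_T(p_fast); T_slow <- two_state_T(p_slow)
  labels <- c("slowR.fastR", "slowR.fastE", "slowE.fastR", "slowE.fastE")
  if (static) {
    kin <- NULL                      # degenerate: no kinetics to plant
  } else {
    kin <- planted_kinetics(kronecker(T_slow, T_fast), labels,
                            slow_loop_residues = slow_block,
                            fast_loop_residues = fast_block)
  }

  set.seed(derive_seed(seed, 29L))
  coords <- vector("list", n_traj)
  hid_slow <- hid_fast <- hid_prod <- vector("list", n_traj)
  for (r in seq_len(n_traj)) {
    sf <- if (static) rep(1L, n_frames) else simulate_chain(T_fast, n_frames)
    ss <- if (static) rep(1L, n_frames) else simulate_chain(T_slow, n_frames)
    arr <- array(0, dim = c(n_frames, n_residues, 3))
    for (t in seq_len(n_frames)) {
      pos <- base
      if (sf[t] == 2L) pos[fast_block, ] <- disp_fast[fast_block, ]
      if (ss[t] == 2L) pos[slow_block, ] <- disp_slow[slow_block, ]
      arr[t, , ] <- pos
    }
    if (jitter_sd > 0)
      arr <- arr + array(rnorm(length(arr), sd = jitter_sd), dim = dim(arr))
    coords[[r]] <- arr
    hid_fast[[r]] <- sf; hid_slow[[r]] <- ss
    hid_prod[[r]] <- 2L * (ss - 1L) + sf
  }
  top <- topology(data.frame(index = seq_len(n_residues),
                             name = "GLY", chain = "A",
                             stringsAsFactors = FALSE))
  ens <- trajectory_ensemble(coords, top, dt = dt)
  structure(list(ensemble = ens, hidden_path = hid_prod,
                 hidden_slow = hid_slow, hidden_fast = hid_fast,
                 kinetics = kin, separability_ok = separability_ok,
                 seed = as.integer(seed)),
            class = "synthetic_ensemble")
}

#' Ground truth for synthetic relaxation data
#'
#' @param S2_true generalized order parameters in `[0, 1]` (recycled to
#'   `n_residues` by [gen_relaxation_data()]).
#' @param tau_e_true internal correlation times (ps).
#' @param tau_m_true global rotational correlation time (ns).
#' @param field_MHz proton Larmor frequency of the spectrometer.
#' @param noise_sd named list of Gaussian noise SDs for `R1`, `R2`
#'   (s^-1) and `NOE` (dimensionless).
#' @param rex_true optional chemical-exchange contributions to R2
#'   (s^-1), default 0.
#' @return object of class `relaxation_truth`.
#' @export
relaxation_truth <- function(S2_true, tau_e_true = 50, tau_m_true = 10,
                             field_MHz = 800,
                             noise_sd = list(R1 = 0.02, R2 = 0.3,
                                             NOE = 0.02),
                             rex_true = 0) {
  if (any(S2_true < 0 | S2_true > 1)) stop_kl("S2_true must lie in [0, 1]")
  if (any(tau_e_true < 0)) stop_kl("tau_e_true must be >= 0")
  if (tau_m_true <= 0) stop_kl("tau_m_true must be positive")
  if (any(tau_e_true / 1000 >= tau_m_true))
    stop_kl("tau_e_true (ps) must be below tau_m_true (ns)")
  if (field_MHz <= 0) stop_kl("field_MHz must be positive")
  structure(list(S2_true = S2_true, tau_e_true = tau_e_true,
                 tau_m_true = tau_m_true, field_MHz = field_MHz,
                 noise_sd = noise_sd, rex_true = rex_true),
            class = "relaxation_truth")
}

#' Forward-modelled synthetic relaxation dataset
#'
#' Computes R1, R2 and heteronuclear NOE for each residue from the
#' Lipari-Szabo model-free forward model at the truth's field strength,
#' then adds Gaussian noise of the stated SDs; the error columns are
#' set to those SDs.
#'
#' @param truth a [relaxation_truth()].
#' @param n_residues number of residues (truth vectors are recycled).
#' @param seed integer seed.
#' @return a [relaxation_dataset()].
#' @export
gen_relaxation_data <- function(truth, n_residues, seed = 1L) {
  stopifnot(inherits(truth, "relaxation_truth"))
  S2 <- rep(truth$S2_true, length.out = n_residues)
  te <- rep(truth$tau_e_true, length.out = n_residues)
  rex <- rep(truth$rex_true, length.out = n_residues)
  set.seed(derive_seed(seed, 41L))
  fw <- vapply(seq_len(n_residues), function(i) {
    unlist(modelfree_forward(S2[i], te[i], truth$tau_m_true, rex[i],
                             truth$field_MHz))
  }, numeric(3))
  ns <- truth$noise_sd
  df <- data.frame(
    residue = seq_len(n_residues),
    R1  = fw["R1", ]  + rnorm(n_residues, sd = ns$R1),
    R1err = ns$R1,
    R2  = fw["R2", ]  + rnorm(n_residues, sd = ns$R2),
    R2err = ns$R2,
    NOE = fw["NOE", ] + rnorm(n_residues, sd = ns$NOE),
    NOEerr = ns$NOE)
  relaxation_dataset(df, field_MHz = truth$field_MHz)
}
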
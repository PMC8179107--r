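## Metastable coarse-graining: PCCA+ memberships of the reversible
## microstate model initialize a discrete-output hidden Markov model
## refined by Baum-Welch; macrostate populations come from the hidden
## stationary distribution, uncertainties from a trajectory bootstrap,
## and macrostate MFPTs from the hidden transition matrix.

#' Choose the macrostate count from an implied-timescale gap
#'
#' Returns `1 + k*` where `k*` maximizes the ratio `t_k / t_{k+1}`
#' among the supplied (descending) timescales: the model keeps the
#' processes above the widest spectral gap.
#'
#' @param timescales numeric vector of implied timescales, slowest
#'   first (>= 3 values).
#' @param override explicit macrostate count; always honored when
#'   given.
#' @param min_ratio gaps below this ratio are considered degenerate.
#' @return integer macrostate count.
#' @export
select_macrostate_count <- function(timescales, override = NULL,
                                    min_ratio = 1.5) {
  if (!is.null(override)) return(as.integer(override))
  timescales <- timescales[is.finite(timescales) & timescales > 0]
  if (length(timescales) < 2)
    stop_kl("need >= 2 finite timescales to locate a gap")
  ratios <- timescales[-length(timescales)] / timescales[-1]
  if (all(ratios < min_ratio))
    stop_kl("no timescale gap exceeds ratio %.2g; supply an explicit count",
            min_ratio)
  unname(1L + which.max(ratios))
}

#' PCCA+ fuzzy memberships of a reversible transition matrix
#'
#' Spectral clustering of the dominant right eigenvectors into
#' `n_macro` metastable memberships via the inner-simplex vertex
#' construction: the rows spanning the largest simplex in eigenvector
#' space become crisp vertices and every other microstate is expressed
#' as a convex combination of them.
#'
#' @param T reversible row-stochastic matrix.
#' @param pi its stationary distribution.
#' @param n_macro number of metastable sets (>= 2).
#' @return `n_micro x n_macro` membership matrix with unit row sums.
#' @export
pcca_memberships <- function(T, pi, n_macro) {
  n <- nrow(T)
  if (n_macro < 2) stop_kl("n_macro must be >= 2")
  if (n_macro > n) stop_kl("n_macro exceeds the %d microstates", n)
  s <- sqrt(pi)
  S <- T * outer(s, 1 / s); S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ## right eigenvectors of T, stationary one first, normalized so psi1 = 1
  X <- e$vectors[, seq_len(n_macro), drop = FALSE] / s
  X <- X / X[1, 1]
  X[, 1] <- 1
  ## inner simplex: successively pick the row farthest from the span
  ## of the already chosen (shifted) vertices
  idx <- integer(n_macro)
  idx[1] <- which.max(rowSums(X^2))
  shifted <- sweep(X, 2, X[idx[1], ])
  for (k in 2:n_macro) {
    M <- shifted
    if (k > 2) {
      V <- t(shifted[idx[2:(k - 1)], , drop = FALSE])
      Q <- qr.Q(qr(V))
      M <- M - (M %*% Q) %*% t(Q)
    }
    idx[k] <- which.max(rowSums(M^2))
  }
  ## memberships: chi = X %*% inv(X[vertices, ])
  A <- tryCatch(solve(X[idx, , drop = FALSE]),
                error = function(e)
                  stop_kl("degenerate eigenvector simplex; reduce n_macro"))
  chi <- X %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi / rs
}

## Strided observation sequences for an HMM at lag > 1: one
## subsequence per offset, so every transition pair at the lag is used
## exactly once.
stride_sequences <- function(seqs, lag) {
  if (lag == 1L) return(seqs)
  out <- list()
  for (s in seqs) for (o in seq_len(lag)) {
    sub <- s[seq.int(o, length(s), by = lag)]
    if (length(sub) >= 2) out[[length(out) + 1]] <- sub
  }
  out
}

baum_welch <- function(seqs, A, B, pi0, tol = 1e-6, max_iter = 500L) {
  n <- nrow(A); m <- ncol(B)
  if (max_iter == 0L)
    return(list(A = A, B = B, pi0 = pi0, loglik = NA_real_,
                iterations = 0L))
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    xi <- matrix(0, n, n); go <- matrix(0, n, m); g0 <- numeric(n)
    ll <- 0
    for (s in seqs) {
      st <- hmm_forward_backward(as.integer(s), A, B, pi0)
      ll <- ll + st$loglik
      xi <- xi + st$xi_sum; go <- go + st$gamma_obs; g0 <- g0 + st$gamma0
    }
    A <- (xi + 1e-12) / rowSums(xi + 1e-12)
    B <- (go + 1e-12) / rowSums(go + 1e-12)
    pi0 <- (g0 + 1e-12) / sum(g0 + 1e-12)
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
  }
  list(A = A, B = B, pi0 = pi0, loglik = ll, iterations = it)
}

#' HMM coarse-graining of discrete trajectories into metastable states
#'
#' Estimates a reversible microstate model at the given lag, derives
#' PCCA+ memberships as initialization, and refines a discrete-output
#' hidden Markov model by Baum-Welch (stopping when the log-likelihood
#' gain drops below `tol`).  Macrostate populations are the hidden
#' chain's stationary distribution.
#'
#' @param dtrajs a `discrete_trajectories` or list of integer state
#'   sequences.
#' @param n_macrostates number of metastable states (>= 2).
#' @param lag lag in frames.
#' @param dt physical time per frame (metadata).
#' @param tol Baum-Welch log-likelihood convergence threshold.
#' @param max_iter Baum-Welch iteration cap.
#' @return object of class `metastable_model`: `n_macrostates`,
#'   `memberships` (microstate -> macrostate posterior),
#'   `coarse_T` (hidden transition matrix at the lag), `populations`,
#'   `populations_sd` (`NA` until [population_uncertainty()] fills
#'   them), `emission`, `mfpt` (physical time), `timescales`
#'   (physical), `assignments` (per-trajectory frame macrostate
#'   labels), `micro_msm`, `lag`, `dt`, `loglik`.
#' @export
coarse_grain_hmm <- function(dtrajs, n_macrostates, lag = 1L, dt = 1,
                             tol = 1e-6, max_iter = 500L) {
  seqs <- if (inherits(dtrajs, "discrete_trajectories")) dtrajs$dtrajs
          else dtrajs
  n_macrostates <- as.integer(n_macrostates)
  n_obs <- max(unlist(seqs))
  msm <- estimate_reversible_msm(count_matrix(seqs, lag,
                                              n_states = n_obs),
                                 lag = lag, dt = dt)
  if (n_macrostates >= length(msm$active)) {
    ## degenerate request: macrostates are the microstates themselves
    n_macrostates <- length(msm$active)
    chi <- diag(n_macrostates)
  } else {
    chi <- pcca_memberships(msm$T, msm$pi, n_macrostates)
  }
  fit_from <- function(chi0) {
    ## initial hidden matrices from the membership coarse-graining
    W <- chi0 * msm$pi                      # n_micro x n_macro, joint
    pop0 <- colSums(W)
    A <- t(W) %*% msm$T %*% chi0
    A <- A / pop0
    A[A < 1e-10] <- 1e-10
    A <- A / rowSums(A)
    B <- matrix(1e-10, n_macrostates, n_obs)
    B[, msm$active] <- t(W)
    B <- B / rowSums(B)
    bw <- baum_welch(stride_sequences(seqs, lag), A, B,
                     pop0 / sum(pop0), tol = tol, max_iter = max_iter)
    pop <- stationary_distribution(bw$A)
    if (any(pop < 1e-8))
      stop_kl("empty macrostate after Baum-Welch")
    list(bw = bw, pop = pop)
  }
  fit <- tryCatch(fit_from(chi), error = function(e) {
    crisp <- diag(ncol(chi))[max.col(chi), , drop = FALSE]
    fit_from(crisp)
  })
  bw <- fit$bw; pop <- fit$pop
  ## microstate -> macrostate posterior memberships via Bayes on the
  ## emission model
  post <- t(bw$B) * rep(pop, each = n_obs)   # n_obs x n_macro
  rs <- rowSums(post); rs[rs == 0] <- 1
  memberships <- post / rs
  macro_of_micro <- max.col(memberships)
  assignments <- lapply(seqs, function(s) macro_of_micro[s])
  mfpt <- matrix(0, n_macrostates, n_macrostates)
  for (i in seq_len(n_macrostates)) for (j in seq_len(n_macrostates)) {
    if (i != j) mfpt[i, j] <- true_mfpt(bw$A, i, j) * lag * dt
  }
  s <- sqrt(pop)
  S <- bw$A * outer(s, 1 / s); S <- (S + t(S)) / 2
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ts <- implied_ts(ev, lag * dt)
  structure(list(n_macrostates = n_macrostates, memberships = memberships,
                 coarse_T = bw$A, populations = pop,
                 populations_sd = rep(NA_real_, n_macrostates),
                 emission = bw$B, mfpt = mfpt, timescales = ts,
                 timescale_sd = NA_real_,
                 assignments = assignments, micro_msm = msm,
                 lag = as.integer(lag), dt = dt, loglik = bw$loglik),
            class = "metastable_model")
}

#' @export
print.metastable_model <- function(x, ...) {
  cat(sprintf("metastable model: %d macrostates (HMM at lag %d, dt %g)\n",
              x$n_macrostates, x$lag, x$dt))
  pops <- sprintf("%.3f%s", x$populations,
                  ifelse(is.na(x$populations_sd), "",
                         sprintf(" +/- %.3f", x$populations_sd)))
  cat("  populations:", paste(pops, collapse = ", "), "\n")
  invisible(x)
}

## Greedy macrostate matching by pi-weighted membership overlap.
match_macrostates_by_membership <- function(ref, other, pi_micro) {
  O <- t(ref * pi_micro) %*% other
  n <- ncol(ref)
  perm <- integer(n)
  used <- logical(n)
  for (k in order(-apply(O, 1, max))) {
    j <- order(-O[k, ])
    j <- j[!used[j]][1]
    perm[k] <- j; used[j] <- TRUE
  }
  perm
}

#' Bootstrap uncertainties for macrostate populations
#'
#' Resamples whole trajectories with replacement (the resampling unit
#' that respects temporal correlation), re-estimates the coarse model
#' on each replica, matches its macrostates to the reference model by
#' maximal membership overlap, and returns per-macrostate population
#' SDs plus the SD of the slowest hidden timescale.  With a single
#' trajectory it falls back, with a warning, to a block bootstrap over
#' contiguous segments.
#'
#' @param dtrajs the `discrete_trajectories` the model was built from.
#' @param model the reference [coarse_grain_hmm()] model.
#' @param n_boot number of bootstrap replicas (>= 1).
#' @param seed integer seed.
#' @param n_blocks blocks used by the single-trajectory fallback.
#' @return the model, with `populations_sd`, `timescale_sd`,
#'   `mfpt_sd` and a `bootstrap` field (replicate populations and
#'   MFPTs) filled in.
#' @export
population_uncertainty <- function(dtrajs, model, n_boot = 50L,
                                   seed = 1L, n_blocks = 10L) {
  stopifnot(inherits(model, "metastable_model"))
  seqs <- if (inherits(dtrajs, "discrete_trajectories")) dtrajs$dtrajs
          else dtrajs
  n_boot <- as.integer(n_boot)
  if (n_boot < 1) stop_kl("n_boot must be >= 1")
  if (length(seqs) < 2) {
    warning("single trajectory: falling back to a block bootstrap over ",
            n_blocks, " contiguous segments", call. = FALSE)
    L <- length(seqs[[1]])
    bounds <- floor(seq(0, L, length.out = n_blocks + 1))
    seqs <- lapply(seq_len(n_blocks), function(b)
      seqs[[1]][(bounds[b] + 1):bounds[b + 1]])
  }
  set.seed(derive_seed(seed, 71L))
  n <- model$n_macrostates
  pops <- matrix(NA_real_, n_boot, n)
  mfpts <- array(NA_real_, c(n_boot, n, n))
  ts1 <- rep(NA_real_, n_boot)
  pi_micro <- numeric(nrow(model$memberships))
  pi_micro[model$micro_msm$active] <- model$micro_msm$pi
  for (b in seq_len(n_boot)) {
    take <- sample.int(length(seqs), length(seqs), replace = TRUE)
    rep_model <- tryCatch(
      coarse_grain_hmm(seqs[take], n, lag = model$lag, dt = model$dt),
      error = function(e) NULL)
    if (is.null(rep_model)) next
    if (rep_model$n_macrostates != n) next
    common <- seq_len(min(nrow(model$memberships),
                          nrow(rep_model$memberships)))
    perm <- match_macrostates_by_membership(
      model$memberships[common, , drop = FALSE],
      rep_model$memberships[common, , drop = FALSE], pi_micro[common])
    pops[b, ] <- rep_model$populations[perm]
    mfpts[b, , ] <- rep_model$mfpt[perm, perm]
    ts1[b] <- rep_model$timescales[2]
  }
  ok <- rowSums(is.na(pops)) == 0
  if (!any(ok)) stop_kl("all bootstrap replicas failed")
  model$populations_sd <- apply(pops[ok, , drop = FALSE], 2, sd)
  model$timescale_sd <- sd(ts1[ok])
  model$mfpt_sd <- apply(mfpts[ok, , , drop = FALSE], c(2, 3), sd)
  model$bootstrap <- list(populations = pops[ok, , drop = FALSE],
                          mfpt = mfpts[ok, , , drop = FALSE],
                          slowest_timescale = ts1[ok])
  model
}

#' Mean first passage time between macrostates
#'
#' Linear-system MFPT on the hidden transition matrix, converted to
#' physical time (`x lag x dt`); the bootstrap SD is attached when the
#' model carries bootstrap replicas.
#'
#' @param model a [coarse_grain_hmm()] model.
#' @param source,target macrostate indices (disjoint).
#' @param dt physical time per frame; defaults to the model's.
#' @return list with `mfpt` and `sd` (`NA` without bootstrap).
#' @export
macro_mfpt <- function(model, source, target, dt = model$dt) {
  stopifnot(inherits(model, "metastable_model"))
  m <- true_mfpt(model$coarse_T, source, target) * model$lag * dt
  sdv <- NA_real_
  if (!is.null(model$bootstrap) && length(source) == 1 &&
      length(target) == 1) {
    reps <- model$bootstrap$mfpt[, source, target] * dt / model$dt
    sdv <- sd(reps, na.rm = TRUE)
  }
  list(mfpt = m, sd = sdv)
}
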
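## Microstate Markov state model: k-means discretization of the tIC
## projection, sliding-window transition counts, reversible
## maximum-likelihood transition-matrix estimation, implied timescales,
## Chapman-Kolmogorov validation and free-energy surfaces.

#' Discretize projected frames into microstates
#'
#' Seeded k-means (k-means++ initialization, Lloyd iterations) in tIC
#' space; every frame is assigned to its nearest center.
#'
#' @param projected `frames x d` matrix of tIC coordinates.
#' @param k number of microstates.
#' @param seed integer seed (clustering is deterministic given it).
#' @param segments per-trajectory frame counts (default: one segment).
#' @return object of class `discrete_trajectories`: `dtrajs` (list of
#'   1-based integer state sequences), `n_states`, `centers`, `seed`.
#' @export
cluster_microstates <- function(projected, k, seed = 1L,
                                segments = nrow(projected)) {
  projected <- as.matrix(projected)
  k <- as.integer(k)
  if (k < 1) stop_kl("k must be >= 1")
  if (k > nrow(projected))
    stop_kl("k = %d exceeds the %d available frames", k, nrow(projected))
  set.seed(derive_seed(seed, 57L))
  if (k == 1L) {
    centers <- matrix(colMeans(projected), 1)
    labels <- rep(1L, nrow(projected))
  } else {
    ## k-means++ seeding
    n <- nrow(projected)
    ci <- sample.int(n, 1)
    centers <- projected[ci, , drop = FALSE]
    d2 <- rowSums(sweep(projected, 2, centers[1, ])^2)
    for (j in 2:k) {
      ci <- sample.int(n, 1, prob = pmax(d2, 1e-300))
      centers <- rbind(centers, projected[ci, , drop = FALSE])
      d2 <- pmin(d2, rowSums(sweep(projected, 2, centers[j, ])^2))
    }
    km <- suppressWarnings(
      kmeans(projected, centers = centers, iter.max = 200,
             algorithm = "Lloyd"))
    centers <- km$centers
    labels <- km$cluster
  }
  ends <- cumsum(segments)
  starts <- c(1L, head(ends, -1) + 1L)
  dtrajs <- Map(function(s, e) as.integer(labels[s:e]), starts, ends)
  structure(list(dtrajs = dtrajs, n_states = k, centers = centers,
                 seed = as.integer(seed)),
            class = "discrete_trajectories")
}

#' Sliding-window transition count matrix
#'
#' `C[i, j]` counts frame pairs `(t, t + lag)` with states `(i, j)`;
#' pairs never cross trajectory boundaries and counts from multiple
#' trajectories add.
#'
#' @param dtrajs a `discrete_trajectories`, or a list of integer state
#'   sequences.
#' @param lag lag in frames; must be below the shortest trajectory.
#' @param n_states total state count (inferred if omitted).
#' @return `n_states x n_states` count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  seqs <- if (inherits(dtrajs, "discrete_trajectories")) dtrajs$dtrajs
          else dtrajs
  lag <- as.integer(lag)
  if (lag < 1) stop_kl("lag must be >= 1")
  if (lag >= min(lengths(seqs)))
    stop_kl("lag = %d is not below the shortest trajectory (%d frames)",
            lag, min(lengths(seqs)))
  n <- n_states %||%
    (if (inherits(dtrajs, "discrete_trajectories")) dtrajs$n_states
     else max(unlist(seqs)))
  C <- matrix(0, n, n)
  for (s in seqs) {
    L <- length(s)
    from <- s[seq_len(L - lag)]
    to <- s[(lag + 1):L]
    tab <- tabulate((from - 1L) * n + to, nbins = n * n)
    C <- C + matrix(tab, n, n, byrow = TRUE)
  }
  C
}

#' Largest strongly connected set of a count matrix
#'
#' States in the strongly connected component carrying the greatest
#' total transition counts; states outside it are reported as dropped.
#'
#' @param counts square nonnegative count matrix.
#' @return integer vector of active state indices, with attribute
#'   `"dropped"`.
#' @export
largest_connected_set <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts) ||
      nrow(counts) == 0)
    stop_kl("counts must be a nonempty square matrix")
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  totals <- vapply(seq_len(comp$no), function(c) {
    s <- which(comp$membership == c)
    sum(counts[s, s, drop = FALSE])
  }, numeric(1))
  active <- sort(which(comp$membership == which.max(totals)))
  structure(active, dropped = setdiff(seq_len(nrow(counts)), active))
}

#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the transition matrix maximizing the likelihood of the
#' counts under detailed balance, via the standard self-consistent
#' fixed-point iteration on the unnormalized flux matrix
#' `x_ij <- (C_ij + C_ji) / (C_i/x_i + C_j/x_j)`; the stationary
#' distribution is the row-sum of the converged flux.  Counts are
#' restricted to their largest strongly connected set first.
#'
#' @param counts transition count matrix.
#' @param lag lag in frames at which `counts` were harvested.
#' @param dt physical time per frame (ns; metadata for timescales).
#' @param tol convergence threshold on the relative flux change.
#' @param max_iter sweep cap.
#' @return object of class `markov_model`: `T` (row-stochastic,
#'   reversible), `pi`, `eigenvalues` (descending), `timescales`
#'   (physical units, `-lag*dt/log(lambda)`), `active`, `counts`,
#'   `lag`, `dt`.
#' @export
estimate_reversible_msm <- function(counts, lag = 1L, dt = 1,
                                    tol = 1e-10, max_iter = 1e6) {
  active <- largest_connected_set(counts)
  C <- counts[active, active, drop = FALSE]
  if (!is_irreducible(C))
    stop_kl("active-set counts are not irreducible")
  n <- nrow(C)
  Cs <- C + t(C)
  Ci <- rowSums(C)
  x <- Cs / sum(Cs)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(Ci / xi, Ci / xi, "+")
    x_new <- Cs / denom
    x_new <- x_new / sum(x_new)
    delta <- max(abs(x_new - x) / pmax(x, 1e-300))
    x <- x_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop_kl("reversible MLE did not converge in %g sweeps (residual %.3g)",
            max_iter, delta)
  pi <- rowSums(x)
  T <- x / pi
  ## reversible T is similar to a symmetric matrix in the pi metric
  s <- sqrt(pi)
  S <- (T * outer(s, 1 / s)) ; S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  ts <- implied_ts(ev, lag * dt)
  structure(list(lag = as.integer(lag), dt = dt, active = as.integer(active),
                 counts = counts, T = T, pi = pi, eigenvalues = ev,
                 timescales = ts),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("reversible MSM: %d active states, lag %d frames (dt %g)\n",
              length(x$active), x$lag, x$dt))
  k <- min(5, length(x$timescales) - 1)
  cat("  slowest timescales: ",
      paste(signif(x$timescales[2:(k + 1)], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Implied timescales across lag times
#'
#' @param dtrajs a `discrete_trajectories` or list of state sequences.
#' @param lags candidate lags (frames), each below the shortest
#'   trajectory.
#' @param n_its number of timescales per lag.
#' @param dt physical time per frame.
#' @return data.frame `lag`, `its1..its<n_its>` in physical units; a
#'   lag whose estimation fails yields `NA`s rather than aborting.
#' @export
implied_timescales <- function(dtrajs, lags, n_its = 3, dt = 1) {
  rows <- lapply(lags, function(l) {
    ts <- tryCatch({
      m <- estimate_reversible_msm(count_matrix(dtrajs, l), lag = l,
                                   dt = dt)
      m$timescales[-1]         # drop the stationary eigenvalue
    }, error = function(e) rep(NA_real_, n_its))
    length(ts) <- n_its
    c(lag = l, stats::setNames(ts, paste0("its", seq_len(n_its))))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Chapman-Kolmogorov test on macro-set occupation
#'
#' Compares the model propagated to longer lags, `T(tau)^f`, with
#' models re-estimated at `f * tau`, projected on coarse state sets.
#'
#' @param msm a [estimate_reversible_msm()] model.
#' @param dtrajs the discrete trajectories it was estimated from.
#' @param macro_sets list of integer microstate sets (indices into the
#'   full state space).
#' @param factors integer lag multiples to test.
#' @return data.frame with columns `factor`, `set_from`, `set_to`,
#'   `predicted`, `estimated`, `deviation`.
#' @export
ck_test <- function(msm, dtrajs, macro_sets, factors = 1:5) {
  stopifnot(inherits(msm, "markov_model"))
  sets_active <- lapply(macro_sets, function(s) {
    m <- match(s, msm$active); m[!is.na(m)]
  })
  rows <- list()
  for (f in factors) {
    Tf <- if (f == 1) msm$T else {
      P <- msm$T
      for (i in seq_len(f - 1)) P <- P %*% msm$T
      P
    }
    est_msm <- estimate_reversible_msm(
      count_matrix(dtrajs, msm$lag * f), lag = msm$lag * f, dt = msm$dt)
    sets_est <- lapply(macro_sets, function(s) {
      m <- match(s, est_msm$active); m[!is.na(m)]
    })
    for (a in seq_along(macro_sets)) for (b in seq_along(macro_sets)) {
      wa <- msm$pi[sets_active[[a]]]; wa <- wa / sum(wa)
      pred <- sum(wa * rowSums(Tf[sets_active[[a]], sets_active[[b]],
                                  drop = FALSE]))
      wae <- est_msm$pi[sets_est[[a]]]; wae <- wae / sum(wae)
      est <- sum(wae * rowSums(est_msm$T[sets_est[[a]], sets_est[[b]],
                                         drop = FALSE]))
      rows[[length(rows) + 1]] <-
        data.frame(factor = f, set_from = a, set_to = b,
                   predicted = pred, estimated = est,
                   deviation = abs(pred - est))
    }
  }
  do.call(rbind, rows)
}

#' Free-energy surface over the two leading tICs
#'
#' 2D histogram of the projected frames (optionally weighted, e.g. by
#' per-frame stationary weights), converted to free energy
#' `F = -kT log p` and shifted so the minimum is zero; empty bins are
#' masked as `NA`.
#'
#' @param projected `frames x >=2` tIC coordinate matrix.
#' @param bins bins per axis (>= 10).
#' @param kT thermal energy unit of the output (default 1 kT).
#' @param weights optional per-frame weights.
#' @return object of class `free_energy_surface`: `x_edges`,
#'   `y_edges`, `F` (bins x bins, `NA` where unsampled), `kT`.
#' @export
free_energy_surface <- function(projected, bins = 50L, kT = 1,
                                weights = NULL) {
  projected <- as.matrix(projected)
  if (ncol(projected) < 2)
    stop_kl("free-energy surface needs >= 2 projected components")
  bins <- as.integer(bins)
  if (bins < 10) stop_kl("use at least 10 bins per axis")
  x <- projected[, 1]; y <- projected[, 2]
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop_kl("all frames fall in one bin; review the projection or bins")
  xe <- seq(min(x), max(x), length.out = bins + 1)
  ye <- seq(min(y), max(y), length.out = bins + 1)
  xi <- pmin(findInterval(x, xe, all.inside = TRUE), bins)
  yi <- pmin(findInterval(y, ye, all.inside = TRUE), bins)
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (length(w) != length(x))
    stop_kl("weights length (%d) must match frames (%d)", length(w),
            length(x))
  H <- matrix(0, bins, bins)
  for (t in seq_along(x)) H[xi[t], yi[t]] <- H[xi[t], yi[t]] + w[t]
  p <- H / sum(H)
  F <- -kT * log(p)
  F[!is.finite(F)] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(list(x_edges = xe, y_edges = ye, F = F, kT = kT),
            class = "free_energy_surface")
}
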
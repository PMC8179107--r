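## Time-lagged independent component analysis.  The slow collective
## coordinates of a feature time series are the solutions of the
## generalized eigenproblem  C(tau) v = lambda C(0) v, with C(0) the
## instantaneous and C(tau) the time-lagged covariance.  The
## symmetrized (reversible) estimator is used throughout, matching the
## equilibrium assumption of the downstream Markov state model.

#' Instantaneous and time-lagged covariance estimation
#'
#' Means are removed (pooled over the two lag-shifted frame sets) and
#' the lagged covariance is symmetrized, `(C + t(C))/2`, enforcing
#' reversibility.  Frame pairs never cross trajectory segment
#' boundaries.
#'
#' @param fm a [feature_matrix()].
#' @param lag lag time in frames (>= 1); every segment must be longer
#'   than `lag`.
#' @return object of class `tica_covariances`: `C0`, `Ctau`, `means`,
#'   `labels`, `lag`, `n_pairs`, and `rank_deficient` flag.
#' @export
estimate_covariances <- function(fm, lag) {
  stopifnot(inherits(fm, "feature_matrix"))
  lag <- as.integer(lag)
  if (lag < 1) stop_kl("lag must be >= 1 frame, got %d", lag)
  short <- which(fm$segments <= lag)
  if (length(short))
    stop_kl("segments {%s} have <= lag = %d frames",
            paste(short, collapse = ","), lag)
  d <- ncol(fm$values)
  sxy <- s0 <- matrix(0, d, d)
  ssum <- numeric(d); n <- 0
  for (rows in segment_ranges(fm)) {
    L <- length(rows)
    X <- fm$values[rows[seq_len(L - lag)], , drop = FALSE]
    Y <- fm$values[rows[(lag + 1):L], , drop = FALSE]
    ssum <- ssum + colSums(X) + colSums(Y)
    n <- n + (L - lag)
  }
  means <- ssum / (2 * n)
  for (rows in segment_ranges(fm)) {
    L <- length(rows)
    X <- sweep(fm$values[rows[seq_len(L - lag)], , drop = FALSE], 2, means)
    Y <- sweep(fm$values[rows[(lag + 1):L], , drop = FALSE], 2, means)
    s0 <- s0 + crossprod(X) + crossprod(Y)
    sxy <- sxy + crossprod(X, Y)
  }
  C0 <- s0 / (2 * n)
  Ctau <- (sxy + t(sxy)) / (2 * n)
  dimnames(C0) <- dimnames(Ctau) <- list(fm$labels, fm$labels)
  ev_min <- min(eigen(C0, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(C0 = C0, Ctau = Ctau, means = means, labels = fm$labels,
                 lag = lag, n_pairs = n,
                 rank_deficient = ev_min < 1e-10 * max(diag(C0))),
            class = "tica_covariances")
}

#' Fit a tICA model from covariance matrices
#'
#' Solves `Ctau v = lambda C0 v` after adding `reg_epsilon *
#' trace(C0)/d` to the diagonal of `C0`.  Components are ordered by
#' eigenvalue (slowest first) and each eigenvector's sign is fixed so
#' its largest-magnitude loading is positive; loadings are normalized
#' to `v' C0 v = 1`.
#'
#' @param cov a `tica_covariances`, or a [feature_matrix()] (in which
#'   case `lag` must be given and covariances are estimated first).
#' @param n_components number of components to retain (default: all).
#' @param reg_epsilon relative diagonal regularization of `C0`
#'   (default `1e-6`); 0 disables it.
#' @param lag lag in frames, only when `cov` is a feature matrix.
#' @return object of class `tica_model`: `eigenvalues`, `loadings`
#'   (features x components), `timescales` (frames; `-lag/log(lambda)`
#'   for `0 < lambda < 1`, `Inf`/`NA` otherwise), `means`, `labels`,
#'   `lag`, `nonphysical` flag for eigenvalues beyond `1 + tol`.
#' @export
fit_tica <- function(cov, n_components = NULL, reg_epsilon = 1e-6,
                     lag = NULL) {
  if (inherits(cov, "feature_matrix")) {
    if (is.null(lag)) stop_kl("lag is required when fitting from a feature matrix")
    cov <- estimate_covariances(cov, lag)
  }
  stopifnot(inherits(cov, "tica_covariances"))
  d <- ncol(cov$C0)
  eps_abs <- reg_epsilon * sum(diag(cov$C0)) / d
  C0r <- cov$C0 + diag(eps_abs, d)
  ch <- tryCatch(chol(C0r), error = function(e)
    stop_kl("C0 is numerically singular; increase reg_epsilon (currently %g)",
            reg_epsilon))
  ## whiten: M = L^-T Ctau L^-1 is symmetric; its eigenvalues solve the
  ## generalized problem and v = L^-1 u satisfies v' C0 v = 1
  Linv <- backsolve(ch, diag(d))
  M <- t(Linv) %*% cov$Ctau %*% Linv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  k <- min(n_components %||% d, d)
  lambda <- e$values[seq_len(k)]
  V <- Linv %*% e$vectors[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) V[, c] <- -V[, c]
  }
  rownames(V) <- cov$labels
  colnames(V) <- paste0("tIC", seq_len(k))
  ts <- implied_ts(lambda, cov$lag)
  structure(list(lag = cov$lag, eigenvalues = lambda, loadings = V,
                 timescales = ts, means = cov$means, labels = cov$labels,
                 n_components = k,
                 nonphysical = any(abs(lambda) > 1 + 1e-6)),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: lag %d frames, %d components over %d features\n",
              x$lag, x$n_components, length(x$labels)))
  k <- min(5, x$n_components)
  cat("  eigenvalues: ", paste(signif(x$eigenvalues[1:k], 4),
                               collapse = ", "), "\n")
  cat("  timescales (frames): ", paste(signif(x$timescales[1:k], 4),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' Project frames onto tICA components
#'
#' Mean-centers features and applies the loading matrix.  Features are
#' matched to the model by label (order-insensitive).
#'
#' @param model a [fit_tica()] model.
#' @param fm a [feature_matrix()], or a numeric matrix whose column
#'   names are feature labels.
#' @return `frames x n_components` matrix of tIC coordinates.
#' @export
tica_project <- function(model, fm) {
  stopifnot(inherits(model, "tica_model"))
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(colnames(vals)))
    stop_kl("projection input must carry feature labels as column names")
  pos <- match(model$labels, colnames(vals))
  if (anyNA(pos)) {
    missing <- model$labels[is.na(pos)]
    stop_kl("projection input lacks model features: %s",
            paste(head(missing, 5), collapse = ", "))
  }
  sweep(vals[, pos, drop = FALSE], 2, model$means) %*% model$loadings
}

#' Pearson correlation of each feature with each tIC
#'
#' Correlates the raw feature time series with the projected component
#' time series; constant features get correlation 0 and are flagged.
#'
#' @param model a [fit_tica()] model.
#' @param fm the [feature_matrix()] to correlate.
#' @param n_tics number of leading components (default: all retained).
#' @return `features x n_tics` correlation matrix in `[-1, 1]`, with a
#'   `"constant_features"` attribute listing zero-variance features.
#' @export
feature_tic_correlation <- function(model, fm, n_tics = model$n_components) {
  if (n_tics > model$n_components)
    stop_kl("n_tics = %d exceeds the model's %d components", n_tics,
            model$n_components)
  proj <- tica_project(model, fm)[, seq_len(n_tics), drop = FALSE]
  vals <- fm$values[, model$labels, drop = FALSE]
  sds <- apply(vals, 2, sd)
  const <- sds == 0
  cc <- matrix(0, ncol(vals), n_tics,
               dimnames = list(model$labels, colnames(proj)))
  if (any(!const))
    cc[!const, ] <- suppressWarnings(cor(vals[, !const, drop = FALSE],
                                         proj))
  cc[is.na(cc)] <- 0
  attr(cc, "constant_features") <- model$labels[const]
  cc
}

#' Implied-timescale convergence of tICA with lag
#'
#' Helper for lag selection: fits tICA at each lag and tabulates the
#' leading implied timescales.
#'
#' @param fm a [feature_matrix()].
#' @param lags integer vector of candidate lags.
#' @param n_its number of timescales to report.
#' @param reg_epsilon passed to [fit_tica()].
#' @return data.frame with columns `lag`, `its1..its<n_its>` (frames).
#' @export
tica_its <- function(fm, lags, n_its = 3, reg_epsilon = 1e-6) {
  rows <- lapply(lags, function(l) {
    m <- fit_tica(fm, n_components = n_its, reg_epsilon = reg_epsilon,
                  lag = l)
    c(lag = l, stats::setNames(m$timescales[seq_len(n_its)],
                               paste0("its", seq_len(n_its))))
  })
  as.data.frame(do.call(rbind, rows))
}
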
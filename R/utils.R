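#' @useDynLib kinloops, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor kmeans median nlminb optimize rnorm runif sd uniroot
#'   var
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

## Internal validation and linear-algebra helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kl <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a row-stochastic matrix
#'
#' @param T square numeric matrix of transition probabilities.
#' @param tol tolerance on row sums.
#' @param require_irreducible if `TRUE`, the chain must be a single
#'   strongly connected communicating class.
#' @return `T`, invisibly, after validation.
#' @keywords internal
check_stochastic <- function(T, tol = 1e-8, require_irreducible = FALSE) {
  if (!is.matrix(T) || nrow(T) != ncol(T))
    stop_kl("transition matrix must be square, got %d x %d",
            NROW(T), NCOL(T))
  if (any(T < -tol))
    stop_kl("transition matrix has negative entries (min %.3g)", min(T))
  rs <- rowSums(T)
  if (any(abs(rs - 1) > tol))
    stop_kl("transition matrix rows must sum to 1 (max deviation %.3g)",
            max(abs(rs - 1)))
  if (require_irreducible && !is_irreducible(T))
    stop_kl("transition matrix is reducible: not all states communicate")
  invisible(T)
}

#' Strong connectivity of a transition/count matrix
#' @param M square nonnegative matrix; an edge i->j exists where M[i,j] > 0.
#' @keywords internal
is_irreducible <- function(M) {
  g <- igraph::graph_from_adjacency_matrix((M > 0) * 1, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves pi T = pi, sum(pi) = 1 via the leading left eigenvector.
#'
#' @param T row-stochastic matrix.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(T) {
  check_stochastic(T)
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v))))
    stop_kl("leading eigenvector has mixed signs; chain may be reducible")
  v <- pmax(v, 0)
  v / sum(v)
}

## Implied timescales -lag/log(ev) for eigenvalues in (0, 1); Inf at or
## above 1, NA otherwise (negative eigenvalues have no timescale).
implied_ts <- function(ev, lag) {
  ts <- rep(NA_real_, length(ev))
  ok <- is.finite(ev) & ev > 0 & ev < 1
  ts[ok] <- -lag / log(ev[ok])
  ts[is.finite(ev) & ev >= 1] <- Inf
  ts
}

## Deterministic per-purpose sub-seed from one master seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset) %% 1009L
}
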
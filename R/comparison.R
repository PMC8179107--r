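## Two-system comparison in one shared kinetic coordinate space:
## joint tICA over both ensembles, projection of reference
## conformations, geometric macrostate matching, and population-shift
## / MFPT-ratio tables.

#' Joint tICA over two systems
#'
#' Accumulates covariances over the concatenated segment lists of both
#' systems (no frame pair ever crosses a segment, hence never a
#' system), yielding one model whose coordinate space is shared by
#' both ensembles so their landscapes are directly comparable.
#'
#' @param fm_A,fm_B [feature_matrix()] objects with identical ordered
#'   feature labels.
#' @param lag tICA lag in frames.
#' @param n_components,reg_epsilon passed to [fit_tica()].
#' @return a [fit_tica()] model fitted on the pooled data.
#' @export
joint_tica <- function(fm_A, fm_B, lag, n_components = NULL,
                       reg_epsilon = 1e-6) {
  stopifnot(inherits(fm_A, "feature_matrix"),
            inherits(fm_B, "feature_matrix"))
  if (!identical(fm_A$labels, fm_B$labels)) {
    d <- c(setdiff(fm_A$labels, fm_B$labels),
           setdiff(fm_B$labels, fm_A$labels))
    stop_kl("feature sets differ between systems: %s",
            paste(head(d, 5), collapse = ", "))
  }
  pooled <- feature_matrix(rbind(fm_A$values, fm_B$values), fm_A$labels,
                           c(fm_A$segments, fm_B$segments))
  fit_tica(pooled, n_components = n_components,
           reg_epsilon = reg_epsilon, lag = lag)
}

#' Project reference conformations into the shared tIC space
#'
#' Computes the distance features of each single conformation and
#' projects them with the shared model, so experimental structures can
#' be placed on the simulated landscape.
#'
#' @param model shared [fit_tica()] model.
#' @param structures list of `n_residues x 3` coordinate matrices (or
#'   a single matrix).
#' @param defs pair definitions of the model's features.
#' @param top the [topology()] the definitions refer to.
#' @return `n_structures x n_components` matrix; a structure missing
#'   required residues yields an `NA` row and a warning.
#' @export
project_references <- function(model, structures, defs, top) {
  if (is.matrix(structures)) structures <- list(structures)
  out <- matrix(NA_real_, length(structures), model$n_components)
  colnames(out) <- colnames(model$loadings)
  for (s in seq_along(structures)) {
    row <- tryCatch({
      f <- features_of_conformation(structures[[s]], defs, top)
      v <- matrix(f, 1, dimnames = list(NULL, defs$label))
      tica_project(model, v)
    }, error = function(e) {
      warning(sprintf("structure %d: %s", s, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) out[s, ] <- row
  }
  out
}

## Macrostate centroids in tIC space from frame assignments.
macrostate_centroids <- function(model, projected) {
  assign_all <- unlist(model$assignments)
  if (length(assign_all) != nrow(projected))
    stop_kl("projection (%d frames) does not match the model's %d assigned frames",
            nrow(projected), length(assign_all))
  t(vapply(seq_len(model$n_macrostates), function(a) {
    colMeans(projected[assign_all == a, , drop = FALSE])
  }, numeric(ncol(projected))))
}

#' Match macrostates of two systems in the shared tIC space
#'
#' Greedy matching by smallest Euclidean distance between macrostate
#' centroids; candidate pairs farther apart than `threshold` are left
#' unmatched and the corresponding states are declared exclusive to
#' their system.  Ties are broken deterministically by population.
#'
#' @param model_A,model_B [coarse_grain_hmm()] models of the two
#'   systems, fitted on projections in the same shared tICA space.
#' @param proj_A,proj_B the corresponding projected frames.
#' @param threshold exclusivity distance; default half the median
#'   inter-centroid distance between the systems.
#' @return object of class `state_matching`: `matched` (data.frame
#'   `state_A`, `state_B`, `distance`), `exclusive_A`, `exclusive_B`
#'   (data.frames with populations), `centroids_A`, `centroids_B`,
#'   `threshold`.
#' @export
match_macrostates <- function(model_A, model_B, proj_A, proj_B,
                              threshold = NULL) {
  cA <- macrostate_centroids(model_A, proj_A)
  cB <- macrostate_centroids(model_B, proj_B)
  D <- outer(seq_len(nrow(cA)), seq_len(nrow(cB)),
             Vectorize(function(i, j) sqrt(sum((cA[i, ] - cB[j, ])^2))))
  if (is.null(threshold)) threshold <- median(D) / 2
  ## deterministic greedy: repeatedly take the closest available pair,
  ## population as tie-break
  avail_A <- rep(TRUE, nrow(cA)); avail_B <- rep(TRUE, nrow(cB))
  matched <- list()
  repeat {
    Dm <- D
    Dm[!avail_A, ] <- Inf; Dm[, !avail_B] <- Inf
    if (all(!is.finite(Dm)) || min(Dm) >= threshold) break
    cand <- which(Dm == min(Dm), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      popsum <- model_A$populations[cand[, 1]] +
        model_B$populations[cand[, 2]]
      cand <- cand[order(-popsum, cand[, 1], cand[, 2]), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    matched[[length(matched) + 1]] <-
      data.frame(state_A = i, state_B = j, distance = D[i, j])
    avail_A[i] <- FALSE; avail_B[j] <- FALSE
  }
  matched <- if (length(matched)) do.call(rbind, matched) else
    data.frame(state_A = integer(), state_B = integer(),
               distance = numeric())
  structure(list(
    matched = matched,
    exclusive_A = data.frame(state = which(avail_A),
                             population = model_A$populations[avail_A]),
    exclusive_B = data.frame(state = which(avail_B),
                             population = model_B$populations[avail_B]),
    centroids_A = cA, centroids_B = cB, threshold = threshold),
    class = "state_matching")
}

#' @export
print.state_matching <- function(x, ...) {
  cat(sprintf("state matching: %d matched pairs, %d A-exclusive, %d B-exclusive (threshold %.3g)\n",
              nrow(x$matched), nrow(x$exclusive_A), nrow(x$exclusive_B),
              x$threshold))
  invisible(x)
}

#' Population shifts and MFPT ratios between matched macrostates
#'
#' For every matched pair, the population shift `P_B - P_A` with
#' bootstrap SDs propagated in quadrature (when available); for every
#' ordered pair of matched states, the ratio `MFPT_A / MFPT_B` of the
#' corresponding transitions.  Unreachable transitions are flagged and
#' their ratios omitted.
#'
#' @param model_A,model_B the two [coarse_grain_hmm()] models.
#' @param matching a [match_macrostates()] result.
#' @param dt physical time per frame (defaults to the models').
#' @return list with `population_shifts` and `mfpt_ratios`
#'   data.frames.
#' @export
compare_kinetics <- function(model_A, model_B, matching,
                             dt = model_A$dt) {
  stopifnot(inherits(matching, "state_matching"))
  m <- matching$matched
  if (nrow(m) == 0) stop_kl("matching contains no matched pairs")
  shifts <- data.frame(
    state_A = m$state_A, state_B = m$state_B,
    pop_A = model_A$populations[m$state_A],
    pop_B = model_B$populations[m$state_B],
    delta = model_B$populations[m$state_B] -
      model_A$populations[m$state_A],
    delta_sd = sqrt(model_A$populations_sd[m$state_A]^2 +
                    model_B$populations_sd[m$state_B]^2))
  ratios <- list()
  for (p in seq_len(nrow(m))) for (q in seq_len(nrow(m))) {
    if (p == q) next
    mA <- tryCatch(macro_mfpt(model_A, m$state_A[p], m$state_A[q],
                              dt = dt)$mfpt, error = function(e) NA)
    mB <- tryCatch(macro_mfpt(model_B, m$state_B[p], m$state_B[q],
                              dt = dt)$mfpt, error = function(e) NA)
    ratios[[length(ratios) + 1]] <- data.frame(
      from = p, to = q, mfpt_A = mA, mfpt_B = mB,
      ratio = if (is.na(mA) || is.na(mB)) NA_real_ else mA / mB,
      flagged = is.na(mA) || is.na(mB))
  }
  list(population_shifts = shifts, mfpt_ratios = do.call(rbind, ratios))
}
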
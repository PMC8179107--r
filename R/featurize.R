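## Featurization: C-alpha pairwise-distance enumeration and computation,
## occupancy-based feature pruning, and per-residue RMSF.

#' Chain topology
#'
#' @param residues data.frame with columns `index` (1-based, strictly
#'   increasing), `name` (3-letter code) and `chain`.
#' @param terminal_clip number of residues at each terminus flagged as
#'   clipped; clipped residues are excluded from pair enumeration.
#' @return object of class `topology`.
#' @export
topology <- function(residues, terminal_clip = 0L) {
  stopifnot(is.data.frame(residues),
            all(c("index", "name", "chain") %in% names(residues)))
  if (any(diff(residues$index) <= 0))
    stop_kl("residue indices must be strictly increasing")
  n <- nrow(residues)
  terminal_clip <- as.integer(terminal_clip)
  if (terminal_clip < 0 || 2L * terminal_clip >= n)
    stop_kl("terminal_clip must satisfy 0 <= 2*clip < n_residues (n = %d)", n)
  structure(list(residues = residues, n_residues = n,
                 terminal_clip = terminal_clip),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d residues (chain %s), terminal clip %d\n",
              x$n_residues, paste(unique(x$residues$chain), collapse = ","),
              x$terminal_clip))
  invisible(x)
}

#' Trajectory ensemble of C-alpha coordinates
#'
#' @param coords list of numeric arrays, one per independent
#'   trajectory, each `frames x n_residues x 3` in Angstrom.
#' @param topology a [topology()] shared by all trajectories.
#' @param dt frame interval in ns (metadata).
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, topology, dt = 1) {
  stopifnot(inherits(topology, "topology"), is.list(coords),
            length(coords) >= 1)
  for (r in seq_along(coords)) {
    a <- coords[[r]]
    if (length(dim(a)) != 3 || dim(a)[2] != topology$n_residues ||
        dim(a)[3] != 3)
      stop_kl("trajectory %d: expected frames x %d x 3 array", r,
              topology$n_residues)
    if (dim(a)[1] < 2) stop_kl("trajectory %d has fewer than 2 frames", r)
    if (anyNA(a) || any(!is.finite(a)))
      stop_kl("trajectory %d contains NA/non-finite coordinates", r)
  }
  structure(list(coords = coords, topology = topology, dt = dt),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$coords, function(a) dim(a)[1], integer(1))
  cat(sprintf("trajectory ensemble: %d trajectories (%s frames), %d residues, dt = %g ns\n",
              length(nf), paste(nf, collapse = "+"),
              x$topology$n_residues, x$dt))
  invisible(x)
}

#' Feature matrix of per-frame distance features
#'
#' @param values `frames x features` numeric matrix.
#' @param labels feature labels (`"D_i_j"` for residue-pair distances).
#' @param segments integer vector of per-trajectory frame counts;
#'   must partition the rows.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, segments = nrow(values)) {
  values <- as.matrix(values)
  if (length(labels) != ncol(values))
    stop_kl("got %d labels for %d feature columns", length(labels),
            ncol(values))
  segments <- as.integer(segments)
  if (sum(segments) != nrow(values) || any(segments < 1))
    stop_kl("segments (%s) must partition the %d rows",
            paste(segments, collapse = "+"), nrow(values))
  colnames(values) <- labels
  structure(list(values = values, labels = as.character(labels),
                 segments = segments),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d frames (%d segment%s) x %d features\n",
              nrow(x$values), length(x$segments),
              if (length(x$segments) == 1) "" else "s", ncol(x$values)))
  invisible(x)
}

## Row index ranges of each trajectory segment.
segment_ranges <- function(fm) {
  ends <- cumsum(fm$segments)
  starts <- c(1L, head(ends, -1) + 1L)
  Map(seq, starts, ends)
}

#' Enumerate all eligible C-alpha residue pairs
#'
#' All unordered pairs i < j over the topology's residues, excluding
#' the clipped terminal residues, in deterministic lexicographic order.
#' For n eligible residues this yields n(n-1)/2 pair features.
#'
#' @param top a [topology()].
#' @return data.frame with columns `residue_i`, `residue_j`, `label`.
#' @export
enumerate_ca_pairs <- function(top) {
  stopifnot(inherits(top, "topology"))
  n <- top$n_residues; clip <- top$terminal_clip
  eligible <- top$residues$index[seq.int(clip + 1L, n - clip)]
  if (length(eligible) < 2)
    stop_kl("need at least 2 eligible residues after clipping, have %d",
            length(eligible))
  idx <- which(upper.tri(matrix(0, length(eligible), length(eligible))),
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- eligible[idx[, 1]]; j <- eligible[idx[, 2]]
  data.frame(residue_i = i, residue_j = j,
             label = paste0("D_", i, "_", j), stringsAsFactors = FALSE)
}

#' Compute pairwise-distance features over an ensemble
#'
#' Euclidean C-alpha--C-alpha distance in Angstrom for each frame and
#' each pair definition; trajectory segment boundaries are recorded.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param defs pair definitions from [enumerate_ca_pairs()].
#' @return a [feature_matrix()].
#' @export
compute_features <- function(ensemble, defs) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"), is.data.frame(defs))
  top <- ensemble$topology
  pos_i <- match(defs$residue_i, top$residues$index)
  pos_j <- match(defs$residue_j, top$residues$index)
  bad <- which(is.na(pos_i) | is.na(pos_j))
  if (length(bad))
    stop_kl("pair definition %s references residues absent from the topology",
            defs$label[bad[1]])
  vals <- lapply(ensemble$coords, function(a) {
    d2 <- (a[, pos_i, 1, drop = TRUE] - a[, pos_j, 1, drop = TRUE])^2 +
          (a[, pos_i, 2, drop = TRUE] - a[, pos_j, 2, drop = TRUE])^2 +
          (a[, pos_i, 3, drop = TRUE] - a[, pos_j, 3, drop = TRUE])^2
    sqrt(matrix(d2, nrow = dim(a)[1]))
  })
  feature_matrix(do.call(rbind, vals), defs$label,
                 vapply(ensemble$coords, function(a) dim(a)[1], integer(1)))
}

## Single-conformation feature vector (for reference structures).
features_of_conformation <- function(xyz, defs, top) {
  pos_i <- match(defs$residue_i, top$residues$index)
  pos_j <- match(defs$residue_j, top$residues$index)
  if (anyNA(pos_i) || anyNA(pos_j))
    stop_kl("conformation is missing residues required by the feature set")
  sqrt(rowSums((xyz[pos_i, , drop = FALSE] - xyz[pos_j, , drop = FALSE])^2))
}

#' Prune features that are consistently too close or too far
#'
#' A feature is removed iff its distance is below `d_min` on every
#' frame, or above `d_max` on every frame, evaluated over the union of
#' all frames of every feature matrix supplied (so two systems pruned
#' together share one feature set).  Features spanning the band on some
#' frames are retained.
#'
#' @param fm a [feature_matrix()], or a list of them with identical
#'   feature labels (e.g. wildtype-like and mutant-like systems).
#' @param d_min,d_max distance thresholds in Angstrom (defaults 3, 10).
#' @return list with `pruned` (feature matrix, or list matching the
#'   input), and `report`: data.frame of removed `label` and the
#'   triggering `rule` (`"too_close"` / `"too_far"`).
#' @export
prune_features <- function(fm, d_min = 3, d_max = 10) {
  single <- inherits(fm, "feature_matrix")
  fms <- if (single) list(fm) else fm
  stopifnot(all(vapply(fms, inherits, logical(1), "feature_matrix")))
  labels <- fms[[1]]$labels
  for (f in fms) if (!identical(f$labels, labels))
    stop_kl("all feature matrices must share one ordered feature set")
  too_close <- rep(TRUE, length(labels))
  too_far <- rep(TRUE, length(labels))
  for (f in fms) {
    too_close <- too_close & apply(f$values < d_min, 2, all)
    too_far <- too_far & apply(f$values > d_max, 2, all)
  }
  drop <- too_close | too_far
  if (all(drop))
    stop_kl("all %d features would be pruned; review d_min/d_max thresholds",
            length(labels))
  report <- data.frame(
    label = labels[drop],
    rule = ifelse(too_close[drop], "too_close", "too_far"),
    stringsAsFactors = FALSE)
  keep <- which(!drop)
  pruned <- lapply(fms, function(f)
    feature_matrix(f$values[, keep, drop = FALSE], labels[keep],
                   f$segments))
  list(pruned = if (single) pruned[[1]] else pruned, report = report)
}

#' Per-residue C-alpha RMSF
#'
#' Root-mean-square fluctuation of each residue about the mean
#' structure.  Frames of each trajectory are least-squares superposed
#' onto the ensemble-average structure before deviations are computed,
#' and deviations are pooled across trajectories.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @return numeric vector of per-residue RMSF (Angstrom), named by
#'   residue index.
#' @export
ca_rmsf <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  n_res <- ensemble$topology$n_residues
  xyz_list <- lapply(ensemble$coords, function(a) {
    nf <- dim(a)[1]
    ## flatten to bio3d xyz layout: frames x (x1,y1,z1,x2,...)
    m <- matrix(0, nf, 3 * n_res)
    m[, seq(1, 3 * n_res, 3)] <- a[, , 1]
    m[, seq(2, 3 * n_res, 3)] <- a[, , 2]
    m[, seq(3, 3 * n_res, 3)] <- a[, , 3]
    m
  })
  allxyz <- do.call(rbind, xyz_list)
  if (nrow(allxyz) < 2) stop_kl("RMSF requires at least 2 frames")
  inds <- seq_len(3 * n_res)
  ## iterate align -> mean -> realign: converges to the intrinsic mean
  ## structure, making the result invariant to per-frame rigid motion
  ref <- allxyz[1, ]
  pooled <- allxyz
  for (it in 1:3) {
    ## suppressWarnings: fit.xyz's internal RMSD report can sqrt a
    ## tiny negative for near-identical structures
    pooled <- suppressWarnings(
      bio3d::fit.xyz(fixed = ref, mobile = pooled,
                     fixed.inds = inds, mobile.inds = inds))
    ref <- colMeans(pooled)
  }
  mu <- ref
  dev2 <- sweep(pooled, 2, mu)^2
  per_res <- dev2[, seq(1, 3 * n_res, 3)] + dev2[, seq(2, 3 * n_res, 3)] +
    dev2[, seq(3, 3 * n_res, 3)]
  out <- sqrt(colMeans(per_res))
  names(out) <- ensemble$topology$residues$index
  out
}
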
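## Iterative kinetic feature selection: alternate tICA fitting with
## elimination of features that correlate weakly with the leading
## slow components, reducing an exhaustive pair set to a compact
## kinetically relevant one.  Residues recurring among the surviving
## pairs are reported as "anchor" residues of the slow processes.

#' Configuration for iterative tICA feature selection
#'
#' @param lag tICA lag in frames.
#' @param n_tics number of leading components the correlation score
#'   considers (default 2: one per slow loop process expected).
#' @param keep_fraction fraction of features kept per early iteration
#'   (default 0.5); used when `corr_threshold` is `NULL`.
#' @param corr_threshold alternative rule: drop features whose maximum
#'   absolute tIC correlation falls below this value.
#' @param K target feature count; elimination never goes below `K`
#'   (default 24).
#' @param max_iterations iteration cap.
#' @param reg_epsilon tICA regularization (see [fit_tica()]).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(lag, n_tics = 2L, keep_fraction = 0.5,
                             corr_threshold = NULL, K = 24L,
                             max_iterations = 50L, reg_epsilon = 1e-6) {
  if (keep_fraction <= 0 || keep_fraction >= 1)
    stop_kl("keep_fraction must lie in (0, 1)")
  if (!is.null(corr_threshold) &&
      (corr_threshold < 0 || corr_threshold >= 1))
    stop_kl("corr_threshold must lie in [0, 1)")
  if (K < 2) stop_kl("target feature count K must be >= 2")
  structure(list(lag = as.integer(lag), n_tics = as.integer(n_tics),
                 keep_fraction = keep_fraction,
                 corr_threshold = corr_threshold, K = as.integer(K),
                 max_iterations = as.integer(max_iterations),
                 reg_epsilon = reg_epsilon),
            class = "selection_config")
}

## "D_i_j" labels -> pair definition data.frame.
labels_to_defs <- function(labels) {
  parts <- strsplit(sub("^D_", "", labels), "_", fixed = TRUE)
  data.frame(residue_i = vapply(parts, function(p) as.integer(p[1]),
                                integer(1)),
             residue_j = vapply(parts, function(p) as.integer(p[2]),
                                integer(1)),
             label = labels, stringsAsFactors = FALSE)
}

#' Iterative tICA-correlation feature elimination
#'
#' Repeats: fit tICA on the current feature set; score each feature by
#' its maximum absolute Pearson correlation with the first `n_tics`
#' components; eliminate the lowest-scoring features (bottom
#' `1 - keep_fraction` while more than `2K` remain, then one at a time)
#' until exactly `K` features survive.  Deterministic: score ties are
#' broken by lexicographic feature label.
#'
#' @param fm a pruned [feature_matrix()] (see [prune_features()]).
#' @param cfg a [selection_config()].
#' @return object of class `selection_result`: `selected` (pair
#'   definitions), `log` (per-iteration feature count, score range and
#'   slowest timescale), `anchor_table` (residue occurrence counts
#'   among selected pairs), `status` (`"converged"`, `"stalled"`, or
#'   `"max_iterations"`), and the final `model`.
#' @export
iterative_tica_selection <- function(fm, cfg) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(cfg, "selection_config"))
  cur <- fm
  log <- list()
  status <- "max_iterations"
  model <- NULL
  iter <- 0L
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    n <- ncol(cur$values)
    model <- fit_tica(cur, n_components = min(cfg$n_tics, n),
                      reg_epsilon = cfg$reg_epsilon, lag = cfg$lag)
    cc <- feature_tic_correlation(model, cur)
    score <- apply(abs(cc), 1, max)
    log[[iter]] <- data.frame(iteration = iter, n_features = n,
                              min_score = min(score),
                              max_score = max(score),
                              slowest_timescale = model$timescales[1])
    if (n <= cfg$K) { status <- "converged"; break }
    if (max(score) - min(score) < 1e-12) { status <- "stalled"; break }
    ## deterministic ranking: high score first, label as tie-break
    ord <- order(-score, names(score))
    n_keep <- if (n > 2L * cfg$K) {
      max(cfg$K, ceiling(n * cfg$keep_fraction))
    } else {
      n - 1L
    }
    if (!is.null(cfg$corr_threshold)) {
      n_keep <- max(cfg$K, sum(score >= cfg$corr_threshold))
      if (n_keep == n) { status <- "converged"; break }
    }
    n_keep <- max(n_keep, cfg$K)
    keep_labels <- sort(names(score)[ord[seq_len(n_keep)]])
    keep_idx <- match(keep_labels, cur$labels)
    cur <- feature_matrix(cur$values[, keep_idx, drop = FALSE],
                          cur$labels[keep_idx], cur$segments)
    if (n_keep == cfg$K) { status <- "converged" }
    if (status == "converged" && n_keep == cfg$K) {
      ## log the final state with a fresh fit for reporting
      model <- fit_tica(cur, n_components = min(cfg$n_tics, cfg$K),
                        reg_epsilon = cfg$reg_epsilon, lag = cfg$lag)
      cc <- feature_tic_correlation(model, cur)
      score <- apply(abs(cc), 1, max)
      log[[iter + 1L]] <- data.frame(iteration = iter + 1L,
                                     n_features = cfg$K,
                                     min_score = min(score),
                                     max_score = max(score),
                                     slowest_timescale = model$timescales[1])
      break
    }
  }
  selected <- labels_to_defs(cur$labels)
  ## anchor ranking: occurrence count first; equally recurrent
  ## residues are ordered by how strongly their pairs track the
  ## slowest component (tIC1), so anchors of the slowest process lead
  tic1 <- if (is.null(model)) {
    stats::setNames(rep(0, nrow(selected)), selected$label)
  } else {
    abs(feature_tic_correlation(model, cur)[, 1])[selected$label]
  }
  res_all <- c(selected$residue_i, selected$residue_j)
  res_score <- tapply(rep(tic1, 2), res_all, sum)
  counts <- table(res_all)
  anchor_table <- data.frame(residue = as.integer(names(counts)),
                             count = as.integer(counts),
                             tic1_score = as.numeric(res_score[names(counts)]))
  anchor_table <- anchor_table[order(-anchor_table$count,
                                     -anchor_table$tic1_score,
                                     anchor_table$residue), ,
                               drop = FALSE]
  rownames(anchor_table) <- NULL
  structure(list(selected = selected,
                 log = do.call(rbind, log),
                 anchor_table = anchor_table,
                 status = status, model = model),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("feature selection: %d pairs selected (%s) in %d iterations\n",
              nrow(x$selected), x$status,
              if (is.null(x$log)) 0L else max(x$log$iteration)))
  cat("top anchors:\n")
  print(head(x$anchor_table, 5), row.names = FALSE)
  invisible(x)
}

#' Anchor residues of a selected pair set
#'
#' Residues occurring in at least `threshold` selected pairs, sorted
#' by occurrence count (descending) then residue index.
#'
#' @param selected pair definitions (data.frame with `residue_i`,
#'   `residue_j`), e.g. `selection_result$selected`.
#' @param threshold minimum number of pairs a residue must appear in.
#' @return data.frame with columns `residue`, `count`.
#' @export
anchor_report <- function(selected, threshold = 2L) {
  stopifnot(is.data.frame(selected), nrow(selected) > 0)
  counts <- table(c(selected$residue_i, selected$residue_j))
  df <- data.frame(residue = as.integer(names(counts)),
                   count = as.integer(counts))
  df <- df[df$count >= threshold, , drop = FALSE]
  df[order(-df$count, df$residue), , drop = FALSE]
}
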
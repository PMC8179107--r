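## Config-driven orchestration: featurize -> prune -> select -> joint
## tICA -> microstate MSM -> HMM coarse-graining -> two-system
## comparison, plus the relaxation branch, under one reproducibility
## seed.  Every stage's artifacts are serialized to the output
## directory and a manifest records parameters, seed and checksums.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file parseable to one)
#' with a `systems` list of one or two systems — each either
#' `list(synthetic = list(...))` with [gen_toy_loop_trajectory()]
#' arguments, or `list(topology = "x.pdb", trajectories = c(...))` —
#' plus stage parameters and a single `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return validated config (class `pipeline_config`) with defaults
#'   filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_kl("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(clip = 2L, d_min = 3, d_max = 10, lag = 5L, K = 24L,
                   n_tics = 2L, k_micro = 50L, n_macro = "auto",
                   n_boot = 30L, bins = 30L, kT = 1, dt = 1, seed = 1L,
                   out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$systems) || !length(config$systems))
    stop_kl("config must declare at least one system")
  if (length(config$systems) > 2)
    stop_kl("at most two systems can be compared")
  for (nm in names(config$systems)) {
    sys <- config$systems[[nm]]
    if (is.null(sys$synthetic)) {
      for (p in c(sys$topology, unlist(sys$trajectories)))
        if (!file.exists(p))
          stop_kl("system %s: path does not exist: %s", nm, p)
    }
  }
  if (!is.null(config$relaxation) &&
      !is.null(config$relaxation$csv) &&
      !file.exists(config$relaxation$csv))
    stop_kl("relaxation CSV does not exist: %s", config$relaxation$csv)
  class(config) <- "pipeline_config"
  config
}

load_system <- function(sys, cfg, sys_seed) {
  if (!is.null(sys$synthetic)) {
    args <- sys$synthetic
    args$seed <- args$seed %||% sys_seed
    se <- do.call(gen_toy_loop_trajectory, args)
    list(ensemble = se$ensemble, truth = se)
  } else {
    top <- load_topology(sys$topology, chain = sys$chain,
                         terminal_clip = cfg$clip)
    ens <- load_trajectories(unlist(sys$trajectories), top,
                             stride = sys$stride %||% 1L, dt = cfg$dt)
    list(ensemble = ens, truth = NULL)
  }
}

#' Run the full loop-kinetics analysis pipeline
#'
#' Executes featurization, joint pruning, iterative feature selection
#' on the first system, joint tICA, per-system microstate MSMs, HMM
#' coarse-graining with bootstrap uncertainties, and (with two
#' systems) macrostate matching with population-shift and MFPT-ratio
#' tables; an optional relaxation branch runs tau_m estimation,
#' model-free fitting and R2/R1 classification.
#'
#' @param config a [pipeline_config()] (or something it accepts).
#' @return report bundle (list) with all fitted models and tables;
#'   written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE,
                                recursive = TRUE)
  report <- list(config = cfg)

  ## 1. load / generate and featurize every system
  systems <- list()
  for (i in seq_along(cfg$systems)) {
    nm <- names(cfg$systems)[i] %||% paste0("sys", i)
    systems[[nm]] <- load_system(cfg$systems[[i]], cfg,
                                 derive_seed(cfg$seed, i))
  }
  top1 <- systems[[1]]$ensemble$topology
  top1$terminal_clip <- as.integer(cfg$clip)
  defs <- enumerate_ca_pairs(top1)
  fms <- lapply(systems, function(s)
    compute_features(s$ensemble, defs))

  ## 2. joint pruning so all systems share one feature set
  pr <- prune_features(if (length(fms) == 1) fms[[1]] else fms,
                       d_min = cfg$d_min, d_max = cfg$d_max)
  fms <- if (length(fms) == 1) list(pr$pruned) else pr$pruned
  names(fms) <- names(systems)
  report$prune_report <- pr$report

  ## 3. iterative feature selection on the pooled data
  pooled <- if (length(fms) == 1) fms[[1]] else
    feature_matrix(do.call(rbind, lapply(fms, `[[`, "values")),
                   fms[[1]]$labels,
                   unlist(lapply(fms, `[[`, "segments")))
  sel <- iterative_tica_selection(
    pooled, selection_config(lag = cfg$lag, n_tics = cfg$n_tics,
                             K = cfg$K))
  report$selection <- sel
  sel_fms <- lapply(fms, function(f) {
    idx <- match(sel$selected$label, f$labels)
    feature_matrix(f$values[, idx, drop = FALSE], sel$selected$label,
                   f$segments)
  })

  ## 4. shared tICA space over the selected features
  model <- if (length(sel_fms) == 2) {
    joint_tica(sel_fms[[1]], sel_fms[[2]], lag = cfg$lag)
  } else {
    fit_tica(sel_fms[[1]], lag = cfg$lag)
  }
  report$tica <- model
  projs <- lapply(sel_fms, function(f) tica_project(model, f))

  ## 5. per-system MSM + HMM coarse-graining
  metas <- list(); fes <- list()
  for (nm in names(sel_fms)) {
    proj <- projs[[nm]]
    dtraj <- cluster_microstates(proj, k = cfg$k_micro,
                                 seed = derive_seed(cfg$seed, 101L),
                                 segments = sel_fms[[nm]]$segments)
    its <- implied_timescales(dtraj, lags = cfg$lag, n_its = 6,
                              dt = cfg$dt)
    n_macro <- if (identical(cfg$n_macro, "auto")) {
      select_macrostate_count(unlist(its[1, -1]))
    } else as.integer(cfg$n_macro)
    meta <- coarse_grain_hmm(dtraj, n_macro, lag = cfg$lag,
                             dt = cfg$dt)
    if (cfg$n_boot > 0)
      meta <- population_uncertainty(dtraj, meta, n_boot = cfg$n_boot,
                                     seed = derive_seed(cfg$seed, 211L))
    metas[[nm]] <- meta
    fes[[nm]] <- free_energy_surface(proj, bins = cfg$bins, kT = cfg$kT)
  }
  report$metastable <- metas
  report$fes <- fes

  ## 6. two-system comparison
  if (length(metas) == 2) {
    matching <- match_macrostates(metas[[1]], metas[[2]],
                                  projs[[1]], projs[[2]])
    report$matching <- matching
    report$kinetic_comparison <-
      compare_kinetics(metas[[1]], metas[[2]], matching, dt = cfg$dt)
  }

  ## 7. relaxation branch
  if (!is.null(cfg$relaxation)) {
    rel <- if (!is.null(cfg$relaxation$csv)) {
      read_relaxation_csv(cfg$relaxation$csv,
                          field_MHz = cfg$relaxation$field_MHz %||% 800)
    } else cfg$relaxation$dataset
    tm <- estimate_tm(rel)
    report$relaxation <- list(
      tau_m = as.numeric(tm),
      modelfree = modelfree_fit(rel, tau_m = as.numeric(tm)),
      r2r1 = classify_r2r1(rel))
  }

  if (!is.null(out)) write_pipeline_artifacts(report, out)
  class(report) <- "pipeline_report"
  report
}

write_pipeline_artifacts <- function(report, out) {
  cfg <- report$config
  write.csv(report$selection$selected,
            file.path(out, "selected_features.csv"), row.names = FALSE)
  write.csv(report$selection$anchor_table,
            file.path(out, "anchor_table.csv"), row.names = FALSE)
  for (nm in names(report$metastable)) {
    m <- report$metastable[[nm]]
    jsonlite::write_json(
      list(populations = m$populations,
           populations_sd = m$populations_sd,
           coarse_T = m$coarse_T, mfpt = m$mfpt,
           timescales = m$timescales),
      file.path(out, paste0("metastable_", nm, ".json")),
      digits = NA, auto_unbox = TRUE)
    f <- report$fes[[nm]]
    write.csv(as.data.frame(f$F),
              file.path(out, paste0("fes_", nm, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(report$kinetic_comparison)) {
    write.csv(report$kinetic_comparison$population_shifts,
              file.path(out, "population_shifts.csv"),
              row.names = FALSE)
    write.csv(report$kinetic_comparison$mfpt_ratios,
              file.path(out, "mfpt_ratios.csv"), row.names = FALSE)
  }
  params <- cfg[setdiff(names(cfg), "systems")]
  artifacts <- list.files(out, full.names = TRUE)
  manifest <- list(parameters = params,
                   seed = cfg$seed,
                   artifacts = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  selected features: %d\n", nrow(x$selection$selected)))
  for (nm in names(x$metastable)) {
    m <- x$metastable[[nm]]
    cat(sprintf("  %s: %d macrostates, populations %s\n", nm,
                m$n_macrostates,
                paste(sprintf("%.3f", m$populations), collapse = ", ")))
  }
  if (!is.null(x$relaxation))
    cat(sprintf("  relaxation: tau_m = %.2f ns\n", x$relaxation$tau_m))
  invisible(x)
}
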
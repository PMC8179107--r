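## File exchange: PDB topologies, DCD / multi-model PDB trajectories,
## feature CSVs with segment sidecars, relaxation CSVs, ground-truth
## JSON.  PDB parsing and DCD reading go through bio3d; DCD writing is
## a minimal CHARMM-format writer (no installed R package writes DCD).

#' Read a chain topology from a PDB file
#'
#' One residue entry per C-alpha atom of the selected chain.
#'
#' @param path PDB file.
#' @param chain chain identifier; required when the file has several
#'   chains.
#' @param terminal_clip clip width stored on the topology (default 2).
#' @return a [topology()].
#' @export
load_topology <- function(path, chain = NULL, terminal_clip = 2L) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop_kl("no C-alpha atoms found in %s", path)
  chains <- unique(ca$chain)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop_kl("PDB has chains {%s}; a chain selection is required",
              paste(chains, collapse = ","))
    chain <- chains
  }
  ca <- ca[ca$chain == chain, , drop = FALSE]
  if (nrow(ca) == 0) stop_kl("chain %s has no C-alpha atoms", chain)
  ins <- ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert)
  if (anyDuplicated(paste(ca$resno, ins)))
    stop_kl("duplicate residue index within chain %s", chain)
  res <- data.frame(index = ca$resno,
                    name = paste0(ca$resid, ins),
                    chain = ca$chain, stringsAsFactors = FALSE)
  topology(res, terminal_clip = terminal_clip)
}

## Read single-conformation C-alpha coordinates (reference structure).
load_reference_coords <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sel <- pdb$atom$elety == "CA"
  if (!is.null(chain)) sel <- sel & pdb$atom$chain == chain
  ca <- pdb$atom[sel, , drop = FALSE]
  if (nrow(ca) == 0) stop_kl("no C-alpha atoms found in %s", path)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- ca$resno
  xyz
}

#' Load trajectories into an ensemble
#'
#' Reads one or more DCD or multi-model PDB trajectory files whose atom
#' count matches the topology (C-alpha-only trajectories), applies a
#' uniform stride, and scales the frame interval accordingly.
#'
#' @param paths character vector of trajectory files (`.dcd` or
#'   `.pdb`).
#' @param top the matching [topology()].
#' @param stride keep every `stride`-th frame.
#' @param dt frame interval of the unstrided input, ns.
#' @return a [trajectory_ensemble()] with `dt * stride` frame interval.
#' @export
load_trajectories <- function(paths, top, stride = 1L, dt = 1) {
  stopifnot(inherits(top, "topology"))
  if (length(paths) == 0) stop_kl("no trajectory paths supplied")
  stride <- as.integer(stride)
  if (stride < 1) stop_kl("stride must be >= 1")
  n_res <- top$n_residues
  coords <- lapply(paths, function(p) {
    xyz <- if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      bio3d::read.dcd(p, verbose = FALSE)
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      sel <- which(pdb$atom$elety == "CA")
      m <- pdb$xyz[, bio3d::atom2xyz(sel), drop = FALSE]
      m
    }
    if (ncol(xyz) != 3 * n_res)
      stop_kl("%s: trajectory has %d atoms but topology has %d residues",
              p, ncol(xyz) %/% 3, n_res)
    rows <- seq(1, nrow(xyz), by = stride)
    a <- array(0, dim = c(length(rows), n_res, 3))
    a[, , 1] <- xyz[rows, seq(1, 3 * n_res, 3)]
    a[, , 2] <- xyz[rows, seq(2, 3 * n_res, 3)]
    a[, , 3] <- xyz[rows, seq(3, 3 * n_res, 3)]
    a
  })
  trajectory_ensemble(coords, top, dt = dt * stride)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (CORD, no unit cell), readable
#' by `bio3d::read.dcd` and standard MD tools.
#'
#' @param coords `frames x atoms x 3` array, Angstrom.
#' @param path output file.
#' @param dt frame interval stored in the header.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path, dt = 1) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]; natom <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  ## header record: "CORD" + 20 control ints (slot 10 is the float
  ## timestep, slot 20 the CHARMM version flag)
  wi(84); writeChar("CORD", con, 4, eos = NULL)
  wi(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L)); wf(dt)
  wi(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L)); wi(84)
  ## title record
  title <- formatC("Generated by kinloops", width = -80)
  wi(84); wi(1L); writeChar(title, con, 80, eos = NULL); wi(84)
  ## atom-count record
  wi(4); wi(natom); wi(4)
  for (t in seq_len(nf)) for (k in 1:3) {
    wi(4L * natom); wf(coords[t, , k]); wi(4L * natom)
  }
  invisible(path)
}

#' Write a synthetic ensemble to disk
#'
#' Emits a PDB topology (first frame), one DCD per trajectory, and the
#' planted ground truth as JSON.
#'
#' @param se a `synthetic_ensemble` from [gen_toy_loop_trajectory()].
#' @param dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
write_ensemble <- function(se, dir) {
  stopifnot(inherits(se, "synthetic_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ens <- se$ensemble; top <- ens$topology
  first <- ens$coords[[1]][1, , ]
  pdb_path <- file.path(dir, "topology.pdb")
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(first)),
                   resno = top$residues$index,
                   resid = top$residues$name,
                   chain = top$residues$chain,
                   elety = rep("CA", top$n_residues))
  dcd_paths <- vapply(seq_along(ens$coords), function(r) {
    p <- file.path(dir, sprintf("traj_%02d.dcd", r))
    write_dcd(ens$coords[[r]], p, dt = ens$dt)
    p
  }, character(1))
  truth_path <- file.path(dir, "ground_truth.json")
  kin <- se$kinetics
  jsonlite::write_json(list(
    macrostates = kin$macrostates, T_true = kin$T_true,
    pi_true = kin$pi_true, mfpt_true = kin$mfpt_true,
    slow_loop_residues = kin$slow_loop_residues,
    fast_loop_residues = kin$fast_loop_residues,
    seed = se$seed), truth_path, digits = NA, auto_unbox = TRUE)
  invisible(list(topology = pdb_path, trajectories = dcd_paths,
                 truth = truth_path))
}

#' Write / read a feature matrix as CSV with a segment sidecar
#'
#' The CSV header row carries the feature labels; per-trajectory
#' segment lengths go to `<path>.segments.json`.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file path.
#' @return `path` ([write_feature_csv()]) or a [feature_matrix()]
#'   ([read_feature_csv()]).
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  write.csv(as.data.frame(fm$values, check.names = FALSE), path,
            row.names = FALSE)
  jsonlite::write_json(list(segments = fm$segments),
                       paste0(path, ".segments.json"))
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".segments.json")
  segments <- if (file.exists(sidecar)) {
    unlist(jsonlite::read_json(sidecar)$segments)
  } else nrow(df)
  feature_matrix(as.matrix(df), names(df), segments)
}

#' Read a per-residue relaxation table from CSV
#'
#' Expects columns `residue, R1, R1err, R2, R2err, NOE, NOEerr`.
#'
#' @param path CSV file.
#' @param field_MHz proton Larmor frequency of the measurements.
#' @return a [relaxation_dataset()].
#' @export
read_relaxation_csv <- function(path, field_MHz) {
  df <- read.csv(path)
  need <- c("residue", "R1", "R1err", "R2", "R2err", "NOE", "NOEerr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_kl("relaxation CSV is missing columns: %s",
            paste(miss, collapse = ", "))
  relaxation_dataset(df[, need], field_MHz = field_MHz)
}
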
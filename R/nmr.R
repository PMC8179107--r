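## Lipari-Szabo model-free analysis of backbone amide 15N relaxation:
## forward model for R1, R2 and heteronuclear NOE from (S2, tau_e,
## tau_m, Rex) at a stated field, isotropic tau_m estimation from the
## rigid R2/R1 ratio, per-residue model-free fitting, and the
## qualitative R2/R1 timescale classification.

#' Physical constants for amide 15N relaxation
#'
#' @param r_NH N-H bond length (m).
#' @param csa 15N chemical shift anisotropy (dimensionless, e.g.
#'   `-172e-6`).
#' @param gamma_H,gamma_N gyromagnetic ratios (rad s^-1 T^-1).
#' @return named list of constants, including the derived dipolar
#'   coupling `d` (rad s^-1).
#' @export
nmr_constants <- function(r_NH = 1.02e-10, csa = -172e-6,
                          gamma_H = 2.6752218744e8,
                          gamma_N = -2.7126e7) {
  mu0 <- 4 * pi * 1e-7
  hbar <- 1.054571817e-34
  list(r_NH = r_NH, csa = csa, gamma_H = gamma_H, gamma_N = gamma_N,
       d = mu0 * hbar * gamma_H * gamma_N / (4 * pi * r_NH^3))
}

#' Per-residue relaxation dataset
#'
#' @param data data.frame with columns `residue`, `R1`, `R1err`, `R2`,
#'   `R2err`, `NOE`, `NOEerr` (rates in s^-1; `NA` allowed for
#'   unmeasured residues).
#' @param field_MHz proton Larmor frequency of the spectrometer.
#' @param constants an [nmr_constants()] list.
#' @return object of class `relaxation_dataset`.
#' @export
relaxation_dataset <- function(data, field_MHz,
                               constants = nmr_constants()) {
  stopifnot(is.data.frame(data))
  need <- c("residue", "R1", "R1err", "R2", "R2err", "NOE", "NOEerr")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_kl("missing columns: %s", paste(miss, collapse = ", "))
  if (any(data$R1 <= 0, na.rm = TRUE) || any(data$R2 <= 0, na.rm = TRUE))
    stop_kl("R1 and R2 must be positive where measured")
  if (any(c(data$R1err, data$R2err, data$NOEerr) < 0, na.rm = TRUE))
    stop_kl("errors must be nonnegative")
  if (field_MHz <= 0) stop_kl("field_MHz must be positive")
  structure(list(data = data, field_MHz = field_MHz,
                 constants = constants),
            class = "relaxation_dataset")
}

#' @export
print.relaxation_dataset <- function(x, ...) {
  cat(sprintf("relaxation dataset: %d residues at %g MHz\n",
              nrow(x$data), x$field_MHz))
  invisible(x)
}

## Model-free spectral density (s/rad) with the 2/5 normalization.
## tau in seconds.
jw <- function(w, S2, tau_e, tau_m) {
  tp <- if (tau_e > 0) tau_m * tau_e / (tau_m + tau_e) else 0
  j <- S2 * tau_m / (1 + (w * tau_m)^2)
  if (tau_e > 0) j <- j + (1 - S2) * tp / (1 + (w * tp)^2)
  0.4 * j
}

#' Model-free forward calculation of R1, R2 and NOE
#'
#' Standard Lipari-Szabo expressions from dipolar and CSA
#' contributions of the spectral density at
#' `{0, wN, wH - wN, wH, wH + wN}`, with an additive chemical-exchange
#' term on R2.
#'
#' @param S2 generalized order parameter in `[0, 1]`.
#' @param tau_e effective internal correlation time (ps).
#' @param tau_m global rotational correlation time (ns).
#' @param Rex chemical-exchange contribution to R2 (s^-1).
#' @param field_MHz proton Larmor frequency.
#' @param constants an [nmr_constants()] list.
#' @return list with `R1`, `R2` (s^-1) and `NOE` (dimensionless).
#' @export
modelfree_forward <- function(S2, tau_e = 0, tau_m = 10, Rex = 0,
                              field_MHz = 800,
                              constants = nmr_constants()) {
  if (tau_m <= 0) stop_kl("tau_m must be positive")
  if (S2 < 0 || S2 > 1) stop_kl("S2 must lie in [0, 1]")
  if (tau_e < 0) stop_kl("tau_e must be >= 0")
  tm <- tau_m * 1e-9; te <- tau_e * 1e-12
  wH <- 2 * pi * field_MHz * 1e6
  wN <- wH * constants$gamma_N / constants$gamma_H
  d2 <- constants$d^2
  c2 <- (wN * constants$csa)^2 / 3
  J <- function(w) jw(abs(w), S2, te, tm)
  R1 <- d2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                  6 * J(wH + wN)) +
        c2 / 6 * (4 * J(0) + 3 * J(wN)) + Rex
  NOE <- 1 + (constants$gamma_H / constants$gamma_N) * d2 / (4 * R1) *
    (6 * J(wH + wN) - J(wH - wN))
  list(R1 = R1, R2 = R2, NOE = NOE)
}

## Rigid-limit R2/R1 ratio as a function of tau_m (ns).
rigid_r2r1 <- function(tau_m, field_MHz, constants) {
  fw <- modelfree_forward(1, 0, tau_m, 0, field_MHz, constants)
  fw$R2 / fw$R1
}

#' Estimate the global rotational correlation time
#'
#' Inverts the rigid-limit (`S2 = 1`, `Rex = 0`) R2/R1 ratio per
#' residue and returns the median over retained residues.  The trim
#' rule excludes residues whose R2/R1 lies outside mean +/- 1 SD
#' (internal motion or exchange) or whose NOE falls below the mobility
#' cutoff.
#'
#' @param dataset a [relaxation_dataset()].
#' @param noe_cutoff minimum NOE for a residue to count as rigid
#'   (default 0.65).
#' @param min_residues minimum retained residues (default 5).
#' @return tau_m in ns, with attribute `"n_used"`.
#' @export
estimate_tm <- function(dataset, noe_cutoff = 0.65, min_residues = 5L) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  df <- dataset$data
  ok <- !is.na(df$R1) & !is.na(df$R2) & !is.na(df$NOE)
  ratio <- df$R2[ok] / df$R1[ok]
  mu <- mean(ratio); s <- sd(ratio)
  keep <- abs(ratio - mu) <= s & df$NOE[ok] >= noe_cutoff
  if (sum(keep) < min_residues)
    stop_kl("only %d residues retained after trimming (need >= %d)",
            sum(keep), min_residues)
  tms <- vapply(ratio[keep], function(r) {
    uniroot(function(tm)
      rigid_r2r1(tm, dataset$field_MHz, dataset$constants) - r,
      interval = c(0.5, 100), tol = 1e-8)$root
  }, numeric(1))
  structure(median(tms), n_used = sum(keep))
}

## Weighted chi-square of one residue's rates against the forward
## model; parameters are clamped into their physical ranges so the
## optimizer's finite-difference probes never step outside them.
residue_chi2 <- function(par, obs, err, tau_m, field_MHz, constants) {
  S2 <- min(max(par[["S2"]], 0), 1)
  te <- max(par[["tau_e"]], 0)
  rex <- max(par[["Rex"]], 0)
  fw <- modelfree_forward(S2, te, tau_m, rex, field_MHz, constants)
  val <- sum(((obs - c(fw$R1, fw$R2, fw$NOE)) / err)^2)
  if (!is.finite(val)) 1e12 else val
}

#' Per-residue Lipari-Szabo model-free fit
#'
#' Fits each residue's (R1, R2, NOE) by weighted least squares over
#' the nested candidate models `S2` only, `S2 + tau_e`, and
#' `S2 + tau_e + Rex` at fixed global `tau_m`, and selects the
#' simplest model that the next, more complex one does not improve by
#' more than `delta_chi2`.
#'
#' @param dataset a [relaxation_dataset()].
#' @param tau_m global rotational correlation time (ns), e.g. from
#'   [estimate_tm()].
#' @param delta_chi2 chi-square improvement required to accept an
#'   extra parameter (default 4.6).
#' @return object of class `modelfree_result`: data.frame `fits` with
#'   `residue`, `S2`, `tau_e` (ps), `Rex` (s^-1), `model`, `chi2`,
#'   `converged`; plus `tau_m`, `field_MHz`.
#' @export
modelfree_fit <- function(dataset, tau_m, delta_chi2 = 4.6) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  df <- dataset$data
  fmhz <- dataset$field_MHz; cst <- dataset$constants
  te_max <- 0.5 * tau_m * 1000          # ps; internal motion << tumbling
  fit_one <- function(obs, err) {
    err <- ifelse(err > 0, err, pmax(1e-3 * abs(obs), 1e-8))
    chi2_of <- function(S2, tau_e, Rex)
      residue_chi2(c(S2 = S2, tau_e = tau_e, Rex = Rex), obs, err,
                   tau_m, fmhz, cst)
    ## model 1: S2 only
    o1 <- optimize(function(s) chi2_of(s, 0, 0), c(0, 1), tol = 1e-10)
    m1 <- list(S2 = o1$minimum, tau_e = 0, Rex = 0, chi2 = o1$objective)
    ## model 2: S2 + tau_e, multi-start
    best2 <- NULL
    for (s0 in c(0.4, 0.7, 0.9)) for (t0 in c(10, 50, 500)) {
      o <- nlminb(c(s0, t0), function(p) chi2_of(p[1], p[2], 0),
                  lower = c(0, 0), upper = c(1, te_max),
                  control = list(abs.tol = 1e-14, rel.tol = 1e-12,
                                 x.tol = 1e-12))
      if (is.null(best2) || o$objective < best2$objective) best2 <- o
    }
    m2 <- list(S2 = best2$par[1], tau_e = best2$par[2], Rex = 0,
               chi2 = best2$objective)
    ## model 3: S2 + tau_e + Rex
    o3 <- nlminb(c(m2$S2, max(m2$tau_e, 1), 1),
                 function(p) chi2_of(p[1], p[2], p[3]),
                 lower = c(0, 0, 0), upper = c(1, te_max, 100),
                 control = list(abs.tol = 1e-14, rel.tol = 1e-12,
                                x.tol = 1e-12))
    m3 <- list(S2 = o3$par[1], tau_e = o3$par[2], Rex = o3$par[3],
               chi2 = o3$objective)
    ## simplest model that no more complex candidate improves on by
    ## more than delta_chi2 (comparing against the best of the later
    ## models, so exchange-dominated residues are not stranded at the
    ## S2-only model just because tau_e alone cannot help)
    if (m1$chi2 - min(m2$chi2, m3$chi2) <= delta_chi2) {
      c(m1, model = "S2")
    } else if (m2$chi2 - m3$chi2 <= delta_chi2) {
      c(m2, model = "S2+te")
    } else {
      c(m3, model = "S2+te+Rex")
    }
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    obs <- c(df$R1[i], df$R2[i], df$NOE[i])
    if (anyNA(obs))
      return(data.frame(residue = df$residue[i], S2 = NA, tau_e = NA,
                        Rex = NA, model = NA, chi2 = NA,
                        converged = FALSE))
    err <- c(df$R1err[i], df$R2err[i], df$NOEerr[i])
    f <- tryCatch(fit_one(obs, err), error = function(e) NULL)
    if (is.null(f))
      return(data.frame(residue = df$residue[i], S2 = NA, tau_e = NA,
                        Rex = NA, model = NA, chi2 = NA,
                        converged = FALSE))
    data.frame(residue = df$residue[i], S2 = f$S2, tau_e = f$tau_e,
               Rex = f$Rex, model = f$model, chi2 = f$chi2,
               converged = TRUE)
  })
  structure(list(fits = do.call(rbind, rows), tau_m = tau_m,
                 field_MHz = fmhz),
            class = "modelfree_result")
}

#' @export
print.modelfree_result <- function(x, ...) {
  ok <- x$fits$converged
  cat(sprintf("model-free fit: %d/%d residues converged, tau_m = %.2f ns\n",
              sum(ok), nrow(x$fits), x$tau_m))
  cat(sprintf("  mean S2 = %.3f\n", mean(x$fits$S2[ok])))
  invisible(x)
}

#' Classify backbone timescales from the R2/R1 ratio
#'
#' Residues whose R2/R1 exceeds the global mean by more than one SD
#' are classified `"slow"` (us-ms exchange); residues more than one SD
#' below are `"fast"` (ps-ns flexibility); the rest are `"typical"`.
#'
#' @param dataset a [relaxation_dataset()] with >= 3 residues carrying
#'   both rates.
#' @return object of class `r2r1_classification`: data.frame `table`
#'   (`residue`, `ratio`, `class`), `mean`, `sd`, `excluded` (residues
#'   missing a rate).
#' @export
classify_r2r1 <- function(dataset) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  df <- dataset$data
  ok <- !is.na(df$R1) & !is.na(df$R2)
  if (sum(ok) < 3)
    stop_kl("need >= 3 residues with both R1 and R2, have %d", sum(ok))
  ratio <- df$R2[ok] / df$R1[ok]
  mu <- mean(ratio); s <- sd(ratio)
  cls <- ifelse(ratio > mu + s, "slow",
                ifelse(ratio < mu - s, "fast", "typical"))
  structure(list(table = data.frame(residue = df$residue[ok],
                                    ratio = ratio, class = cls,
                                    stringsAsFactors = FALSE),
                 mean = mu, sd = s,
                 excluded = df$residue[!ok]),
            class = "r2r1_classification")
}

#' @export
print.r2r1_classification <- function(x, ...) {
  cat(sprintf("R2/R1 classification: mean %.2f +/- %.2f over %d residues\n",
              x$mean, x$sd, nrow(x$table)))
  print(table(x$table$class))
  invisible(x)
}
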
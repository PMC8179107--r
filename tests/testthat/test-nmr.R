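test_that("forward model matches an independently coded implementation", {
  ## frozen reference rates computed with a separate implementation of
  ## the standard spectral-density expressions (same constants)
  ref <- list(
    list(p = c(0.85, 50, 14.7, 0, 800),
         r = c(0.620230771472, 21.869072123371, 0.579478648658)),
    list(p = c(1, 0, 10, 0, 800),
         r = c(0.975133232801, 17.725858775796, 0.862552492455)),
    list(p = c(0.6, 200, 8, 3, 600),
         r = c(1.373122240671, 10.721835894395, -0.171306195501)))
  for (case in ref) {
    fw <- modelfree_forward(case$p[1], case$p[2], case$p[3], case$p[4],
                            case$p[5])
    expect_equal(unlist(fw), case$r, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("forward model limits behave physically", {
  ## rigid limit: tau_e drops out
  a <- modelfree_forward(1, 0, 12, 0, 800)
  b <- modelfree_forward(1, 500, 12, 0, 800)
  expect_equal(a, b, tolerance = 1e-12)
  ## exchange adds to R2 only, exactly
  r0 <- modelfree_forward(0.8, 50, 12, 0, 800)
  r5 <- modelfree_forward(0.8, 50, 12, 5, 800)
  expect_equal(r5$R2 - r0$R2, 5, tolerance = 1e-12)
  expect_equal(r5$R1, r0$R1)
  expect_equal(r5$NOE, r0$NOE)
  ## rigid-limit NOE rises monotonically with tau_m over 1-30 ns
  noes <- vapply(seq(1, 30, length.out = 30), function(tm)
    modelfree_forward(1, 0, tm, 0, 800)$NOE, numeric(1))
  expect_true(all(diff(noes) > 0))
  expect_error(modelfree_forward(0.9, 50, -1, 0, 800), "tau_m")
})

test_that("global correlation time is recovered and robust to exchange", {
  tr <- relaxation_truth(S2_true = 1, tau_e_true = 0, tau_m_true = 10,
                         field_MHz = 800,
                         noise_sd = list(R1 = 0, R2 = 0, NOE = 0))
  ds <- gen_relaxation_data(tr, 20, seed = 1)
  tm <- estimate_tm(ds)
  expect_equal(as.numeric(tm), 10, tolerance = 0.02)
  ## one extreme-exchange residue is trimmed away by the R2/R1 rule
  df <- ds$data
  df$R2[7] <- df$R2[7] + 25
  tm2 <- estimate_tm(relaxation_dataset(df, 800))
  expect_equal(as.numeric(tm2), as.numeric(tm), tolerance = 1e-9)
  ## too few residues
  expect_error(estimate_tm(relaxation_dataset(ds$data[1:2, ], 800)),
               "retained")
})

test_that("model-free fitting inverts the forward model on a parameter grid", {
  for (tau_m in c(8, 14.7)) {
    grid <- expand.grid(S2 = c(0.6, 0.85, 0.95), tau_e = c(20, 80))
    fw <- t(mapply(function(s, te)
      unlist(modelfree_forward(s, te, tau_m, 0, 800)),
      grid$S2, grid$tau_e))
    df <- data.frame(residue = seq_len(nrow(grid)),
                     R1 = fw[, "R1"], R1err = 0.01,
                     R2 = fw[, "R2"], R2err = 0.05,
                     NOE = fw[, "NOE"], NOEerr = 0.005)
    fit <- modelfree_fit(relaxation_dataset(df, 800), tau_m = tau_m)
    expect_true(all(fit$fits$converged))
    expect_equal(fit$fits$S2, grid$S2, tolerance = 1e-3)
    expect_equal(fit$fits$tau_e, grid$tau_e, tolerance = 1e-3)
  }
})

test_that("model selection prefers the simplest adequate model", {
  ## rigid residue: S2-only model, S2 = 1.000
  fw <- modelfree_forward(1, 0, 10, 0, 800)
  df <- data.frame(residue = 1, R1 = fw$R1, R1err = 0.01, R2 = fw$R2,
                   R2err = 0.05, NOE = fw$NOE, NOEerr = 0.005)
  fit <- modelfree_fit(relaxation_dataset(df, 800), tau_m = 10)
  expect_equal(fit$fits$model, "S2")
  expect_equal(fit$fits$S2, 1, tolerance = 1e-3)
  ## strong exchange forces the Rex model
  fwx <- modelfree_forward(0.85, 50, 10, 8, 800)
  dfx <- data.frame(residue = 1, R1 = fwx$R1, R1err = 0.01,
                    R2 = fwx$R2, R2err = 0.05, NOE = fwx$NOE,
                    NOEerr = 0.005)
  fitx <- modelfree_fit(relaxation_dataset(dfx, 800), tau_m = 10)
  expect_equal(fitx$fits$model, "S2+te+Rex")
  expect_equal(fitx$fits$Rex, 8, tolerance = 0.05)
})

test_that("noisy data still yield accurate order parameters on average", {
  tr <- relaxation_truth(S2_true = seq(0.5, 0.95, length.out = 50),
                         tau_e_true = 60, tau_m_true = 12,
                         field_MHz = 800,
                         noise_sd = list(R1 = 0.015, R2 = 0.35,
                                         NOE = 0.015))
  errs <- vapply(1:3, function(s) {
    ds <- gen_relaxation_data(tr, 50, seed = s)
    fit <- modelfree_fit(ds, tau_m = 12)
    mean(abs(fit$fits$S2 - rep(tr$S2_true, length.out = 50)),
         na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("R2/R1 classification separates slow, fast and typical residues", {
  ## all-equal ratios: everyone typical, SD zero
  df <- data.frame(residue = 1:5, R1 = 1, R1err = 0.01, R2 = 15,
                   R2err = 0.1, NOE = 0.8, NOEerr = 0.01)
  cl <- classify_r2r1(relaxation_dataset(df, 800))
  expect_true(all(cl$table$class == "typical"))
  expect_equal(cl$sd, 0)
  ## a constructed outlier at mean + >1 SD is slow
  df2 <- df
  df2$R2 <- c(15, 15.1, 14.9, 15, 22)
  cl2 <- classify_r2r1(relaxation_dataset(df2, 800))
  expect_equal(cl2$table$class[5], "slow")
  ## invariance under residue reordering
  df3 <- df2[c(3, 5, 1, 2, 4), ]
  cl3 <- classify_r2r1(relaxation_dataset(df3, 800))
  expect_equal(cl3$table$class[cl3$table$residue == 5], "slow")
  ## residues missing a rate are excluded and listed
  df4 <- df2; df4$R1[2] <- NA
  cl4 <- classify_r2r1(relaxation_dataset(df4, 800))
  expect_equal(cl4$excluded, 2)
  expect_error(classify_r2r1(relaxation_dataset(df4[1:2, ], 800)),
               ">= 3")
})

test_that("a planted exchange residue classifies as microsecond-scale slow", {
  tr <- relaxation_truth(S2_true = 0.85, tau_e_true = 50,
                         tau_m_true = 12, field_MHz = 800,
                         noise_sd = list(R1 = 0.01, R2 = 0.1,
                                         NOE = 0.01),
                         rex_true = c(rep(0, 19), 6))
  ds <- gen_relaxation_data(tr, 20, seed = 9)
  cl <- classify_r2r1(ds)
  expect_equal(cl$table$class[20], "slow")
  expect_true(all(cl$table$class[1:19] != "slow"))
})

test_that("relaxation CSV round-trips through the reader", {
  tr <- relaxation_truth(S2_true = 0.8, tau_e_true = 30,
                         tau_m_true = 10)
  ds <- gen_relaxation_data(tr, 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ds$data, path, row.names = FALSE)
  ds2 <- read_relaxation_csv(path, field_MHz = 800)
  expect_equal(ds2$data, ds$data, tolerance = 1e-12)
  bad <- ds$data[, 1:3]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_relaxation_csv(path2, 800), "missing columns")
})
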
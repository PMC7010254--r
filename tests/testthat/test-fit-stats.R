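test_that("a perfect fit reports the boundary values of every index", {
  spec <- battery()
  R <- correlation_input(implied_correlation(spec), n_effective = 114)
  mod <- extract_ml(R, m = 4, seed = 1)
  fs <- fit_statistics(R, mod, mean_structure = TRUE)
  expect_lt(fs$chi_square, 1e-4)
  expect_equal(fs$cfi, 1)
  expect_equal(fs$rmsea, 0)
  expect_lt(fs$srmr, 1e-4)
  expect_equal(fs$n_free_params, 66)
  expect_false(fs$heywood)
})

test_that("chi-square at or below df pins RMSEA to 0 and CFI to 1", {
  spec <- battery()
  R <- correlation_input(implied_correlation(spec), n_effective = 114)
  mod <- extract_ml(R, m = 4, seed = 1)
  # place F_min so that chi2 lands just below df
  mod$discrepancy <- model_df(12, 4) * 0.98 / (114 - 1)
  fs <- fit_statistics(R, mod, mean_structure = TRUE)
  expect_lte(fs$chi_square, fs$df)
  expect_equal(fs$rmsea, 0)
  expect_equal(fs$cfi, 1)
  expect_gt(fs$tli, 1)  # TLI may exceed 1 here, as in over-fitting solutions
})

test_that("SRMR equals a brute-force double loop over the lower moments", {
  R <- withr::with_seed(9, {
    L <- matrix(stats::rnorm(5 * 1, 0, 0.6), 5, 1)
    S <- L %*% t(L) + diag(stats::runif(5, 0.4, 0.9))
    d <- 1 / sqrt(diag(S)); S * tcrossprod(d)
  })
  # perturb to create residuals, keep PD
  Rp <- R; Rp[1, 2] <- Rp[2, 1] <- R[1, 2] + 0.1; Rp[3, 5] <- Rp[5, 3] <- R[3, 5] - 0.08
  mod <- extract_ml(Rp, m = 1, seed = 1)
  fs <- fit_statistics(Rp, mod, n_effective = 100)
  sigma_hat <- mod$loadings %*% mod$factor_corr %*% t(mod$loadings) +
    diag(mod$uniquenesses)
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:5) if (i <= j) {
    acc <- acc + (Rp[i, j] - sigma_hat[i, j])^2
    cnt <- cnt + 1
  }
  expect_equal(fs$srmr, sqrt(acc / cnt), tolerance = 1e-12)
})

test_that("loading quality bands follow the guideline cut points", {
  expect_equal(loading_quality(0.30), "poor")
  expect_equal(loading_quality(0.44), "poor")
  expect_equal(loading_quality(0.45), "fair")
  expect_equal(loading_quality(0.55), "good")
  expect_equal(loading_quality(0.63), "very good")
  expect_equal(loading_quality(0.71), "excellent")
  expect_equal(loading_quality(-0.80), "excellent")  # absolute value
  expect_equal(loading_quality(c(0.2, 0.5, 0.9)),
               c("poor", "fair", "excellent"))
})

test_that("a uniqueness forced to the floor is flagged as a Heywood case", {
  # r12 = r13 = .95 with r23 = .85 implies lambda_1 > 1 (triad rule):
  # the bounded solution sits on the uniqueness floor
  lam <- c(1.03, 0.92, 0.92, 0.5)
  S <- lam %*% t(lam); diag(S) <- 1
  expect_gt(cogstruct:::min_eigenvalue(S), 0)
  mod <- extract_ml(S, m = 1, seed = 1)
  fs <- fit_statistics(S, mod, n_effective = 200)
  expect_true(fs$heywood)
})

test_that("too-small samples disable test statistics but keep the solution", {
  spec <- battery()
  R <- correlation_input(implied_correlation(spec), n_effective = 10)
  mod <- extract_ml(R, m = 4, seed = 1)
  fs <- fit_statistics(R, mod, mean_structure = TRUE)
  expect_true(is.na(fs$chi_square))
  expect_true(is.na(fs$rmsea))
  expect_false(is.na(fs$srmr))
})
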
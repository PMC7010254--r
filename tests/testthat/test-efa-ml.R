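test_that("model df and free-parameter counts follow the closed forms", {
  expect_equal(model_df(12, 3), 33)
  expect_equal(model_df(12, 4), 24)
  expect_equal(model_df(12, 5), 16)
  expect_equal(model_df(4, 1), 2)
  expect_error(model_df(4, 2), class = "cogstruct_underidentified")
  expect_equal(count_free_parameters(12, 4, mean_structure = TRUE), 66)
  expect_equal(count_free_parameters(12, 4, mean_structure = FALSE), 54)
  for (p in c(5, 9, 12))
    expect_equal(count_free_parameters(p, 1, FALSE), 2 * p)
})

test_that("a perfectly factor-structured matrix is fit exactly", {
  spec <- battery()
  R <- implied_correlation(spec)
  mod <- extract_ml(correlation_input(R, n_effective = 114), m = 4, seed = 1)
  expect_true(mod$converged)
  expect_lt(mod$discrepancy, 1e-8)
  sigma_hat <- mod$loadings %*% t(mod$loadings) + diag(mod$uniquenesses)
  expect_lt(max(abs(sigma_hat - R)), 1e-5)
  # after rotation the generating simple structure reappears
  rot <- rotate_geomin(mod, seed = 1)
  expect_true(all(match_factors(rot$loadings, spec$loadings)$congruence > 0.999))
})

test_that("the one-factor triad closed form is recovered", {
  # lambda = (0.8, 0.7, 0.6) implies r12 = .56, r13 = .48, r23 = .42, and
  # the triad rule lambda_1 = sqrt(r12 r13 / r23) etc. inverts it
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.56
  R[1, 3] <- R[3, 1] <- 0.48
  R[2, 3] <- R[3, 2] <- 0.42
  lam_oracle <- c(sqrt(0.56 * 0.48 / 0.42),
                  sqrt(0.56 * 0.42 / 0.48),
                  sqrt(0.48 * 0.42 / 0.56))
  mod <- extract_ml(R, m = 1, seed = 1)
  expect_equal(as.numeric(mod$loadings), lam_oracle, tolerance = 1e-6)
})

test_that("the ML discrepancy matches an independent optimizer on random inputs", {
  for (trial in 1:5) {
    R <- withr::with_seed(100 + trial, {
      L <- matrix(stats::rnorm(12 * 4, 0, 0.45), 12, 4)
      S <- L %*% t(L) + diag(stats::runif(12, 0.3, 0.8))
      d <- 1 / sqrt(diag(S))
      S * tcrossprod(d)
    })
    mine <- extract_ml(R, m = 4, seed = trial)
    ref <- stats::factanal(covmat = R, factors = 4, rotation = "none",
                           control = list(nstart = 20, lower = 1e-3))
    expect_lt(abs(mine$discrepancy - ref$criteria[["objective"]]), 1e-6)
  }
})

test_that("extraction demands a positive-definite matrix", {
  bad <- matrix(0.99, 4, 4); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(extract_ml(bad, m = 1), class = "cogstruct_not_pd")
})

test_that("upper-tail chi-square probabilities are correct and monotone", {
  expect_equal(chi_square_p(0, 5), 1)
  expect_equal(chi_square_p(20.878, 24),
               stats::pchisq(20.878, 24, lower.tail = FALSE))
  x <- seq(0.5, 60, by = 0.5)
  pv <- chi_square_p(x, 24)
  expect_true(all(diff(pv) < 0))
})
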
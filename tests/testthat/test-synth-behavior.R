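test_that("the behavioral generator is deterministic under a seed", {
  spec <- battery(seed = 42)
  a <- generate_behavioral(spec)
  b <- generate_behavioral(spec)
  expect_identical(a$scores, b$scores)
  expect_identical(a$factor_scores, b$factor_scores)
  c <- generate_behavioral(spec, seed = 43)
  expect_false(identical(a$scores, c$scores))
})

test_that("large-N sample correlations converge to the implied matrix", {
  spec <- battery(n = 1e5, phi = 0, seed = 7)
  bm <- generate_behavioral(spec)
  sigma <- implied_correlation(spec)
  dev <- abs(stats::cor(bm$latent) - sigma)
  expect_lt(max(dev), 3 / sqrt(1e5))            # elementwise
  expect_lt(sqrt(mean(dev^2)), 0.01)            # overall
})

test_that("observed transforms are monotone and on the right scales", {
  spec <- battery(seed = 3)
  bm <- generate_behavioral(spec)
  x <- bm$scores[, -1]
  acc <- names(which(bm$measures == "accuracy"))
  rt <- names(which(bm$measures == "rt"))
  expect_true(all(x[, acc] > 0 & x[, acc] < 1))
  expect_true(all(x[, rt] > 0))
  expect_equal(mean(as.matrix(x[, acc])), 0.75, tolerance = 0.03)
  for (tk in acc)   # strictly increasing in the latent score
    expect_equal(stats::cor(x[[tk]], bm$latent[, tk], method = "spearman"), 1)
  for (tk in rt)    # strictly decreasing: better ability, shorter RT
    expect_equal(stats::cor(x[[tk]], bm$latent[, tk], method = "spearman"), -1)
})

test_that("session missingness reproduces the study completion structure", {
  spec <- battery(seed = 5)
  obs <- session_missing_pattern(114, spec$task_names, seed = 5)
  expect_equal(dim(obs), c(114, 12))
  expect_equal(sum(rowSums(obs) == 12), 72)     # completers
  expect_true(all(rowSums(obs) >= 2))
  pair_n <- crossprod(obs)
  expect_true(all(pair_n[upper.tri(pair_n)] >= 72))
  # flows through the generator and correlation stage
  bm <- generate_behavioral(spec, missing_pattern = "session")
  expect_equal(sum(stats::complete.cases(bm$scores[, -1])), 72)
  ci <- correlation_from_behavioral(bm)
  expect_true(all(ci$available_n[upper.tri(ci$available_n)] >= 72))
  expect_gte(ci$n_effective, 72)
})

test_that("degenerate requests are caught", {
  tiny <- latent_model_spec(cbind(rep(0.6, 12)), n_subjects = 5)
  expect_warning(generate_behavioral(tiny, seed = 1), "unstable")
  spec <- battery(n = 13, seed = 1)
  bad <- matrix(TRUE, 13, 12); bad[1, -1] <- FALSE
  expect_error(generate_behavioral(spec, missing_pattern = bad),
               class = "cogstruct_invalid_spec")
})
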
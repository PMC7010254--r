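test_that("thresholding is strict and counts match a hand count", {
  zero <- stat_map(array(0, c(4, 4, 4)))
  expect_equal(threshold_mask(zero, 2.3)$voxel_count, 0)
  # a voxel exactly at the threshold is excluded
  one <- array(0, c(4, 4, 4)); one[2, 2, 2] <- 2.3
  expect_equal(threshold_mask(stat_map(one), 2.3)$voxel_count, 0)
  # 2x2x2 toy: values above 2.3 are 3.0, 2.4, 5.1
  toy <- stat_map(array(c(3.0, 2.4, 2.3, 1.0, -3.0, 0, 5.1, 2.2), c(2, 2, 2)))
  expect_equal(threshold_mask(toy, 2.3)$voxel_count, 3)
})

test_that("mask intersection is idempotent and matches a loop oracle", {
  g <- c(12, 12, 12)
  a <- activation_mask(withr::with_seed(1, array(stats::runif(prod(g)) < 0.5, g)))
  b <- activation_mask(withr::with_seed(2, array(stats::runif(prod(g)) < 0.5, g)))
  expect_identical(intersection_mask(a, a)$values, a$values)
  ab <- intersection_mask(a, b)
  expect_lte(ab$voxel_count, min(a$voxel_count, b$voxel_count))
  count <- 0L
  for (i in seq_len(prod(g)))
    if (a$values[i] && b$values[i]) count <- count + 1L
  expect_equal(ab$voxel_count, count)
  # disjoint masks intersect to nothing
  expect_equal(intersection_mask(a, activation_mask(!a$values))$voxel_count, 0)
  # grids must agree
  small <- activation_mask(array(TRUE, c(6, 6, 6)))
  expect_error(intersection_mask(a, small), class = "cogstruct_grid_mismatch")
})

test_that("masked spatial correlation behaves like Pearson r", {
  g <- c(4, 4, 4)
  vals <- withr::with_seed(3, array(stats::rnorm(prod(g), 3, 1), g))
  a <- stat_map(vals)
  mask <- activation_mask(array(TRUE, g))
  expect_equal(spatial_correlation(a, a, mask)$r, 1)
  b <- stat_map(2 * vals + 5)  # positive affine rescaling
  expect_equal(spatial_correlation(a, b, mask)$r, 1)
  # 4-voxel hand computation: r((1,2,3,4),(2,1,4,3)) = 0.6
  av <- array(0, g); bv <- array(0, g); mk <- array(FALSE, g)
  av[1:4] <- c(1, 2, 3, 4); bv[1:4] <- c(2, 1, 4, 3); mk[1:4] <- TRUE
  got <- spatial_correlation(stat_map(av), stat_map(bv),
                             activation_mask(mk), n_min = 4)
  expect_equal(got$r, 0.6)
  expect_equal(got$n, 4L)
  # undefined cases error out
  expect_error(spatial_correlation(a, b, activation_mask(mk), n_min = 10),
               class = "cogstruct_undefined_correlation")
  const <- stat_map(array(1, g))
  expect_error(spatial_correlation(const, a, mask),
               class = "cogstruct_undefined_correlation")
})

test_that("pairwise matrix enumerates every unordered pair once", {
  ns <- small_netspec(seed = 4)
  maps <- generate_task_maps(ns, seed = 4)
  pcm <- pairwise_matrix(maps)
  p <- length(pcm$tasks)
  expect_equal(p, 12)
  # 66 pair correlations + 12 unit self-correlations = 78 distinct values
  expect_equal(sum(upper.tri(pcm$r)), 66)
  expect_equal(sum(upper.tri(pcm$r, diag = TRUE)), 78)
  expect_equal(diag(pcm$r), rep(1, 12), ignore_attr = TRUE)
  expect_true(isSymmetric(pcm$r))
  expect_true(all(abs(pcm$r) <= 1))
  expect_true(isSymmetric(pcm$n_voxels + 0))
  # p = 2 and p = 5 match the combinatorial count
  expect_equal(sum(upper.tri(pairwise_matrix(maps[1:2])$r)), 1)
  expect_equal(sum(upper.tri(pairwise_matrix(maps[1:5])$r)), choose(5, 2))
  # entries are invariant under task reordering
  perm <- rev(seq_len(12))
  pcm2 <- pairwise_matrix(maps[perm])
  expect_equal(pcm2$r[pcm$tasks, pcm$tasks], pcm$r, tolerance = 1e-12)
})

test_that("PD repair clips eigenvalues and restores the unit diagonal", {
  pd <- diag(3) * 0.5 + 0.5
  out <- nearest_pd_repair(pd)
  expect_false(attr(out, "repaired"))
  expect_equal(unclass(out), pd, ignore_attr = TRUE)
  # indefinite 3x3
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  rep3 <- nearest_pd_repair(bad)
  expect_true(attr(rep3, "repaired"))
  expect_gte(cogstruct:::min_eigenvalue(unclass(rep3)), 1e-6 * (1 - 1e-8))
  expect_equal(diag(unclass(rep3)), rep(1, 3))
  # random indefinite 12x12: match an independently coded clip-then-rescale
  # projection run to convergence, and stay comparably close to the input
  # as the (differently defined) optimal projection in Matrix::nearPD
  bad12 <- withr::with_seed(8, {
    x <- matrix(stats::rnorm(144), 12); x <- (x + t(x)) / 2
    diag(x) <- 1
    x
  })
  expect_lt(cogstruct:::min_eigenvalue(bad12), 0)
  mine <- unclass(nearest_pd_repair(bad12))
  oracle <- bad12
  for (it in 1:500) {
    e <- eigen(oracle, symmetric = TRUE)
    if (min(e$values) >= 1e-6 * (1 - 1e-10)) break
    oracle <- e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors)
    oracle <- stats::cov2cor(oracle)
  }
  expect_gte(cogstruct:::min_eigenvalue(mine), 1e-6 * (1 - 1e-8))
  expect_equal(diag(mine), rep(1, 12))
  expect_lt(max(abs(mine - oracle)), 1e-8)
  skip_if_not_installed("Matrix")
  ref <- as.matrix(Matrix::nearPD(bad12, corr = TRUE)$mat)
  expect_lte(norm(mine - bad12, "F"), norm(ref - bad12, "F") * 2)
})

test_that("domain conjunction equals chained intersection in any order", {
  g <- c(10, 10, 10)
  ms <- lapply(1:3, function(i)
    activation_mask(withr::with_seed(i, array(stats::runif(prod(g)) < 0.6, g))))
  conj <- domain_conjunction_mask(ms)
  chained <- intersection_mask(intersection_mask(ms[[3]], ms[[1]]), ms[[2]])
  expect_identical(conj$values, chained$values)
  loop <- array(FALSE, g)
  for (i in seq_len(prod(g)))
    loop[i] <- ms[[1]]$values[i] && ms[[2]]$values[i] && ms[[3]]$values[i]
  expect_identical(conj$values, loop)
  # identical inputs reproduce themselves; an empty input empties the result
  expect_identical(domain_conjunction_mask(list(ms[[1]], ms[[1]], ms[[1]]))$values,
                   ms[[1]]$values)
  empty <- activation_mask(array(FALSE, g))
  expect_equal(domain_conjunction_mask(list(ms[[1]], empty, ms[[2]]))$voxel_count, 0)
  expect_error(domain_conjunction_mask(ms[1:2]), class = "cogstruct_invalid_spec")
})
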
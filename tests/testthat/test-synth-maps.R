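test_that("noise-free same-domain maps are identical with spatial correlation 1", {
  ns <- small_netspec(noise_sd = 0)
  maps <- generate_task_maps(ns, seed = 1)
  doms <- battery_domains_for_test()
  a <- maps[[doms$memory[1]]]; b <- maps[[doms$memory[2]]]
  expect_identical(a$values, b$values)
  mask <- intersection_mask(threshold_mask(a), threshold_mask(b))
  expect_equal(spatial_correlation(a, b, mask)$r, 1)
})

test_that("disjoint templates with no shared signal give empty cross-domain intersections", {
  ns <- disjoint_netspec()
  ns$effect_scale <- 5
  maps <- generate_task_maps(ns, seed = 1)
  doms <- battery_domains_for_test()
  m1 <- threshold_mask(maps[[doms$memory[1]]])       # template block 1
  m2 <- threshold_mask(maps[[doms$reasoning[1]]])    # template block 2
  expect_gt(m1$voxel_count, 0)
  expect_gt(m2$voxel_count, 0)
  expect_equal(intersection_mask(m1, m2)$voxel_count, 0)
})

test_that("within-domain similarity exceeds between-domain similarity in expectation", {
  ns <- small_netspec(seed = 10)
  dom_of <- ns$task_domain
  wb <- vapply(1:200, function(i) {
    pcm <- pairwise_matrix(generate_task_maps(ns, seed = 5000 + i))
    same <- outer(dom_of[pcm$tasks], dom_of[pcm$tasks], `==`)
    ut <- upper.tri(pcm$r)
    c(mean(pcm$r[ut & same]), mean(pcm$r[ut & !same]))
  }, numeric(2))
  expect_gt(mean(wb[1, ]), mean(wb[2, ]))
})

test_that("subject beta generation is deterministic and grid-checked", {
  ns <- small_netspec(seed = 2)
  spec <- battery(n = 8, seed = 2)
  bm <- suppressWarnings(generate_behavioral(spec))  # n < p on purpose
  b1 <- generate_subject_betas(ns, bm$factor_scores, seed = 9)
  b2 <- generate_subject_betas(ns, bm$factor_scores, seed = 9)
  expect_identical(b1$maps, b2$maps)
  # unnamed factor scores cannot be matched to domains
  expect_error(generate_subject_betas(ns, unname(bm$factor_scores), seed = 9),
               class = "cogstruct_grid_mismatch")
  # mask on a different grid is rejected
  other <- activation_mask(array(TRUE, c(6, 6, 6)))
  expect_error(extract_mask_means(b1, other), class = "cogstruct_grid_mismatch")
})

test_that("the analytic mask-mean noise variance matches simulation", {
  ns <- small_netspec()
  base <- ns$effect_scale * (ns$shared_template + ns$domain_templates$memory)
  mask <- base > 2.3
  analytic <- cogstruct:::mask_mean_noise_var(ns, mask, sd = 1)
  sims <- withr::with_seed(21, vapply(1:400, function(i) {
    mean(cogstruct:::noise_field(ns$grid_shape, 1, ns$smoothing_fwhm)[mask])
  }, 0.0))
  expect_equal(stats::var(sims), analytic, tolerance = 0.15)
})

test_that("zero coupling leaves brain-behavior correlations in the null band", {
  lat <- battery()
  ns <- small_netspec()   # coupling 0 by default
  mem <- battery_domains_for_test()$memory
  base <- ns$effect_scale * (ns$shared_template + ns$domain_templates$memory)
  mask <- activation_mask(base > 2.3, threshold = 2.3)
  asg <- structure(list(rule = "a_priori", factors = list(memory = mem)),
                   class = "domain_assignment")
  rs <- vapply(1:40, function(i) {
    bm <- generate_behavioral(lat, seed = 600 + i)
    bb <- generate_subject_betas(ns, bm$factor_scores, tasks = mem,
                                 seed = 700 + i)
    brain_behavior(bb, list(memory = mask), bm, asg)$table$r
  }, 0.0)
  # under no coupling, r ~ N(0, 1/sqrt(111)); 95% band with margin
  expect_lt(abs(mean(rs)), 2 * 1 / sqrt(111) / sqrt(40) * 3)
  expect_gt(mean(abs(rs) < 1.96 / sqrt(111)), 0.85)
})

test_that("coupling calibration recovers its target correlation", {
  lat <- battery()
  ns <- small_netspec()
  cc <- calibrate_coupling(ns, lat, "memory", 0.4)
  expect_gt(as.numeric(cc), 0)
  expect_lt(attr(cc, "rho_neural"), 1)
  ns$coupling["memory"] <- as.numeric(cc)
  mem <- battery_domains_for_test()$memory
  base <- ns$effect_scale * (ns$shared_template + ns$domain_templates$memory)
  mask <- activation_mask(base > 2.3, threshold = 2.3)
  asg <- structure(list(rule = "a_priori", factors = list(memory = mem)),
                   class = "domain_assignment")
  rs <- vapply(1:30, function(i) {
    bm <- generate_behavioral(lat, seed = 810 + i)
    bb <- generate_subject_betas(ns, bm$factor_scores, tasks = mem,
                                 seed = 910 + i)
    brain_behavior(bb, list(memory = mask), bm, asg)$table$r
  }, 0.0)
  # mean of 30 replicate r's should sit inside the single-sample 95% CI of 0.4
  ci <- tanh(atanh(0.4) + c(-1, 1) * 1.96 / sqrt(114 - 3))
  expect_gt(mean(rs), ci[1])
  expect_lt(mean(rs), ci[2])
})
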
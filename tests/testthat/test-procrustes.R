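ids7 <- landmark_registry()$id[landmark_registry()$retained]

test_that("the Procrustes objective matches hand values and a naive
           double-loop recomputation", {
  # single sample, single landmark, unit weight, consensus offset by (1,0,0)
  l <- landmark_set(matrix(c(0, 0, 0), 1, dimnames = list("PTP", NULL)))
  W <- matrix(1, 1, 1, dimnames = list(NULL, "PTP"))
  expect_equal(wgp_objective(list(l), W, list(scaling_transform()),
                             matrix(c(1, 0, 0), 1)), 0.5)
  # identical samples, identity transforms, consensus = common values -> 0
  set.seed(8)
  base <- matrix(rnorm(21, sd = 6), 7, 3, dimnames = list(ids7, NULL))
  W7 <- matrix(1, 3, 7, dimnames = list(NULL, ids7))
  ls <- replicate(3, landmark_set(base), simplify = FALSE)
  expect_equal(wgp_objective(ls, W7,
                             replicate(3, scaling_transform(),
                                       simplify = FALSE), base), 0)
  # random instance vs naive recomputation
  inst <- wgp_instance(21, n = 4)
  trs <- replicate(4, scaling_transform(runif(3, 0.5, 2), rnorm(3)),
                   simplify = FALSE)
  g <- matrix(rnorm(21, sd = 5), 7, 3)
  expect_equal(wgp_objective(inst$landmarks, inst$weights, trs, g),
               wgp_objective_naive(inst$landmarks, inst$weights, trs, g),
               tolerance = 1e-12)
  # positive weight on a missing landmark is an error
  lm <- landmark_set(rbind(base[1:6, ],
                           matrix(NA, 1, 3, dimnames = list(ids7[7], NULL))))
  expect_error(wgp_objective(list(lm), matrix(1, 1, 7,
                                              dimnames = list(NULL, ids7)),
                             list(scaling_transform()), base),
               "missing landmark")
  # all-zero weight column is an error
  W0 <- W7; W0[, 3] <- 0
  expect_error(solve_wgp(ls, W0), "positive weight")
})

test_that("exactly matchable configurations are matched to numerical zero", {
  set.seed(2)
  base <- matrix(rnorm(21, sd = 6), 7, 3, dimnames = list(ids7, NULL))
  l1 <- landmark_set(base)
  l2 <- landmark_set(sweep(2 * base, 2, c(5, 0, 0), "+"))
  W <- matrix(1, 2, 7, dimnames = list(NULL, ids7))
  res <- solve_wgp(list(l1, l2), W)
  expect_lt(res$objective, 1e-10)
  expect_true(res$converged)
  # identical complete configurations: identity-like fixed point
  res2 <- solve_wgp(list(l1, landmark_set(base)), W)
  expect_lt(res2$objective, 1e-18)
  for (tr in res2$transforms) {
    expect_equal(tr$scale, c(1, 1, 1), tolerance = 1e-6)
    expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-6)
  }
})

test_that("the ALS solution is translation-equivariant with monotone
           objective trace and tight constraint residuals", {
  inst <- wgp_instance(31, n = 3)
  res <- solve_wgp(inst$landmarks, inst$weights)
  expect_true(all(diff(res$trace) <= 1e-9 * max(res$trace[1], 1)))
  expect_lt(res$constraint_residuals["barycenter_mm"], 1e-8)
  expect_lt(res$constraint_residuals["size_relative"], 1e-8)
  shift <- c(11, -4, 6)
  shifted <- lapply(inst$landmarks, function(l)
    landmark_set(sweep(unclass(l), 2, shift, "+")))
  res2 <- solve_wgp(shifted, inst$weights)
  expect_equal(res2$objective, res$objective, tolerance = 1e-7)
  expect_equal(res2$consensus,
               res$consensus + matrix(shift, 7, 3, byrow = TRUE),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("identity-initialized alternation preserves per-axis structure on
           near-matchable groups", {
  # noisy scaled copies, low noise: both modes find the aligned solution
  inst <- wgp_instance(5, n = 4, miss_frac = 0.15, noise_sd = 0.2)
  res <- solve_wgp(inst$landmarks, inst$weights, global_init = FALSE)
  expect_true(all(diff(res$trace) <= 1e-9 * max(res$trace[1], 1)))
  sds <- apply(res$consensus, 2, sd)
  expect_true(all(sds > 1))  # no axis collapse
  for (tr in res$transforms) {
    expect_true(all(tr$scale > 0.5 & tr$scale < 2))
  }
})

test_that("resample_to_consensus maps rasters backward and landmarks
           forward, consistently", {
  ph <- fix_phantom48()
  ref <- ph$image
  # identity transform: resampling onto the same grid is the identity
  same <- resample_to_consensus(ph, scaling_transform(), ref)
  expect_lt(max(abs(same$image$data - ph$image$data)), 1e-9)
  expect_identical(same$mask$data, ph$mask$data)
  # pure translation: landmarks shift by exactly t
  tr <- scaling_transform(translation = c(3, -2, 1))
  big <- centered_volume(c(56L, 56L, 56L), spacing = 1.0)
  shifted <- resample_to_consensus(ph, tr, big)
  expect_equal(unclass(shifted$landmarks),
               unclass(ph$landmarks) + matrix(c(3, -2, 1), 11, 3,
                                              byrow = TRUE),
               ignore_attr = TRUE)
  # scaling changes the mask volume by the Jacobian (within voxelization)
  sc <- scaling_transform(scale = c(1.2, 1.1, 1.15))
  scaled <- resample_to_consensus(ph, sc, big)
  ratio <- sum(scaled$mask$data) / sum(ph$mask$data)
  expect_equal(ratio, prod(sc$scale), tolerance = 0.03)
  # probability maps stay normalized
  s <- Reduce(`+`, lapply(scaled$probmaps, function(v) v$data))
  expect_lt(max(abs(s - 1)), 1e-6)
})
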
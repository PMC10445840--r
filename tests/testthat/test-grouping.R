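test_that("the temporal kernel weight matches its closed form and truncates
           at 3 sigma", {
  # 1/(3*sqrt(2*pi)), frozen from high-precision evaluation
  expect_equal(kernel_weight(168, 168), 0.1329807601338109, tolerance = 1e-9)
  expect_equal(kernel_weight(171, 168),
               exp(-0.5) / (3 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_identical(kernel_weight(178, 168), 0)  # 10 days > 3 sigma
  expect_gt(kernel_weight(177, 168), 0)         # 9 days is included
  expect_identical(kernel_weight(168, 168, landmark_present = FALSE), 0)
  # symmetric and non-increasing in |delta|
  d <- 0:12
  w <- vapply(d, function(x) kernel_weight(168 + x, 168), 0)
  wneg <- vapply(d, function(x) kernel_weight(168 - x, 168), 0)
  expect_equal(w, wneg)
  expect_true(all(diff(w) <= 0))
  expect_error(kernel_weight(168, 168, sigma_days = 0))
})

make_mock_cohort <- function(gas, operated = FALSE) {
  # light-weight samples: grouping only touches meta + landmarks
  ph <- fix_phantom(seed = 1, ga_weeks = 24)
  samples <- lapply(seq_along(gas), function(i) {
    s <- ph
    s$meta$subject_id <- sprintf("s%02d", i)
    s$meta$session_id <- "ses-1"
    s$meta$ga <- as.integer(gas[i])
    s$meta$operated <- if (length(operated) > 1) operated[i] else operated
    s
  })
  list(samples = samples)
}

test_that("group construction enforces the window, size and bracketing
           rules", {
  cfg <- pipeline_config(week_range = c(24L, 26L))
  # 2 members only -> dropped
  expect_length(build_groups(make_mock_cohort(c(166, 170)), cfg), 0)
  # 3 members, bracketing satisfied -> retained at 24w only
  g <- build_groups(make_mock_cohort(c(165, 168, 171)), cfg)
  expect_length(g, 1)
  expect_identical(g[[1]]$target_ga, 168L)
  expect_length(g[[1]]$members, 3)
  # members beyond 9 days are excluded from the window
  g2 <- build_groups(make_mock_cohort(c(158, 165, 168, 171, 178)), cfg)[[1]]
  expect_length(g2$members, 3)
  # a 26-week candidate whose members are all at <= 25 weeks violates
  # bracketing and is dropped
  cfg26 <- pipeline_config(week_range = c(26L, 26L))
  expect_length(build_groups(make_mock_cohort(c(173, 174, 175)), cfg26), 0)
  # ... and is retained once a member above 26 weeks exists
  expect_length(build_groups(make_mock_cohort(c(173, 174, 175, 183)),
                             cfg26), 1)
  # operated and non-operated sessions never share a group
  mixed <- make_mock_cohort(c(165, 168, 171, 165, 168, 171),
                            operated = c(rep(FALSE, 3), rep(TRUE, 3)))
  gm <- build_groups(mixed, cfg)
  expect_length(gm, 2)
  expect_false(gm[[1]]$operated == gm[[2]]$operated)
  for (g in gm)
    expect_true(all(vapply(g$members, function(s)
      s$meta$operated == g$operated, NA)))
  expect_error(build_groups(list(samples = list()), cfg), "empty cohort")
})

test_that("every retained group passes an independent re-check of the
           grouping rules, for any cohort ordering", {
  cfg <- pipeline_config()
  co <- fix_tiny_cohort()
  groups <- build_groups(co, cfg)
  expect_gt(length(groups), 0)
  for (g in groups) {
    gas <- vapply(g$members, function(s) as.numeric(s$meta$ga), 0)
    expect_true(all(abs(gas - g$target_ga) <= cfg$window_days))
    expect_gte(length(gas), cfg$min_group_size)
    expect_true(any(gas > g$target_ga) && any(gas < g$target_ga))
    expect_equal(g$weights,
                 vapply(gas, kernel_weight, 0, target = g$target_ga,
                        sigma_days = cfg$sigma_days))
  }
  # permuting the cohort yields identical groups
  set.seed(2)
  perm <- co
  perm$samples <- perm$samples[sample(seq_along(perm$samples))]
  groups2 <- build_groups(perm, cfg)
  expect_identical(length(groups), length(groups2))
  for (i in seq_along(groups)) {
    expect_identical(groups[[i]]$target_ga, groups2[[i]]$target_ga)
    expect_identical(
      vapply(groups[[i]]$members, function(s) s$meta$subject_id, ""),
      vapply(groups2[[i]]$members, function(s) s$meta$subject_id, ""))
    expect_identical(groups[[i]]$weights, groups2[[i]]$weights)
  }
})

test_that("flip augmentation doubles a group with mirrored members at
           unchanged weights", {
  cfg <- pipeline_config(week_range = c(24L, 24L))
  g <- build_groups(make_mock_cohort(c(165, 168, 171)), cfg)[[1]]
  ag <- augment_group(g)
  expect_length(ag$members, 6)
  expect_identical(sum(ag$augmented), 3L)
  expect_identical(ag$weights, c(g$weights, g$weights))
  # augmented member = flip of its original
  orig <- g$members[[2]]
  aug <- ag$members[[2 + 3]]
  expect_identical(aug$image$data, flip_image(orig$image)$data)
  expect_equal(unclass(aug$landmarks),
               unclass(flip_landmarks(orig$landmarks,
                                      plane_x = mid_sagittal_x(orig$image))))
  man <- group_manifest(ag)
  expect_identical(nrow(man), 6L)
  expect_identical(sum(man$augmented), 3L)
})
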
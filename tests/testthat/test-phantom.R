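test_that("phantom generation is deterministic and growth-consistent", {
  sp <- phantom_spec(ga_from_weeks_days(26), severity = 0.4, seed = 9,
                     grid_shape = c(40L, 40L, 40L), spacing = 1.2)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(unclass(a$landmarks), unclass(b$landmarks))
  # brain volume grows monotonically with gestational age
  vol <- function(w) sum(make_phantom(phantom_spec(
    ga_from_weeks_days(w), seed = 9))$mask$data)
  v <- vapply(c(22, 26, 30), vol, 0)
  expect_true(all(diff(v) > 0))
  # severity strictly enlarges the ventricle class
  nv <- function(sev) {
    ph <- make_phantom(phantom_spec(ga_from_weeks_days(26), severity = sev,
                                    seed = 9))
    sum(ph$probmaps$ventricles$data)
  }
  expect_gt(nv(0.9), nv(0.1))
  # too small a grid errors
  expect_error(make_phantom(phantom_spec(ga_from_weeks_days(34), seed = 1,
                                         grid_shape = c(24L, 24L, 24L),
                                         spacing = 0.8)),
               "grid too small")
})

test_that("phantom probability maps are one-hot and consistent with the
           mask; landmarks sit inside the brain in mirror pairs", {
  ph <- fix_phantom()
  s <- Reduce(`+`, lapply(ph$probmaps, function(v) v$data))
  expect_equal(max(abs(s - 1)), 0)
  onehot <- Reduce(`+`, lapply(ph$probmaps, function(v) v$data *
                                 (v$data - 1)))
  expect_equal(max(abs(onehot)), 0)  # every value is 0 or 1
  expect_identical(ph$probmaps$background$data > 0.5, ph$mask$data < 0.5)
  expect_true(all(sample_volume(ph$mask, unclass(ph$landmarks),
                                "nearest") == 1))
  reg <- landmark_registry()
  lm <- unclass(ph$landmarks)
  for (i in seq_len(nrow(reg))) {
    p <- reg$partner[i]
    expect_equal(lm[reg$id[i], ],
                 lm[p, ] * c(-1, 1, 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("perturb_phantom applies exactly the transform it reports", {
  ph <- fix_phantom()
  # identity is a no-op with an identity ground truth
  idp <- perturb_phantom(ph)
  expect_equal(unclass(idp$sample$landmarks), unclass(ph$landmarks))
  expect_equal(idp$transform$forward(rbind(c(1, 2, 3))),
               rbind(c(1, 2, 3)))
  expect_lt(max(abs(idp$sample$image$data - ph$image$data)), 1e-9)
  # anisotropic scaling doubles the landmark x extent only
  sc <- perturb_phantom(ph, scale = c(2, 1, 1))
  lm0 <- unclass(ph$landmarks); lm1 <- unclass(sc$sample$landmarks)
  expect_equal(diff(range(lm1[, 1])), 2 * diff(range(lm0[, 1])))
  expect_equal(lm1[, 2:3], lm0[, 2:3], ignore_attr = TRUE)
  # dropped landmarks are missing, everything else present
  dp <- perturb_phantom(ph, drop_landmarks = "LFOM")
  expect_true(is_missing_landmark(dp$sample$landmarks, "LFOM"))
  expect_setequal(present_landmarks(dp$sample$landmarks),
                  setdiff(rownames(lm0), "LFOM"))
  # inverse ground-truth transform recovers landmarks: exact for affine,
  # < 0.1 mm with a smooth warp
  afp <- perturb_phantom(ph, scale = c(1.2, 0.9, 1.05),
                         translation = c(3, -2, 1))
  rec <- afp$transform$inverse(unclass(afp$sample$landmarks))
  expect_lt(max(abs(rec - lm0)), 1e-9)
  wp <- perturb_phantom(ph, scale = c(1.1, 1, 0.95),
                        translation = c(1, 2, -1),
                        smooth_warp_amplitude = 2, seed = 5)
  rec2 <- wp$transform$inverse(unclass(wp$sample$landmarks))
  expect_lt(max(sqrt(rowSums((rec2 - lm0)^2))), 0.1)
  # an uninvertible warp request is refused
  expect_error(perturb_phantom(ph, smooth_warp_amplitude = 30,
                               warp_wavelength_mm = 40), "invertible")
})

test_that("synthetic cohorts are reproducible and respect the surgery age", {
  co <- make_cohort(6, ga_range = c(154L, 203L), seed = 2,
                    grid_shape = c(32L, 32L, 32L), spacing = 1.5)
  co2 <- make_cohort(6, ga_range = c(154L, 203L), seed = 2,
                     grid_shape = c(32L, 32L, 32L), spacing = 1.5)
  expect_identical(co$table, co2$table)
  expect_identical(co$samples[[3]]$image$data, co2$samples[[3]]$image$data)
  # longitudinal: some subject has >= 2 sessions at increasing GA
  multi <- split(co$table$ga, co$table$subject_id)
  expect_true(any(vapply(multi, length, 0L) >= 2))
  for (g in multi) expect_true(all(diff(g) > 0))
  # operated sessions only above the surgery age (25 weeks)
  expect_true(all(co$table$ga[co$table$operated] > 175))
  co3 <- make_cohort(5, ga_range = c(154L, 203L), operated_split = 0,
                     seed = 2, grid_shape = c(32L, 32L, 32L), spacing = 1.5)
  expect_false(any(co3$table$operated))
  expect_error(make_cohort(0), "n_subjects")
})
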
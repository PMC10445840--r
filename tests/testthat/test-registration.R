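test_that("LNCC similarity is 1 for identical images, invariant to positive
           affine intensity maps, and near zero for independent noise", {
  ph <- fix_phantom48()
  img <- normalize_intensity(ph$image, ph$mask)
  expect_gte(lncc_similarity(img, img, ph$mask), 0.99)
  rescaled <- image_volume(3.7 * img$data + 250, img$affine)
  expect_equal(lncc_similarity(img, rescaled, ph$mask),
               lncc_similarity(img, img, ph$mask), tolerance = 1e-9)
  set.seed(6)
  noise <- image_volume(array(rnorm(48^3, 500, 100), dim(img$data)),
                        img$affine)
  expect_lt(lncc_similarity(img, noise, ph$mask), 0.2)
  empty <- image_volume(array(0, dim(img$data)), img$affine)
  expect_error(lncc_similarity(img, img, empty), "empty")
})

test_that("regularization energies vanish on translations, match the
           analytic value on a linear ramp, and the linear energy ignores
           infinitesimal rotations", {
  ffd <- ffd_for_bbox(rbind(c(-18, -18, -18), c(18, 18, 18)), 3)
  expect_equal(unname(regularization_energy(ffd)), c(0, 0))
  tr <- ffd
  tr$theta <- matrix(rep(c(2, -1, 0.5), each = nrow(ffd$theta)), ncol = 3)
  expect_equal(unname(regularization_energy(tr)), c(0, 0))
  nodes <- sbatlas:::lattice_node_coords(ffd)
  ramp <- ffd
  ramp$theta <- cbind(0.1 * nodes[, 1], 0, 0)
  e <- regularization_energy(ramp)
  expect_equal(unname(e["bending"]), 0, tolerance = 1e-20)
  expect_equal(unname(e["linear"]), 0.01, tolerance = 1e-12)
  # skew-symmetric Jacobian (infinitesimal rotation about z): linear = 0
  rot <- ffd
  rot$theta <- cbind(-0.05 * nodes[, 2], 0.05 * nodes[, 1], 0)
  er <- regularization_energy(rot)
  expect_equal(unname(er["bending"]), 0, tolerance = 1e-20)
  expect_equal(unname(er["linear"]), 0, tolerance = 1e-12)
})

test_that("the registration cost assembles its components with the derived
           LNCC coefficient", {
  cfg <- pipeline_config()
  expect_equal(alpha_lncc(cfg), 0.5994)
  ph <- fix_phantom48()
  atl <- list(image = normalize_intensity(ph$image, ph$mask),
              mask = ph$mask, consensus_landmarks = ph$landmarks)
  subj <- brain_sample(ph$meta, atl$image, ph$mask, ph$landmarks)
  ffd <- ffd_for_bbox(sbatlas:::mask_bbox(ph$mask, pad_mm = 6), 3)
  res <- registration_cost(subj, atl, ffd, cfg, use_landmarks = TRUE)
  expect_gte(res$components["lncc"], 0.99)
  expect_equal(unname(res$components["landmark"]), 0)
  expect_equal(unname(res$components["bending"]), 0)
  expect_equal(unname(res$components["linear"]), 0)
  expect_equal(res$cost, -0.5994 * res$components[["lncc"]],
               tolerance = 1e-12)
  # without landmarks the landmark sum is omitted
  res2 <- registration_cost(subj, atl, ffd, cfg, use_landmarks = FALSE)
  expect_equal(unname(res2$components["landmark"]), 0)
})

test_that("analytic registration gradients agree with finite differences", {
  ph <- make_phantom(phantom_spec(ga_from_weeks_days(24), seed = 13,
                                  grid_shape = c(24L, 24L, 24L),
                                  spacing = 2.0))
  cfg <- pipeline_config()
  atl <- list(image = normalize_intensity(ph$image, ph$mask),
              mask = ph$mask, consensus_landmarks = ph$landmarks)
  subj <- brain_sample(ph$meta, atl$image, ph$mask, ph$landmarks)
  ffd <- ffd_for_bbox(sbatlas:::mask_bbox(ph$mask, pad_mm = 12), 6)
  set.seed(3)
  ffd$theta <- matrix(rnorm(nrow(ffd$theta) * 3, sd = 0.3), ncol = 3)
  ctx <- sbatlas:::reg_context(subj, atl, ffd, cfg, use_landmarks = TRUE)
  ev <- sbatlas:::reg_eval(ctx, ffd$theta, want_grad = TRUE)
  idx <- sample(length(ffd$theta), 12)
  h <- 1e-4
  for (j in idx) {
    thp <- ffd$theta; thp[j] <- thp[j] + h
    thm <- ffd$theta; thm[j] <- thm[j] - h
    fd <- (sbatlas:::reg_eval(ctx, thp, want_grad = FALSE)$cost -
             sbatlas:::reg_eval(ctx, thm, want_grad = FALSE)$cost) / (2 * h)
    expect_equal(ev$grad[j], fd, tolerance = 5e-2)
  }
})

test_that("affine initialization recovers translations from landmarks and
           scales from mask moments", {
  ph <- fix_phantom48()
  atl <- list(image = ph$image, mask = ph$mask,
              consensus_landmarks = ph$landmarks)
  # identical inputs -> identity
  id <- fit_affine_init(ph, atl, TRUE)
  expect_equal(id$scale, c(1, 1, 1), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)
  # translated subject, landmark mode: exact recovery
  pert <- perturb_phantom(ph, translation = c(2.5, -1.5, 1))$sample
  tr <- fit_affine_init(pert, atl, TRUE)
  expect_equal(tr$scale, c(1, 1, 1), tolerance = 1e-6)
  expect_lt(max(abs(tr$translation - c(-2.5, 1.5, -1))), 0.1)
  # mask-moment mode on a scaled phantom: scale within 5%
  sc <- perturb_phantom(ph, scale = c(1.15, 0.9, 1.1))$sample
  tr2 <- fit_affine_init(sc, atl, use_landmarks = FALSE)
  expect_equal(tr2$scale, 1 / c(1.15, 0.9, 1.1), tolerance = 0.05)
})

test_that("apply_transform is the identity for identity transforms, maps
           points forward exactly under pure translations, and never
           invents labels", {
  ph <- fix_phantom48()
  parc <- argmax_parcellation(ph$probmaps)
  ffd0 <- ffd_for_bbox(sbatlas:::mask_bbox(ph$mask, pad_mm = 6), 3)
  out <- apply_transform(ffd0, parc, "nearest", ph$image)
  expect_identical(out$data, parc$data)  # bit-exact for labels
  # pure-translation lattice: B-spline partition of unity moves points by t
  tffd <- ffd0
  tffd$theta <- matrix(rep(c(1.5, -2, 0.5), each = nrow(ffd0$theta)),
                       ncol = 3)
  pts <- unclass(ph$landmarks)
  expect_equal(apply_transform(tffd, pts, "forward-points"),
               pts + matrix(c(1.5, -2, 0.5), nrow(pts), 3, byrow = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
  warped <- apply_transform(tffd, parc, "nearest", ph$image)
  expect_true(all(unique(as.vector(warped$data)) %in%
                    unique(as.vector(parc$data))))
  # probability maps warp linearly and stay normalized
  pm <- apply_transform(tffd, ph$probmaps, "linear", ph$image)
  s <- Reduce(`+`, lapply(pm, function(v) v$data))
  expect_lt(max(abs(s - 1)), 1e-6)
  expect_error(apply_transform(ffd0, parc, "nearest"), "output_grid")
})

test_that("FFD transforms serialize losslessly", {
  td <- withr::local_tempdir()
  ffd <- ffd_for_bbox(rbind(c(-10, -10, -10), c(10, 10, 10)), 3,
                      affine = scaling_transform(c(1.1, 1, 0.9),
                                                 c(1, -2, 0)))
  set.seed(12)
  ffd$theta <- matrix(rnorm(nrow(ffd$theta) * 3, sd = 0.4), ncol = 3)
  write_ffd(ffd, file.path(td, "tr"))
  back <- read_ffd(file.path(td, "tr"))
  pts <- matrix(rnorm(30, sd = 5), 10)
  expect_equal(ffd_map_points(back, pts), ffd_map_points(ffd, pts),
               tolerance = 1e-12)
})

test_that("registering a sample to itself stays at the identity", {
  ph <- fix_phantom48()
  img <- normalize_intensity(ph$image, ph$mask)
  atl <- list(image = img, mask = ph$mask,
              consensus_landmarks = ph$landmarks)
  subj <- brain_sample(ph$meta, img, ph$mask, ph$landmarks)
  tr <- register_ffd(subj, atl, pipeline_config(), use_landmarks = TRUE)
  pts <- unclass(ph$landmarks)
  moved <- ffd_map_points(tr, pts)
  # mean displacement below 0.2 voxel (0.2 mm at 1 mm spacing)
  expect_lt(mean(sqrt(rowSums((moved - pts)^2))), 0.2)
})
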
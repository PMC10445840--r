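test_that("Dice matches exhaustive counting and is symmetric and monotone
           under erosion", {
  a <- array(0, c(8, 8, 8)); a[3:4, 3:4, 3:4] <- 1
  b <- array(0, c(8, 8, 8)); b[3:4, 3:4, 4:5] <- 1
  expect_equal(dice(a, b), 0.5)  # 2*4 / (8 + 8)
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, array(0, c(8, 8, 8)) + (a == 0)), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_identical(dice(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), 1)
  expect_error(dice(a, array(0, c(4, 4, 4))), "share one grid")
  # nested boxes: eroding one mask away decreases dice monotonically
  full <- array(0, c(16, 16, 16)); full[3:14, 3:14, 3:14] <- 1
  d <- vapply(0:4, function(k) {
    inner <- array(0, c(16, 16, 16))
    inner[(3 + k):(14 - k), (3 + k):(14 - k), (3 + k):(14 - k)] <- 1
    dice(full, inner)
  }, 0)
  expect_true(all(diff(d) < 0))
})

test_that("hd95 matches point distances and a brute-force all-pairs oracle
           on nested cubes", {
  s1 <- array(0, c(12, 12, 12)); s1[6, 6, 6] <- 1
  s2 <- array(0, c(12, 12, 12)); s2[11, 6, 6] <- 1
  expect_equal(hd95(s1, s2, spacing = 1), 5)
  expect_equal(hd95(s1, s1, spacing = 1), 0)
  expect_equal(hd95(s1, s2, spacing = 1), hd95(s2, s1, spacing = 1))
  # anisotropic spacing
  expect_equal(hd95(s1, s2, spacing = c(2, 1, 1)), 10)
  # nested cubes, gap 2 voxels at 1 mm: against a brute-force oracle
  outer <- array(0, c(14, 14, 14)); outer[3:12, 3:12, 3:12] <- 1
  inner <- array(0, c(14, 14, 14)); inner[5:10, 5:10, 5:10] <- 1
  got <- hd95(outer, inner, spacing = 1)
  brute_boundary <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    keep <- apply(idx, 1, function(v) {
      any(vapply(1:3, function(ax) {
        vv <- v; n <- dim(m)[ax]
        up <- v[ax] + 1; dn <- v[ax] - 1
        up > n || dn < 1 ||
          { vu <- v; vu[ax] <- up; m[vu[1], vu[2], vu[3]] == 0 } ||
          { vd <- v; vd[ax] <- dn; m[vd[1], vd[2], vd[3]] == 0 }
      }, NA))
    })
    idx[keep, , drop = FALSE] - 1
  }
  pa <- brute_boundary(outer); pb <- brute_boundary(inner)
  dmat <- as.matrix(dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                         nrow(pa) + seq_len(nrow(pb))]
  ref <- max(quantile(apply(dmat, 1, min), 0.95),
             quantile(apply(dmat, 2, min), 0.95))
  expect_equal(got, unname(ref))
  expect_error(hd95(s1, array(0, c(12, 12, 12)), spacing = 1), "nonempty")
})

test_that("reliability analysis reproduces the Gaussian percentile model,
           the category thresholds, and the cube-agreement predicate", {
  reg <- landmark_registry()
  ids <- reg$id
  mk <- function(coords) landmark_set(coords)
  base <- matrix(rnorm(33, sd = 10), 11, 3, dimnames = list(ids, NULL))
  # identical sessions: all distances zero, 100% agreement, Excellent
  first <- replicate(5, mk(base), simplify = FALSE)
  rep0 <- reliability_analysis(first, first, voxel_mm = 0.8)
  expect_true(all(rep0$mean_mm == 0))
  expect_true(all(rep0$agreement_probability == 100))
  expect_true(all(rep0$category == "Excellent"))
  expect_true(all(rep0$missing_ratio == 0))
  expect_true(all(rep0$P75 <= rep0$P80 & rep0$P80 <= rep0$P95))
  # synthetic distances with known mean/sd: P95 = mean + 1.6449 * sd
  set.seed(41)
  n <- 400
  firstn <- replicate(n, mk(base), simplify = FALSE)
  dists <- abs(rnorm(n, mean = 1.0, sd = 0.3))  # keep distances positive
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  secondn <- lapply(seq_len(n), function(i) {
    m <- base
    m["PTP", ] <- m["PTP", ] + dists[i] * dirs[i, ]
    mk(m)
  })
  repn <- reliability_analysis(firstn, secondn, voxel_mm = 0.8)
  row <- repn[repn$id == "PTP", ]
  expect_equal(row$P95, row$mean_mm + qnorm(0.95) * row$sd_mm)
  expect_equal(qnorm(0.95), 1.6449, tolerance = 1e-4)
  expect_equal(row$P95, mean(dists) + 1.6449 * sd(dists), tolerance = 1e-3)
  expect_equal(row$mean_mm, mean(dists), tolerance = 1e-9)
  # category boundaries are inclusive at 95 / 80 / 75
  expect_identical(reliability_category(c(95, 94.9, 80, 79, 75, 74)),
                   c("Excellent", "Good", "Good", "Satisfactory",
                     "Satisfactory", "Poor"))
  # missing in either session counts towards the missing ratio
  second_miss <- secondn
  m <- unclass(second_miss[[1]]); m["LFOM", ] <- NA
  second_miss[[1]] <- mk(m)
  repm <- reliability_analysis(firstn, second_miss, voxel_mm = 0.8)
  expect_equal(repm$missing_ratio[repm$id == "LFOM"], 100 / n)
  # fewer than 2 doubly-present pairs: flagged, no category
  one <- reliability_analysis(first[1], first[1], voxel_mm = 0.8)
  expect_true(all(is.na(one$category)))
})

test_that("the empirical cube-agreement rate matches the analytic
           product-of-axes probability for Gaussian jitter", {
  reg <- landmark_registry()
  base <- matrix(0, 11, 3, dimnames = list(reg$id, NULL))
  vox <- 0.8; jit <- 0.6
  n <- 10000
  set.seed(77)
  first <- replicate(n, landmark_set(base), simplify = FALSE)
  noise <- matrix(rnorm(3 * n, sd = jit), n, 3)
  second <- lapply(seq_len(n), function(i) {
    m <- base; m["RALV", ] <- noise[i, ]; landmark_set(m)
  })
  rep <- reliability_analysis(first, second, voxel_mm = vox)
  emp <- rep$cube_agreement_rate[rep$id == "RALV"] / 100
  analytic <- (pnorm(vox / jit) - pnorm(-vox / jit))^3
  expect_lt(abs(emp - analytic), 0.02)
})

test_that("atlas-based segmentation picks the right time point and merges
           the corpus callosum into white matter", {
  atl <- fix_atlas()
  # tie / nearest selection on metadata only
  fake <- function(ga, op) atlas_timepoint(
    ga, op, atl$image, atl$mask, atl$probmaps, atl$parcellation,
    atl$consensus_landmarks)
  tps <- list(fake(7L * 24L, FALSE), fake(7L * 26L, FALSE),
              fake(7L * 26L, TRUE))
  subj <- brain_sample(list(subject_id = "x", session_id = "y",
                            ga = ga_from_weeks_days(24, 2),
                            operated = FALSE),
                       atl$image, atl$mask, atl$consensus_landmarks)
  res <- segment_with_atlas(subj, tps, pipeline_config())
  expect_identical(res$timepoint$target_ga, 7L * 24L)
  expect_false(res$timepoint$operated)
  # no corpus-callosum label survives the merge
  cc <- match("corpus_callosum", tissue_classes())
  expect_false(cc %in% unique(as.vector(res$parcellation$data)))
  expect_error(segment_with_atlas(
    brain_sample(list(subject_id = "x", session_id = "y",
                      ga = 168L, operated = TRUE),
                 atl$image, atl$mask, atl$consensus_landmarks),
    list(fake(168L, FALSE)), pipeline_config()),
    "operation status")
})
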
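#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two binary masks on one grid;
#' by convention two empty masks have Dice 1.
#'
#' @param a,b Binary masks: [image_volume()]s or logical/numeric arrays of
#'   one shape.
#' @return Dice fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- mask_array(a); b <- mask_array(b)
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

mask_array <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  x > 0.5
}

#' 95th-percentile Hausdorff distance
#'
#' The maximum of the two directed 95th-percentile distances between the
#' boundary voxels of two masks, in mm.  Boundary voxels are mask voxels
#' with at least one 6-neighbour outside the mask (or on the grid edge).
#'
#' @param a,b Nonempty binary masks (arrays or [image_volume()]s).
#' @param spacing Voxel size in mm (scalar or length 3); taken from `a`
#'   when it is an `image_volume`.
#' @param percentile Distance percentile (default 0.95).
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, spacing = NULL, percentile = 0.95) {
  if (is.null(spacing))
    spacing <- if (inherits(a, "image_volume")) a$spacing else c(1, 1, 1)
  spacing <- rep_len(as.numeric(spacing), 3L)
  pa <- boundary_points(mask_array(a), spacing)
  pb <- boundary_points(mask_array(b), spacing)
  if (!nrow(pa) || !nrow(pb)) stop("hd95 needs two nonempty masks")
  max(directed_percentile_dist(pa, pb, percentile),
      directed_percentile_dist(pb, pa, percentile))
}

boundary_points <- function(m, spacing) {
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    interior <- interior & shift3_logical(m, ax, 1L) &
      shift3_logical(m, ax, -1L)
  }
  idx <- which(m & !interior, arr.ind = TRUE) - 1
  sweep(idx, 2L, spacing, "*")
}

shift3_logical <- function(m, axis, by) {
  out <- array(FALSE, dim(m))
  s <- shift3(m * 1, axis, by)
  out[s > 0.5] <- TRUE
  out
}

# Directed q-percentile of min distances from points `from` to set `to`,
# brute force in chunks (boundary sets are small).
directed_percentile_dist <- function(from, to, q) {
  n <- nrow(from)
  mins <- numeric(n)
  chunk <- max(1L, floor(2e7 / nrow(to)))
  to2 <- rowSums(to^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    blk <- from[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), to2, "+") - 2 * blk %*% t(to)
    mins[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  stats::quantile(mins, q, names = FALSE, type = 7)
}

#' Atlas-based segmentation of a subject
#'
#' Selects the atlas time point with matching operation status and nearest
#' target gestational age (ties resolve to the younger time point),
#' registers the subject to it with [register_ffd()] — without the landmark
#' term, as anatomical landmarks are not assumed available at segmentation
#' time — and propagates the atlas parcellation back onto the subject grid
#' with nearest-neighbour interpolation.  The corpus-callosum label is
#' merged into white matter, giving 7 evaluated tissue classes plus the
#' whole brain.  When reference labels are supplied, per-tissue and
#' whole-brain [dice()] and [hd95()] scores are returned.
#'
#' @param subject A [brain_sample()].
#' @param atlas List of [atlas_timepoint()]s (or a single one).
#' @param config A [pipeline_config()].
#' @param reference Optional reference label [image_volume()] (labels 0--8;
#'   its corpus callosum is merged the same way).
#' @return List with `parcellation` (label `image_volume` on the subject
#'   grid), `timepoint` (the chosen atlas time point) and, when `reference`
#'   is given, `scores` (data frame with tissue, dice, hd95_mm).
#' @export
segment_with_atlas <- function(subject, atlas, config = pipeline_config(),
                               reference = NULL) {
  if (inherits(atlas, "atlas_timepoint")) atlas <- list(atlas)
  if (!length(atlas)) stop("empty atlas")
  ok <- which(vapply(atlas, function(tp)
    tp$operated == isTRUE(subject$meta$operated), NA))
  if (!length(ok))
    stop("no atlas time point with matching operation status")
  dist <- vapply(atlas[ok], function(tp)
    abs(as.numeric(tp$target_ga) - as.numeric(subject$meta$ga)), 0)
  age <- vapply(atlas[ok], function(tp) as.numeric(tp$target_ga), 0)
  best <- ok[order(dist, age)[1L]]
  tp <- atlas[[best]]
  if (is.null(tp$parcellation)) stop("chosen atlas time point lacks a parcellation")

  tr <- register_ffd(subject, tp, config = config, use_landmarks = FALSE)
  parc <- apply_transform(tr, tp$parcellation, "nearest", subject$image)
  parc$data <- merge_cc(parc$data)
  out <- list(parcellation = parc, timepoint = tp)
  if (!is.null(reference)) {
    ref <- merge_cc(round(reference$data))
    cls <- setdiff(tissue_classes(), "corpus_callosum")
    rows <- lapply(seq_along(cls), function(v) {
      pa <- parc$data == v; pr <- ref == v
      data.frame(tissue = cls[v], dice = dice(pa, pr),
                 hd95_mm = if (any(pa) && any(pr))
                   hd95(pa, pr, spacing = subject$image$spacing)
                 else NA_real_)
    })
    brain <- data.frame(
      tissue = "brain", dice = dice(parc$data > 0, ref > 0),
      hd95_mm = hd95(parc$data > 0, ref > 0,
                     spacing = subject$image$spacing))
    out$scores <- rbind(brain, do.call(rbind, rows))
  }
  out
}

merge_cc <- function(lab) {
  cc <- match("corpus_callosum", tissue_classes())
  wm <- match("white_matter", tissue_classes())
  lab[lab == cc] <- wm
  lab
}

#' Intra-rater landmark reliability analysis
#'
#' Compares two annotation sessions of the same volumes.  Per landmark it
#' reports the missing ratio (percentage of volumes where the landmark is
#' absent in either session), the mean and sd of the Euclidean distances
#' between the paired placements, Gaussian-model distance percentiles
#' (P75/P80/P95 as `mean + z_q * sd`), the Gaussian probability that a
#' repeat placement falls within `agreement_radius_mm`, the empirical
#' cube-agreement rate (second placement inside the 3 x 3 x 3 voxel cube
#' centred on the first, i.e. within one voxel per axis), and the
#' reliability category: `Excellent` when the agreement probability is at
#' least 95%, `Good` at least 80%, `Satisfactory` at least 75%, else
#' `Poor`.  Landmarks with fewer than 2 doubly-present pairs are flagged
#' with an `NA` category.
#'
#' The Gaussian model is fitted to non-negative distances, as the published
#' protocol prescribes, so some of its mass can fall below zero; the
#' agreement radius is exposed as a parameter (default: the circumscribed
#' radius `sqrt(3) * voxel_mm` of the agreement cube).
#'
#' @param first,second Lists of [landmark_set()]s (same volumes, same
#'   order).
#' @param registry Landmark registry.
#' @param voxel_mm Voxel size in mm (for the cube predicate).
#' @param agreement_radius_mm Agreement radius of the Gaussian model.
#' @return A data frame of class `reliability_report`, one row per
#'   registry landmark.
#' @export
reliability_analysis <- function(first, second,
                                 registry = landmark_registry(),
                                 voxel_mm = 0.8,
                                 agreement_radius_mm = sqrt(3) * voxel_mm) {
  stopifnot(length(first) == length(second), length(first) >= 1L)
  nvol <- length(first)
  rows <- lapply(registry$id, function(id) {
    p1 <- t(vapply(first, function(l)
      if (id %in% rownames(l)) unclass(l)[id, ] else rep(NA_real_, 3L),
      numeric(3L)))
    p2 <- t(vapply(second, function(l)
      if (id %in% rownames(l)) unclass(l)[id, ] else rep(NA_real_, 3L),
      numeric(3L)))
    both <- stats::complete.cases(p1) & stats::complete.cases(p2)
    missing_ratio <- 100 * (1 - sum(both) / nvol)
    if (sum(both) < 2L)
      return(data.frame(id = id, n_pairs = sum(both),
                        missing_ratio = missing_ratio, mean_mm = NA_real_,
                        sd_mm = NA_real_, P75 = NA_real_, P80 = NA_real_,
                        P95 = NA_real_, agreement_probability = NA_real_,
                        cube_agreement_rate = NA_real_,
                        category = NA_character_))
    delta <- p1[both, , drop = FALSE] - p2[both, , drop = FALSE]
    dist <- sqrt(rowSums(delta^2))
    mu <- mean(dist); sdv <- stats::sd(dist)
    pq <- function(q) mu + stats::qnorm(q) * sdv
    agree_p <- if (sdv > 0) 100 * stats::pnorm(agreement_radius_mm, mu, sdv)
      else 100 * (mu <= agreement_radius_mm)
    cube <- 100 * mean(apply(abs(delta) <= voxel_mm, 1L, all))
    data.frame(id = id, n_pairs = sum(both),
               missing_ratio = missing_ratio, mean_mm = mu, sd_mm = sdv,
               P75 = pq(0.75), P80 = pq(0.80), P95 = pq(0.95),
               agreement_probability = agree_p,
               cube_agreement_rate = cube,
               category = reliability_category(agree_p))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' @param agreement_probability Agreement probability in percent.
#' @rdname reliability_analysis
#' @export
reliability_category <- function(agreement_probability) {
  ifelse(agreement_probability >= 95, "Excellent",
         ifelse(agreement_probability >= 80, "Good",
                ifelse(agreement_probability >= 75, "Satisfactory",
                       "Poor")))
}

#' @param report A `reliability_report`.
#' @param path TSV output path.
#' @rdname reliability_analysis
#' @export
write_reliability_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
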
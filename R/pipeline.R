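#' Atlas time points
#'
#' One volume of the spatio-temporal atlas: the average image, brain mask,
#' tissue probability maps and parcellation for one (gestational week,
#' operation status) group, together with the consensus landmarks of the
#' Procrustes alignment and provenance (member ids, weights, traces).  The
#' average image is exactly symmetric about the grid's central sagittal
#' plane and the consensus landmarks are symmetric across mirror pairs.
#'
#' @param target_ga Target gestational age in days (whole week).
#' @param operated Operation status of the group.
#' @param image,mask [image_volume()]s.
#' @param probmaps A [probmaps()] or `NULL`.
#' @param parcellation Integer label [image_volume()] or `NULL`.
#' @param consensus_landmarks A [landmark_set()].
#' @param provenance List of bookkeeping fields.
#' @return Object of class `atlas_timepoint`.
#' @export
atlas_timepoint <- function(target_ga, operated, image, mask, probmaps,
                            parcellation, consensus_landmarks,
                            provenance = list()) {
  structure(list(target_ga = validate_ga_days(target_ga),
                 operated = isTRUE(operated), image = image, mask = mask,
                 probmaps = probmaps, parcellation = parcellation,
                 consensus_landmarks = consensus_landmarks,
                 provenance = provenance),
            class = "atlas_timepoint")
}

#' @param x An `atlas_timepoint`.
#' @param ... Ignored.
#' @rdname atlas_timepoint
#' @export
print.atlas_timepoint <- function(x, ...) {
  cat(sprintf("<atlas_timepoint> %s %s, %s voxels, %d members\n",
              format_ga(x$target_ga),
              if (x$operated) "operated" else "non-operated",
              paste(dim(x$image$data), collapse = "x"),
              length(x$provenance$member_ids %||% integer())))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize an atlas time point from landmarks alone
#'
#' The initialization stage: builds the landmark weight matrix (temporal
#' kernel weight x landmark missingness) over the retained landmarks, runs
#' the weighted generalized Procrustes alignment ([solve_wgp()]) — note
#' that image intensity is not used here — resamples every member onto the
#' consensus grid, normalizes intensities, and computes time-weighted
#' symmetric averages of the images, masks (thresholded at 0.5) and
#' probability maps.  The consensus grid is voxelized at the input spacing
#' over the transformed masks' bounding box (padded by
#' `config$atlas_pad_voxels`), centred along x on the consensus barycenter
#' so the mirror plane of the averaging operator coincides with the
#' consensus mid-sagittal plane.
#'
#' @param group An (augmented) `atlas_group` from [augment_group()].
#' @param config A [pipeline_config()].
#' @return An [atlas_timepoint()].
#' @export
initialize_atlas <- function(group, config = pipeline_config()) {
  stopifnot(inherits(group, "atlas_group"))
  reg <- landmark_registry()
  ids <- reg$id[reg$retained]
  n <- length(group$members)
  W <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    pres <- intersect(present_landmarks(group$members[[i]]$landmarks), ids)
    W[i, pres] <- group$weights[i]
  }
  if (any(colSums(W) <= 0))
    stop("landmark(s) never annotated in the group: ",
         paste(ids[colSums(W) <= 0], collapse = ", "))
  lmks <- lapply(group$members, `[[`, "landmarks")
  # identity-initialized alternation: preserves the per-axis structure of
  # the consensus (see ?solve_wgp, Details)
  wgp <- solve_wgp(lmks, W, tol = config$wgp_tol,
                   max_iter = config$wgp_max_iter, global_init = FALSE)

  spacing <- group$members[[1L]]$image$spacing
  ref <- consensus_grid(group, wgp, spacing, config$atlas_pad_voxels)
  warped <- lapply(seq_len(n), function(i) {
    s <- resample_to_consensus(group$members[[i]], wgp$transforms[[i]], ref)
    s$image <- normalize_intensity(s$image, s$mask)
    s
  })
  atlas_from_members(warped, group, ref, wgp$consensus,
                     provenance = list(
                       member_ids = member_ids(group),
                       weights = group$weights,
                       augmented = group$augmented,
                       wgp_objective = wgp$objective,
                       wgp_iterations = wgp$iterations,
                       wgp_trace = wgp$trace,
                       refinement_iterations = 0L))
}

member_ids <- function(group) {
  vapply(group$members, function(s)
    paste0(s$meta$subject_id, "/", s$meta$session_id), "")
}

consensus_grid <- function(group, wgp, spacing, pad_voxels) {
  # forward-transform each member's mask bounding box into consensus space
  corners <- do.call(rbind, lapply(seq_along(group$members), function(i) {
    bb <- mask_bbox(group$members[[i]]$mask)
    grid <- as.matrix(expand.grid(bb[, 1L], bb[, 2L], bb[, 3L]))
    apply_scaling(wgp$transforms[[i]], grid)
  }))
  lo <- apply(corners, 2L, min); hi <- apply(corners, 2L, max)
  pad <- pad_voxels * spacing
  cx <- mean(wgp$consensus[, 1L])
  hw_x <- max(abs(c(lo[1L], hi[1L]) - cx)) + pad[1L]
  # x: an even voxel count symmetric about the consensus barycenter, so the
  # mirror plane of the averaging operator is exactly the consensus
  # mid-sagittal plane; y/z: centres snapped to the first member's voxel
  # lattice so that identity transforms resample without interpolation
  n_x <- max(2L, 2L * as.integer(ceiling(hw_x / spacing[1L])))
  origin1 <- group$members[[1L]]$image$affine[1:3, 4L]
  mid <- (lo + hi) / 2
  ctr <- origin1 + spacing * round((mid - origin1) / spacing)
  ctr[1L] <- cx
  half_yz <- (hi - lo)[2:3] / 2 + pad[2:3]
  n_yz <- 2L * as.integer(ceiling(half_yz / spacing[2:3])) + 1L
  centered_volume(c(n_x, n_yz), spacing = spacing, center = ctr)
}

# Average warped, normalized members into an atlas_timepoint.
atlas_from_members <- function(warped, group, ref, consensus, provenance) {
  w <- group$weights
  img <- weighted_symmetric_average(lapply(warped, `[[`, "image"), w)
  mk <- weighted_symmetric_average(lapply(warped, `[[`, "mask"), w)
  mk$data <- (mk$data >= 0.5) * 1.0
  pm <- NULL; parc <- NULL
  if (all(vapply(warped, function(s) !is.null(s$probmaps), NA))) {
    pm <- weighted_symmetric_average_probmaps(
      lapply(warped, `[[`, "probmaps"), w)
    parc <- argmax_parcellation(pm)
  }
  g <- symmetrize_consensus(consensus, mid_sagittal_x(ref))
  atlas_timepoint(group$target_ga, group$operated, img, mk, pm, parc,
                  landmark_set(g), provenance)
}

# Enforce exact mirror symmetry of the consensus landmarks about plane_x
# (they are symmetric up to numerical error because augmented groups are
# mirror-invariant; this removes the residual).
symmetrize_consensus <- function(g, plane_x) {
  reg <- landmark_registry()
  out <- g
  for (i in seq_len(nrow(g))) {
    id <- rownames(g)[i]
    partner <- reg$partner[reg$id == id]
    if (!partner %in% rownames(g)) next
    mirrored <- g[partner, ]
    mirrored[1L] <- 2 * plane_x - mirrored[1L]
    out[i, ] <- (g[i, ] + mirrored) / 2
  }
  out
}

#' Refine an atlas time point by registration
#'
#' Improves the sharpness of an initialized atlas by non-linearly
#' registering every group member to the current atlas
#' ([register_ffd()] with the landmark term, using the landmarks shared
#' between the member and the consensus), resampling the members onto the
#' atlas grid, and recomputing the time-weighted symmetric averages; the
#' cycle is repeated `config$refinement_iterations` times.  The consensus
#' landmarks are kept fixed; post-warp landmark residuals are logged in the
#' provenance.  Registrations are performed with the atlas frame as the
#' fixed image so member intensities are pulled back onto the atlas grid
#' without inverting the transform.
#'
#' @param atlas An initialized [atlas_timepoint()].
#' @param group The `atlas_group` it was built from.
#' @param config A [pipeline_config()].
#' @return The refined [atlas_timepoint()].
#' @export
refine_atlas <- function(atlas, group, config = pipeline_config()) {
  stopifnot(inherits(atlas, "atlas_timepoint"))
  ids <- member_ids(group)
  lncc_trace <- c()
  for (it in seq_len(config$refinement_iterations)) {
    atlas_as_subject <- brain_sample(
      meta = list(subject_id = "atlas", session_id = sprintf("iter%d", it),
                  ga = atlas$target_ga, operated = atlas$operated),
      image = atlas$image, mask = atlas$mask,
      landmarks = atlas$consensus_landmarks)
    warped <- vector("list", length(group$members))
    for (i in seq_along(group$members)) {
      member <- group$members[[i]]
      tr <- tryCatch(
        register_ffd(atlas_as_subject,
                     list(image = member$image, mask = member$mask,
                          landmarks = member$landmarks),
                     config = config, use_landmarks = TRUE),
        error = function(e)
          stop("registration failed for member ", ids[i], ": ",
               conditionMessage(e)))
      img <- apply_transform(tr, member$image, "linear", atlas$image)
      mk <- apply_transform(tr, member$mask, "linear", atlas$image)
      mk$data <- (mk$data >= 0.5) * 1.0
      if (!any(mk$data > 0.5)) mk <- atlas$mask
      pm <- if (!is.null(member$probmaps))
        apply_transform(tr, member$probmaps, "linear", atlas$image)
      warped[[i]] <- brain_sample(member$meta,
                                  normalize_intensity(img, mk), mk,
                                  member$landmarks, pm)
    }
    prov <- atlas$provenance
    new_atlas <- atlas_from_members(warped, group, atlas$image,
                                    unclass(atlas$consensus_landmarks),
                                    provenance = prov)
    lncc_trace <- c(lncc_trace, mean(vapply(warped, function(s)
      lncc_similarity(s$image, new_atlas$image, new_atlas$mask,
                      config$lncc_kernel_sd_mm), 0)))
    atlas <- new_atlas
    atlas$provenance$refinement_iterations <- it
    atlas$provenance$mean_member_lncc <- lncc_trace
  }
  atlas
}

#' Build the full spatio-temporal atlas
#'
#' Orchestrates the pipeline: [build_groups()], flip augmentation,
#' landmark-only initialization ([initialize_atlas()]),
#' registration-based refinement ([refine_atlas()]) and the final
#' maximum-probability parcellation, independently per retained group.
#'
#' @param cohort A cohort (list with `samples`).
#' @param config A [pipeline_config()].
#' @param refine Set `FALSE` to stop after initialization (useful for quick
#'   previews).
#' @return List of [atlas_timepoint()]s.
#' @export
build_spatiotemporal_atlas <- function(cohort, config = pipeline_config(),
                                       refine = TRUE) {
  groups <- build_groups(cohort, config)
  if (!length(groups))
    stop("no retained group: no (week, status) candidate satisfied the ",
         "window, size and bracketing rules")
  out <- list()
  for (g in groups) {
    tp <- tryCatch({
      ag <- augment_group(g)
      atl <- initialize_atlas(ag, config)
      if (refine) atl <- refine_atlas(atl, ag, config)
      atl
    }, error = function(e) {
      warning(sprintf("group %s/%s failed: %s", format_ga(g$target_ga),
                      if (g$operated) "operated" else "non-operated",
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(tp)) out[[length(out) + 1L]] <- tp
  }
  if (!length(out)) stop("all retained groups failed")
  out
}

#' Write / read an atlas directory
#'
#' One folder per time point (e.g. `nonoperated_24wk/`) containing
#' `srr.nii.gz` (average image), `mask.nii.gz`, `parcellation.nii.gz`,
#' `lmks.nii.gz` (consensus landmarks as a label map) plus `lmks.tsv`,
#' `provenance.tsv` and a top-level `index.tsv`.
#'
#' @param timepoints List of [atlas_timepoint()]s.
#' @param dir Output directory.
#' @export
write_atlas <- function(timepoints, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- list()
  for (tp in timepoints) {
    nm <- sprintf("%s_%02dwk",
                  if (tp$operated) "operated" else "nonoperated",
                  tp$target_ga %/% 7L)
    d <- file.path(dir, nm)
    dir.create(d, showWarnings = FALSE)
    write_volume(tp$image, file.path(d, "srr.nii.gz"))
    write_volume(tp$mask, file.path(d, "mask.nii.gz"))
    if (!is.null(tp$parcellation))
      write_volume(tp$parcellation, file.path(d, "parcellation.nii.gz"))
    write_landmarks(tp$consensus_landmarks, file.path(d, "lmks.nii.gz"),
                    dialect = "labelmap", reference = tp$image)
    write_landmarks(tp$consensus_landmarks, file.path(d, "lmks.tsv"))
    prov <- data.frame(member = tp$provenance$member_ids,
                       weight = tp$provenance$weights,
                       augmented = tp$provenance$augmented)
    utils::write.table(prov, file.path(d, "provenance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    idx[[length(idx) + 1L]] <- data.frame(
      folder = nm, ga_weeks = tp$target_ga %/% 7L, operated = tp$operated)
  }
  utils::write.table(do.call(rbind, idx), file.path(dir, "index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  idx <- utils::read.delim(file.path(dir, "index.tsv"),
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    d <- file.path(dir, idx$folder[i])
    parc_path <- file.path(d, "parcellation.nii.gz")
    parc <- if (file.exists(parc_path)) read_volume(parc_path)
    atlas_timepoint(
      target_ga = 7L * idx$ga_weeks[i], operated = idx$operated[i],
      image = read_volume(file.path(d, "srr.nii.gz")),
      mask = read_volume(file.path(d, "mask.nii.gz")),
      probmaps = if (!is.null(parc)) probmaps_from_labels(parc),
      parcellation = parc,
      consensus_landmarks = read_landmarks(file.path(d, "lmks.tsv")))
  })
}
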
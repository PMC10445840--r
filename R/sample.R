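#' Tissue classes of the parcellation
#'
#' The fetal brain is divided into eight tissue types: white matter
#' (excluding the corpus callosum), the ventricular system, the cerebellum,
#' extra-axial cerebrospinal fluid, cortical grey matter, deep grey matter,
#' the brainstem, and the corpus callosum.  Parcellation label maps use
#' integer labels 1--8 in this order (0 = background); probability-map
#' stacks carry an additional background class.
#'
#' @return Character vector of the 8 tissue class names (label order).
#' @export
tissue_classes <- function() {
  c("white_matter", "ventricles", "cerebellum", "extra_axial_csf",
    "cortical_gm", "deep_gm", "brainstem", "corpus_callosum")
}

prob_classes <- function() c("background", tissue_classes())

#' Tissue probability maps
#'
#' A `probmaps` object is a named list of [image_volume()]s, one per class
#' in `prob_classes()` (background + the 8 tissues), sharing a single grid
#' and summing to 1 at every voxel.
#'
#' @param maps Named list of `image_volume`s (or 3D arrays with `affine`).
#' @param affine Affine for array input.
#' @return Object of class `probmaps`.
#' @export
probmaps <- function(maps, affine = NULL) {
  if (!all(prob_classes() %in% names(maps)))
    stop("probability maps must cover classes: ",
         paste(prob_classes(), collapse = ", "))
  maps <- maps[prob_classes()]
  maps <- lapply(maps, function(m) {
    if (is.array(m) && !inherits(m, "image_volume")) {
      if (is.null(affine)) stop("array probmaps need an affine")
      image_volume(m, affine)
    } else m
  })
  structure(maps, class = "probmaps")
}

#' @param labels An integer label [image_volume()] (values 0--8).
#' @rdname probmaps
#' @export
probmaps_from_labels <- function(labels) {
  cls <- prob_classes()
  maps <- lapply(seq_along(cls) - 1L, function(v)
    image_volume((round(labels$data) == v) * 1.0, labels$affine))
  names(maps) <- cls
  probmaps(maps)
}

flip_probmaps <- function(pm) {
  probmaps(lapply(pm, flip_image))
}

#' A single subject/session sample
#'
#' Bundles one reconstructed 3D MRI with its brain mask, landmark set,
#' optional tissue probability maps and session metadata.  All raster
#' members must share one grid.
#'
#' @param meta List with `subject_id`, `session_id`, `ga` (days),
#'   `operated` (logical).
#' @param image,mask [image_volume()]s on a common grid (mask binary).
#' @param landmarks A [landmark_set()].
#' @param probmaps Optional [probmaps()].
#' @return Object of class `brain_sample`.
#' @export
brain_sample <- function(meta, image, mask, landmarks, probmaps = NULL) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "image_volume"))
  if (!identical(dim(image$data), dim(mask$data)) ||
      max(abs(image$affine - mask$affine)) > 1e-6)
    stop("image and mask must share one grid")
  if (!is.null(probmaps)) {
    stopifnot(inherits(probmaps, "probmaps"))
    if (!identical(dim(probmaps[[1L]]$data), dim(image$data)))
      stop("probability maps must share the image grid")
  }
  meta$ga <- validate_ga_days(meta$ga)
  structure(list(meta = meta, image = image, mask = mask,
                 landmarks = landmarks, probmaps = probmaps),
            class = "brain_sample")
}

#' @param x A `brain_sample`.
#' @param ... Ignored.
#' @rdname brain_sample
#' @export
print.brain_sample <- function(x, ...) {
  cat(sprintf("<brain_sample> %s/%s, GA %s, %s, %s voxels\n",
              x$meta$subject_id, x$meta$session_id, format_ga(x$meta$ga),
              if (isTRUE(x$meta$operated)) "operated" else "non-operated",
              paste(dim(x$image$data), collapse = "x")))
  invisible(x)
}

#' Mirror a whole sample about its grid's central sagittal plane
#'
#' Applies [flip_image()] to the image, mask and every probability map and
#' [flip_landmarks()] about the grid mid-plane, keeping the two consistent:
#' a landmark sitting on an image feature stays on that feature.
#'
#' @param sample A [brain_sample()].
#' @return The mirrored `brain_sample`.
#' @export
flip_sample <- function(sample) {
  plane_x <- mid_sagittal_x(sample$image)
  brain_sample(
    meta = sample$meta,
    image = flip_image(sample$image),
    mask = flip_image(sample$mask),
    landmarks = flip_landmarks(sample$landmarks, plane_x = plane_x),
    probmaps = if (!is.null(sample$probmaps)) flip_probmaps(sample$probmaps))
}
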
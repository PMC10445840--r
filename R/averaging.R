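#' Linear intensity normalization
#'
#' Linearly rescales image intensities (`a * I + b`) so that the mean and
#' standard deviation inside the brain mask become exactly `target_mean`
#' and `target_sd` (2000 and 500 by default, chosen to match the intensity
#' profile of the normal fetal-brain atlas the method builds on).  Voxels
#' outside the mask get the same linear map.  Applying the normalization to
#' an already-normalized volume is the identity.
#'
#' @param image An [image_volume()].
#' @param mask A binary [image_volume()] on the same grid (nonempty).
#' @param target_mean,target_sd Target in-mask moments.
#' @return The normalized `image_volume`.
#' @export
normalize_intensity <- function(image, mask, target_mean = 2000,
                                target_sd = 500) {
  inm <- mask$data > 0.5
  if (!any(inm)) stop("empty brain mask")
  v <- image$data[inm]
  m <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0)
    stop("constant image intensity inside the mask")
  a <- target_sd / s
  b <- target_mean - a * m
  image_volume(a * image$data + b, image$affine)
}

#' Time-weighted, left-right-symmetric averaging
#'
#' Averages co-registered volumes as
#' \deqn{I_{avg} = \frac{1}{2N} \sum_{i=1}^N \tilde w_i (I_i + S(I_i))}
#' where `S` mirrors a volume about the grid's central sagittal plane
#' ([flip_image()]) and the weights are the temporal kernel weights,
#' renormalized to sum to `N` so the operator is a convex combination of
#' symmetrized volumes (otherwise the mean intensity would drift with group
#' size).  The result is exactly `S`-symmetric and invariant to uniform
#' weight rescaling.
#'
#' @param images List of N [image_volume()]s on one grid.
#' @param weights N non-negative temporal weights, not all zero.
#' @return The averaged `image_volume`.
#' @export
weighted_symmetric_average <- function(images, weights) {
  n <- length(images)
  stopifnot(n >= 1L, length(weights) == n)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  d <- dim(images[[1L]]$data)
  for (im in images)
    if (!identical(dim(im$data), d) ||
        max(abs(im$affine - images[[1L]]$affine)) > 1e-6)
      stop("images must share one grid")
  w <- weights * n / sum(weights)
  acc <- array(0, d)
  for (i in seq_len(n)) {
    im <- images[[i]]
    acc <- acc + w[i] * (im$data + flip_image(im)$data)
  }
  image_volume(acc / (2 * n), images[[1L]]$affine)
}

#' @param maps List of N [probmaps()] (each class-normalized).
#' @rdname weighted_symmetric_average
#' @export
weighted_symmetric_average_probmaps <- function(maps, weights) {
  stopifnot(length(maps) >= 1L)
  tolsum <- vapply(maps, function(pm) {
    s <- Reduce(`+`, lapply(pm, function(v) v$data))
    max(abs(s - 1))
  }, 0)
  if (any(tolsum > 1e-6))
    stop("input probability maps are not normalized (class sums != 1)")
  cls <- prob_classes()
  out <- lapply(cls, function(nm)
    weighted_symmetric_average(lapply(maps, `[[`, nm), weights))
  names(out) <- cls
  probmaps(out)
}

#' Maximum-probability parcellation
#'
#' Assigns each voxel the tissue class of maximal averaged probability
#' (label 0 where the background class wins).  Ties resolve to the lowest
#' class index, deterministically.
#'
#' @param pm A [probmaps()].
#' @return An integer label [image_volume()] (labels 0--8, see
#'   [tissue_classes()]).
#' @export
argmax_parcellation <- function(pm) {
  cls <- prob_classes()
  d <- dim(pm[[1L]]$data)
  best <- pm[[1L]]$data
  lab <- array(0L, d)
  for (v in seq_along(cls)[-1L]) {
    cur <- pm[[cls[v]]]$data
    hit <- cur > best
    lab[hit] <- v - 1L
    best[hit] <- cur[hit]
  }
  image_volume(lab, pm[[1L]]$affine)
}
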
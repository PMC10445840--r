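#' The anatomical landmark registry
#'
#' The annotation protocol defines 11 named anatomical landmarks for fetal
#' brains with spina bifida aperta: the anterior horns of the right and left
#' lateral ventricles, the posterior tectum plate, the right and left
#' cerebellar-brainstem junctions, the right and left deep grey matter
#' borders at the foramen of Monro, and the right and left deep grey matter
#' borders at the anterior and posterior cavum septi pellucidi (CSP) lines.
#' The four CSP landmarks proved too unreliable for atlas construction and
#' are kept in the registry with `retained = FALSE` so that reliability
#' analyses can still refer to them; the seven retained landmarks drive the
#' Procrustes initialization and the registration landmark term.
#'
#' Label-map landmark files encode landmark `id` at row `i` of the registry
#' as integer label `i` (retained landmarks are labels 1--7, the CSP
#' landmarks 8--11).
#'
#' @return A data frame with one row per landmark and columns `id` (short
#'   code), `name` (long name), `laterality` (`"left"`, `"right"` or
#'   `"midline"`), `partner` (the id of the mirror landmark; midline
#'   landmarks are their own partner), `retained` (logical) and `label`
#'   (integer label-map value).
#' @examples
#' reg <- landmark_registry()
#' nrow(reg)           # 11
#' sum(reg$retained)   # 7
#' @export
landmark_registry <- function() {
  reg <- data.frame(
    id = c("RALV", "LALV", "PTP", "LCB", "RCB", "LFOM", "RFOM",
           "LACSP", "RACSP", "LPCSP", "RPCSP"),
    name = c(
      "anterior horn of the right lateral ventricle",
      "anterior horn of the left lateral ventricle",
      "posterior tectum plate",
      "left cerebellar-brainstem junction",
      "right cerebellar-brainstem junction",
      "left deep grey matter border at foramen of Monro",
      "right deep grey matter border at foramen of Monro",
      "left deep grey matter border at anterior CSP line",
      "right deep grey matter border at anterior CSP line",
      "left deep grey matter border at posterior CSP line",
      "right deep grey matter border at posterior CSP line"),
    laterality = c("right", "left", "midline", "left", "right", "left",
                   "right", "left", "right", "left", "right"),
    partner = c("LALV", "RALV", "PTP", "RCB", "LCB", "RFOM", "LFOM",
                "RACSP", "LACSP", "RPCSP", "LPCSP"),
    retained = c(rep(TRUE, 7L), rep(FALSE, 4L)),
    stringsAsFactors = FALSE
  )
  reg$label <- seq_len(nrow(reg))
  reg
}

#' @param path File to write the registry to (tab-separated).
#' @rdname landmark_registry
#' @export
write_landmark_registry <- function(path) {
  utils::write.table(landmark_registry(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Landmark sets
#'
#' A landmark set stores the physical (mm) coordinates of named landmarks
#' for one volume, with explicit missingness: a landmark that the rater
#' could not identify is present in the set but has `NA` coordinates.
#'
#' @param coords Numeric matrix with 3 columns (x, y, z in mm) and row names
#'   giving landmark ids, or a named list of length-3 vectors.  `NA` rows
#'   mark missing landmarks.
#' @param registry Landmark registry data frame (default
#'   [landmark_registry()]); ids must be a subset of the registry ids.
#' @return An object of class `landmark_set`: a K x 3 matrix with row names.
#' @export
landmark_set <- function(coords, registry = landmark_registry()) {
  if (is.list(coords) && !is.matrix(coords)) {
    ids <- names(coords)
    coords <- do.call(rbind, lapply(coords, function(p) {
      if (is.null(p)) rep(NA_real_, 3L) else as.numeric(p)
    }))
    rownames(coords) <- ids
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("landmark coordinates must have 3 columns")
  if (is.null(rownames(coords))) {
    if (nrow(coords) > 0L) stop("landmark coordinates must be named")
    rownames(coords) <- character(0)
  }
  bad <- setdiff(rownames(coords), registry$id)
  if (length(bad))
    stop("unknown landmark id(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(rownames(coords)))
    stop("duplicate landmark ids")
  # a partially specified point is not meaningful
  partial <- apply(coords, 1L, function(r) any(is.na(r)) && !all(is.na(r)))
  if (any(partial)) stop("landmarks must be fully specified or fully NA")
  colnames(coords) <- c("x", "y", "z")
  structure(coords, class = c("landmark_set", "matrix", "array"))
}

#' @param x,lmks A `landmark_set`.
#' @rdname landmark_set
#' @export
present_landmarks <- function(lmks) {
  rownames(lmks)[stats::complete.cases(unclass(lmks))]
}

#' @rdname landmark_set
#' @export
is_missing_landmark <- function(lmks, x) {
  !(x %in% present_landmarks(lmks))
}

#' @param ... Ignored.
#' @rdname landmark_set
#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks (%d present)\n",
              nrow(x), length(present_landmarks(x))))
  print(unclass(x))
  invisible(x)
}

#' Mirror a landmark set across a sagittal plane
#'
#' Reflects every landmark about the plane `x = plane_x` and swaps
#' left/right landmark identities through the registry's mirror-partner
#' mapping (midline landmarks keep their id).  Missingness follows the
#' swapped id, so a missing left landmark becomes a missing right landmark.
#' The operation is an involution: applying it twice with the same plane
#' restores the original set.
#'
#' @param lmks A [landmark_set()].
#' @param registry Landmark registry.
#' @param plane_x Physical x coordinate (mm) of the mirror plane.
#' @return A `landmark_set` with reflected coordinates and swapped ids.
#' @export
flip_landmarks <- function(lmks, registry = landmark_registry(), plane_x = 0) {
  ids <- rownames(lmks)
  idx <- match(ids, registry$id)
  if (anyNA(idx)) stop("landmark id absent from registry")
  partner <- registry$partner[idx]
  if (!all(partner %in% ids))
    stop("mirror partner of some landmark not in the set: ",
         paste(setdiff(partner, ids), collapse = ", "))
  out <- unclass(lmks)
  out[, 1L] <- 2 * plane_x - out[, 1L]
  out <- out[match(ids, partner), , drop = FALSE]
  rownames(out) <- ids
  landmark_set(out, registry)
}
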
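#' 3D image volumes
#'
#' An `image_volume` couples a 3D numeric array with a 4x4 affine matrix
#' mapping *0-based* voxel indices to physical RAS coordinates in mm (the
#' NIfTI convention: first axis left-to-right, second posterior-to-anterior,
#' third inferior-to-superior).  All package-internal geometry (landmarks,
#' transforms, atlas grids) lives in this physical space.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index-to-mm matrix; must be invertible.
#' @return An object of class `image_volume` with elements `data`, `affine`
#'   and `spacing` (mm per voxel along each axis).
#' @export
image_volume <- function(data, affine) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "double"
  attributes(data) <- list(dim = dim(data))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  structure(list(data = data, affine = affine, spacing = spacing),
            class = "image_volume")
}

#' @param x,vol An `image_volume`.
#' @param ... Ignored.
#' @rdname image_volume
#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Construct a grid-centred volume
#'
#' Convenience constructor for a canonical grid whose physical origin is the
#' grid centre: `affine = diag(spacing)` with translation placing voxel
#' `(dim-1)/2` at 0 mm.  Phantoms and atlas grids use this layout so the
#' central sagittal plane is `x = 0`.
#'
#' @param data 3D array (or dim vector for an empty volume).
#' @param spacing Voxel size(s) in mm (scalar or length 3).
#' @param center Physical coordinates of the grid centre (default origin).
#' @rdname image_volume
#' @export
centered_volume <- function(data, spacing = 0.8, center = c(0, 0, 0)) {
  if (!is.array(data)) data <- array(0, dim = data)
  spacing <- rep_len(as.numeric(spacing), 3L)
  d <- dim(data)
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4L] <- center - spacing * (d - 1) / 2
  image_volume(data, aff)
}

#' Convert between voxel indices and world coordinates
#'
#' @param vol An [image_volume()].
#' @param pts n x 3 matrix of points: 0-based voxel indices for
#'   `voxel_to_world()`, physical mm for `world_to_voxel()`.
#' @return n x 3 matrix of converted points.
#' @export
voxel_to_world <- function(vol, pts) {
  pts <- rbind3(pts)
  sweep(pts %*% t(vol$affine[1:3, 1:3]), 2L, vol$affine[1:3, 4L], "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind3(pts)
  inv <- solve(vol$affine)
  sweep(pts, 2L, vol$affine[1:3, 4L], "-") %*% t(inv[1:3, 1:3])
}

rbind3 <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  storage.mode(pts) <- "double"
  pts
}

#' Physical coordinates of every voxel centre
#'
#' @param vol An [image_volume()].
#' @return n_voxel x 3 matrix in array (column-major) order.
#' @export
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1L]) - 1, d[2L] * d[3L]),
    rep.int(rep(seq_len(d[2L]) - 1, each = d[1L]), d[3L]),
    rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L])
  )
  voxel_to_world(vol, ijk)
}

#' Sample a volume at physical points
#'
#' Trilinear (`"linear"`) or nearest-neighbour (`"nearest"`) interpolation
#' of `vol` at arbitrary physical locations; points outside the grid get
#' `fill`.
#'
#' @param vol An [image_volume()].
#' @param pts n x 3 matrix of physical points (mm).
#' @param mode `"linear"` or `"nearest"`.
#' @param fill Value returned outside the volume.
#' @return Numeric vector of length `nrow(pts)`.
#' @export
sample_volume <- function(vol, pts, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  vox <- world_to_voxel(vol, pts)
  if (mode == "linear")
    sample_trilinear_cpp(vol$data, dim(vol$data), vox, fill)
  else
    sample_nearest_cpp(vol$data, dim(vol$data), vox, fill)
}

#' Mirror a volume about its central sagittal plane
#'
#' Returns the left-right mirror image: voxel data are reversed along the
#' first (left-right) axis while the grid is kept, so physical content is
#' reflected about the mid-plane of the grid along x.  The operator is an
#' involution.  The first voxel axis must be aligned with the physical x
#' axis (canonical RAS grids satisfy this).
#'
#' @param vol An [image_volume()].
#' @return The mirrored `image_volume` (same grid).
#' @export
flip_image <- function(vol) {
  dircos <- abs(vol$affine[1:3, 1L]) / vol$spacing[1L]
  if (dircos[1L] < 1 - 1e-6)
    stop("first voxel axis is not aligned with left-right; ",
         "reorient the volume to RAS first")
  d <- dim(vol$data)
  image_volume(vol$data[d[1L]:1L, , , drop = FALSE], vol$affine)
}

#' Physical x coordinate of a grid's central sagittal plane
#'
#' @param vol An [image_volume()].
#' @export
mid_sagittal_x <- function(vol) {
  d <- dim(vol$data)
  voxel_to_world(vol, matrix((d - 1) / 2, ncol = 3L))[1L, 1L]
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Dense separable convolution with a truncated (3 sd), boundary-renormalized
#' Gaussian kernel along each axis, so smoothing a constant array returns it
#' unchanged.  Used for local LNCC moments and pyramid construction.
#'
#' @param arr 3D array.
#' @param sd_vox Kernel standard deviation in voxels (scalar or length 3);
#'   components `<= 0` skip that axis.
#' @return Smoothed array of the same dimension.
#' @export
gauss_smooth3 <- function(arr, sd_vox) {
  sd_vox <- rep_len(sd_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sd_vox[ax] <= 0) next
    K <- gauss_matrix(d[ax], sd_vox[ax])
    if (ax == 1L) {
      arr <- array(K %*% matrix(arr, d[1L]), dim = d)
    } else if (ax == 2L) {
      a <- aperm(arr, c(2L, 1L, 3L))
      a <- array(K %*% matrix(a, d[2L]), dim = d[c(2L, 1L, 3L)])
      arr <- aperm(a, c(2L, 1L, 3L))
    } else {
      arr <- array(matrix(arr, d[1L] * d[2L]) %*% t(K), dim = d)
    }
  }
  arr
}

gauss_matrix <- function(n, sd) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    w <- exp(-0.5 * ((i - j) / sd)^2)
    w[abs(i - j) > 3 * sd] <- 0
    w
  })
  K / rowSums(K)
}
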
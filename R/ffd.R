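#' Cubic B-spline free-form deformation transforms
#'
#' An `ffd_transform` maps subject-space physical points to atlas-space
#' physical points as `phi(p) = A(p) + d(p)`, where `A` is an initial
#' anisotropic-scaling affine ([scaling_transform()]) and `d` is a
#' displacement field parameterized by cubic B-splines on a regular
#' control-point lattice (displacements in mm at each control point,
#' default spacing 3 mm).  With an identity affine and zero displacements
#' the transform is the identity map.
#'
#' @param origin Physical coordinates (mm) of control node (0, 0, 0).
#' @param spacing_mm Control-point spacing (scalar or length 3).
#' @param cdim Lattice dimensions (length 3, each >= 4).
#' @param theta ncp x 3 matrix of control-point displacements (mm),
#'   column-major over the lattice; defaults to zeros.
#' @param affine Initial [scaling_transform()] (default identity).
#' @return Object of class `ffd_transform`.
#' @export
ffd_transform <- function(origin, spacing_mm, cdim, theta = NULL,
                          affine = scaling_transform()) {
  cdim <- as.integer(cdim)
  stopifnot(length(origin) == 3L, length(cdim) == 3L, all(cdim >= 4L))
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  stopifnot(all(spacing_mm > 0))
  ncp <- prod(cdim)
  if (is.null(theta)) theta <- matrix(0, ncp, 3L)
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) == ncp, ncol(theta) == 3L)
  structure(list(origin = as.numeric(origin), spacing = spacing_mm,
                 cdim = cdim, theta = theta, affine = affine),
            class = "ffd_transform")
}

#' @param x An `ffd_transform`.
#' @param ... Ignored.
#' @rdname ffd_transform
#' @export
print.ffd_transform <- function(x, ...) {
  cat(sprintf(paste0("<ffd_transform> %s control lattice, spacing %s mm, ",
                     "max |displacement| %.3g mm\n"),
              paste(x$cdim, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              max(abs(x$theta))))
  invisible(x)
}

#' Build a lattice covering a physical bounding box
#'
#' @param bbox 2 x 3 matrix (min row, max row) in mm.
#' @param spacing_mm Control spacing.
#' @param affine Initial affine.
#' @rdname ffd_transform
#' @export
ffd_for_bbox <- function(bbox, spacing_mm, affine = scaling_transform()) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  extent <- bbox[2L, ] - bbox[1L, ]
  # cubic support needs one node before and two after the covered span
  cdim <- pmax(4L, as.integer(ceiling(extent / spacing_mm)) + 6L)
  origin <- bbox[1L, ] - 2 * spacing_mm
  ffd_transform(origin, spacing_mm, cdim, affine = affine)
}

# Cubic B-spline basis values for fractional offsets t in [0, 1).
bspline_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (4 - 6 * t2 + 3 * t3) / 6,
        (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
        t3 / 6)
}

# Per-axis support (0-based base node index and 4 weights) of points on a
# lattice; points are clamped into the covered span.
ffd_support <- function(ffd, pts) {
  base <- matrix(0L, nrow(pts), 3L)
  W <- vector("list", 3L)
  for (d in 1:3) {
    u <- (pts[, d] - ffd$origin[d]) / ffd$spacing[d]
    u <- pmin(pmax(u, 1 + 1e-9), ffd$cdim[d] - 3 - 1e-9)
    i <- floor(u)
    base[, d] <- as.integer(i) - 1L
    W[[d]] <- bspline_weights(u - i)
  }
  list(base = base, wx = W[[1L]], wy = W[[2L]], wz = W[[3L]])
}

# Displacement at points (n x 3 mm), optionally with precomputed support.
ffd_displacement <- function(ffd, pts, support = NULL) {
  if (is.null(support)) support <- ffd_support(ffd, rbind3(pts))
  ffd_eval_cpp(ffd$theta, ffd$cdim, support$base,
               support$wx, support$wy, support$wz)
}

#' Map points through an FFD transform
#'
#' @param ffd An [ffd_transform()].
#' @param pts n x 3 matrix of subject-space physical points (mm).
#' @return n x 3 matrix of atlas-space points.
#' @export
ffd_map_points <- function(ffd, pts) {
  pts <- rbind3(pts)
  apply_scaling(ffd$affine, pts) + ffd_displacement(ffd, pts)
}

# --- lattice differential operators (zero-padded shifts) ------------------

shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  else if (axis == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

d_central <- function(a, axis, h) (shift3(a, axis, -1) - shift3(a, axis, 1)) / (2 * h)
d_second <- function(a, axis, h) (shift3(a, axis, -1) - 2 * a + shift3(a, axis, 1)) / h^2

lattice_interior_mask <- function(cdim) {
  m <- array(0, cdim)
  m[2:(cdim[1L] - 1L), 2:(cdim[2L] - 1L), 2:(cdim[3L] - 1L)] <- 1
  m
}

#' Bending and linear regularization energies
#'
#' Evaluated on the control-point lattice of the displacement field:
#' *bending energy* is the mean (over interior lattice nodes) squared
#' second spatial derivative of the displacement
#' (\eqn{u_{xx}^2 + u_{yy}^2 + u_{zz}^2 + 2u_{xy}^2 + 2u_{xz}^2 +
#' 2u_{yz}^2}, summed over the three displacement components); *linear
#' energy* is the mean squared Frobenius norm of the symmetric part of the
#' displacement Jacobian.  Both vanish for the identity and for any uniform
#' translation; the linear energy also vanishes for rigid (skew-symmetric
#' Jacobian) infinitesimal displacements while penalizing stretches.
#'
#' @param ffd An [ffd_transform()].
#' @return Named numeric vector `c(bending = ..., linear = ...)`.
#' @export
regularization_energy <- function(ffd) {
  eg <- reg_energy_grad(ffd$theta, ffd$cdim, ffd$spacing, want_grad = FALSE)
  c(bending = eg$bending, linear = eg$linear)
}

reg_energy_grad <- function(theta, cdim, spacing, want_grad = TRUE) {
  m <- lattice_interior_mask(cdim)
  nint <- sum(m)
  be <- 0; le <- 0
  gbe <- if (want_grad) matrix(0, nrow(theta), 3L) else NULL
  gle <- if (want_grad) matrix(0, nrow(theta), 3L) else NULL
  U <- lapply(1:3, function(d) array(theta[, d], cdim))
  # bending: pure and mixed second derivatives per component
  for (d in 1:3) {
    u <- U[[d]]
    for (ax in 1:3) {
      s <- d_second(u, ax, spacing[ax])
      be <- be + sum(m * s^2) / nint
      if (want_grad)
        gbe[, d] <- gbe[, d] + as.vector(
          d_second(m * s, ax, spacing[ax])) * 2 / nint
    }
    combs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    for (cc in combs) {
      s <- d_central(d_central(u, cc[1L], spacing[cc[1L]]),
                     cc[2L], spacing[cc[2L]])
      be <- be + 2 * sum(m * s^2) / nint
      if (want_grad)
        gbe[, d] <- gbe[, d] + as.vector(
          d_central(d_central(m * s, cc[2L], spacing[cc[2L]]),
                    cc[1L], spacing[cc[1L]])) * 4 / nint
    }
  }
  # linear: symmetric part of the Jacobian
  J <- vector("list", 9L)
  for (a in 1:3) for (b in 1:3)
    J[[(a - 1L) * 3L + b]] <- d_central(U[[a]], b, spacing[b])
  for (a in 1:3) for (b in 1:3) {
    e_ab <- 0.5 * (J[[(a - 1L) * 3L + b]] + J[[(b - 1L) * 3L + a]])
    le <- le + sum(m * e_ab^2) / nint
  }
  if (want_grad) {
    for (cc in 1:3) for (b in 1:3) {
      e_cb <- 0.5 * (J[[(cc - 1L) * 3L + b]] + J[[(b - 1L) * 3L + cc]])
      # adjoint of the central difference under zero padding is -itself
      gle[, cc] <- gle[, cc] - as.vector(
        d_central(m * e_cb, b, spacing[b])) * 2 / nint
    }
  }
  list(bending = be, linear = le, grad_bending = gbe, grad_linear = gle)
}

# --- local normalized cross-correlation -----------------------------------

#' Local normalized cross-correlation similarity
#'
#' Mean, over in-mask voxels, of the squared local correlation coefficient
#' between two volumes, with local moments computed by Gaussian smoothing
#' (kernel sd in mm).  Values lie in \[0, 1\] for non-degenerate windows; a
#' variance floor of 1e-6 guards flat windows.  The measure is invariant to
#' positive affine intensity rescaling of either volume.
#'
#' @param fixed,warped [image_volume()]s on one grid.
#' @param mask Binary [image_volume()] on the same grid (nonempty).
#' @param kernel_sd_mm Gaussian window sd in mm (default 6).
#' @return Scalar similarity.
#' @export
lncc_similarity <- function(fixed, warped, mask, kernel_sd_mm = 6) {
  stopifnot(kernel_sd_mm > 0)
  if (!any(mask$data > 0.5)) stop("empty brain mask")
  sd_vox <- kernel_sd_mm / fixed$spacing
  mom_f <- lncc_fixed_moments(fixed$data, sd_vox)
  lncc_value(fixed$data, warped$data, mask$data > 0.5, sd_vox, mom_f)$value
}

lncc_fixed_moments <- function(f, sd_vox, eps = 1e-6) {
  mu_f <- gauss_smooth3(f, sd_vox)
  var_f <- pmax(gauss_smooth3(f * f, sd_vox) - mu_f^2, eps)
  list(mu_f = mu_f, var_f = var_f, eps = eps)
}

lncc_value <- function(f, w, inmask, sd_vox, mom, want_grad = FALSE) {
  mu_w <- gauss_smooth3(w, sd_vox)
  raw_var_w <- gauss_smooth3(w * w, sd_vox) - mu_w^2
  var_w <- pmax(raw_var_w, mom$eps)
  cov <- gauss_smooth3(f * w, sd_vox) - mom$mu_f * mu_w
  rho2 <- cov^2 / (mom$var_f * var_w)
  nm <- sum(inmask)
  out <- list(value = sum(rho2[inmask]) / nm)
  if (want_grad) {
    a <- array(0, dim(f)); b <- array(0, dim(f))
    a[inmask] <- 2 * cov[inmask] / (mom$var_f * var_w)[inmask]
    live <- inmask & (raw_var_w > mom$eps)
    b[live] <- -(cov^2 / (mom$var_f * var_w^2))[live]
    Ga <- gauss_smooth3(a, sd_vox)
    Gam <- gauss_smooth3(a * mom$mu_f, sd_vox)
    Gb <- gauss_smooth3(b, sd_vox)
    Gbm <- gauss_smooth3(b * mu_w, sd_vox)
    out$grad_w <- (f * Ga - Gam + 2 * (w * Gb - Gbm)) / nm
  }
  out
}
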
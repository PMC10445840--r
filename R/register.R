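#' Affine initialization for non-linear registration
#'
#' Estimates the initial anisotropic scaling + translation mapping subject
#' space to atlas space.  With `use_landmarks = TRUE` and at least 4 shared
#' present landmarks, a per-axis least-squares fit of atlas landmark
#' coordinates on subject landmark coordinates is used; otherwise the
#' transform is matched from brain-mask moments (centroids and per-axis
#' second moments).
#'
#' @param subject A [brain_sample()].
#' @param atlas An `atlas_timepoint` (or any list with `image`, `mask` and
#'   landmarks under `consensus_landmarks` or `landmarks`).
#' @param use_landmarks Prefer the landmark fit (default `TRUE`).
#' @return A [scaling_transform()].
#' @export
fit_affine_init <- function(subject, atlas, use_landmarks = TRUE) {
  atl_lmks <- atlas$consensus_landmarks
  if (is.null(atl_lmks)) atl_lmks <- atlas$landmarks
  if (use_landmarks && !is.null(atl_lmks)) {
    shared <- intersect(present_landmarks(subject$landmarks),
                        present_landmarks(atl_lmks))
    if (length(shared) >= 4L) {
      xs <- unclass(subject$landmarks)[shared, , drop = FALSE]
      xa <- unclass(atl_lmks)[shared, , drop = FALSE]
      sc <- c(1, 1, 1); tr <- c(0, 0, 0)
      for (d in 1:3) {
        vx <- stats::var(xs[, d])
        if (is.finite(vx) && vx > 1e-10) {
          m <- stats::cov(xs[, d], xa[, d]) / vx
          if (is.finite(m) && m > 1e-8) {
            sc[d] <- m
            tr[d] <- mean(xa[, d]) - m * mean(xs[, d])
            next
          }
        }
        tr[d] <- mean(xa[, d]) - mean(xs[, d])
      }
      return(scaling_transform(sc, tr))
    }
  }
  # mask-moment fallback
  ms <- mask_moments(subject$mask)
  ma <- mask_moments(atlas$mask)
  sc <- ma$sd / ms$sd
  sc[!is.finite(sc) | sc <= 0] <- 1
  scaling_transform(sc, ma$center - sc * ms$center)
}

mask_moments <- function(mask) {
  idx <- which(mask$data > 0.5, arr.ind = TRUE) - 1
  if (!nrow(idx)) stop("empty brain mask")
  pts <- voxel_to_world(mask, idx)
  list(center = colMeans(pts), sd = apply(pts, 2L, stats::sd))
}

#' Registration objective
#'
#' The cost minimized by [register_ffd()]:
#' \deqn{-\alpha_{LNCC}\, \mathrm{LNCC}(I_{subject}, I_{atlas}\circ\phi)
#'   + \alpha_{LMKS} \sum_{k \in \Omega} \|\phi(x_k^{subject}) -
#'   x_k^{atlas}\|^2 + \alpha_{BE}\, BE(\phi) + \alpha_{LE}\, LE(\phi)}
#' where \eqn{\Omega} is the set of landmarks present in both volumes,
#' `alpha_lncc = (1 - alpha_lmks) (1 - alpha_be - alpha_le)` (0.5994 at the
#' defaults), and the atlas image is pulled back into subject space through
#' `phi`.  The landmark sum is omitted when `use_landmarks` is `FALSE` or no
#' landmark is shared.
#'
#' @param subject A [brain_sample()].
#' @param atlas Atlas time point (see [fit_affine_init()]).
#' @param transform An [ffd_transform()] (subject to atlas space).
#' @param config A [pipeline_config()] (registration weights).
#' @param use_landmarks Include the landmark distance term.
#' @return A list with `cost` and the individual `components`.
#' @export
registration_cost <- function(subject, atlas, transform,
                              config = pipeline_config(),
                              use_landmarks = TRUE) {
  ctx <- reg_context(subject, atlas, transform, config, use_landmarks,
                     level_factor = 1L)
  ev <- reg_eval(ctx, transform$theta, want_grad = FALSE)
  list(cost = ev$cost, components = ev$components)
}

# Precompute everything that is constant during one pyramid level.
reg_context <- function(subject, atlas, ffd, config, use_landmarks,
                        level_factor = 1L) {
  fx <- subject$image; mk <- subject$mask
  atl <- atlas$image
  if (level_factor > 1L) {
    fx <- decimate_volume(fx, level_factor, smooth = TRUE)
    mk <- decimate_volume(mk, level_factor, smooth = FALSE)
    mk$data <- (mk$data >= 0.5) * 1.0
    atl <- image_volume(gauss_smooth3(atl$data, level_factor / 2),
                        atl$affine)
  }
  if (!any(mk$data > 0.5)) stop("empty brain mask at pyramid level")
  pts <- grid_world_coords(fx)
  aff_pts <- apply_scaling(ffd$affine, pts)
  support <- ffd_support(ffd, pts)
  sd_vox <- config$lncc_kernel_sd_mm / fx$spacing
  mom <- lncc_fixed_moments(fx$data, sd_vox)
  # atlas intensity gradient (per mm), for the chain rule
  agrad <- lapply(1:3, function(ax)
    image_volume(d_central(atl$data, ax, atl$spacing[ax]), atl$affine))

  lmk_sub <- NULL; lmk_atl <- NULL; lmk_support <- NULL; lmk_aff <- NULL
  if (use_landmarks) {
    atl_lmks <- atlas$consensus_landmarks
    if (is.null(atl_lmks)) atl_lmks <- atlas$landmarks
    if (!is.null(atl_lmks)) {
      shared <- intersect(present_landmarks(subject$landmarks),
                          present_landmarks(atl_lmks))
      if (length(shared)) {
        lmk_sub <- unclass(subject$landmarks)[shared, , drop = FALSE]
        lmk_atl <- unclass(atl_lmks)[shared, , drop = FALSE]
        lmk_support <- ffd_support(ffd, lmk_sub)
        lmk_aff <- apply_scaling(ffd$affine, lmk_sub)
      }
    }
  }
  list(ffd = ffd, config = config, fixed = fx, mask = mk, atl = atl,
       agrad = agrad, pts = pts, aff_pts = aff_pts, support = support,
       inmask = mk$data > 0.5, sd_vox = sd_vox, mom = mom,
       lmk_sub = lmk_sub, lmk_atl = lmk_atl, lmk_support = lmk_support,
       lmk_aff = lmk_aff, a_lncc = alpha_lncc(config))
}

reg_eval <- function(ctx, theta, want_grad = TRUE) {
  cfg <- ctx$config
  d <- dim(ctx$fixed$data)
  disp <- ffd_eval_cpp(theta, ctx$ffd$cdim, ctx$support$base,
                       ctx$support$wx, ctx$support$wy, ctx$support$wz)
  q <- ctx$aff_pts + disp
  qvox <- world_to_voxel(ctx$atl, q)
  w <- array(sample_trilinear_cpp(ctx$atl$data, dim(ctx$atl$data), qvox, 0),
             d)
  ln <- lncc_value(ctx$fixed$data, w, ctx$inmask, ctx$sd_vox, ctx$mom,
                   want_grad = want_grad)
  lmk_term <- 0
  resid <- NULL; lmk_disp <- NULL
  if (!is.null(ctx$lmk_sub)) {
    lmk_disp <- ffd_eval_cpp(theta, ctx$ffd$cdim, ctx$lmk_support$base,
                             ctx$lmk_support$wx, ctx$lmk_support$wy,
                             ctx$lmk_support$wz)
    resid <- ctx$lmk_aff + lmk_disp - ctx$lmk_atl
    lmk_term <- sum(resid^2)
  }
  reg <- reg_energy_grad(theta, ctx$ffd$cdim, ctx$ffd$spacing,
                         want_grad = want_grad)
  cost <- -ctx$a_lncc * ln$value + cfg$alpha_lmks * lmk_term +
    cfg$alpha_be * reg$bending + cfg$alpha_le * reg$linear
  out <- list(cost = cost,
              components = c(lncc = ln$value, landmark = lmk_term,
                             bending = reg$bending, linear = reg$linear))
  if (want_grad) {
    dgrad <- vapply(1:3, function(ax)
      sample_trilinear_cpp(ctx$agrad[[ax]]$data, dim(ctx$atl$data), qvox, 0),
      numeric(nrow(qvox)))
    v <- (-ctx$a_lncc) * as.vector(ln$grad_w) * dgrad
    g <- ffd_scatter_cpp(v, ctx$ffd$cdim, ctx$support$base,
                         ctx$support$wx, ctx$support$wy, ctx$support$wz)
    if (!is.null(resid))
      g <- g + ffd_scatter_cpp(2 * cfg$alpha_lmks * resid, ctx$ffd$cdim,
                               ctx$lmk_support$base, ctx$lmk_support$wx,
                               ctx$lmk_support$wy, ctx$lmk_support$wz)
    g <- g + cfg$alpha_be * reg$grad_bending + cfg$alpha_le * reg$grad_linear
    out$grad <- g
  }
  out
}

decimate_volume <- function(vol, factor, smooth = TRUE) {
  if (factor <= 1L) return(vol)
  dat <- vol$data
  if (smooth) dat <- gauss_smooth3(dat, factor / 2)
  d <- dim(dat)
  ix <- seq(1L, d[1L], by = factor)
  iy <- seq(1L, d[2L], by = factor)
  iz <- seq(1L, d[3L], by = factor)
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  image_volume(dat[ix, iy, iz, drop = FALSE], aff)
}

#' Non-linear registration of a subject to an atlas time point
#'
#' Coarse-to-fine minimization of [registration_cost()]: the transform is
#' initialized with [fit_affine_init()], then the B-spline displacement
#' lattice is optimized by gradient descent with backtracking line search
#' (steps are only accepted when the cost decreases) over a 3-level image
#' pyramid (x4, x2, x1 downsampling) whose control spacing halves per level
#' down to `config$grid_spacing_mm`.  The procedure is deterministic.
#'
#' @inheritParams registration_cost
#' @param use_landmarks Use the landmark distance term (and prefer landmarks
#'   for the affine initialization).
#' @param seed Unused (kept for interface stability); the optimization is
#'   deterministic.
#' @param trace_env Optional environment collecting per-level cost traces
#'   (field `trace`).
#' @return The fitted [ffd_transform()].
#' @export
register_ffd <- function(subject, atlas, config = pipeline_config(),
                         use_landmarks = TRUE, seed = NULL,
                         trace_env = NULL) {
  affine <- fit_affine_init(subject, atlas, use_landmarks)
  levels <- config$pyramid_levels
  iters <- rep_len(config$optim_iter, levels)
  ffd <- NULL
  traces <- list()
  for (lev in seq_len(levels)) {
    factor <- 2^(levels - lev)
    spacing <- config$grid_spacing_mm * factor
    bbox <- mask_bbox(subject$mask, pad_mm = 2 * spacing)
    new_ffd <- ffd_for_bbox(bbox, spacing, affine = affine)
    if (!is.null(ffd)) {
      # carry the coarse displacement field over to the finer lattice
      nodes <- lattice_node_coords(new_ffd)
      new_ffd$theta <- ffd_displacement(ffd, nodes)
    }
    ffd <- new_ffd
    ctx <- reg_context(subject, atlas, ffd, config, use_landmarks,
                       level_factor = factor)
    res <- descend(ctx, ffd$theta, max_iter = iters[lev],
                   step0 = spacing / 4)
    ffd$theta <- res$theta
    traces[[lev]] <- res$trace
  }
  if (!is.null(trace_env)) trace_env$trace <- traces
  ffd
}

lattice_node_coords <- function(ffd) {
  cd <- ffd$cdim
  ijk <- cbind(rep.int(seq_len(cd[1L]) - 1, cd[2L] * cd[3L]),
               rep.int(rep(seq_len(cd[2L]) - 1, each = cd[1L]), cd[3L]),
               rep(seq_len(cd[3L]) - 1, each = cd[1L] * cd[2L]))
  sweep(ijk * matrix(ffd$spacing, nrow(ijk), 3L, byrow = TRUE), 2L,
        ffd$origin, "+")
}

mask_bbox <- function(mask, pad_mm = 0) {
  idx <- which(mask$data > 0.5, arr.ind = TRUE) - 1
  if (!nrow(idx)) stop("empty brain mask")
  pts <- voxel_to_world(mask, idx)
  rbind(apply(pts, 2L, min) - pad_mm, apply(pts, 2L, max) + pad_mm)
}

# Gradient descent with backtracking; accepted steps strictly decrease the
# cost, so the per-level cost trace is monotone.
descend <- function(ctx, theta, max_iter, step0, shrink = 0.5, grow = 1.3,
                    min_step = 1e-4, rel_tol = 1e-7) {
  ev <- reg_eval(ctx, theta, want_grad = TRUE)
  cost <- ev$cost
  trace <- cost
  step <- step0
  for (it in seq_len(max_iter)) {
    gmax <- max(abs(ev$grad))
    if (!is.finite(cost)) stop("non-finite registration cost")
    if (gmax < 1e-12) break
    dir <- -ev$grad / gmax
    accepted <- FALSE
    while (step >= min_step) {
      cand <- theta + step * dir
      ev_c <- reg_eval(ctx, cand, want_grad = FALSE)
      if (is.finite(ev_c$cost) && ev_c$cost < cost) {
        accepted <- TRUE
        break
      }
      step <- step * shrink
    }
    if (!accepted) break
    theta <- cand
    prev <- cost
    ev <- reg_eval(ctx, theta, want_grad = TRUE)
    cost <- ev$cost
    trace <- c(trace, cost)
    step <- min(step * grow, step0)
    if (prev - cost < rel_tol * max(abs(prev), 1e-12)) break
  }
  list(theta = theta, cost = cost, trace = trace)
}

#' Apply a fitted transform to images, labels, probability maps or points
#'
#' For rasters, the input (living in atlas space) is pulled back onto
#' `output_grid` (subject space): the output value at physical point `y` is
#' the input sampled at `phi(y)` — trilinear for `"linear"` (images,
#' probability maps), nearest-neighbour for `"nearest"` (label maps, so the
#' output label set is a subset of the input's).  For `"forward-points"`,
#' subject-space points are mapped to atlas space.
#'
#' @param transform An [ffd_transform()] (or [scaling_transform()]).
#' @param x An [image_volume()], [probmaps()], or n x 3 point matrix.
#' @param mode `"linear"`, `"nearest"` or `"forward-points"`.
#' @param output_grid An [image_volume()] defining the output grid
#'   (required for raster modes).
#' @param fill Fill value outside the input volume.
#' @return Same kind as `x`.
#' @export
apply_transform <- function(transform, x,
                            mode = c("linear", "nearest", "forward-points"),
                            output_grid = NULL, fill = 0) {
  mode <- match.arg(mode)
  map_points <- function(pts) {
    if (inherits(transform, "ffd_transform")) ffd_map_points(transform, pts)
    else apply_scaling(transform, pts)
  }
  if (mode == "forward-points") {
    if (!is.matrix(x) && !is.numeric(x))
      stop("'forward-points' mode expects an n x 3 point matrix")
    return(map_points(rbind3(x)))
  }
  if (inherits(x, "probmaps")) {
    if (mode != "linear") stop("probability maps need mode 'linear'")
    out <- c(list(background = apply_transform(transform, x$background,
                                               "linear", output_grid,
                                               fill = 1)),
             lapply(x[tissue_classes()], apply_transform,
                    transform = transform, mode = "linear",
                    output_grid = output_grid, fill = 0))
    return(probmaps(out))
  }
  if (!inherits(x, "image_volume"))
    stop("unsupported input kind for mode '", mode, "'")
  if (is.null(output_grid)) stop("raster modes need an 'output_grid'")
  q <- map_points(grid_world_coords(output_grid))
  vals <- sample_volume(x, q, mode = mode, fill = fill)
  image_volume(array(vals, dim(output_grid$data)), output_grid$affine)
}

#' Serialize / restore an FFD transform
#'
#' The displacement lattice is written as a 5-D NIfTI (x, y, z, 1,
#' component) with a JSON sidecar holding the lattice geometry and the
#' affine initialization.
#'
#' @param ffd An [ffd_transform()].
#' @param path Output path without extension; `<path>.nii.gz` and
#'   `<path>.json` are written.
#' @export
write_ffd <- function(ffd, path) {
  meta <- list(origin = ffd$origin, spacing = ffd$spacing, cdim = ffd$cdim,
               affine_scale = ffd$affine$scale,
               affine_translation = ffd$affine$translation)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  arr <- array(ffd$theta, c(ffd$cdim, 3L))
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, paste0(path, ".nii.gz"), datatype = "double")
  invisible(path)
}

#' @rdname write_ffd
#' @export
read_ffd <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(paste0(path, ".nii.gz")))
  ffd_transform(meta$origin, meta$spacing, meta$cdim,
                theta = matrix(arr, ncol = 3L),
                affine = scaling_transform(meta$affine_scale,
                                           meta$affine_translation))
}
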
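#' Anisotropic scaling transforms
#'
#' The Procrustes alignment restricts each sample's spatial transform to an
#' anisotropic scaling plus translation:
#' `apply(x) = diag(scale) x + translation`.  Rotations are deliberately
#' excluded (input volumes are assumed already in a standard orientation).
#'
#' @param scale Length-3 positive scale factors.
#' @param translation Length-3 translation in mm.
#' @return Object of class `scaling_transform`.
#' @export
scaling_transform <- function(scale = c(1, 1, 1), translation = c(0, 0, 0)) {
  scale <- as.numeric(scale); translation <- as.numeric(translation)
  stopifnot(length(scale) == 3L, length(translation) == 3L)
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("scale components must be positive")
  structure(list(scale = scale, translation = translation),
            class = "scaling_transform")
}

#' @param transform A `scaling_transform`.
#' @param pts n x 3 matrix of points (mm).
#' @rdname scaling_transform
#' @export
apply_scaling <- function(transform, pts) {
  pts <- rbind3(pts)
  sweep(sweep(pts, 2L, transform$scale, "*"), 2L,
        transform$translation, "+")
}

#' @rdname scaling_transform
#' @export
invert_scaling <- function(transform) {
  scaling_transform(1 / transform$scale,
                    -transform$translation / transform$scale)
}

#' @param x A `scaling_transform`.
#' @param ... Ignored.
#' @rdname scaling_transform
#' @export
print.scaling_transform <- function(x, ...) {
  cat(sprintf("<scaling_transform> scale (%s), translation (%s) mm\n",
              paste(signif(x$scale, 5), collapse = ", "),
              paste(signif(x$translation, 5), collapse = ", ")))
  invisible(x)
}

# Stack a list of landmark_sets into an n x K x 3 array over `ids`.
stack_landmarks <- function(landmarks, ids) {
  n <- length(landmarks)
  X <- array(NA_real_, c(n, length(ids), 3L))
  for (i in seq_len(n)) {
    li <- unclass(landmarks[[i]])
    common <- intersect(ids, rownames(li))
    X[i, match(common, ids), ] <- li[common, , drop = FALSE]
  }
  X
}

#' Weighted generalized Procrustes objective
#'
#' The alignment objective
#' \deqn{\frac{1}{2} \sum_{i=1}^n \sum_{k=1}^K w_{i,k}
#'   \| M_i x_{i,k} + t_i - g_k \|^2}
#' over per-sample anisotropic scalings \eqn{M_i}, translations \eqn{t_i}
#' and consensus landmark positions \eqn{g_k}.  Missing landmarks carry
#' weight 0 and contribute nothing; a positive weight on a missing landmark
#' is an error.
#'
#' @param landmarks List of n [landmark_set()]s.
#' @param weights n x K non-negative matrix with column names giving the
#'   landmark ids in play (zero exactly where missing/out-of-window).
#' @param transforms List of n [scaling_transform()]s.
#' @param consensus K x 3 matrix of consensus positions.
#' @return Non-negative scalar.
#' @export
wgp_objective <- function(landmarks, weights, transforms, consensus) {
  ids <- colnames(weights)
  X <- stack_landmarks(landmarks, ids)
  check_weights(X, weights)
  total <- 0
  for (i in seq_len(nrow(weights))) {
    y <- apply_scaling(transforms[[i]], X[i, , ])
    r2 <- rowSums((y - consensus)^2)
    r2[is.na(r2)] <- 0  # zero-weight missing entries
    total <- total + 0.5 * sum(weights[i, ] * r2)
  }
  total
}

check_weights <- function(X, weights) {
  if (any(weights < 0)) stop("weights must be non-negative")
  miss <- is.na(X[, , 1L, drop = FALSE])[, , 1L]
  if (any(weights[miss] > 0))
    stop("positive weight on a missing landmark")
  if (any(colSums(weights) <= 0))
    stop("every landmark must have positive weight for at least one sample")
  invisible(TRUE)
}

# Weighted means of the raw landmarks (the constraint targets of the
# consensus): xbar_k, their barycenter c*, and the size target s*^2.
wgp_constraint_targets <- function(X, weights) {
  K <- ncol(weights)
  xbar <- matrix(0, K, 3L)
  for (k in seq_len(K)) {
    w <- weights[, k]
    pos <- which(w > 0)
    xk <- matrix(X[pos, k, ], ncol = 3L)
    xbar[k, ] <- colSums(xk * w[pos]) / sum(w)
  }
  ctr <- colMeans(xbar)
  list(xbar = xbar, center = ctr,
       size2 = mean(rowSums(sweep(xbar, 2L, ctr, "-")^2)))
}

# Exact constrained consensus update given the transforms: minimize
# sum_k W_k ||g_k - ybar_k||^2 subject to mean(g) = c and
# mean ||g - c||^2 = s2 -- a diagonal special case of the trust-region
# solve shared with the reduced problem.
solve_consensus <- function(ybar, Wk, ctr, s2) {
  A <- lapply(1:3, function(d) diag(Wk, nrow = length(Wk)))
  b <- -(Wk * ybar)
  trs_consensus(A, b, ctr, s2, prefer = ybar)
}

# Global minimizer of 1/2 sum_d (g_d' A_d g_d + 2 b_d' g_d) over K x 3
# configurations g with mean(g) = center and mean ||g_k - center||^2 =
# size2: eliminate the linear constraint with a mean-zero basis, then solve
# the spherically constrained quadratic through its secular equation
# (classic trust-region subproblem).  In the hard case the solution set is
# an affine sphere of equal-cost minimizers; `prefer` (a K x 3 reference
# configuration, e.g. the raw weighted landmark means) picks the one
# nearest that reference, so exactly matchable inputs keep their aligned
# consensus instead of an arbitrary degenerate one.
trs_consensus <- function(A, b, center, size2, prefer = NULL) {
  K <- nrow(b)
  if (size2 <= 1e-24 || K < 2L)
    return(matrix(center, K, 3L, byrow = TRUE))
  P <- qr.Q(qr(cbind(rep(1, K), diag(K))))[, 2:K, drop = FALSE]
  ev <- lapply(1:3, function(d) eigen(crossprod(P, A[[d]] %*% P),
                                      symmetric = TRUE))
  vals <- unlist(lapply(ev, `[[`, "values"))
  beta <- unlist(lapply(1:3, function(d)
    crossprod(ev[[d]]$vectors,
              crossprod(P, A[[d]] %*% rep(center[d], K) + b[, d]))))
  r2 <- K * size2
  lmin <- min(vals)
  scale_ref <- max(abs(vals), 1)
  znorm2 <- function(lam) sum((beta / (vals + lam))^2)
  lo <- -lmin + 1e-12 * scale_ref
  if (znorm2(lo) >= r2) {
    hi <- lo + scale_ref
    while (znorm2(hi) > r2) hi <- lo + (hi - lo) * 2
    lam <- stats::uniroot(function(l) znorm2(l) - r2, c(lo, hi),
                          tol = 1e-14)$root
    zc <- beta / (vals + lam)
  } else {
    # hard case: pseudo-inverse solution at the pole, augmented within the
    # minimal eigenspace to reach the required norm
    at_min <- abs(vals - lmin) < 1e-10 * scale_ref
    zc <- ifelse(at_min, 0, beta / (vals - lmin))
    alpha <- sqrt(max(r2 - sum(zc^2), 0))
    dir <- rep(0, length(vals))
    if (!is.null(prefer)) {
      zp <- unlist(lapply(1:3, function(d)
        crossprod(ev[[d]]$vectors,
                  crossprod(P, prefer[, d] - center[d]))))
      dir[at_min] <- -zp[at_min]  # account for the sign flip below
    }
    if (sqrt(sum(dir^2)) < 1e-12 * max(1, alpha))
      dir[which.min(vals)] <- 1
    dir <- dir / sqrt(sum(dir^2))
    zc <- zc + alpha * dir
  }
  zc <- -zc  # stationarity is (A + lam I) z = -beta
  zm <- matrix(zc, K - 1L, 3L)
  g <- sapply(1:3, function(d)
    center[d] + P %*% (ev[[d]]$vectors %*% zm[, d]))
  matrix(g, K, 3L)
}

# Transform-step geometry for sample i, axis d: whether the scale is
# identifiable (>= 2 positively weighted landmarks with spread) -- the
# pattern depends on the inputs only, not on the consensus.
wgp_axis_pattern <- function(X, weights) {
  n <- nrow(weights)
  ok <- array(FALSE, c(n, 3L))
  for (i in seq_len(n)) {
    w <- weights[i, ]; pos <- which(w > 0)
    for (d in 1:3) {
      x <- X[i, pos, d]
      sw <- sum(w[pos])
      mx <- sum(w[pos] * x) / sw
      ok[i, d] <- length(pos) >= 2L &&
        sum(w[pos] * (x - mx)^2) > 1e-12 * sw
    }
  }
  ok
}

# Exact consensus solve of the reduced problem: the objective is jointly
# convex in (transforms, consensus), and the optimal transforms are linear
# in g, so eliminating them leaves one quadratic form per axis,
# F_red(g) = 1/2 sum_d (g_d' A_d g_d + 2 b_d' g_d) + const.  Minimizing it
# under the barycenter (linear) and size (spherical) constraints is a
# trust-region subproblem solved through its secular equation.
wgp_reduced_consensus <- function(X, weights, tg, pattern) {
  K <- ncol(weights); n <- nrow(weights)
  A <- vector("list", 3L); b <- matrix(0, K, 3L)
  for (d in 1:3) A[[d]] <- matrix(0, K, K)
  for (i in seq_len(n)) {
    w <- weights[i, ]
    sw <- sum(w)
    for (d in 1:3) {
      x <- X[i, , d]; x[w == 0] <- 0
      mx <- sum(w * x) / sw
      xt <- ifelse(w > 0, x - mx, 0)
      M <- outer(rep(1, K), w / sw) - diag(K)
      cvec <- rep(0, K)
      if (pattern[i, d]) {
        V <- sum(w * xt^2)
        M <- M + outer(xt, w * xt / V)
      } else {
        cvec <- xt
      }
      WM <- w * M  # diag(w) %*% M
      A[[d]] <- A[[d]] + crossprod(M, WM)
      b[, d] <- b[, d] + crossprod(WM, cvec)
    }
  }
  trs_consensus(A, b, tg$center, tg$size2, prefer = tg$xbar)
}

# Clamped per-axis reduced cost (scale >= 0): used to pick, per axis, the
# orientation of the reduced consensus that positive scalings can realize
# (the sign-free reduced problem is invariant under per-axis mirroring).
wgp_axis_cost <- function(X, weights, gd, d, pattern) {
  tot <- 0
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]; pos <- which(w > 0)
    x <- X[i, pos, d]; gk <- gd[pos]; wd <- w[pos]
    sw <- sum(wd)
    mx <- sum(wd * x) / sw; mg <- sum(wd * gk) / sw
    if (pattern[i, d]) {
      vx <- sum(wd * (x - mx)^2)
      m <- max(sum(wd * (x - mx) * (gk - mg)) / vx, 1e-8)
    } else m <- 1
    tot <- tot + 0.5 * sum(wd * (m * (x - mx) + mg - gk)^2)
  }
  tot
}

#' Solve the weighted generalized Procrustes problem
#'
#' Alternating least squares for [wgp_objective()] under the two consensus
#' constraints that fix the barycenter and the size of the consensus
#' configuration to those of the weighted raw-landmark means (removing the
#' trivial collapse-to-a-point solution).  Each iteration performs two exact
#' minimizations, so the objective is non-increasing:
#'
#' 1. *Transforms*: per sample and per axis, the scaling problem separates
#'    into a 1-D weighted linear regression of the consensus on the raw
#'    coordinates (closed form).  Axes with fewer than two positively
#'    weighted landmarks or with no coordinate spread fall back to scale 1
#'    and a weighted mean translation.
#' 2. *Consensus*: the weighted mean of the transformed landmarks, exactly
#'    projected onto the two constraints by solving the associated
#'    secular equation for the Lagrange multiplier (this reduces to
#'    "translate, then rescale about the barycenter" when all landmark
#'    total weights are equal).
#'
#' Because the objective is jointly convex in the transforms and the
#' consensus, eliminating the transforms (they are linear in the consensus)
#' leaves one quadratic form per axis; with `global_init = TRUE` the
#' alternation is jump-started at the exact minimizer of that reduced
#' quadratic over the constraint set (a trust-region-style secular-equation
#' solve, orientation-corrected per axis so that positive scalings can
#' realize it), which makes the alternation converge to the constrained
#' global optimum in a few sweeps.  Note a property of the problem itself:
#' because only the overall size of the consensus is constrained and scale
#' factors may approach zero, the global optimum of a noisy instance can
#' collapse the consensus along one or two axes.  With
#' `global_init = FALSE` the solver starts from identity transforms and the
#' weighted raw-landmark means (a feasible point) and converges to the
#' structure-preserving local solution of the classical alternation; the
#' atlas pipeline uses this mode.
#'
#' @inheritParams wgp_objective
#' @param tol Relative objective-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @param global_init Jump-start at the reduced-problem global solve
#'   (default `TRUE`; see Details).
#' @return An object of class `wgp_result` with `transforms` (list of
#'   [scaling_transform()]), `consensus` (K x 3 matrix, row names = ids),
#'   `objective`, `trace` (objective after each iteration), `iterations`,
#'   `converged`, and `constraint_residuals` (barycenter in mm, size
#'   relative).
#' @export
solve_wgp <- function(landmarks, weights, tol = 1e-10, max_iter = 100L,
                      global_init = TRUE) {
  ids <- colnames(weights)
  if (is.null(ids)) stop("'weights' must have landmark ids as column names")
  n <- nrow(weights)
  X <- stack_landmarks(landmarks, ids)
  check_weights(X, weights)
  tg <- wgp_constraint_targets(X, weights)

  g <- tg$xbar
  if (global_init) {
    pattern <- wgp_axis_pattern(X, weights)
    g <- tryCatch(wgp_reduced_consensus(X, weights, tg, pattern),
                  error = function(e) tg$xbar)
    for (d in 1:3) {
      gm <- 2 * tg$center[d] - g[, d]
      if (wgp_axis_cost(X, weights, gm, d, pattern) <
            wgp_axis_cost(X, weights, g[, d], d, pattern))
        g[, d] <- gm
    }
  }
  transforms <- replicate(n, scaling_transform(), simplify = FALSE)
  obj <- wgp_objective_fast(X, weights, transforms, g)
  trace <- obj

  for (iter in seq_len(max_iter)) {
    # (a) per-sample, per-axis weighted regression against the consensus
    for (i in seq_len(n)) {
      w <- weights[i, ]
      pos <- which(w > 0)
      sc <- c(1, 1, 1); tr <- c(0, 0, 0)
      for (d in 1:3) {
        x <- X[i, pos, d]; gd <- g[pos, d]; wd <- w[pos]
        sw <- sum(wd)
        mx <- sum(wd * x) / sw; mg <- sum(wd * gd) / sw
        vx <- sum(wd * (x - mx)^2)
        if (length(pos) >= 2L && vx > 1e-12 * sw) {
          m <- sum(wd * (x - mx) * (gd - mg)) / vx
          if (!is.finite(m) || m <= 1e-8) m <- 1e-8
          sc[d] <- m; tr[d] <- mg - m * mx
        } else {
          sc[d] <- 1; tr[d] <- mg - mx
        }
      }
      transforms[[i]] <- scaling_transform(sc, tr)
    }
    # (b) constrained consensus update
    Wk <- colSums(weights)
    ybar <- matrix(0, length(ids), 3L)
    for (k in seq_along(ids)) {
      w <- weights[, k]; pos <- which(w > 0)
      yk <- t(vapply(pos, function(i)
        transforms[[i]]$scale * X[i, k, ] + transforms[[i]]$translation,
        numeric(3L)))
      ybar[k, ] <- colSums(yk * w[pos]) / Wk[k]
    }
    g <- solve_consensus(ybar, Wk, tg$center, tg$size2)

    obj_new <- wgp_objective_fast(X, weights, transforms, g)
    trace <- c(trace, obj_new)
    done <- abs(obj - obj_new) <= tol * max(obj, 1e-8 * tg$size2, 1e-300)
    obj <- obj_new
    if (done) break
  }
  rownames(g) <- ids
  gc_res <- sqrt(sum((colMeans(g) - tg$center)^2))
  size2 <- mean(rowSums(sweep(g, 2L, colMeans(g), "-")^2))
  size_res <- if (tg$size2 > 0) abs(size2 - tg$size2) / tg$size2 else size2
  structure(list(
    transforms = transforms, consensus = g, objective = obj,
    trace = trace, iterations = length(trace) - 1L,
    converged = done,
    constraint_residuals = c(barycenter_mm = gc_res,
                             size_relative = size_res)),
    class = "wgp_result")
}

wgp_objective_fast <- function(X, weights, transforms, g) {
  total <- 0
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    pos <- which(w > 0)
    y <- sweep(X[i, pos, , drop = FALSE][, , , drop = TRUE],
               2L, transforms[[i]]$scale, "*")
    if (length(pos) == 1L) y <- matrix(y, 1L, 3L)
    y <- sweep(y, 2L, transforms[[i]]$translation, "+")
    total <- total + 0.5 * sum(w[pos] *
                                 rowSums((y - g[pos, , drop = FALSE])^2))
  }
  total
}

#' @param x A `wgp_result`.
#' @param ... Ignored.
#' @rdname solve_wgp
#' @export
print.wgp_result <- function(x, ...) {
  cat(sprintf(paste0("<wgp_result> %d samples, objective %.6g after %d",
                     " iterations (%s)\n"),
              length(x$transforms), x$objective, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Resample a sample into the consensus frame
#'
#' Applies a solved Procrustes transform to a whole sample: rasters are
#' pulled back onto `reference` (output value at physical point `y` is the
#' input sampled at `M^{-1}(y - t)`; image and probability maps trilinear,
#' mask thresholded at 0.5) and landmarks are mapped forward as
#' `M x + t`.
#'
#' @param sample A [brain_sample()].
#' @param transform The sample's [scaling_transform()] from [solve_wgp()].
#' @param reference An [image_volume()] defining the output grid.
#' @return A `brain_sample` on the reference grid.
#' @export
resample_to_consensus <- function(sample, transform, reference) {
  inv <- invert_scaling(transform)
  src <- apply_scaling(inv, grid_world_coords(reference))
  d <- dim(reference$data)
  pull <- function(vol, fill = 0)
    image_volume(array(sample_volume(vol, src, "linear", fill), d),
                 reference$affine)
  img <- pull(sample$image)
  mask <- pull(sample$mask)
  mask$data <- (mask$data >= 0.5) * 1.0
  pm <- NULL
  if (!is.null(sample$probmaps))
    pm <- probmaps(c(
      list(background = pull(sample$probmaps$background, fill = 1)),
      lapply(sample$probmaps[tissue_classes()], pull)))
  coords <- unclass(sample$landmarks)
  pres <- present_landmarks(sample$landmarks)
  coords[pres, ] <- apply_scaling(transform, coords[pres, , drop = FALSE])
  brain_sample(sample$meta, img, mask, landmark_set(coords), pm)
}

#' Serialize / restore scaling transforms
#'
#' Text record: one line per transform with scale and translation (and an
#' optional frame id), readable back with `read_scaling_transforms()`.
#'
#' @param transforms List of [scaling_transform()]s.
#' @param path File path.
#' @param ids Optional reference-frame / sample ids.
#' @export
write_scaling_transforms <- function(transforms, path, ids = NULL) {
  tab <- do.call(rbind, lapply(transforms, function(tr)
    c(tr$scale, tr$translation)))
  colnames(tab) <- c("sx", "sy", "sz", "tx", "ty", "tz")
  out <- data.frame(id = if (is.null(ids)) seq_along(transforms) else ids,
                    tab)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaling_transforms
#' @export
read_scaling_transforms <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    scaling_transform(unlist(tab[i, c("sx", "sy", "sz")]),
                      unlist(tab[i, c("tx", "ty", "tz")])))
  names(out) <- tab$id
  out
}
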
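#' Synthetic fetal-brain phantom specification
#'
#' The phantom emulates the anatomy the atlas pipeline is built for: a
#' brain-shaped nest of ellipsoidal compartments covering the 8 tissue
#' classes (white matter shell, enlarged lateral ventricles, cerebellum,
#' extra-axial CSF rim, cortical grey matter rim, deep grey matter core,
#' brainstem, corpus callosum bridge), bilaterally symmetric about `x = 0`,
#' with anatomical landmarks at analytically known loci and a linear growth
#' model over gestation (overall scale 1.0 at 21 weeks to 1.8 at 34 weeks).
#' `severity` in \[0, 1\] enlarges the lateral ventricles (ventriculomegaly,
#' the cardinal spina bifida finding), scaling their semi-axes by
#' `1 + severity`.
#'
#' @param ga Gestational age in days (see [ga_from_weeks_days()]).
#' @param operated Post-surgery status flag (metadata only).
#' @param severity Ventricle enlargement factor in \[0, 1\].
#' @param noise_sd Gaussian intensity noise sd (intensity units).
#' @param bias_amplitude Relative amplitude of a low-order polynomial bias
#'   field (0 disables it).
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @param grid_shape Grid dimensions (length 3).
#' @param spacing Isotropic voxel size in mm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(ga, operated = FALSE, severity = 0.5,
                         noise_sd = 20, bias_amplitude = 0, seed = 1L,
                         grid_shape = c(64L, 64L, 64L), spacing = 0.8) {
  stopifnot(severity >= 0, severity <= 1, noise_sd >= 0, spacing > 0,
            length(grid_shape) == 3L, all(grid_shape >= 8L))
  structure(list(ga = validate_ga_days(ga), operated = isTRUE(operated),
                 severity = severity, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape), spacing = spacing),
            class = "phantom_spec")
}

# Growth model: linear overall scale in GA, 1.0 at 21w to 1.8 at 34w.
phantom_scale <- function(ga_days) {
  1 + 0.8 * (ga_days / 7 - 21) / 13
}

# Base-scale geometry (mm, grid centred at 0). Regions are tested in
# priority order; every region is clipped to the outer brain ellipsoid.
phantom_geometry <- function(severity) {
  v <- 1 + severity
  list(
    outer = list(c = c(0, 0, 0), s = c(11, 13.5, 10)),
    cortex_outer = list(c = c(0, 0, 0), s = c(10.2, 12.6, 9.2)),
    wm_outer = list(c = c(0, 0, 0), s = c(9.4, 11.7, 8.5)),
    vent_r = list(c = c(3.2, 1.5, 1.0), s = c(2.0, 4.5, 2.0) * v),
    vent_l = list(c = c(-3.2, 1.5, 1.0), s = c(2.0, 4.5, 2.0) * v),
    cc = list(c = c(0, 2.0, 3.6), s = c(3.5, 3.0, 0.8)),
    dgm = list(c = c(0, 0.5, 0.5), s = c(2.8, 3.5, 2.5)),
    cereb = list(c = c(0, -8.5, -5.5), s = c(4.5, 2.5, 2.2)),
    bstem = list(c = c(0, -5.5, -6.0), s = c(1.6, 1.6, 2.5))
  )
}

# Analytic landmark loci at base scale (laterality: left = -x in RAS).
phantom_landmark_loci <- function(severity) {
  v <- 1 + severity
  rbind(
    RALV  = c(3.2, 1.5 + 4.5 * v, 1.0),
    LALV  = c(-3.2, 1.5 + 4.5 * v, 1.0),
    PTP   = c(0, -3.0, 0.5),
    LCB   = c(-1.8, -6.3, -5.5),
    RCB   = c(1.8, -6.3, -5.5),
    LFOM  = c(-2.8, 0.5, 0.5),
    RFOM  = c(2.8, 0.5, 0.5),
    LACSP = c(-1.0, 3.0, 1.0),
    RACSP = c(1.0, 3.0, 1.0),
    LPCSP = c(-1.0, 0.8, 1.0),
    RPCSP = c(1.0, 0.8, 1.0)
  )
}

phantom_intensities <- function() {
  c(background = 0, white_matter = 400, ventricles = 900, cerebellum = 350,
    extra_axial_csf = 850, cortical_gm = 300, deep_gm = 320,
    brainstem = 330, corpus_callosum = 450)
}

inside_ellipsoid <- function(pts, ell, scale) {
  q <- sweep(pts, 2L, ell$c * scale, "-")
  q <- sweep(q, 2L, ell$s * scale, "/")
  rowSums(q^2) <= 1
}

# Tissue label (0..8) at arbitrary physical points of a phantom.
phantom_labels_at <- function(pts, severity, scale) {
  g <- phantom_geometry(severity)
  lab <- integer(nrow(pts))
  outer <- inside_ellipsoid(pts, g$outer, scale)
  pri <- list(ventricles = quote(inside_ellipsoid(pts, g$vent_r, scale) |
                                   inside_ellipsoid(pts, g$vent_l, scale)),
              corpus_callosum = quote(inside_ellipsoid(pts, g$cc, scale)),
              deep_gm = quote(inside_ellipsoid(pts, g$dgm, scale)),
              cerebellum = quote(inside_ellipsoid(pts, g$cereb, scale)),
              brainstem = quote(inside_ellipsoid(pts, g$bstem, scale)),
              white_matter = quote(inside_ellipsoid(pts, g$wm_outer, scale)),
              cortical_gm = quote(inside_ellipsoid(pts, g$cortex_outer,
                                                   scale)),
              extra_axial_csf = quote(outer))
  cls <- tissue_classes()
  for (nm in names(pri)) {
    hit <- outer & eval(pri[[nm]]) & lab == 0L
    lab[hit] <- match(nm, cls)
  }
  lab
}

#' Generate a synthetic brain phantom
#'
#' Rasterizes the phantom geometry of a [phantom_spec()] onto its grid and
#' returns a complete [brain_sample()]: intensity image (per-tissue mean
#' plus Gaussian noise and optional bias field), binary brain mask, one-hot
#' tissue probability maps (8 classes + background) and a [landmark_set()]
#' with all 11 protocol landmarks at their analytic positions.  Paired
#' landmarks are exact mirror images; the output is deterministic for a
#' fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [brain_sample()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- phantom_scale(spec$ga)
  half_extent <- (spec$grid_shape - 1) / 2 * spec$spacing
  outer <- phantom_geometry(spec$severity)$outer$s * s
  if (any(outer + spec$spacing > half_extent))
    stop("grid too small to contain the brain at GA ", format_ga(spec$ga))

  ref <- centered_volume(spec$grid_shape, spacing = spec$spacing)
  pts <- grid_world_coords(ref)
  lab <- phantom_labels_at(pts, spec$severity, s)
  labvol <- image_volume(array(lab, spec$grid_shape), ref$affine)

  means <- phantom_intensities()
  img <- means[lab + 1L]
  with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    if (spec$bias_amplitude > 0) {
      u <- sweep(pts, 2L, half_extent, "/")
      coef <- stats::runif(9L, -1, 1)
      poly <- coef[1L] * u[, 1L] + coef[2L] * u[, 2L] + coef[3L] * u[, 3L] +
        coef[4L] * u[, 1L]^2 + coef[5L] * u[, 2L]^2 + coef[6L] * u[, 3L]^2 +
        coef[7L] * u[, 1L] * u[, 2L] + coef[8L] * u[, 1L] * u[, 3L] +
        coef[9L] * u[, 2L] * u[, 3L]
      img <- img * (1 + spec$bias_amplitude * poly)
    }
  })

  lmks <- landmark_set(phantom_landmark_loci(spec$severity) * s)
  brain_sample(
    meta = list(subject_id = sprintf("phantom-ga%03d", spec$ga),
                session_id = sprintf("seed%d", spec$seed),
                ga = spec$ga, operated = spec$operated),
    image = image_volume(array(img, spec$grid_shape), ref$affine),
    mask = image_volume(array((lab > 0L) * 1.0, spec$grid_shape),
                        ref$affine),
    landmarks = lmks,
    probmaps = probmaps_from_labels(labvol))
}

#' Perturb a sample by a known transform
#'
#' Applies an anisotropic scaling, a translation and (optionally) a smooth
#' sinusoidal warp to a sample, returning both the perturbed sample and the
#' exact ground-truth transform.  The forward map is
#' `f(p) = diag(scale) p + translation + u(p)` with `u` a band-limited
#' displacement of peak magnitude `smooth_warp_amplitude` mm; rasters are
#' pulled back through the numerically inverted map (fixed-point iteration,
#' which converges because the warp is constrained to be contractive), and
#' landmarks are mapped forward exactly.
#'
#' @param sample A [brain_sample()].
#' @param scale Length-3 positive scale factors.
#' @param translation Length-3 translation in mm.
#' @param smooth_warp_amplitude Peak warp displacement in mm (0 disables).
#' @param drop_landmarks Character vector of landmark ids to mark missing.
#' @param seed Seed for the random warp directions/phases.
#' @param warp_wavelength_mm Spatial wavelength of the warp (default 40).
#' @return A list with `sample` (the perturbed [brain_sample()]) and
#'   `transform` (a `phantom_transform` with `$forward(pts)` and
#'   `$inverse(pts)`).
#' @export
perturb_phantom <- function(sample, scale = c(1, 1, 1),
                            translation = c(0, 0, 0),
                            smooth_warp_amplitude = 0,
                            drop_landmarks = character(), seed = 1L,
                            warp_wavelength_mm = 40) {
  stopifnot(length(scale) == 3L, all(scale > 0), length(translation) == 3L)
  lipschitz <- 2 * pi * smooth_warp_amplitude / warp_wavelength_mm
  if (lipschitz >= 0.8)
    stop("requested warp is too large to be invertible; ",
         "reduce smooth_warp_amplitude or increase warp_wavelength_mm")

  warp <- NULL
  if (smooth_warp_amplitude > 0) {
    warp <- with_seed(seed, {
      dirs <- matrix(stats::rnorm(9L), 3L, 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(amp = smooth_warp_amplitude / sqrt(3), dirs = dirs,
           phase = stats::runif(3L, 0, 2 * pi),
           k = 2 * pi / warp_wavelength_mm)
    })
  }
  u_of <- function(pts) {
    if (is.null(warp)) return(matrix(0, nrow(pts), 3L))
    do.call(cbind, lapply(1:3, function(d)
      warp$amp * sin(warp$k * drop(pts %*% warp$dirs[d, ]) + warp$phase[d])))
  }
  forward <- function(pts) {
    pts <- rbind3(pts)
    sweep(pts, 2L, scale, "*") +
      matrix(translation, nrow(pts), 3L, byrow = TRUE) + u_of(pts)
  }
  inverse <- function(pts) {
    pts <- rbind3(pts)
    rhs <- sweep(pts, 2L, translation, "-")
    p <- sweep(rhs, 2L, scale, "/")
    if (!is.null(warp)) {
      for (it in 1:60) {
        p_new <- sweep(rhs - u_of(p), 2L, scale, "/")
        if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
        p <- p_new
      }
    }
    p
  }
  transform <- structure(
    list(scale = scale, translation = translation, warp = warp,
         forward = forward, inverse = inverse),
    class = "phantom_transform")

  grid_pts <- grid_world_coords(sample$image)
  src <- inverse(grid_pts)
  d <- dim(sample$image$data)
  resamp <- function(vol, fill = 0)
    image_volume(array(sample_volume(vol, src, "linear", fill), d),
                 vol$affine)
  img2 <- resamp(sample$image)
  mask2 <- resamp(sample$mask)
  mask2$data <- (mask2$data >= 0.5) * 1.0
  pm2 <- NULL
  if (!is.null(sample$probmaps)) {
    pm2 <- probmaps(c(
      list(background = resamp(sample$probmaps$background, fill = 1)),
      lapply(sample$probmaps[tissue_classes()], resamp)))
  }
  coords <- unclass(sample$landmarks)
  pres <- present_landmarks(sample$landmarks)
  coords[pres, ] <- forward(coords[pres, , drop = FALSE])
  coords[intersect(drop_landmarks, rownames(coords)), ] <- NA_real_
  list(sample = brain_sample(sample$meta, img2, mask2,
                             landmark_set(coords), pm2),
       transform = transform)
}

#' Generate a synthetic cohort
#'
#' Builds a reproducible cohort of phantom sessions emulating a mixed
#' operated/non-operated fetal population: per-subject growth trajectories
#' (optionally longitudinal with 1--3 sessions at increasing gestational
#' age), per-subject ventricle severity, random small anisotropic
#' scale/translation perturbations of the canonical frame, and sporadic
#' missing landmarks.  Operated subjects only have sessions after the fetal
#' surgery age (25 weeks).
#'
#' @param n_subjects Number of subjects.
#' @param ga_range Gestational-age range in days (length 2).
#' @param operated_split Fraction of subjects that are operated.
#' @param longitudinal Allow several sessions per subject.
#' @param seed Integer seed.
#' @param grid_shape,spacing,noise_sd Passed to [phantom_spec()].
#' @param drop_prob Per-landmark probability of being marked missing.
#' @return A list with `samples` (list of [brain_sample()]) and `table`
#'   (data frame of session metadata).
#' @export
make_cohort <- function(n_subjects, ga_range = c(154L, 238L),
                        operated_split = 0.5, longitudinal = TRUE,
                        seed = 1L, grid_shape = c(64L, 64L, 64L),
                        spacing = 0.8, noise_sd = 20, drop_prob = 0.05) {
  stopifnot(n_subjects >= 1)
  ga_range <- validate_ga_days(ga_range)
  if (length(ga_range) != 2L || ga_range[1L] > ga_range[2L])
    stop("'ga_range' must be c(low, high) in days")
  surgery_ga <- 175L  # 25 weeks

  plan <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(si) {
      operated <- stats::runif(1) < operated_split
      lo <- if (operated) max(ga_range[1L], surgery_ga + 1L) else ga_range[1L]
      if (lo > ga_range[2L]) lo <- ga_range[2L]
      n_ses <- if (longitudinal) sample.int(3L, 1L) else 1L
      ga0 <- round(stats::runif(1, lo, ga_range[2L]))
      gas <- unique(pmin(ga_range[2L],
                         ga0 + round(cumsum(c(0, stats::runif(
                           max(0L, n_ses - 1L), 14, 28))))))
      list(operated = operated, gas = validate_ga_days(gas),
           severity = stats::runif(1, 0.3, 0.9),
           scales = matrix(stats::runif(3L * length(gas), 0.92, 1.08),
                           ncol = 3L),
           trans = matrix(stats::runif(3L * length(gas), -2.5, 2.5),
                          ncol = 3L),
           drops = matrix(stats::runif(length(gas) * 7L) < drop_prob,
                          ncol = 7L))
    })
  })

  samples <- list()
  rows <- list()
  retained <- landmark_registry()$id[landmark_registry()$retained]
  for (si in seq_along(plan)) {
    p <- plan[[si]]
    for (gi in seq_along(p$gas)) {
      base <- make_phantom(phantom_spec(
        ga = p$gas[gi], operated = p$operated, severity = p$severity,
        noise_sd = noise_sd, seed = seed + 1000L * si + gi,
        grid_shape = grid_shape, spacing = spacing))
      pert <- perturb_phantom(
        base, scale = p$scales[gi, ], translation = p$trans[gi, ],
        drop_landmarks = retained[p$drops[gi, ]],
        seed = seed + 2000L * si + gi)
      smp <- pert$sample
      smp$meta$subject_id <- sprintf("sub-%02d", si)
      smp$meta$session_id <- sprintf("ses-%d", gi)
      samples[[length(samples) + 1L]] <- smp
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = smp$meta$subject_id, session_id = smp$meta$session_id,
        ga = p$gas[gi], ga_weeks = p$gas[gi] %/% 7L,
        ga_days = p$gas[gi] %% 7L, operated = p$operated,
        severity = p$severity)
    }
  }
  list(samples = samples, table = do.call(rbind, rows))
}

# Run code with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
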
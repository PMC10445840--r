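#' Read and write NIfTI volumes
#'
#' `read_volume()` loads a NIfTI-1/2 file, reorients it to canonical RAS
#' (so the first voxel axis runs left to right and the central sagittal
#' plane is the x mid-plane of the grid), and returns an [image_volume()].
#' `write_volume()` writes one back; data round-trip exactly (double
#' precision) and the affine to better than 1e-5 mm.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol An [image_volume()].
#' @return `read_volume()` returns an `image_volume`; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4L] == 1L)
    dim(dat) <- dim(dat)[1:3]
  image_volume(dat, aff)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  spacing <- vol$spacing
  hdr <- list(pixdim = c(-1, spacing, 0, 0, 0, 0))
  img <- RNifti::asNifti(vol$data, reference = hdr, datatype = "double")
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write landmark files
#'
#' Two dialects are supported.  The *labelmap* dialect is an integer NIfTI
#' volume in which voxels of value `v` mark landmark `v` of the registry
#' (labels 1--11, 0 = background); raters may mark a small blob, so the
#' landmark position is the physical centroid of its labelled voxels.  The
#' *tsv* dialect is a tab-separated table with columns `id`, `x_mm`, `y_mm`,
#' `z_mm`.  Landmarks absent from the file are returned as missing.
#'
#' @param path File path.
#' @param registry Landmark registry (default [landmark_registry()]).
#' @param dialect `"labelmap"` or `"tsv"`; `read_landmarks()` guesses from
#'   the file extension when omitted.
#' @param lmks A [landmark_set()] to write.
#' @param reference For writing the labelmap dialect: an [image_volume()]
#'   defining the output grid (each landmark is written as the single voxel
#'   nearest to its coordinates).
#' @return `read_landmarks()` returns a [landmark_set()] covering all
#'   registry ids.
#' @export
read_landmarks <- function(path, registry = landmark_registry(),
                           dialect = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.nii(\\.gz)?$", path)) "labelmap" else "tsv"
  dialect <- match.arg(dialect, c("labelmap", "tsv"))
  coords <- matrix(NA_real_, nrow(registry), 3L,
                   dimnames = list(registry$id, NULL))
  if (dialect == "labelmap") {
    vol <- read_volume(path)
    labs <- round(vol$data)
    present <- sort(unique(labs[labs > 0]))
    if (length(setdiff(present, registry$label)))
      stop("label value outside the landmark registry: ",
           paste(setdiff(present, registry$label), collapse = ", "))
    for (v in present) {
      idx <- which(labs == v, arr.ind = TRUE) - 1  # 0-based voxel indices
      ctr <- colMeans(voxel_to_world(vol, idx))
      coords[registry$id[registry$label == v], ] <- ctr
    }
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(tab)))
      stop("landmark tsv must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$id)) stop("duplicate landmark id rows in ", path)
    if (length(setdiff(tab$id, registry$id)))
      stop("unknown landmark id(s): ",
           paste(setdiff(tab$id, registry$id), collapse = ", "))
    keep <- stats::complete.cases(tab[, c("x_mm", "y_mm", "z_mm")])
    coords[tab$id[keep], ] <- as.matrix(tab[keep, c("x_mm", "y_mm", "z_mm")])
  }
  landmark_set(coords, registry)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lmks, path, registry = landmark_registry(),
                            dialect = c("tsv", "labelmap"),
                            reference = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- data.frame(id = rownames(lmks), x_mm = lmks[, 1L],
                      y_mm = lmks[, 2L], z_mm = lmks[, 3L])
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(reference))
      stop("labelmap dialect needs a reference volume for the grid")
    lab <- array(0, dim(reference$data))
    pres <- present_landmarks(lmks)
    vox <- round(world_to_voxel(reference, unclass(lmks)[pres, ,
                                                         drop = FALSE]))
    d <- dim(lab)
    for (i in seq_along(pres)) {
      v <- pmin(pmax(vox[i, ], 0), d - 1) + 1
      lab[v[1L], v[2L], v[3L]] <-
        registry$label[registry$id == pres[i]]
    }
    write_volume(image_volume(lab, reference$affine), path)
  }
  invisible(path)
}

#' Read a cohort table
#'
#' The cohort table is a tab-separated file with one row per MRI session and
#' columns `subject_id`, `session_id`, `ga_weeks`, `ga_days`, `operated`
#' plus file paths `image`, `mask`, `landmarks` and (optionally) `probmaps`
#' (a directory of per-class NIfTI maps or a single multi-label
#' parcellation).  Relative paths are resolved against the table's
#' directory.
#'
#' @param path Path to the TSV.
#' @param load Load the referenced files into [brain_sample()] objects
#'   (default) or return the parsed table only.
#' @return A list with `table` (data frame, with `ga` in days) and, when
#'   `load = TRUE`, `samples` (list of `brain_sample`).
#' @export
read_cohort <- function(path, load = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "ga_weeks", "ga_days", "operated",
            "image", "mask", "landmarks")
  if (!all(need %in% names(tab)))
    stop("cohort table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[, c("subject_id", "session_id")]))
    stop("(subject_id, session_id) pairs must be unique")
  tab$ga <- mapply(ga_from_weeks_days, tab$ga_weeks, tab$ga_days)
  tab$operated <- as.logical(tab$operated)
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p),
                                p, file.path(root, p))
  out <- list(table = tab)
  if (load) {
    out$samples <- lapply(seq_len(nrow(tab)), function(i) {
      probs <- NULL
      if (!is.null(tab$probmaps) && !is.na(tab$probmaps[i]) &&
          nzchar(tab$probmaps[i])) {
        pv <- read_volume(resolve(tab$probmaps[i]))
        probs <- probmaps_from_labels(pv)
      }
      brain_sample(
        meta = list(subject_id = tab$subject_id[i],
                    session_id = tab$session_id[i],
                    ga = tab$ga[i], operated = tab$operated[i]),
        image = read_volume(resolve(tab$image[i])),
        mask = read_volume(resolve(tab$mask[i])),
        landmarks = read_landmarks(resolve(tab$landmarks[i])),
        probmaps = probs)
    })
  }
  out
}

#' Pipeline configuration
#'
#' All tunable pipeline parameters with their default values.  Defaults
#' correspond to the published atlas-construction settings: temporal kernel
#' sd 3 days with a 9-day (3 sigma) inclusion window, minimum group size 3,
#' whole-week time points over 21--34 weeks, regularization weights
#' `alpha_be = 0.1` and `alpha_le = 0.3`, landmark weight
#' `alpha_lmks = 0.001`, LNCC kernel sd 6 mm, B-spline control-point spacing
#' 3 mm and a 3-level registration pyramid.  `alpha_lncc` is always derived
#' as `(1 - alpha_lmks) * (1 - alpha_be - alpha_le)`.
#'
#' @param ... Named overrides of the defaults listed above (see
#'   `pipeline_config()` for the full set).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sigma_days = 3,
    window_days = 9,
    min_group_size = 3,
    week_range = c(21L, 34L),
    alpha_be = 0.1,
    alpha_le = 0.3,
    alpha_lmks = 0.001,
    lncc_kernel_sd_mm = 6,
    grid_spacing_mm = 3,
    pyramid_levels = 3L,
    optim_iter = c(40L, 30L, 20L),
    refinement_iterations = 2L,
    agreement_radius_mm = sqrt(3) * 0.8,
    wgp_tol = 1e-10,
    wgp_max_iter = 100L,
    atlas_pad_voxels = 5L,
    seed = 1L,
    output_dir = "atlas"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num <- c("sigma_days", "window_days", "min_group_size", "alpha_lmks",
           "lncc_kernel_sd_mm", "grid_spacing_mm", "pyramid_levels",
           "refinement_iterations", "agreement_radius_mm", "wgp_tol",
           "wgp_max_iter")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
      stop("config field '", f, "' must be positive")
  for (f in c("alpha_be", "alpha_le"))
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0))
      stop("config field '", f, "' must be non-negative")
  if (cfg$alpha_be + cfg$alpha_le >= 1)
    stop("alpha_be + alpha_le must be < 1")
  if (cfg$alpha_lmks >= 1) stop("alpha_lmks must be < 1")
  if (length(cfg$week_range) != 2L || cfg$week_range[1L] > cfg$week_range[2L])
    stop("week_range must be c(low, high)")
  structure(cfg, class = "pipeline_config")
}

#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @rdname pipeline_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @export
alpha_lncc <- function(cfg) {
  (1 - cfg$alpha_lmks) * (1 - cfg$alpha_be - cfg$alpha_le)
}
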
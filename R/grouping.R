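#' Truncated temporal Gaussian kernel weight
#'
#' Weight of a volume's contribution to an atlas time point, as a Gaussian
#' kernel in the gestational-age difference, truncated to zero strictly
#' beyond 3 sigma (with the default sigma of 3 days this gives the 9-day
#' inclusion window).  A missing landmark forces the weight to zero, which
#' is how missing annotations enter the weighted Procrustes problem.
#'
#' @param ga,target Gestational ages in days.
#' @param sigma_days Kernel standard deviation in days (default 3).
#' @param landmark_present Set `FALSE` to zero the weight (missing
#'   annotation).
#' @return Non-negative scalar weight
#'   \eqn{\frac{1}{\sqrt{2\pi}\sigma} e^{-\frac{1}{2}
#'   (\Delta GA/\sigma)^2}}, or 0 beyond the window.
#' @examples
#' kernel_weight(ga_from_weeks_days(24), ga_from_weeks_days(24))  # 0.1329808
#' kernel_weight(178, 168)  # 0: 10 days exceeds the 9-day window
#' @export
kernel_weight <- function(ga, target, sigma_days = 3,
                          landmark_present = TRUE) {
  stopifnot(sigma_days > 0)
  if (!isTRUE(landmark_present)) return(0)
  delta <- as.numeric(ga) - as.numeric(target)
  if (abs(delta) > 3 * sigma_days) return(0)
  exp(-0.5 * (delta / sigma_days)^2) / (sqrt(2 * pi) * sigma_days)
}

#' Build gestational-age / operation-status groups
#'
#' Candidate groups are formed at each whole week of `config$week_range`,
#' separately for operated and non-operated sessions.  A session joins a
#' candidate group when its gestational age is within `config$window_days`
#' (default 9 days, i.e. 3 sigma) of the group's target age; its
#' contribution is weighted by [kernel_weight()].  A candidate group is
#' retained only if (i) it has at least `config$min_group_size` members
#' before flip augmentation, and (ii) it contains members both strictly
#' above and strictly below the target age (bracketing rule, so a time
#' point is never extrapolated from one side).
#'
#' @param cohort A list with `samples` (list of [brain_sample()]), e.g. from
#'   [make_cohort()] or [read_cohort()].
#' @param config A [pipeline_config()].
#' @return A list of `atlas_group` objects, each with `target_ga` (days),
#'   `operated`, `members` (list of samples), `weights` and `augmented`
#'   (logical per member).  May be empty.
#' @export
build_groups <- function(cohort, config = pipeline_config()) {
  samples <- cohort$samples
  if (!length(samples)) stop("empty cohort")
  gas <- vapply(samples, function(s) as.numeric(s$meta$ga), 0)
  ops <- vapply(samples, function(s) isTRUE(s$meta$operated), NA)
  # order-independence: process members in (ga, subject, session) order
  ord <- order(gas,
               vapply(samples, function(s) s$meta$subject_id, ""),
               vapply(samples, function(s) s$meta$session_id, ""))
  samples <- samples[ord]; gas <- gas[ord]; ops <- ops[ord]

  groups <- list()
  for (week in seq(config$week_range[1L], config$week_range[2L])) {
    target <- 7 * week
    for (op in c(FALSE, TRUE)) {
      sel <- which(ops == op & abs(gas - target) <= config$window_days)
      if (length(sel) < config$min_group_size) next
      if (!any(gas[sel] > target) || !any(gas[sel] < target)) next
      w <- vapply(gas[sel], kernel_weight, 0, target = target,
                  sigma_days = config$sigma_days)
      keep <- w > 0
      groups[[length(groups) + 1L]] <- structure(
        list(target_ga = as.integer(target), operated = op,
             members = samples[sel[keep]], weights = w[keep],
             augmented = rep(FALSE, sum(keep))),
        class = "atlas_group")
    }
  }
  groups
}

#' Flip-augment a group
#'
#' Duplicates every member as its left-right mirrored copy
#' ([flip_sample()]), with the same temporal weight and `augmented = TRUE`.
#' Flip augmentation synthetically doubles the group and encourages the
#' atlas to be symmetric about the central sagittal plane.
#'
#' @param group An `atlas_group` from [build_groups()].
#' @param registry Landmark registry (mirror-partner mapping).
#' @return The augmented `atlas_group`.
#' @export
augment_group <- function(group, registry = landmark_registry()) {
  stopifnot(inherits(group, "atlas_group"))
  flipped <- lapply(group$members, flip_sample)
  structure(
    list(target_ga = group$target_ga, operated = group$operated,
         members = c(group$members, flipped),
         weights = c(group$weights, group$weights),
         augmented = c(group$augmented, rep(TRUE, length(flipped)))),
    class = "atlas_group")
}

#' @param x An `atlas_group`.
#' @param ... Ignored.
#' @rdname build_groups
#' @export
print.atlas_group <- function(x, ...) {
  cat(sprintf("<atlas_group> %s %s: %d members (%d augmented)\n",
              format_ga(x$target_ga),
              if (x$operated) "operated" else "non-operated",
              length(x$members), sum(x$augmented)))
  invisible(x)
}

#' Dump a group manifest
#'
#' @param group An `atlas_group`.
#' @param path Optional TSV path; when `NULL` the manifest data frame is
#'   returned.
#' @rdname build_groups
#' @export
group_manifest <- function(group, path = NULL) {
  tab <- data.frame(
    subject_id = vapply(group$members, function(s) s$meta$subject_id, ""),
    session_id = vapply(group$members, function(s) s$meta$session_id, ""),
    ga_days = vapply(group$members, function(s) as.integer(s$meta$ga), 0L),
    weight = group$weights,
    augmented = group$augmented)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  tab
}
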
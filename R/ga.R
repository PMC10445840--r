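#' Gestational age helpers
#'
#' Gestational age (GA) is stored throughout the package as a single
#' non-negative integer number of days.  Clinical notation uses
#' "weeks + days" (e.g. 24w+3d); these helpers convert between the two
#' representations exactly.  Whole-week atlas time points use
#' `days = 7 * week`.
#'
#' @param weeks Completed weeks of gestation (non-negative integer).
#' @param extra_days Additional days, 0--6.
#' @return `ga_from_weeks_days()` returns the total number of days as an
#'   integer; `ga_to_weeks_days()` returns a list with elements `weeks` and
#'   `days`; `format_ga()` returns a string such as `"24w+3d"`.
#' @examples
#' ga_from_weeks_days(24, 0)  # 168
#' ga_from_weeks_days(22, 4)  # 158
#' ga_to_weeks_days(178)      # list(weeks = 25, days = 3)
#' @export
ga_from_weeks_days <- function(weeks, extra_days = 0L) {
  weeks <- as.integer(weeks)
  extra_days <- as.integer(extra_days)
  if (any(is.na(weeks)) || any(weeks < 0L))
    stop("'weeks' must be a non-negative integer")
  if (any(is.na(extra_days)) || any(extra_days < 0L) || any(extra_days > 6L))
    stop("'extra_days' must be an integer in 0..6")
  days <- 7L * weeks + extra_days
  validate_ga_days(days)
  days
}

#' @param days Total gestational age in days.
#' @rdname ga_from_weeks_days
#' @export
ga_to_weeks_days <- function(days) {
  days <- validate_ga_days(days)
  list(weeks = days %/% 7L, days = days %% 7L)
}

#' @rdname ga_from_weeks_days
#' @export
format_ga <- function(days) {
  wd <- ga_to_weeks_days(days)
  sprintf("%dw+%dd", wd$weeks, wd$days)
}

# GA sanity bound: 320 days (~45 weeks) comfortably covers fetal imaging.
validate_ga_days <- function(days) {
  days <- as.integer(days)
  if (any(is.na(days)) || any(days < 0L) || any(days > 320L))
    stop("gestational age must be an integer number of days in 0..320")
  days
}
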
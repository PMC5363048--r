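#' Interpolate a measurement series onto a weekly grid
#'
#' Linear interpolation of one child's irregular (age, value)
#' measurements onto integer weeks, from the first to the last
#' measured age. No extrapolation: the grid runs from the ceiling of
#' the first measurement age to the floor of the last, and every value
#' lies between its two bracketing measurements. Fractional measurement
#' ages are used exactly; only the output grid is integer.
#'
#' @param age_weeks measurement ages in weeks (strictly increasing), or
#'   a data.frame with columns `age_weeks` and `value`.
#' @param value measurement values (ignored when `age_weeks` is a
#'   data.frame).
#' @param child_id,measure optional labels carried on the result.
#' @return object of class `"weekly_curve"`: list with `child_id`,
#'   `measure`, `first_week`, `last_week`, and `values` (one value per
#'   integer week from `first_week` to `last_week`).
#' @examples
#' wc <- interpolate_weekly(c(0, 10), c(34, 39))
#' wc$values[6]  # week 5: midpoint 36.5
#' @export
interpolate_weekly <- function(age_weeks, value = NULL, child_id = NA,
                               measure = NA) {
  if (is.data.frame(age_weeks)) {
    df <- age_weeks
    if (is.na(child_id) && !is.null(df$child_id)) child_id <- df$child_id[1]
    if (is.na(measure) && !is.null(df$measure)) measure <- df$measure[1]
    value <- df$value
    age_weeks <- df$age_weeks
  }
  if (length(age_weeks) < 2)
    stop("interpolate_weekly: need at least 2 measurements to interpolate",
         call. = FALSE)
  if (is.unsorted(age_weeks, strictly = TRUE))
    stop("interpolate_weekly: ages must be strictly increasing")
  first_week <- as.integer(ceiling(age_weeks[1]))
  last_week <- as.integer(floor(age_weeks[length(age_weeks)]))
  values <- if (last_week < first_week) numeric(0) else
    approx(age_weeks, value, xout = first_week:last_week,
           method = "linear", ties = "ordered")$y
  structure(list(child_id = child_id, measure = measure,
                 first_week = first_week, last_week = last_week,
                 values = values),
            class = "weekly_curve")
}

#' @export
print.weekly_curve <- function(x, ...) {
  cat("Weekly curve", if (!is.na(x$child_id)) paste0("[", x$child_id, ", ",
                                                     x$measure, "]"),
      "weeks", x$first_week, "to", x$last_week,
      sprintf("(%d values)\n", length(x$values)))
  invisible(x)
}
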
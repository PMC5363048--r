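#' Bin a weekly curve into 3-month age points
#'
#' Bin 0 (birth) carries the raw birth measurement when one exists
#' (HC and weight only; height is not measured at birth). Each later
#' bin at m months averages the interpolated weekly values in a
#' 13-week window centred on the nearest integer week to
#' `m * 4.348` weeks, intersected with the curve's measured span;
#' bins whose window misses the span entirely are absent.
#'
#' @param curve a `"weekly_curve"` from [interpolate_weekly()].
#' @param birth_value raw birth measurement (age < 1 week), or `NULL`.
#' @param bin_months bin centres in months (default 0 to 24 by 3).
#' @return data.frame with columns `child_id`, `measure`,
#'   `bin_age_months`, `value`, `n_weeks_used` (0 rows if nothing is
#'   covered).
#' @export
bin_curve <- function(curve, birth_value = NULL, bin_months = BIN_MONTHS) {
  stopifnot(inherits(curve, "weekly_curve"))
  rows <- list()
  for (m in bin_months) {
    if (m == 0) {
      if (!is.null(birth_value) && is.finite(birth_value))
        rows[[length(rows) + 1L]] <- c(bin = 0, value = birth_value, n = 1)
      next
    }
    center <- as.integer(round(months_to_weeks(m)))
    wks <- max(center - 6L, curve$first_week):min(center + 6L,
                                                  curve$last_week)
    if (!length(wks) || wks[1] > wks[length(wks)]) next
    idx <- wks - curve$first_week + 1L
    rows[[length(rows) + 1L]] <- c(bin = m,
                                   value = mean(curve$values[idx]),
                                   n = length(idx))
  }
  if (!length(rows))
    return(data.frame(child_id = character(0), measure = character(0),
                      bin_age_months = numeric(0), value = numeric(0),
                      n_weeks_used = integer(0)))
  m <- do.call(rbind, rows)
  data.frame(child_id = curve$child_id, measure = curve$measure,
             bin_age_months = m[, "bin"], value = m[, "value"],
             n_weeks_used = as.integer(m[, "n"]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Interpolate and bin every child in a cohort
#'
#' Runs [interpolate_weekly()] and [bin_curve()] on every child x
#' measure series. A child with a single measurement for a measure
#' cannot be interpolated; if that single point is a birth measurement
#' it still populates bin 0.
#'
#' @param x a [cohort()].
#' @param measures measures to process.
#' @return data.frame of binned values (see [bin_curve()]).
#' @export
bin_cohort <- function(x, measures = MEASURES) {
  stopifnot(inherits(x, "cohort"))
  out <- list()
  for (m in measures) {
    for (id in x$children$child_id) {
      s <- child_series(x, id, m)
      if (!nrow(s)) next
      birth <- if (m != "height" && s$age_weeks[1] < 1) s$value[1] else NULL
      if (nrow(s) >= 2) {
        curve <- interpolate_weekly(s$age_weeks, s$value, child_id = id,
                                    measure = m)
        out[[length(out) + 1L]] <- bin_curve(curve, birth_value = birth)
      } else if (!is.null(birth)) {
        out[[length(out) + 1L]] <- data.frame(
          child_id = id, measure = m, bin_age_months = 0,
          value = birth, n_weeks_used = 1L, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Welch two-sample t-test
#'
#' Two-tailed two-sample t-test with unequal variances:
#' \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom. Degenerate conventions:
#' when both samples have zero variance, t = 0 and p = 1 if the means
#' are equal, otherwise t is signed infinite with p = 0.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `t_stat`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    stop("welch_t_test: need at least 2 finite values per group",
         call. = FALSE)
  vx <- var(x); vy <- var(y)
  mx <- mean(x); my <- mean(y)
  if (vx == 0 && vy == 0) {
    if (mx == my)
      return(list(t_stat = 0, df = nx + ny - 2, p_value = 1,
                  mean_x = mx, mean_y = my))
    return(list(t_stat = sign(mx - my) * Inf, df = nx + ny - 2,
                p_value = 0, mean_x = mx, mean_y = my))
  }
  se2 <- vx / nx + vy / ny
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df),
       mean_x = mx, mean_y = my)
}

#' Binned group comparison of growth measures
#'
#' For each measure and 3-month age bin, compares autism vs control
#' binned values with a two-tailed Welch t-test. Children lacking
#' coverage of a bin are excluded from that bin only (pairwise
#' deletion). With `stratify_by_module = TRUE` each ADOS-module
#' stratum of the autism group is compared against the full control
#' group. p-values are deliberately uncorrected; the optional `fdr`
#' flag appends a Benjamini-Hochberg column without altering the
#' primary columns.
#'
#' @param x a [cohort()].
#' @param stratify_by_module split the autism group by ADOS module.
#' @param males_only restrict both groups to male children.
#' @param binned precomputed output of [bin_cohort()] (computed if
#'   `NULL`).
#' @param fdr append a `p_adj` Benjamini-Hochberg column.
#' @return data.frame: `measure`, `bin_age_months` (and `stratum` when
#'   stratified), `mean_case`, `mean_control`, `diff` (case minus
#'   control), `t_stat`, `df`, `p_value`, `n_case`, `n_control`,
#'   `significant` ("*" when p < 0.05). Bins with fewer than 2
#'   children in a group get `NA` test columns with a warning.
#' @export
compare_bins <- function(x, stratify_by_module = FALSE, males_only = FALSE,
                         binned = NULL, fdr = FALSE) {
  stopifnot(inherits(x, "cohort"))
  ch <- x$children
  if (males_only) ch <- ch[ch$sex == "male", , drop = FALSE]
  if (is.null(binned)) binned <- bin_cohort(x)
  binned <- binned[binned$child_id %in% ch$child_id, , drop = FALSE]
  binned$group <- ch$group[match(binned$child_id, ch$child_id)]

  strata <- if (stratify_by_module) ADOS_MODULES else "all"
  out <- list()
  for (m in unique(binned$measure)) {
    bm <- binned[binned$measure == m, ]
    for (b in sort(unique(bm$bin_age_months))) {
      bb <- bm[bm$bin_age_months == b, ]
      ctrl <- bb$value[bb$group == "control"]
      for (st in strata) {
        case_ids <- if (st == "all") ch$child_id[ch$group == "autism"] else
          ch$child_id[ch$group == "autism" &
                        !is.na(ch$ados_module) & ch$ados_module == st]
        case <- bb$value[bb$group == "autism" & bb$child_id %in% case_ids]
        row <- data.frame(
          measure = m, bin_age_months = b,
          mean_case = if (length(case)) mean(case) else NA_real_,
          mean_control = if (length(ctrl)) mean(ctrl) else NA_real_,
          diff = NA_real_, t_stat = NA_real_, df = NA_real_,
          p_value = NA_real_,
          n_case = length(case), n_control = length(ctrl),
          stringsAsFactors = FALSE)
        if (stratify_by_module) row <- cbind(stratum = st, row,
                                             stringsAsFactors = FALSE)
        if (length(case) >= 2 && length(ctrl) >= 2) {
          w <- welch_t_test(case, ctrl)
          row$diff <- w$mean_x - w$mean_y
          row$t_stat <- w$t_stat; row$df <- w$df; row$p_value <- w$p_value
        } else {
          row$diff <- row$mean_case - row$mean_control
          warning("compare_bins: fewer than 2 children in a group for ",
                  m, " at ", b, " months",
                  if (stratify_by_module) paste0(" (stratum ", st, ")"),
                  call. = FALSE)
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, out)
  out$significant <- ifelse(!is.na(out$p_value) & out$p_value < 0.05, "*", "")
  if (fdr) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
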
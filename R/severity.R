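#' Correlate binned head circumference with ADOS severity
#'
#' Within the autism group (controls carry no ADOS scores), computes
#' the Pearson correlation between each child's binned HC value and
#' their ADOS total score and calibrated severity score (CSS), per age
#' bin, with a two-tailed p-value from the t approximation
#' (`stats::cor.test`). p-values are deliberately uncorrected.
#'
#' @param x a [cohort()] containing autism children with ADOS scores.
#' @param binned precomputed [bin_cohort()] output (computed if `NULL`).
#' @return data.frame: `bin_age_months`, `score_kind` ("ados_total" or
#'   "ados_css"), `r`, `p_value`, `n`. Bins with fewer than 3 scored
#'   children get `NA` r/p with a warning.
#' @export
correlate_severity <- function(x, binned = NULL) {
  stopifnot(inherits(x, "cohort"))
  ch <- x$children[x$children$group == "autism", , drop = FALSE]
  if (!nrow(ch)) stop("correlate_severity: no autism children in cohort")
  if (is.null(binned)) binned <- bin_cohort(x, measures = "hc")
  hc <- binned[binned$measure == "hc" & binned$child_id %in% ch$child_id, ]

  out <- list()
  for (b in sort(unique(hc$bin_age_months))) {
    bb <- hc[hc$bin_age_months == b, ]
    for (kind in c("ados_total", "ados_css")) {
      score <- ch[[kind]][match(bb$child_id, ch$child_id)]
      keep <- is.finite(bb$value) & is.finite(score)
      n <- sum(keep)
      if (n >= 3 && sd(bb$value[keep]) > 0 && sd(score[keep]) > 0) {
        ct <- cor.test(bb$value[keep], score[keep], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
        warning("correlate_severity: fewer than 3 usable children (or no ",
                "variance) for ", kind, " at ", b, " months", call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        bin_age_months = b, score_kind = kind, r = r, p_value = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
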
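#' Construct a cohort object
#'
#' A cohort bundles child-level metadata with long-format measurement
#' series. `children` has one row per child; `measurements` one row per
#' child x visit x measure. Use [validate_cohort()] (called here by
#' default) to enforce the design invariants: matched same-sex pairs
#' born within 30 days of each other, ADOS scores present exactly for
#' the autism group, strictly increasing measurement ages, no height at
#' birth, and ages within the 0--115 week study window.
#'
#' @param children data.frame with columns `child_id`, `group`
#'   ("autism"/"control"), `sex` ("male"/"female"), `pair_id`,
#'   `birth_offset_days`, `ados_module`, `ados_total`, `ados_css`,
#'   `age_at_diagnosis_months` (ADOS and diagnosis columns are `NA` for
#'   controls).
#' @param measurements data.frame with columns `child_id`, `measure`
#'   ("hc"/"weight"/"height"), `age_weeks`, `value` (cm for hc/height,
#'   kg for weight).
#' @param provenance "synthetic" or "file".
#' @param seed integer seed used to generate the cohort, or `NULL`.
#' @param validate validate invariants on construction (default `TRUE`).
#' @return an object of class `"cohort"`.
#' @seealso [generate_cohort()], [read_cohort()], [write_cohort()]
#' @export
cohort <- function(children, measurements, provenance = c("file", "synthetic"),
                   seed = NULL, validate = TRUE) {
  provenance <- match.arg(provenance)
  obj <- structure(
    list(children = as.data.frame(children),
         measurements = as.data.frame(measurements),
         provenance = provenance,
         seed = seed),
    class = "cohort")
  if (validate) obj <- validate_cohort(obj, strict = TRUE)
  obj
}

CHILD_COLS <- c("child_id", "group", "sex", "pair_id", "birth_offset_days",
                "ados_module", "ados_total", "ados_css",
                "age_at_diagnosis_months")
MEAS_COLS <- c("child_id", "measure", "age_weeks", "value")

MAX_AGE_WEEKS <- 115

#' Validate a cohort against its design invariants
#'
#' Checks the matched-pair structure (each pair joins exactly one autism
#' and one control child of the same sex, `|birth_offset_days| <= 30`),
#' the ADOS columns (present iff autism; totals in 1--28, calibrated
#' severity in 1--10), and the measurement series (strictly increasing
#' ages per child x measure, positive values, ages within 0--115 weeks,
#' no height point before 1 week of age, all `child_id`s resolvable).
#'
#' @param x a [cohort()] object.
#' @param strict if `TRUE` (default) any violation aborts with an
#'   informative error; if `FALSE`, offending measurement rows and
#'   children with invalid metadata (with their pair partners and
#'   series) are dropped, and the counts are reported in a message and
#'   attached as the `"dropped"` attribute.
#' @return the validated (possibly pruned) cohort.
#' @export
validate_cohort <- function(x, strict = TRUE) {
  stopifnot(inherits(x, "cohort"))
  ch <- x$children
  ms <- x$measurements

  miss_c <- setdiff(CHILD_COLS, names(ch))
  miss_m <- setdiff(MEAS_COLS, names(ms))
  if (length(miss_c) || length(miss_m))
    stop("cohort format error: missing column(s) ",
         paste(c(miss_c, miss_m), collapse = ", "))

  fail <- function(...) stop("cohort validation error: ", ..., call. = FALSE)
  bad_child <- character(0)
  bad_meas <- logical(nrow(ms))
  note <- function(msg, ids) {
    if (strict) fail(msg, ": ", paste(utils::head(ids, 5), collapse = ", "))
    bad_child <<- union(bad_child, ids)
  }

  if (anyDuplicated(ch$child_id))
    fail("duplicate child_id in children table")

  ok_group <- ch$group %in% c("autism", "control")
  if (any(!ok_group)) note("invalid group label", ch$child_id[!ok_group])
  ok_sex <- ch$sex %in% c("male", "female")
  if (any(!ok_sex)) note("invalid sex label", ch$child_id[!ok_sex])

  is_aut <- ch$group == "autism"
  has_ados <- !is.na(ch$ados_total) | !is.na(ch$ados_css) |
    !is.na(ch$ados_module)
  full_ados <- !is.na(ch$ados_total) & !is.na(ch$ados_css) &
    !is.na(ch$ados_module)
  wrong <- (is_aut & !full_ados) | (!is_aut & has_ados)
  wrong[is.na(wrong)] <- TRUE
  if (any(wrong))
    note("ADOS fields must be present iff group is autism",
         ch$child_id[wrong])

  bad_rng <- (!is.na(ch$ados_total) & (ch$ados_total < 1 | ch$ados_total > 28)) |
    (!is.na(ch$ados_css) & (ch$ados_css < 1 | ch$ados_css > 10)) |
    (!is.na(ch$ados_module) & !(ch$ados_module %in% ADOS_MODULES))
  if (any(bad_rng)) note("ADOS score out of range", ch$child_id[bad_rng])

  bad_off <- is.na(ch$birth_offset_days) | abs(ch$birth_offset_days) > 30
  if (any(bad_off))
    note("matched-pair birth offset exceeds 30 days", ch$child_id[bad_off])

  # pair structure: exactly one case + one control, same sex
  for (p in unique(ch$pair_id)) {
    sub <- ch[ch$pair_id == p, ]
    if (nrow(sub) != 2 ||
        !identical(sort(as.character(sub$group)), c("autism", "control")) ||
        length(unique(sub$sex)) != 1)
      note(paste0("pair ", p,
                  " must join one autism and one control child of the same sex"),
           sub$child_id)
  }

  unresolved <- !(ms$child_id %in% ch$child_id)
  if (any(unresolved)) {
    if (strict)
      stop("cohort reference error: measurement rows with unresolvable ",
           "child_id: ", paste(unique(ms$child_id[unresolved]), collapse = ", "),
           call. = FALSE)
    bad_meas <- bad_meas | unresolved
  }

  bad_val <- !is.finite(ms$value) | ms$value <= 0 |
    !is.finite(ms$age_weeks) | ms$age_weeks < 0 |
    ms$age_weeks > MAX_AGE_WEEKS |
    !(ms$measure %in% MEASURES)
  if (any(bad_val, na.rm = TRUE)) {
    if (strict)
      fail("measurement with nonpositive value, out-of-range age or ",
           "unknown measure for child ",
           paste(unique(ms$child_id[bad_val]), collapse = ", "))
    bad_meas <- bad_meas | bad_val
  }

  bad_ht <- ms$measure == "height" & ms$age_weeks < 1
  if (any(bad_ht, na.rm = TRUE)) {
    if (strict)
      fail("height measured before 1 week of age (height is not measured ",
           "at birth) for child ",
           paste(unique(ms$child_id[bad_ht]), collapse = ", "),
           " at row ", paste(which(bad_ht), collapse = ", "))
    bad_meas <- bad_meas | bad_ht
  }

  key <- interaction(ms$child_id, ms$measure, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    a <- ms$age_weeks[idx]
    if (is.unsorted(a, strictly = TRUE)) {
      o <- order(a)
      if (anyDuplicated(a)) {
        if (strict)
          fail("duplicate or non-increasing ages within series ", k)
        bad_meas[idx[duplicated(a[o])[order(o)]]] <- TRUE
      } else {
        # reorderable: sorting is a formatting fix, not data loss
        ms[idx, ] <- ms[idx[o], ]
      }
    }
  }

  if (!strict && (length(bad_child) || any(bad_meas))) {
    drop_pairs <- unique(ch$pair_id[ch$child_id %in% bad_child])
    drop_children <- ch$child_id[ch$pair_id %in% drop_pairs]
    n_ch <- length(drop_children)
    ch <- ch[!(ch$child_id %in% drop_children), , drop = FALSE]
    bad_meas <- bad_meas | ms$child_id %in% drop_children
    n_ms <- sum(bad_meas)
    ms <- ms[!bad_meas, , drop = FALSE]
    if (n_ch + n_ms > 0)
      message("validate_cohort: dropped ", n_ch, " children and ",
              n_ms, " measurement rows violating invariants")
    x$children <- ch
    x$measurements <- ms
    attr(x, "dropped") <- c(children = n_ch, measurements = n_ms)
  } else {
    x$children <- ch
    x$measurements <- ms
  }

  if (strict && sum(x$children$group == "autism") !=
      sum(x$children$group == "control"))
    fail("unequal group sizes break the matched design")
  x
}

#' @export
print.cohort <- function(x, ...) {
  ch <- x$children
  cat("Matched case-control cohort (", x$provenance, ")\n", sep = "")
  cat("  children:    ", nrow(ch), " (",
      sum(ch$group == "autism"), " autism / ",
      sum(ch$group == "control"), " control; ",
      sum(ch$sex == "female"), " female)\n", sep = "")
  cat("  measurements:", nrow(x$measurements), "rows across",
      length(unique(x$measurements$measure)), "measures\n")
  if (!is.null(x$seed)) cat("  seed:        ", x$seed, "\n")
  invisible(x)
}

#' Read a cohort from a directory of CSV files
#'
#' Expects `children.csv` and `measurements.csv` in `path`, in the
#' layout written by [write_cohort()] (UTF-8, comma-separated, header
#' row; empty cells for missing ADOS fields).
#'
#' @param path directory containing the two CSV files.
#' @param strict passed to [validate_cohort()]: abort on any invariant
#'   violation (`TRUE`, default) or drop and count offending rows.
#' @return a validated [cohort()] with provenance `"file"`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  fc <- file.path(path, "children.csv")
  fm <- file.path(path, "measurements.csv")
  if (!file.exists(fc) || !file.exists(fm))
    stop("read_cohort: expected children.csv and measurements.csv under ",
         path)
  ch <- read.csv(fc, stringsAsFactors = FALSE,
                 colClasses = c(child_id = "character",
                                pair_id = "character"))
  ms <- read.csv(fm, stringsAsFactors = FALSE,
                 colClasses = c(child_id = "character"))
  for (col in c("ados_module")) if (col %in% names(ch))
    ch[[col]][!is.na(ch[[col]]) & ch[[col]] == ""] <- NA
  obj <- cohort(ch, ms, provenance = "file", validate = FALSE)
  validate_cohort(obj, strict = strict)
}

#' Write a cohort to a directory of CSV files
#'
#' Emits `children.csv` (sorted by child_id) and `measurements.csv`
#' (sorted by child_id, measure, age_weeks) so output order is
#' deterministic. Missing ADOS fields become empty cells.
#'
#' @param x a [cohort()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("write_cohort: cannot create directory ", path)
  ch <- x$children[order(x$children$child_id), CHILD_COLS, drop = FALSE]
  ms <- x$measurements[order(x$measurements$child_id,
                             x$measurements$measure,
                             x$measurements$age_weeks),
                       MEAS_COLS, drop = FALSE]
  write.csv(ch, file.path(path, "children.csv"), row.names = FALSE, na = "")
  write.csv(ms, file.path(path, "measurements.csv"), row.names = FALSE, na = "")
  invisible(path)
}

# measurement series of one child for one measure, ordered by age
child_series <- function(x, id, measure) {
  ms <- x$measurements
  s <- ms[ms$child_id == id & ms$measure == measure, , drop = FALSE]
  s[order(s$age_weeks), , drop = FALSE]
}
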
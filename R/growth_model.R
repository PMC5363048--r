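#' Evaluate the negative exponential growth model
#'
#' \deqn{y(x) = \alpha + (\beta - \alpha) e^{-\gamma x}}
#' where \eqn{\alpha} is the asymptote (maximum size within the time
#' frame considered), \eqn{\beta} the intercept at birth, and
#' \eqn{\gamma} the rate of growth from birth toward the asymptote.
#'
#' @param params named vector `c(alpha, beta, gamma)` (see
#'   [growth_params()]).
#' @param age_weeks age(s) in weeks, `>= 0`.
#' @return model value(s), same units as alpha/beta.
#' @examples
#' growth_curve(growth_params(50, 35, 0.03), 0)  # 35 at birth
#' @export
growth_curve <- function(params, age_weeks) {
  stopifnot(all(age_weeks >= 0))
  a <- params[["alpha"]]; b <- params[["beta"]]; g <- params[["gamma"]]
  a + (b - a) * exp(-g * age_weeks)
}

#' Fit the growth model to one child's measurements
#'
#' Least-squares fit of the three-parameter negative exponential model
#' to the raw measurement points of a single child and measure (raw
#' points, never interpolated values: interpolation would fabricate
#' observations and inflate n).
#'
#' Initialization: beta0 = first measured value; alpha0 = last measured
#' value + 2% of the value range; gamma0 from the slope of
#' `log(alpha0 - value)` against age over points below alpha0. Bounds:
#' gamma in (1e-6, 1], alpha in (beta0, 3 alpha0]. Levenberg-Marquardt
#' iterations stop when the relative change in the residual sum of
#' squares is below 1e-10 or after 500 iterations.
#'
#' @param age_weeks ages in weeks (>= 4 points), or a data.frame with
#'   `age_weeks` and `value` columns.
#' @param value measurement values.
#' @param child_id,measure optional labels carried on the result.
#' @return object of class `"growth_fit"`: list with `params`
#'   (alpha, beta, gamma), `r_squared` (about the child's own
#'   measurement mean), `residual_ss`, `n_points`, `converged`,
#'   `child_id`, `measure`. On optimizer failure `converged` is
#'   `FALSE` and the parameters are `NA`.
#' @export
fit_growth <- function(age_weeks, value = NULL, child_id = NA, measure = NA) {
  if (is.data.frame(age_weeks)) {
    df <- age_weeks
    if (is.na(child_id) && !is.null(df$child_id)) child_id <- df$child_id[1]
    if (is.na(measure) && !is.null(df$measure)) measure <- df$measure[1]
    value <- df$value
    age_weeks <- df$age_weeks
  }
  n <- length(age_weeks)
  if (n < 4)
    stop("fit_growth: need at least 4 measurements to fit 3 parameters",
         call. = FALSE)
  o <- order(age_weeks)
  x <- age_weeks[o]; y <- value[o]

  b0 <- y[1]
  a0 <- y[n] + 0.02 * diff(range(y))
  below <- y < a0
  g0 <- 0.03
  if (sum(below) >= 2) {
    sl <- coef(lm(log(a0 - y[below]) ~ x[below]))[2]
    if (is.finite(sl) && sl < 0) g0 <- min(1, max(1e-4, -sl))
  }
  start <- c(a = a0, b = b0, g = g0)
  lower <- c(a = b0, b = 1e-6, g = 1e-6)
  upper <- c(a = 3 * a0, b = Inf, g = 1)
  start <- pmin(pmax(start, lower + 1e-9), upper)

  tss <- sum((y - mean(y))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + (b - a) * exp(-g * x),
                      start = as.list(start), lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)

  if (is.null(fit)) {
    params <- c(alpha = NA_real_, beta = NA_real_, gamma = NA_real_)
    rss <- NA_real_; r2 <- NA_real_; conv <- FALSE
  } else {
    cf <- coef(fit)
    params <- c(alpha = unname(cf["a"]), beta = unname(cf["b"]),
                gamma = unname(cf["g"]))
    rss <- sum(resid(fit)^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    conv <- fit$convInfo$isConv &&
      params[["alpha"]] > params[["beta"]] && params[["gamma"]] > 0
  }
  structure(list(child_id = child_id, measure = measure, params = params,
                 r_squared = r2, residual_ss = rss, n_points = n,
                 converged = conv),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth fit%s: alpha=%.3f beta=%.3f gamma=%.5f  R^2=%.4f  n=%d%s\n",
    if (!is.na(x$child_id)) paste0(" [", x$child_id, ", ", x$measure, "]")
    else "",
    x$params[["alpha"]], x$params[["beta"]], x$params[["gamma"]],
    x$r_squared, x$n_points,
    if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Fit the growth model to every child in a cohort
#'
#' Children with fewer than 4 points for a measure are skipped (with a
#' message); the negative exponential model needs at least one more
#' point than parameters.
#'
#' @param x a [cohort()].
#' @param measures measures to fit (default all three).
#' @param sex optional `"male"`/`"female"` filter (e.g. for a
#'   males-only reanalysis).
#' @return data.frame with one row per child x measure: `child_id`,
#'   `measure`, `group`, `alpha`, `beta`, `gamma`, `r_squared`,
#'   `n_points`, `converged`.
#' @export
fit_cohort <- function(x, measures = MEASURES, sex = NULL) {
  stopifnot(inherits(x, "cohort"))
  ch <- x$children
  if (!is.null(sex)) ch <- ch[ch$sex %in% sex, , drop = FALSE]
  rows <- list(); skipped <- 0L
  for (m in measures) {
    for (id in ch$child_id) {
      s <- child_series(x, id, m)
      if (nrow(s) < 4) { skipped <- skipped + 1L; next }
      f <- fit_growth(s$age_weeks, s$value, child_id = id, measure = m)
      rows[[length(rows) + 1L]] <- data.frame(
        child_id = id, measure = m,
        group = ch$group[ch$child_id == id],
        alpha = f$params[["alpha"]], beta = f$params[["beta"]],
        gamma = f$params[["gamma"]], r_squared = f$r_squared,
        n_points = f$n_points, converged = f$converged,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    message("fit_cohort: skipped ", skipped,
            " child-measure series with fewer than 4 points")
  do.call(rbind, rows)
}

#' Compare fitted growth parameters between groups
#'
#' Two-tailed unequal-variance (Welch) t-tests on each fitted parameter
#' (alpha, beta, gamma), per measure, between case and control fits.
#' Nonconverged fits are excluded listwise. p-values are deliberately
#' not corrected for multiple comparisons (sensitivity-first design).
#'
#' @param fits_case,fits_control data.frames as returned by
#'   [fit_cohort()] (the `group` column is ignored; list membership
#'   defines the groups).
#' @return data.frame: `measure`, `parameter`, `mean_case`,
#'   `mean_control`, `diff`, `t_stat`, `df`, `p_value`, `n_case`,
#'   `n_control`.
#' @export
compare_params <- function(fits_case, fits_control) {
  fits_case <- fits_case[fits_case$converged, , drop = FALSE]
  fits_control <- fits_control[fits_control$converged, , drop = FALSE]
  if (!nrow(fits_case) || !nrow(fits_control))
    stop("compare_params: need converged fits in both groups")
  out <- list()
  for (m in intersect(unique(fits_case$measure),
                      unique(fits_control$measure))) {
    fc <- fits_case[fits_case$measure == m, ]
    fk <- fits_control[fits_control$measure == m, ]
    if (nrow(fc) < 2 || nrow(fk) < 2)
      stop("compare_params: fewer than 2 converged fits for measure ", m)
    for (p in c("alpha", "beta", "gamma")) {
      w <- welch_t_test(fc[[p]], fk[[p]])
      out[[length(out) + 1L]] <- data.frame(
        measure = m, parameter = p,
        mean_case = mean(fc[[p]]), mean_control = mean(fk[[p]]),
        diff = mean(fc[[p]]) - mean(fk[[p]]),
        t_stat = w$t_stat, df = w$df, p_value = w$p_value,
        n_case = nrow(fc), n_control = nrow(fk),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
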
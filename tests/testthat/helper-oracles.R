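# Independent oracles used to cross-check the package's own routines.

# nonlinear least-squares oracle: stats::nls with the port algorithm
# (independent of the Levenberg-Marquardt route used by fit_growth)
port_fit <- function(x, y, start = NULL) {
  if (is.null(start))
    start <- list(a = max(y) + 0.02 * diff(range(y)), b = y[1], g = 0.03)
  f <- nls(y ~ a + (b - a) * exp(-g * x), start = start,
           algorithm = "port",
           lower = c(a = y[1], b = 1e-6, g = 1e-6),
           upper = c(a = 3 * start$a, b = Inf, g = 1),
           control = nls.control(maxiter = 500, tol = 1e-12,
                                 warnOnly = TRUE))
  coef(f)
}

# permutation-test p-value for a mean difference, two-sided,
# using the Welch statistic as the test statistic
perm_welch_p <- function(x, y, n_perm = 10000) {
  obs <- abs(welch_t_test(x, y)$t_stat)
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), nx)
    t <- abs(welch_t_test(pool[idx], pool[-idx])$t_stat)
    if (t >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# tiny hand-built valid cohort: two matched pairs, a few measurements
tiny_cohort <- function() {
  children <- data.frame(
    child_id = c("A001", "C001", "A002", "C002"),
    group = c("autism", "control", "autism", "control"),
    sex = c("male", "male", "female", "female"),
    pair_id = c("P001", "P001", "P002", "P002"),
    birth_offset_days = c(10L, 0L, -5L, 0L),
    ados_module = c("module1", NA, "module2", NA),
    ados_total = c(16L, NA, 20L, NA),
    ados_css = c(7L, NA, 8L, NA),
    age_at_diagnosis_months = c(36, NA, 40, NA),
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    child_id = rep(c("A001", "C001", "A002", "C002"), each = 3),
    measure = "hc",
    age_weeks = rep(c(0, 26, 52), 4),
    value = c(34, 43, 46, 35, 43.5, 46.5, 33.8, 42.5, 45.8,
              34.5, 43.2, 46.1),
    stringsAsFactors = FALSE)
  cohort(children, measurements, provenance = "file")
}
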
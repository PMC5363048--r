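test_that("the growth curve evaluates the negative exponential exactly", {
  expect_equal(growth_curve(growth_params(50, 35, 0.03), 0), 35)
  expect_equal(growth_curve(c(alpha = 50, beta = 35, gamma = 0), 57), 35)
  expect_equal(growth_curve(growth_params(49.5, 35, 0.033), 104),
               49.5 - 14.5 * exp(-0.033 * 104), tolerance = 1e-12)
  expect_equal(growth_curve(growth_params(49.5, 35, 0.033), 104), 49.03,
               tolerance = 1e-2)
})

test_that("growth_params enforces an increasing growth parameterization", {
  expect_error(growth_params(30, 35, 0.03), "alpha > beta")
  expect_error(growth_params(50, -1, 0.03), "alpha > beta")
  expect_error(growth_params(50, 35, 0), "alpha > beta|gamma")
  expect_silent(growth_params(0, 0, 0, check = FALSE))
})

test_that("noiseless five-point series are recovered to machine-level accuracy", {
  truth <- growth_params(49.5, 35, 0.033)
  x <- c(0, 13, 26, 52, 104)
  y <- growth_curve(truth, x)
  f <- fit_growth(x, y)
  expect_true(f$converged)
  expect_equal(unname(f$params["alpha"]), 49.5, tolerance = 1e-6)
  expect_equal(unname(f$params["beta"]), 35, tolerance = 1e-6)
  expect_equal(unname(f$params["gamma"]), 0.033, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("fitting fewer than four points is an error", {
  expect_error(fit_growth(c(0, 13, 26), c(35, 40, 43)), "at least 4")
})

test_that("the published control means are fit with R^2 above 0.99", {
  tab <- published_control_means("hc")
  f <- fit_growth(tab$age_weeks, tab$value)
  expect_true(f$converged)
  expect_gt(f$r_squared, 0.99)
  # matches the frozen default-parameter constants
  frozen <- default_growth_params("hc")
  expect_equal(unname(f$params["alpha"]), unname(frozen["alpha"]),
               tolerance = 1e-3)
  expect_equal(unname(f$params["beta"]), unname(frozen["beta"]),
               tolerance = 1e-3)
  expect_equal(unname(f$params["gamma"]), unname(frozen["gamma"]),
               tolerance = 1e-2)
  # birth intercept close to the printed 35 cm
  expect_equal(unname(f$params["beta"]), 35, tolerance = 0.25)
})

test_that("fit agrees with an independent port-algorithm oracle on noisy data", {
  set.seed(7)
  truth <- growth_params(49, 34.5, 0.03)
  x <- sort(c(0, runif(7, 2, 104)))
  y <- growth_curve(truth, x) + rnorm(8, 0, 0.3)
  f <- fit_growth(x, y)
  o <- port_fit(x, y)
  expect_equal(unname(f$params["alpha"]), unname(o["a"]), tolerance = 1e-4)
  expect_equal(unname(f$params["beta"]), unname(o["b"]), tolerance = 1e-4)
  expect_equal(unname(f$params["gamma"]), unname(o["g"]), tolerance = 1e-3)
})

test_that("parameter recovery errors shrink as measurement noise shrinks", {
  truth <- growth_params(49.2, 35.1, 0.031)
  x <- months_to_weeks(c(0, 1, 2, 4, 6, 9, 12, 15, 18, 24))
  err <- sapply(c(0.5, 0.1, 0.01), function(s) {
    set.seed(100 + round(s * 1000))
    e <- replicate(30, {
      y <- growth_curve(truth, x) + rnorm(length(x), 0, s)
      f <- fit_growth(x, y)
      abs(f$params["alpha"] - truth["alpha"])
    })
    median(e)
  })
  expect_true(all(diff(err) < 0))
})

test_that("r_squared is invariant under affine rescaling of the value axis", {
  set.seed(3)
  x <- c(0, 8, 20, 40, 70, 104)
  y <- growth_curve(growth_params(49, 35, 0.03), x) + rnorm(6, 0, 0.3)
  f1 <- fit_growth(x, y)
  f2 <- fit_growth(x, 10 * y + 2)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-6)
})

test_that("converged fits never exceed the constant-mean residual bound", {
  set.seed(9)
  for (i in 1:10) {
    x <- sort(c(0, runif(6, 1, 104)))
    y <- growth_curve(growth_params(49, 35, 0.03), x) + rnorm(7, 0, 1)
    f <- fit_growth(x, y)
    if (f$converged) expect_lte(f$r_squared, 1)
  }
})

test_that("parameter group comparison matches a hand-computed Welch test", {
  mk <- function(ids, a, b, g) data.frame(
    child_id = ids, measure = "hc", group = NA,
    alpha = a, beta = b, gamma = g, r_squared = 0.99, n_points = 8,
    converged = TRUE, stringsAsFactors = FALSE)
  case <- mk(c("A1", "A2", "A3"), c(49, 50, 48), c(34, 35, 33),
             c(0.030, 0.031, 0.029))
  ctrl <- mk(c("C1", "C2", "C3"), c(49.5, 50.5, 48.5), c(35, 36, 34),
             c(0.030, 0.031, 0.029))
  pc <- compare_params(case, ctrl)
  expect_equal(nrow(pc), 3)
  beta_row <- pc[pc$parameter == "beta", ]
  # hand Welch: means 34 vs 35, equal variances 1, n = 3
  expect_equal(beta_row$t_stat, (34 - 35) / sqrt(1 / 3 + 1 / 3),
               tolerance = 1e-10)
  expect_equal(beta_row$df, 4, tolerance = 1e-10)
  expect_equal(beta_row$p_value, 2 * pt(-abs(beta_row$t_stat), 4),
               tolerance = 1e-12)
  # identical gamma lists: t = 0, p = 1
  g_row <- pc[pc$parameter == "gamma", ]
  expect_equal(g_row$t_stat, 0)
  expect_equal(g_row$p_value, 1)
})

test_that("a constructed birth-size shift is detected only in the intercept", {
  set.seed(11)
  n <- 40
  mk <- function(shift) data.frame(
    child_id = paste0("x", 1:n), measure = "hc", group = NA,
    alpha = rnorm(n, 49, 0.05), beta = rnorm(n, 35 + shift, 0.05),
    gamma = rnorm(n, 0.03, 0.0005), r_squared = 0.99, n_points = 8,
    converged = TRUE, stringsAsFactors = FALSE)
  pc <- compare_params(mk(-0.6), mk(0))
  expect_lt(pc$p_value[pc$parameter == "beta"], 1e-6)
  expect_gt(pc$p_value[pc$parameter == "alpha"], 0.01)
  expect_gt(pc$p_value[pc$parameter == "gamma"], 0.01)
  expect_lt(pc$diff[pc$parameter == "beta"], 0)
})

test_that("nonconverged fits are excluded from comparisons", {
  mk <- function(ids) data.frame(
    child_id = ids, measure = "hc", group = NA,
    alpha = rnorm(length(ids), 49), beta = rnorm(length(ids), 35),
    gamma = 0.03, r_squared = 0.99, n_points = 8,
    converged = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  set.seed(2)
  pc <- compare_params(mk(c("A1", "A2", "A3")), mk(c("C1", "C2", "C3")))
  expect_true(all(pc$n_case == 2))
  expect_true(all(pc$n_control == 2))
  bad <- data.frame(child_id = "A1", measure = "hc", group = NA,
                    alpha = 49, beta = 35, gamma = 0.03, r_squared = 0.99,
                    n_points = 8, converged = FALSE)
  expect_error(compare_params(bad, mk(c("C1", "C2", "C3"))), "converged")
})
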
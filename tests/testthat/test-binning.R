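test_that("binning a constant curve returns the constant in every bin", {
  wc <- interpolate_weekly(c(0, 104), c(40, 40))
  out <- bin_curve(wc, birth_value = 40)
  expect_equal(sort(out$bin_age_months), seq(0, 24, by = 3))
  expect_true(all(out$value == 40))
})

test_that("bins outside the measured span are absent", {
  wc <- interpolate_weekly(c(0, 30), c(34, 43))
  out <- bin_curve(wc, birth_value = 34)
  expect_equal(sort(out$bin_age_months), c(0, 3, 6))
})

test_that("a symmetric window around a linear curve recovers the centre value", {
  ages <- c(0, 104)
  vals <- 30 + 0.1 * ages
  wc <- interpolate_weekly(ages, vals)
  out <- bin_curve(wc)
  b12 <- out$value[out$bin_age_months == 12]
  # 12-month centre rounds to week 52; mean over 13 weeks = centre value
  expect_equal(b12, 30 + 0.1 * 52, tolerance = 1e-10)
  expect_equal(out$n_weeks_used[out$bin_age_months == 12], 13)
  expect_equal(b12, 30 + 0.1 * months_to_weeks(12), tolerance = 0.05)
})

test_that("bin 0 carries the raw birth measurement, and height has no bin 0", {
  co <- generate_cohort(generator_config(n_pairs = 5), seed = 13)
  binned <- bin_cohort(co)
  expect_false(any(binned$bin_age_months == 0 & binned$measure == "height"))
  ms <- co$measurements
  for (id in co$children$child_id[1:4]) {
    birth <- ms$value[ms$child_id == id & ms$measure == "hc" &
                        ms$age_weeks == 0]
    got <- binned$value[binned$child_id == id & binned$measure == "hc" &
                          binned$bin_age_months == 0]
    expect_equal(got, birth)
  }
})

test_that("welch_t_test matches hand computation and stats::t.test", {
  w <- welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  # hand: means 2.5/3.5, sample variances 5/3 each
  expect_equal(w$t_stat, -1 / sqrt((5 / 3) / 4 + (5 / 3) / 4),
               tolerance = 1e-10)
  expect_equal(w$df, 6, tolerance = 1e-10)   # equal variances: 2n - 2
  expect_equal(w$t_stat, -1.0954, tolerance = 1e-4)
  expect_equal(w$p_value, 0.31533, tolerance = 1e-4)

  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1), 0, 1)
    y <- rnorm(sample(3:12, 1), 0.5, 2)
    w <- welch_t_test(x, y)
    tt <- t.test(x, y)
    expect_equal(w$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-8)
    expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t_test honours its degenerate-case conventions", {
  w <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t_stat, 0)
  expect_equal(w$p_value, 1)
  w2 <- welch_t_test(c(2, 2), c(1, 1))
  expect_equal(w2$t_stat, Inf)
  expect_equal(w2$p_value, 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # extreme separation
  set.seed(5)
  w3 <- welch_t_test(rnorm(50, 10, 1), rnorm(50, 0, 1))
  expect_lt(w3$p_value, 1e-15)
})

test_that("welch p-value agrees with a permutation oracle on small samples", {
  set.seed(6)
  x <- rnorm(8, 0, 1)
  y <- rnorm(8, 0.8, 1)
  p_w <- welch_t_test(x, y)$p_value
  p_perm <- perm_welch_p(x, y, n_perm = 20000)
  expect_equal(p_w, p_perm, tolerance = 0.05)
})

test_that("swapping group labels negates t and diff but keeps p", {
  co <- generate_cohort(generator_config(n_pairs = 20), seed = 17)
  a <- compare_bins(co)
  swapped <- co
  swapped$children$group <- ifelse(co$children$group == "autism",
                                   "control", "autism")
  # move ADOS metadata to the pair partner so the swapped cohort stays valid
  ch <- co$children
  partner <- vapply(seq_len(nrow(ch)), function(i)
    which(ch$pair_id == ch$pair_id[i] & ch$child_id != ch$child_id[i]), 1L)
  swapped$children[c("ados_module", "ados_total", "ados_css",
                     "age_at_diagnosis_months")] <-
    ch[partner, c("ados_module", "ados_total", "ados_css",
                  "age_at_diagnosis_months")]
  b <- compare_bins(swapped)
  key <- paste(a$measure, a$bin_age_months)
  keyb <- paste(b$measure, b$bin_age_months)
  b <- b[match(key, keyb), ]
  ok <- !is.na(a$t_stat) & !is.na(b$t_stat)
  expect_true(any(ok))
  expect_equal(b$t_stat[ok], -a$t_stat[ok], tolerance = 1e-10)
  expect_equal(b$diff[ok], -a$diff[ok], tolerance = 1e-10)
  expect_equal(b$p_value[ok], a$p_value[ok], tolerance = 1e-10)
})

test_that("the report covers measures x bins with height lacking birth", {
  co <- generate_cohort(generator_config(n_pairs = 40), seed = 19)
  out <- compare_bins(co)
  expect_equal(sum(out$measure == "hc"), 9)
  expect_equal(sum(out$measure == "weight"), 9)
  expect_equal(sum(out$measure == "height"), 8)
  expect_false(any(out$measure == "height" & out$bin_age_months == 0))
  expect_true(all(out$diff[!is.na(out$diff)] ==
                    (out$mean_case - out$mean_control)[!is.na(out$diff)]))
})

test_that("an injected birth deficit is detected at birth but not later", {
  cfg <- generator_config(
    n_pairs = 300,
    param_sds = list(hc = growth_params(0.3, 0.3, 0.001, check = FALSE),
                     weight = growth_params(0.2, 0.1, 0.001, check = FALSE),
                     height = growth_params(0.5, 0.5, 0.001, check = FALSE)),
    group_effect = list(hc = growth_params(0, -0.6, 0, check = FALSE),
                        weight = growth_params(0, 0, 0, check = FALSE),
                        height = growth_params(0, 0, 0, check = FALSE)))
  co <- generate_cohort(cfg, seed = 23)
  out <- compare_bins(co)
  hc <- out[out$measure == "hc", ]
  expect_lt(hc$p_value[hc$bin_age_months == 0], 0.01)
  expect_lt(hc$diff[hc$bin_age_months == 0], 0)   # control larger at birth
  expect_lt(hc$p_value[hc$bin_age_months == 3], 0.05)
  expect_gt(hc$p_value[hc$bin_age_months == 24], 0.05)
})

test_that("module-stratified rows compare each stratum to all controls", {
  co <- generate_cohort(generator_config(n_pairs = 40), seed = 29)
  # tiny strata legitimately yield NA test rows with warnings
  out <- suppressWarnings(compare_bins(co, stratify_by_module = TRUE))
  ch <- co$children
  n_mod1 <- sum(ch$ados_module == "module1", na.rm = TRUE)
  row <- out[out$stratum == "module1" & out$measure == "hc" &
               out$bin_age_months == 0, ]
  expect_equal(row$n_case, n_mod1)
  expect_equal(row$n_control, 40)
  expect_equal(sort(unique(out$stratum)),
               sort(c("toddler", "module1", "module2")))
})
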
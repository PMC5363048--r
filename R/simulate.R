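#' Growth-model parameter triple
#'
#' @param alpha asymptote (cm or kg).
#' @param beta intercept at birth (cm or kg).
#' @param gamma growth rate toward the asymptote (per week).
#' @param check enforce `alpha > beta > 0` and `gamma > 0` (set `FALSE`
#'   for additive offsets, which may be zero or negative).
#' @return named numeric vector `c(alpha, beta, gamma)`.
#' @export
growth_params <- function(alpha, beta, gamma, check = TRUE) {
  p <- c(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma))
  if (check && !(p["alpha"] > p["beta"] && p["beta"] > 0 && p["gamma"] > 0))
    stop("growth_params: need alpha > beta > 0 and gamma > 0")
  p
}

zero_offset <- function() growth_params(0, 0, 0, check = FALSE)

#' Synthetic cohort generator configuration
#'
#' Defaults emulate the study conditions: 66 matched pairs with 6
#' females per group, the Israeli well-baby schedule (birth plus months
#' 1, 2, 4, 6, 9, 12, 15, 18, 24), per-visit attendance probability
#' 0.82 calibrated so the mean visit count is about 8.4, growth
#' parameter means fitted to the published control trajectories
#' ([default_growth_params()]), and measurement noise of 0.3 cm (HC),
#' 0.15 kg (weight), 0.5 cm (height).
#'
#' @param n_pairs number of matched case-control pairs.
#' @param prop_female proportion of female pairs.
#' @param param_means named list (hc/weight/height) of mean
#'   [growth_params()].
#' @param param_sds named list of between-child SDs for each parameter.
#' @param noise_sd named vector of measurement noise SDs per measure.
#' @param visit_weeks scheduled visit ages in weeks, starting at 0.
#' @param attendance_prob probability a non-birth scheduled visit is
#'   attended; the birth visit is always measured (HC and weight only,
#'   never height).
#' @param visit_jitter_sd_weeks SD of Gaussian jitter on non-birth
#'   visit ages (parental compliance); birth stays at exactly 0.
#' @param min_visits minimum attended visits per child (resampled until
#'   satisfied).
#' @param group_effect additive offsets applied to autism children's
#'   parameter means (per measure, or a single triple recycled for all
#'   measures); default all zero, i.e. a null cohort.
#' @param sex_effect additive offsets applied to male children's
#'   parameter means (per measure).
#' @param ados_module_probs probabilities of toddler / module 1 /
#'   module 2 assignment, defaults proportional to the study's 14/36/15
#'   strata.
#' @param severity_hc_corr rank correlation between ADOS scores and the
#'   child's latent HC asymptote (0 = independent).
#' @param seed default seed used by [generate_cohort()].
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(
    n_pairs = 66,
    prop_female = 6 / 66,
    param_means = lapply(setNames(MEASURES, MEASURES), default_growth_params),
    param_sds = list(
      hc     = growth_params(1.4, 1.2, 0.004, check = FALSE),
      weight = growth_params(0.9, 0.35, 0.003, check = FALSE),
      height = growth_params(3.0, 2.0, 0.002, check = FALSE)),
    noise_sd = c(hc = 0.3, weight = 0.15, height = 0.5),
    visit_weeks = months_to_weeks(c(0, 1, 2, 4, 6, 9, 12, 15, 18, 24)),
    attendance_prob = 0.82,
    visit_jitter_sd_weeks = 1.0,
    min_visits = 4,
    group_effect = NULL,
    sex_effect = NULL,
    ados_module_probs = c(toddler = 14, module1 = 36, module2 = 15) / 65,
    severity_hc_corr = 0,
    seed = NULL) {
  as_offsets <- function(x, default) {
    if (is.null(x)) return(lapply(setNames(MEASURES, MEASURES),
                                  function(m) default[[m]]))
    if (is.numeric(x)) x <- list(hc = x, weight = x, height = x)
    out <- lapply(setNames(MEASURES, MEASURES), function(m) {
      v <- if (!is.null(x[[m]])) x[[m]] else default[[m]]
      growth_params(v[["alpha"]], v[["beta"]], v[["gamma"]], check = FALSE)
    })
    out
  }
  zero <- lapply(setNames(MEASURES, MEASURES), function(m) zero_offset())
  # modest male size advantage; identical in both groups of a matched
  # same-sex pair so it never biases case-control contrasts
  male_default <- list(hc = growth_params(0.9, 0.5, 0, check = FALSE),
                       weight = growth_params(0.5, 0.1, 0, check = FALSE),
                       height = growth_params(1.2, 0.5, 0, check = FALSE))
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    prop_female = prop_female,
    param_means = param_means,
    param_sds = param_sds,
    noise_sd = noise_sd,
    visit_weeks = sort(visit_weeks),
    attendance_prob = attendance_prob,
    visit_jitter_sd_weeks = visit_jitter_sd_weeks,
    min_visits = as.integer(min_visits),
    group_effect = as_offsets(group_effect, zero),
    sex_effect = as_offsets(sex_effect, male_default),
    ados_module_probs = ados_module_probs,
    severity_hc_corr = severity_hc_corr,
    seed = seed)
  stopifnot(cfg$n_pairs >= 1,
            cfg$prop_female >= 0, cfg$prop_female <= 1,
            cfg$attendance_prob > 0, cfg$attendance_prob <= 1,
            cfg$visit_weeks[1] == 0,
            cfg$min_visits >= 1,
            abs(sum(cfg$ados_module_probs) - 1) < 1e-8,
            abs(cfg$severity_hc_corr) <= 1)
  structure(cfg, class = "generator_config")
}

# truncated-normal draw of one parameter triple: resample until the
# triple is a valid increasing-growth parameterization
draw_params <- function(mean_p, sd_p, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    p <- rnorm(3, mean = mean_p, sd = sd_p)
    if (p[1] > p[2] && p[2] > 0 && p[3] > 0)
      return(growth_params(p[1], p[2], p[3]))
  }
  stop("generate_cohort: could not draw valid growth parameters; ",
       "check param_means/param_sds")
}

# attended visit ages: birth exact 0; scheduled visits kept with
# probability attendance_prob, jittered, resampled until >= min_visits
# attended and ages strictly increasing and positive
draw_visit_ages <- function(cfg, max_tries = 1000L) {
  sched <- cfg$visit_weeks[-1]
  for (i in seq_len(max_tries)) {
    keep <- runif(length(sched)) < cfg$attendance_prob
    if (sum(keep) + 1L < cfg$min_visits) next
    ages <- sched[keep] + rnorm(sum(keep), 0, cfg$visit_jitter_sd_weeks)
    ages <- c(0, ages)
    if (all(diff(ages) > 0.5) && all(ages >= 0) &&
        all(ages <= MAX_AGE_WEEKS))
      return(ages)
  }
  stop("generate_cohort: attendance_prob makes min_visits unreachable")
}

# map latent z-scores to uniform-integer scores on [lo, hi] through a
# Gaussian copula rank-correlated with the latent HC asymptote
copula_scores <- function(z_alpha, rho, lo, hi) {
  n <- length(z_alpha)
  z <- rho * z_alpha + sqrt(1 - rho^2) * rnorm(n)
  pmin(hi, pmax(lo, floor(lo + pnorm(z) * (hi - lo + 1))))
}

#' Generate a synthetic matched case-control cohort
#'
#' Each pair is one autism and one control child of the same sex born
#' within 30 days. Per child and measure, latent growth parameters are
#' drawn from truncated normals around the configured means (plus group
#' and sex offsets), each attended visit yields one noisy measurement
#' per measure from the negative exponential curve, height is never
#' measured at birth, and autism children receive an ADOS module, total
#' score (7--26) and calibrated severity score (4--10), optionally
#' rank-correlated with the child's latent HC asymptote. Deterministic
#' for a fixed seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; overrides `config$seed`.
#' @return a validated [cohort()] with provenance `"synthetic"`. The
#'   latent per-child parameters used for simulation are attached as
#'   the `"latent"` attribute (data.frame child_id, measure, alpha,
#'   beta, gamma) for recovery studies.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  n_pairs <- config$n_pairs
  n_female <- round(config$prop_female * n_pairs)
  sexes <- rep(c("female", "male"), c(n_female, n_pairs - n_female))

  children <- vector("list", 2 * n_pairs)
  meas <- vector("list", 2 * n_pairs)
  latent <- vector("list", 2 * n_pairs)
  k <- 0L

  for (i in seq_len(n_pairs)) {
    pair_id <- sprintf("P%03d", i)
    sex <- sexes[i]
    offset <- sample(-30:30, 1)
    for (grp in c("autism", "control")) {
      k <- k + 1L
      id <- sprintf("%s%03d", if (grp == "autism") "A" else "C", i)
      pars <- lapply(setNames(MEASURES, MEASURES), function(m) {
        mu <- config$param_means[[m]]
        if (grp == "autism") mu <- mu + config$group_effect[[m]]
        if (sex == "male") mu <- mu + config$sex_effect[[m]]
        draw_params(mu, config$param_sds[[m]])
      })
      ages <- draw_visit_ages(config)
      rows <- do.call(rbind, lapply(MEASURES, function(m) {
        a <- if (m == "height") ages[ages >= 1] else ages
        if (!length(a)) return(NULL)
        data.frame(child_id = id, measure = m, age_weeks = a,
                   value = growth_curve(pars[[m]], a) +
                     rnorm(length(a), 0, config$noise_sd[[m]]),
                   stringsAsFactors = FALSE)
      }))
      children[[k]] <- data.frame(
        child_id = id, group = grp, sex = sex, pair_id = pair_id,
        birth_offset_days = if (grp == "autism") offset else 0L,
        ados_module = NA_character_, ados_total = NA_integer_,
        ados_css = NA_integer_, age_at_diagnosis_months = NA_real_,
        stringsAsFactors = FALSE)
      meas[[k]] <- rows
      latent[[k]] <- data.frame(
        child_id = id, measure = MEASURES,
        alpha = vapply(pars, `[[`, 0, "alpha"),
        beta = vapply(pars, `[[`, 0, "beta"),
        gamma = vapply(pars, `[[`, 0, "gamma"),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }

  children <- do.call(rbind, children)
  meas <- do.call(rbind, meas)
  latent <- do.call(rbind, latent)

  # ADOS metadata for the autism group
  aut <- which(children$group == "autism")
  n_aut <- length(aut)
  children$ados_module[aut] <- sample(ADOS_MODULES, n_aut, replace = TRUE,
                                      prob = config$ados_module_probs)
  rho <- config$severity_hc_corr
  if (rho == 0) {
    children$ados_total[aut] <- sample(7:26, n_aut, replace = TRUE)
    children$ados_css[aut] <- sample(4:10, n_aut, replace = TRUE)
  } else {
    alpha_hc <- latent$alpha[latent$measure == "hc"]
    alpha_hc <- alpha_hc[match(children$child_id[aut],
                               latent$child_id[latent$measure == "hc"])]
    z_a <- qnorm(rank(alpha_hc) / (n_aut + 1))
    children$ados_total[aut] <- copula_scores(z_a, rho, 7, 26)
    children$ados_css[aut] <- copula_scores(z_a, rho, 4, 10)
  }
  children$age_at_diagnosis_months[aut] <-
    round(pmin(64, pmax(12, rnorm(n_aut, 36.94, 13))), 1)

  out <- cohort(children, meas, provenance = "synthetic", seed = seed,
                validate = TRUE)
  attr(out, "latent") <- latent
  out
}
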
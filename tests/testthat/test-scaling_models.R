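quiet_fit_traits <- function(recs) {
  suppressMessages(fit_trait_lme(recs))
}

make_records <- function(web_id, x, y, eco = "freshwater",
                         ppmr = NULL, omn = NULL) {
  n <- length(x)
  tibble::tibble(
    web_id = web_id, ecosystem_type = eco,
    predator_id = sprintf("p%02d", seq_len(n)),
    predator_taxon = sprintf("sp%02d", seq_len(n)),
    prey_biomass = 10^x, predator_biomass = 10^y,
    log10_prey_biomass = x, log10_predator_biomass = y,
    ppmr_log10 = if (is.null(ppmr)) stats::rnorm(n) else ppmr,
    omnivory = if (is.null(omn)) stats::runif(n) else omn,
    trophic_level = 3)
}

test_that("per-web OLS recovers exact and two-point slopes and skips degenerate webs", {
  r1 <- make_records("a", c(0, 1, 2), 0.2 + 0.75 * c(0, 1, 2))
  ols <- fit_per_web_ols(r1)
  expect_equal(ols$k_i, 0.75, tolerance = 1e-12)
  expect_equal(ols$c_i, 0.2, tolerance = 1e-12)

  r2 <- make_records("b", c(1, 3), c(0.5, 1.7))
  expect_equal(fit_per_web_ols(r2)$k_i, (1.7 - 0.5) / (3 - 1))

  r3 <- make_records("c", c(2, 2, 2), c(1, 2, 3))
  expect_message(out <- fit_per_web_ols(r3), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("noise-free generator webs are fitted exactly", {
  cfg <- synthetic_config(n_webs = 4, ecosystems = "freshwater",
                          sigma_k = 0.1, sigma_c = 0.2, sigma_res = 0,
                          seed = 31)
  ds <- generate_dataset(cfg)
  within <- quiet(build_within_table(ds$webs))
  ols <- fit_per_web_ols(within)
  truth <- ds$truth$k_i[match(ols$web_id, ds$truth$web_id)]
  expect_equal(ols$k_i, truth, tolerance = 1e-9)
})

test_that("with one web the mixed-model wrapper reduces to the per-web OLS slope", {
  set.seed(41)
  x <- stats::runif(12, 0, 3)
  r <- make_records("solo", x, -0.3 + 0.8 * x + stats::rnorm(12, 0, 0.2))
  fit <- fit_within_lme(r)
  ols <- fit_per_web_ols(r)
  expect_equal(fit$k_bar, ols$k_i, tolerance = 1e-6)
})

test_that("the within-web LME recovers the generating exponent and reports structure", {
  cfg <- synthetic_config(n_webs = 8, ecosystems = c("freshwater", "marine"),
                          species_per_web = 35, seed = 51)
  ds <- generate_dataset(cfg)
  within <- quiet(build_within_table(ds$webs))
  fit <- quiet(fit_within_lme(within))
  expect_s3_class(fit, "scaling_fit")
  expect_true(fit$ci_k[1] < 0.75 && 0.75 < fit$ci_k[2])
  expect_true(fit$ci_k[1] < fit$k_bar && fit$k_bar < fit$ci_k[2])
  expect_equal(nrow(fit$k_by_ecosystem), 2)
  expect_equal(sort(unique(fit$random_effects$web_id)),
               sort(unique(within$web_id)))
  expect_gt(fit$sigma_res, 0.2)
  expect_lt(fit$sigma_res, 0.4)
  expect_true(!is.null(fit$model_comparison$random_structure))
  # ML likelihood of the selected model is >= any nested simpler model
  lrt <- fit$model_comparison$fixed_effects_lrt
  expect_true(all(lrt$chisq >= -1e-8))
})

test_that("a single ecosystem type skips the interaction test gracefully", {
  cfg <- synthetic_config(n_webs = 5, ecosystems = "marine",
                          species_per_web = 35, seed = 61)
  ds <- generate_dataset(cfg)
  within <- quiet(build_within_table(ds$webs))
  fit <- quiet(fit_within_lme(within))
  expect_match(paste(fit$notes, collapse = " "), "interaction test skipped")
  expect_null(fit$model_comparison$fixed_effects_lrt)
})

test_that("confidence intervals tighten as webs accumulate", {
  f <- function(n_webs, seed) {
    cfg <- synthetic_config(n_webs = n_webs, ecosystems = "marine",
                            species_per_web = 35, seed = seed)
    within <- quiet(build_within_table(generate_dataset(cfg)$webs))
    fit <- quiet(fit_within_lme(within))
    diff(fit$ci_k)
  }
  expect_lt(f(24, 71), f(6, 71))
})

test_that("an injected PPmR effect is recovered by the trait model", {
  cfg <- synthetic_config(n_webs = 30, ecosystems = "marine",
                          species_per_web = 35, ppmr_effect = 0.3, seed = 81)
  ds <- generate_dataset(cfg)
  within <- quiet(build_within_table(ds$webs))
  expect_gte(nrow(within), 400)
  fit <- quiet(fit_trait_lme(within))
  expect_true("ppmr_log10" %in% fit$trait_terms)
  expect_lt(abs(fit$trait_coefficients[["ppmr_log10"]] - 0.3), 0.05)
  expect_true(!is.null(fit$anova))
  expect_true(all(c("df_den", "p_value") %in% names(fit$anova)))
  expect_gte(nrow(fit$partial_residuals), nrow(within))
})

test_that("a constant trait column is dropped with a warning", {
  set.seed(91)
  recs <- dplyr::bind_rows(lapply(1:4, function(i) {
    x <- stats::runif(10, 0, 3)
    make_records(paste0("w", i), x, 0.75 * x + stats::rnorm(10, 0, 0.2),
                 omn = 0)
  }))
  base <- quiet(fit_within_lme(recs))
  expect_warning(
    fit <- suppressMessages(fit_trait_lme(recs, base_fit = base)),
    "omnivory")
  expect_false("omnivory" %in% fit$trait_terms)
})

test_that("trait F-tests behave at the nominal type-I level when no effect exists", {
  seeds <- 100 + seq_len(10)
  sig <- vapply(seeds, function(s) {
    cfg <- synthetic_config(n_webs = 12, ecosystems = "marine",
                            species_per_web = 35, seed = s)
    within <- quiet(build_within_table(generate_dataset(cfg)$webs))
    fit <- quiet(fit_trait_lme(within))
    a <- fit$anova
    p <- a$p_value[a$term %in% c("ppmr_log10", "omnivory")]
    any(p < 0.05)
  }, logical(1))
  # with alpha = 0.05 per trait, false alarms should stay the exception
  expect_lte(sum(sig), 4)
})

test_that("across-web ANCOVA: exact common power law and a clear interaction are both detected", {
  # all webs on one exact line with slope 0.66
  x <- seq(0, 3, length.out = 30)
  ex <- tibble::tibble(
    web_id = sprintf("w%02d", 1:30),
    ecosystem_type = rep(c("freshwater", "marine", "terrestrial"), 10),
    log10_total_prey_biomass = x,
    log10_total_predator_biomass = -0.4 + 0.66 * x,
    log10_mean_prey_mass = stats::rnorm(30))
  fit <- fit_across_ancova(ex)
  expect_equal(fit$k_bar, 0.66, tolerance = 1e-10)
  expect_equal(fit$k_by_ecosystem$k, rep(0.66, 3), tolerance = 1e-8)
  expect_gt(fit$interaction_test$p_value, 0.05)

  # slopes 0.5 vs 0.9 with small noise: interaction detected
  set.seed(111)
  hits <- vapply(1:20, function(r) {
    x1 <- stats::runif(40, 0, 3); x2 <- stats::runif(40, 0, 3)
    d <- tibble::tibble(
      web_id = sprintf("w%02d", 1:80),
      ecosystem_type = rep(c("freshwater", "marine"), each = 40),
      log10_total_prey_biomass = c(x1, x2),
      log10_total_predator_biomass =
        c(0.5 * x1, 0.9 * x2) + stats::rnorm(80, 0, 0.05),
      log10_mean_prey_mass = 0)
    fit_across_ancova(d)$interaction_test$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("across-web ANCOVA handles a single ecosystem and rejects degenerate designs", {
  set.seed(121)
  x <- stats::runif(20, 0, 3)
  d <- tibble::tibble(
    web_id = sprintf("w%02d", 1:20), ecosystem_type = "marine",
    log10_total_prey_biomass = x,
    log10_total_predator_biomass = 0.7 * x + stats::rnorm(20, 0, 0.1),
    log10_mean_prey_mass = 0)
  fit <- fit_across_ancova(d)
  expect_match(fit$kind, "single ecosystem")
  expect_true(fit$ci_k[1] < 0.7 && 0.7 < fit$ci_k[2])

  d0 <- d
  d0$log10_total_prey_biomass <- 1
  expect_error(fit_across_ancova(d0), class = "trophoscale_rank_error")
})

test_that("the prey body-mass diagnostic distinguishes density- from size-driven gradients", {
  set.seed(131)
  x <- stats::runif(45, 0, 3)
  base <- tibble::tibble(
    web_id = sprintf("w%02d", 1:45),
    ecosystem_type = rep(c("freshwater", "marine", "terrestrial"), 15),
    log10_total_prey_biomass = x,
    log10_total_predator_biomass = 0.7 * x)
  # constant prey mass -> slope exactly 0
  d1 <- dplyr::mutate(base, log10_mean_prey_mass = -2)
  f1 <- fit_prey_mass_model(d1)
  expect_equal(f1$k_bar, 0, tolerance = 1e-12)
  # prey mass proportional to prey biomass -> slope exactly 1
  d2 <- dplyr::mutate(base, log10_mean_prey_mass = x - 5)
  f2 <- fit_prey_mass_model(d2)
  expect_equal(f2$k_bar, 1, tolerance = 1e-10)
  # decoupled prey mass: slope CI covers 0
  d3 <- dplyr::mutate(base, log10_mean_prey_mass = stats::rnorm(45))
  f3 <- fit_prey_mass_model(d3)
  expect_true(f3$ci_k[1] < 0 && 0 < f3$ci_k[2])
  # outlier ids are removed before fitting
  f4 <- fit_prey_mass_model(d1, outlier_ids = c("w01", "w02"))
  expect_equal(f4$n_outliers_removed, 2)
})

test_that("per-species scaling across webs is fitted and guarded", {
  x <- seq(0, 3, length.out = 10)
  recs <- dplyr::bind_rows(lapply(1:10, function(i) {
    r <- make_records(paste0("w", i), x[i], -0.2 + 0.75 * x[i])
    r$predator_taxon <- "Salmo trutta"
    r
  }))
  fit <- fit_species_across_webs(recs, "Salmo trutta")
  expect_equal(fit$k_bar, 0.75, tolerance = 1e-10)
  expect_equal(fit$n_webs, 10)

  # biomass invariant with prey biomass -> slope ~ 0
  flat <- recs
  flat$log10_predator_biomass <- 0.5
  expect_equal(fit_species_across_webs(flat, "Salmo trutta")$k_bar, 0,
               tolerance = 1e-10)

  expect_error(fit_species_across_webs(recs[1:3, ], "Salmo trutta"),
               class = "trophoscale_fewwebs_error")
})

test_that("power-law fold-change identities hold for any exponent", {
  k <- stats::runif(5, 0.3, 1.2)
  expect_equal(biomass_gain(k, 2), (2^k - 1) * 100)
  expect_equal(predator_fold_change(1, 5), 5)
  expect_equal(biomass_gain(1, 2), 100)
})
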
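# Power-law fits on log-log scales: within-web linear mixed-effects models
# with random slopes/intercepts per web, per-web OLS, across-web ANCOVA,
# and trait-augmented mixed models. OLS (type 1 regression) is used for all
# fixed-effect estimation, matching standard practice for predator-prey
# biomass allometry.

.y_within <- "log10_predator_biomass"
.x_within <- "log10_prey_biomass"
.eco <- "ecosystem_type"
.grp <- "web_id"

new_scaling_fit <- function(...) {
  structure(list(...), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s\n", x$kind))
  if (!is.null(x$k_bar)) {
    cat(sprintf("  k_bar = %.4f (95%% CI %.4f to %.4f)\n",
                x$k_bar, x$ci_k[1], x$ci_k[2]))
  }
  if (!is.null(x$c_bar)) cat(sprintf("  c_bar = %.4f\n", x$c_bar))
  if (!is.null(x$k_by_ecosystem) && nrow(x$k_by_ecosystem) > 0) {
    for (i in seq_len(nrow(x$k_by_ecosystem))) {
      r <- x$k_by_ecosystem[i, ]
      cat(sprintf("  k[%s] = %.4f (%.4f to %.4f)\n",
                  r$ecosystem_type, r$k, r$ci_lo, r$ci_hi))
    }
  }
  if (!is.null(x$sigma_res)) cat(sprintf("  sigma_res = %.4f\n", x$sigma_res))
  if (!is.null(x$r2_marginal)) {
    cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
                x$r2_marginal, x$r2_conditional))
  }
  if (length(x$notes) > 0) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  c(est - z * se, est + z * se)
}

# absolute slope (and Wald CI) per factor level from a model with
# treatment-coded x:factor interaction terms; works for lm and merMod
slopes_by_level <- function(model, data, xvar = .x_within, fvar = .eco,
                            level = 0.95) {
  beta <- if (inherits(model, "merMod")) lme4::fixef(model) else stats::coef(model)
  V <- as.matrix(suppressWarnings(stats::vcov(model)))
  lv <- levels(droplevels(factor(data[[fvar]])))
  purrr::map_dfr(lv, function(L) {
    w <- stats::setNames(rep(0, length(beta)), names(beta))
    w[xvar] <- 1
    cand <- c(paste0(xvar, ":", fvar, L), paste0(fvar, L, ":", xvar))
    hit <- intersect(cand, names(beta))
    if (length(hit) == 1) w[hit] <- 1
    est <- sum(w * beta)
    se <- sqrt(drop(t(w) %*% V %*% w))
    ci <- wald_ci(est, se, level)
    tibble::tibble(ecosystem_type = L, k = est, se = se,
                   ci_lo = ci[1], ci_hi = ci[2])
  })
}

# marginal / conditional variance explained for a fitted lmer model,
# variance of the random part taken over the observed covariate values
r2_mixed <- function(model) {
  X <- lme4::getME(model, "X")
  beta <- lme4::fixef(model)
  var_f <- stats::var(as.numeric(X %*% beta))
  mf <- stats::model.frame(model)
  vc <- lme4::VarCorr(model)
  var_r <- sum(vapply(vc, function(S) {
    trm <- rownames(S)
    Zb <- vapply(trm, function(t) {
      if (t == "(Intercept)") rep(1, nrow(mf)) else as.numeric(mf[[t]])
    }, numeric(nrow(mf)))
    Zb <- matrix(Zb, nrow = nrow(mf))
    mean(rowSums((Zb %*% as.matrix(S)) * Zb))
  }, numeric(1)))
  var_e <- stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  list(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

# variance components for the web grouping factor from a fitted lmer model
random_structure <- function(model, xvar = .x_within) {
  vc <- lme4::VarCorr(model)
  sigma_c <- 0
  sigma_k <- 0
  rho <- NA_real_
  for (S in vc) {
    sds <- attr(S, "stddev")
    if ("(Intercept)" %in% names(sds)) sigma_c <- max(sigma_c, sds[["(Intercept)"]])
    if (xvar %in% names(sds)) sigma_k <- max(sigma_k, sds[[xvar]])
    cr <- attr(S, "correlation")
    if (!is.null(cr) && all(c("(Intercept)", xvar) %in% rownames(cr))) {
      rho <- cr["(Intercept)", xvar]
    }
  }
  list(sigma_c = sigma_c, sigma_k = sigma_k, rho = rho)
}

ranef_table <- function(model, xvar = .x_within) {
  re <- lme4::ranef(model)[[.grp]]
  tibble::tibble(
    web_id = rownames(re),
    eps_c = if ("(Intercept)" %in% names(re)) re[["(Intercept)"]] else 0,
    eps_k = if (xvar %in% names(re)) re[[xvar]] else 0
  )
}

fit_lmer_safe <- function(formula, data, REML = TRUE) {
  tryCatch(
    withCallingHandlers(
      lmerTest::lmer(formula, data = data, REML = REML,
                     control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        if (grepl("converge|singular|boundary", conditionMessage(w)))
          invokeRestart("muffleWarning")
      },
      message = function(m) {
        if (grepl("singular|boundary", conditionMessage(m)))
          invokeRestart("muffleMessage")
      }),
    error = function(e) {
      rlang::abort(paste0("mixed-model fit failed to converge: ",
                          conditionMessage(e)),
                   class = "trophoscale_convergence_error")
    })
}

#' Fit the within-web power law with a linear mixed-effects model
#'
#' Models log10 predator biomass against log10 available prey biomass with
#' per-web random deviations of slope and intercept. The model is selected
#' top-down in two stages:
#' \enumerate{
#' \item with the full fixed structure (`log10_prey_biomass *
#'   ecosystem_type`), random structures \{correlated random slope +
#'   intercept; uncorrelated; intercept only\} are compared by AIC under
#'   REML; a singular best fit falls back to the next-simpler structure
#'   with a warning;
#' \item under that random structure, the ecosystem-by-slope interaction is
#'   tested with a likelihood-ratio test on maximum-likelihood fits; a
#'   non-significant interaction (and then a non-significant ecosystem main
#'   effect) is dropped.
#' }
#' The selected model is refitted by REML and the mean exponent `k_bar` is
#' reported with a 95% Wald confidence interval. Per-ecosystem slopes are
#' always reported from the full-interaction REML fit. When the records are
#' exactly collinear (noise-free data) the model degenerates to pooled OLS;
#' this is detected and the exact fit returned with zero variance
#' components.
#'
#' @param within Predator-record table from [build_within_table()].
#' @param alpha Significance level of the fixed-effect likelihood-ratio
#'   tests (default 0.05).
#' @param level Confidence level for intervals (default 0.95).
#' @return A `scaling_fit` with elements `k_bar`, `c_bar`, `ci_k`,
#'   `k_by_ecosystem`, `random_effects` (per-web `eps_k`, `eps_c`),
#'   `sigma_k`, `sigma_c`, `rho`, `sigma_res`, `r2_marginal`,
#'   `r2_conditional`, `model_comparison`, and the fitted `model`.
#' @export
fit_within_lme <- function(within, alpha = 0.05, level = 0.95) {
  d <- as.data.frame(within)
  d[[.eco]] <- factor(d[[.eco]])
  d[[.grp]] <- factor(d[[.grp]])
  n_webs <- nlevels(d[[.grp]])
  multi_eco <- nlevels(d[[.eco]]) >= 2
  notes <- character(0)

  # noise-free degenerate limit: all records on one exact line
  pooled <- stats::lm(stats::reformulate(.x_within, .y_within), data = d)
  if (stats::sigma(pooled) < 1e-8) {
    per_web <- fit_per_web_ols(within)
    co <- stats::coef(pooled)
    return(new_scaling_fit(
      kind = "within-web LME (noise-free degenerate: exact pooled OLS)",
      k_bar = unname(co[.x_within]), c_bar = unname(co[1]),
      ci_k = c(unname(co[.x_within]), unname(co[.x_within])),
      k_by_ecosystem = tibble::tibble(
        ecosystem_type = levels(d[[.eco]]), k = unname(co[.x_within]),
        se = 0, ci_lo = unname(co[.x_within]), ci_hi = unname(co[.x_within])),
      random_effects = tibble::tibble(
        web_id = per_web$web_id,
        eps_c = per_web$c_i - unname(co[1]),
        eps_k = per_web$k_i - unname(co[.x_within])),
      sigma_k = 0, sigma_c = 0, rho = NA_real_, sigma_res = 0,
      r2_marginal = 1, r2_conditional = 1,
      model_comparison = NULL, model = pooled,
      notes = "records are exactly collinear; variance components are zero"
    ))
  }

  if (n_webs < 2) {
    # single web: random effects are unidentifiable, fall back to OLS
    fml <- if (multi_eco) {
      stats::as.formula(paste(.y_within, "~", .x_within, "*", .eco))
    } else stats::reformulate(.x_within, .y_within)
    m <- stats::lm(fml, data = d)
    co <- stats::coef(m)
    se <- sqrt(diag(stats::vcov(m)))[.x_within]
    ci <- wald_ci(unname(co[.x_within]), unname(se), level)
    return(new_scaling_fit(
      kind = "within-web fit (single web: plain OLS, random effects suppressed)",
      k_bar = unname(co[.x_within]), c_bar = unname(co[1]), ci_k = ci,
      k_by_ecosystem = slopes_by_level(m, d, level = level),
      random_effects = NULL, sigma_k = NA_real_, sigma_c = NA_real_,
      rho = NA_real_, sigma_res = stats::sigma(m),
      r2_marginal = suppressWarnings(summary(m)$r.squared),
      r2_conditional = suppressWarnings(summary(m)$r.squared),
      model_comparison = NULL, model = m,
      notes = "single web: mixed model replaced by OLS"))
  }

  fixed_full <- if (multi_eco) {
    paste(.y_within, "~", .x_within, "*", .eco)
  } else paste(.y_within, "~", .x_within)
  re_terms <- c(
    correlated = paste0("(1 + ", .x_within, " | ", .grp, ")"),
    uncorrelated = paste0("(1 + ", .x_within, " || ", .grp, ")"),
    intercept_only = paste0("(1 | ", .grp, ")"))

  # stage 1: choose the random structure by AIC under REML
  stage1 <- purrr::map(re_terms, function(re) {
    m <- fit_lmer_safe(stats::as.formula(paste(fixed_full, "+", re)), d,
                       REML = TRUE)
    list(model = m, aic = stats::AIC(m), singular = lme4::isSingular(m))
  })
  aics <- vapply(stage1, `[[`, numeric(1), "aic")
  order_pref <- names(sort(aics))
  chosen_re <- order_pref[1]
  if (stage1[[chosen_re]]$singular) {
    # fall back to the next-simpler structure than the singular winner
    simpler <- names(re_terms)[seq_along(re_terms) >
                                 match(chosen_re, names(re_terms))]
    if (length(simpler) > 0) {
      fallback <- simpler[1]
      warning(sprintf("random structure '%s' is singular; falling back to '%s'",
                      chosen_re, fallback), call. = FALSE)
      notes <- c(notes, sprintf("singular '%s' random structure replaced by '%s'",
                                chosen_re, fallback))
      chosen_re <- fallback
    } else {
      warning("intercept-only random structure is singular (near-zero between-web variance); keeping it",
              call. = FALSE)
    }
  }
  re_chosen <- re_terms[[chosen_re]]
  stage1_tbl <- tibble::tibble(
    random_structure = names(re_terms),
    AIC = unname(aics),
    singular = vapply(stage1, `[[`, logical(1), "singular"),
    selected = names(re_terms) == chosen_re)

  # stage 2: fixed-effect selection by likelihood-ratio tests under ML
  lrt_tbl <- NULL
  fixed_selected <- paste(.y_within, "~", .x_within)
  if (multi_eco) {
    f_int <- paste(.y_within, "~", .x_within, "*", .eco)
    f_add <- paste(.y_within, "~", .x_within, "+", .eco)
    f_x <- paste(.y_within, "~", .x_within)
    m_int <- fit_lmer_safe(stats::as.formula(paste(f_int, "+", re_chosen)), d,
                           REML = FALSE)
    m_add <- fit_lmer_safe(stats::as.formula(paste(f_add, "+", re_chosen)), d,
                           REML = FALSE)
    m_x <- fit_lmer_safe(stats::as.formula(paste(f_x, "+", re_chosen)), d,
                         REML = FALSE)
    a1 <- stats::anova(m_add, m_int)
    a2 <- stats::anova(m_x, m_add)
    lrt_tbl <- tibble::tibble(
      test = c("slope x ecosystem interaction", "ecosystem intercept"),
      chisq = c(a1$Chisq[2], a2$Chisq[2]),
      df = c(a1$Df[2], a2$Df[2]),
      p_value = c(a1$`Pr(>Chisq)`[2], a2$`Pr(>Chisq)`[2]))
    if (lrt_tbl$p_value[1] < alpha) {
      fixed_selected <- f_int
    } else if (lrt_tbl$p_value[2] < alpha) {
      fixed_selected <- f_add
    } else {
      fixed_selected <- f_x
    }
  } else {
    notes <- c(notes, "single ecosystem type: interaction test skipped")
  }

  # final model refitted by REML
  final <- fit_lmer_safe(
    stats::as.formula(paste(fixed_selected, "+", re_chosen)), d, REML = TRUE)
  beta <- lme4::fixef(final)
  V <- as.matrix(stats::vcov(final))
  interaction_kept <- multi_eco && grepl("\\*", fixed_selected)

  if (interaction_kept) {
    # average the per-ecosystem slopes for k_bar
    lv <- levels(d[[.eco]])
    w <- stats::setNames(rep(0, length(beta)), names(beta))
    w[.x_within] <- 1
    for (L in lv[-1]) {
      cand <- intersect(c(paste0(.x_within, ":", .eco, L),
                          paste0(.eco, L, ":", .x_within)), names(beta))
      w[cand] <- 1 / length(lv)
    }
    k_bar <- sum(w * beta)
    k_se <- sqrt(drop(t(w) %*% V %*% w))
  } else {
    k_bar <- unname(beta[.x_within])
    k_se <- sqrt(V[.x_within, .x_within])
  }
  ci_k <- wald_ci(k_bar, k_se, level)

  # per-ecosystem slopes from the full-interaction REML fit
  eco_model <- if (multi_eco) {
    fit_lmer_safe(stats::as.formula(
      paste(.y_within, "~", .x_within, "*", .eco, "+", re_chosen)), d,
      REML = TRUE)
  } else final
  k_eco <- slopes_by_level(eco_model, d, level = level)

  rs <- random_structure(final)
  r2 <- r2_mixed(final)
  new_scaling_fit(
    kind = "within-web LME power law",
    k_bar = k_bar, c_bar = unname(beta["(Intercept)"]), ci_k = ci_k,
    k_by_ecosystem = k_eco,
    random_effects = ranef_table(final),
    sigma_k = rs$sigma_k, sigma_c = rs$sigma_c, rho = rs$rho,
    sigma_res = stats::sigma(final),
    r2_marginal = r2$marginal, r2_conditional = r2$conditional,
    model_comparison = list(random_structure = stage1_tbl,
                            fixed_effects_lrt = lrt_tbl),
    selected_fixed = fixed_selected, selected_random = chosen_re,
    model = final, notes = notes)
}

#' Fit per-web OLS power laws
#'
#' Ordinary least-squares slope and intercept of log10 predator biomass on
#' log10 available prey biomass, separately for each web. Webs whose
#' covariate has zero variance are skipped with a message.
#'
#' @param within Predator-record table from [build_within_table()].
#' @return Tibble with columns `web_id, ecosystem_type, k_i, c_i, n, r2`.
#' @export
fit_per_web_ols <- function(within) {
  purrr::map_dfr(split(as.data.frame(within), within$web_id), function(d) {
    if (nrow(d) < 2 || stats::var(d[[.x_within]]) == 0) {
      message(sprintf("fit_per_web_ols: web '%s' skipped (fewer than 2 records or zero covariate variance)",
                      d$web_id[1]))
      return(NULL)
    }
    m <- stats::lm(stats::reformulate(.x_within, .y_within), data = d)
    co <- stats::coef(m)
    tibble::tibble(
      web_id = d$web_id[1], ecosystem_type = d$ecosystem_type[1],
      k_i = unname(co[.x_within]), c_i = unname(co[1]),
      n = nrow(d), r2 = suppressWarnings(summary(m)$r.squared))
  })
}

#' Add predator traits to the within-web mixed model
#'
#' Augments the selected within-web model with log10 predator-prey body
#' mass ratio (PPmR) and omnivory as fixed effects, each interacting with
#' ecosystem type when several types are present. Candidate predictors that
#' are constant, or pairwise correlated with |r| > `r_max` with the prey-
#' biomass covariate or an already-kept trait, are dropped with a warning.
#' Term significance is assessed with F-tests using Satterthwaite
#' denominator degrees of freedom.
#'
#' @param within Predator-record table.
#' @param base_fit Optional result of [fit_within_lme()] on the same table
#'   (computed if missing) supplying the selected random structure.
#' @param r_max Collinearity threshold on |Pearson r| (default 0.7).
#' @param level Confidence level.
#' @return A `scaling_fit` with additional elements `trait_terms` (kept
#'   predictors), `anova` (Satterthwaite F table), `trait_coefficients`,
#'   `partial_residuals` (tibble for trait panels), and the before/after
#'   marginal and conditional R2.
#' @export
fit_trait_lme <- function(within, base_fit = NULL, r_max = 0.7, level = 0.95) {
  d <- as.data.frame(within)
  d[[.eco]] <- factor(d[[.eco]])
  d[[.grp]] <- factor(d[[.grp]])
  multi_eco <- nlevels(d[[.eco]]) >= 2
  if (is.null(base_fit)) base_fit <- fit_within_lme(within, level = level)

  candidates <- c("ppmr_log10", "omnivory")
  kept <- character(0)
  for (tr in candidates) {
    v <- d[[tr]]
    if (anyNA(v) || stats::var(v) < 1e-12) {
      warning(sprintf("trait '%s' is constant or has missing values; dropped",
                      tr), call. = FALSE)
      next
    }
    against <- c(.x_within, kept)
    r <- vapply(against, function(a) abs(stats::cor(v, d[[a]])), numeric(1))
    if (any(r > r_max)) {
      warning(sprintf("trait '%s' correlated (|r| = %.2f > %.1f) with '%s'; dropped",
                      tr, max(r), r_max, against[which.max(r)]), call. = FALSE)
      next
    }
    kept <- c(kept, tr)
  }

  base_fixed <- if (!is.null(base_fit$selected_fixed)) {
    base_fit$selected_fixed
  } else if (multi_eco) {
    paste(.y_within, "~", .x_within, "*", .eco)
  } else paste(.y_within, "~", .x_within)
  re_chosen <- if (!is.null(base_fit$selected_random)) {
    c(correlated = paste0("(1 + ", .x_within, " | ", .grp, ")"),
      uncorrelated = paste0("(1 + ", .x_within, " || ", .grp, ")"),
      intercept_only = paste0("(1 | ", .grp, ")"))[[base_fit$selected_random]]
  } else paste0("(1 + ", .x_within, " | ", .grp, ")")

  trait_terms <- if (length(kept) == 0) {
    character(0)
  } else if (multi_eco) {
    paste(kept, "*", .eco)
  } else kept
  fml <- stats::as.formula(paste(
    c(base_fixed, trait_terms, re_chosen), collapse = " + "))
  m <- fit_lmer_safe(fml, d, REML = TRUE)

  ftab <- tryCatch({
    a <- stats::anova(m, ddf = "Satterthwaite")
    tibble::tibble(term = rownames(a), F = a$`F value`,
                   df_num = a$NumDF, df_den = a$DenDF,
                   p_value = a$`Pr(>F)`)
  }, error = function(e) {
    message("Satterthwaite F-tests unavailable (", conditionMessage(e),
            "); falling back to likelihood-ratio tests")
    NULL
  })

  beta <- lme4::fixef(m)
  X <- lme4::getME(m, "X")
  res <- stats::residuals(m)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(m), "term.labels")
  partial <- purrr::map_dfr(kept, function(tr) {
    idx <- which(labs == tr | grepl(paste0("^", tr, ":"), labs) |
                   grepl(paste0(":", tr, "$"), labs))
    cols <- which(asg %in% idx)
    contrib <- as.numeric(X[, cols, drop = FALSE] %*% beta[cols])
    tibble::tibble(web_id = d[[.grp]], ecosystem_type = d[[.eco]],
                   predator_id = d$predator_id, trait = tr,
                   trait_value = d[[tr]],
                   partial_residual = res + contrib)
  })

  rs <- random_structure(m)
  r2 <- r2_mixed(m)
  new_scaling_fit(
    kind = "within-web LME with predator traits",
    k_bar = unname(beta[.x_within]),
    ci_k = wald_ci(unname(beta[.x_within]),
                   sqrt(as.matrix(stats::vcov(m))[.x_within, .x_within]),
                   level),
    c_bar = unname(beta["(Intercept)"]),
    k_by_ecosystem = slopes_by_level(m, d, level = level),
    trait_terms = kept,
    trait_coefficients = if (length(kept) > 0) {
      beta[grepl(paste(kept, collapse = "|"), names(beta))]
    } else numeric(0),
    anova = ftab,
    partial_residuals = partial,
    random_effects = ranef_table(m),
    sigma_k = rs$sigma_k, sigma_c = rs$sigma_c, rho = rs$rho,
    sigma_res = stats::sigma(m),
    r2_marginal = r2$marginal, r2_conditional = r2$conditional,
    r2_marginal_base = base_fit$r2_marginal,
    r2_conditional_base = base_fit$r2_conditional,
    model = m, notes = character(0))
}

#' Across-web ANCOVA of biomass totals
#'
#' With one data point per web, mixed models are unnecessary: the exponent
#' is estimated by analysis of covariance of log10 total predator biomass
#' on log10 total prey biomass with ecosystem type as a factor. The
#' ecosystem-by-slope interaction is tested with an F-test comparing the
#' separate-slope model to the common-slope model; the common slope from
#' the additive model is reported as `k_bar` with its confidence interval,
#' alongside per-ecosystem slopes from the interaction model.
#'
#' @param across Web summary table from [build_across_table()].
#' @param response,xvar Column names of the response and covariate
#'   (defaults: log10 total predator and prey biomass).
#' @param level Confidence level.
#' @return A `scaling_fit` with `k_bar`, `ci_k`, `k_by_ecosystem`,
#'   `interaction_test` (F, df, p), and the fitted models.
#' @export
fit_across_ancova <- function(across,
                              response = "log10_total_predator_biomass",
                              xvar = "log10_total_prey_biomass",
                              level = 0.95) {
  d <- as.data.frame(across)
  d[[.eco]] <- droplevels(factor(d[[.eco]]))
  multi_eco <- nlevels(d[[.eco]]) >= 2
  if (stats::var(d[[xvar]]) == 0) {
    rlang::abort("across-web covariate has zero variance (rank-deficient design)",
                 class = "trophoscale_rank_error")
  }

  if (!multi_eco) {
    m <- stats::lm(stats::reformulate(xvar, response), data = d)
    ci <- suppressWarnings(stats::confint(m, xvar, level = level))
    return(new_scaling_fit(
      kind = "across-web OLS (single ecosystem type)",
      k_bar = unname(stats::coef(m)[xvar]),
      c_bar = unname(stats::coef(m)[1]),
      ci_k = as.numeric(ci),
      k_by_ecosystem = tibble::tibble(
        ecosystem_type = levels(d[[.eco]]),
        k = unname(stats::coef(m)[xvar]),
        se = suppressWarnings(summary(m)$coefficients[xvar, "Std. Error"]),
        ci_lo = ci[1], ci_hi = ci[2]),
      interaction_test = NULL, sigma_res = stats::sigma(m),
      r2_marginal = suppressWarnings(summary(m)$r.squared),
      r2_conditional = suppressWarnings(summary(m)$r.squared),
      model = m, notes = "single ecosystem type: interaction test skipped"))
  }

  m_int <- stats::lm(stats::as.formula(paste(response, "~", xvar, "*", .eco)),
                     data = d)
  m_add <- stats::lm(stats::as.formula(paste(response, "~", xvar, "+", .eco)),
                     data = d)
  if (m_int$rank < length(stats::coef(m_int))) {
    rlang::abort("across-web ANCOVA design is rank deficient",
                 class = "trophoscale_rank_error")
  }
  a <- stats::anova(m_add, m_int)
  itest <- tibble::tibble(F = a$F[2], df_num = a$Df[2], df_den = a$Res.Df[2],
                          p_value = a$`Pr(>F)`[2])
  ci <- suppressWarnings(stats::confint(m_add, xvar, level = level))

  # slope per ecosystem from the separate-slope model, t-based intervals
  kb <- slopes_by_level(m_int, d, xvar = xvar, level = level)
  tq <- stats::qt((1 + level) / 2, df = stats::df.residual(m_int))
  kb$ci_lo <- kb$k - tq * kb$se
  kb$ci_hi <- kb$k + tq * kb$se

  new_scaling_fit(
    kind = "across-web ANCOVA power law",
    k_bar = unname(stats::coef(m_add)[xvar]),
    c_bar = unname(stats::coef(m_add)[1]),
    ci_k = as.numeric(ci),
    k_by_ecosystem = kb,
    interaction_test = itest,
    slope_test = {
      sm <- suppressWarnings(summary(m_add)$coefficients)
      tibble::tibble(t = sm[xvar, "t value"], p_value = sm[xvar, "Pr(>|t|)"])
    },
    sigma_res = stats::sigma(m_add),
    r2_marginal = suppressWarnings(summary(m_add)$r.squared),
    r2_conditional = suppressWarnings(summary(m_add)$r.squared),
    model = m_add, model_interaction = m_int, notes = character(0))
}

#' Mean prey body mass versus total prey biomass
#'
#' Diagnostic for whether biomass scaling is driven by prey size rather
#' than prey density: re-runs the across-web ANCOVA with log10 mean prey
#' body mass as the response. A slope near 1 would implicate prey body
#' mass; a slope near 0 implicates prey density. Outlying webs (an
#' annotation, e.g. streams naturally lacking fish) are removed by id
#' before fitting.
#'
#' @param across Web summary table from [build_across_table()].
#' @param outlier_ids Web ids to exclude (default none).
#' @param level Confidence level.
#' @return A `scaling_fit`; `slope_test` carries the t-test of the common
#'   slope against zero.
#' @export
fit_prey_mass_model <- function(across, outlier_ids = character(),
                                level = 0.95) {
  d <- across[!(across$web_id %in% outlier_ids), ]
  fit <- fit_across_ancova(d, response = "log10_mean_prey_mass",
                           xvar = "log10_total_prey_biomass", level = level)
  fit$kind <- "across-web prey body-mass diagnostic"
  fit$n_outliers_removed <- sum(across$web_id %in% outlier_ids)
  fit
}

#' Biomass scaling of one predator species across webs
#'
#' For a species occurring as a retained predator in several webs, fits the
#' OLS power law of its biomass against its available prey biomass across
#' webs.
#'
#' @param within Predator-record table (must carry `predator_taxon`).
#' @param species_name Taxon name to select.
#' @param min_webs Minimum number of distinct webs required (default 5).
#' @param level Confidence level.
#' @return A `scaling_fit` with `k_bar`, `ci_k`, `n_webs`.
#' @export
fit_species_across_webs <- function(within, species_name, min_webs = 5,
                                    level = 0.95) {
  d <- as.data.frame(within[within$predator_taxon == species_name, ])
  nw <- length(unique(d$web_id))
  if (nw < min_webs) {
    rlang::abort(sprintf(
      "species '%s' occurs as a predator in only %d web(s); %d required",
      species_name, nw, min_webs), class = "trophoscale_fewwebs_error")
  }
  m <- stats::lm(stats::reformulate(.x_within, .y_within), data = d)
  ci <- suppressWarnings(stats::confint(m, .x_within, level = level))
  new_scaling_fit(
    kind = sprintf("species '%s' across %d webs (OLS)", species_name, nw),
    k_bar = unname(stats::coef(m)[.x_within]),
    c_bar = unname(stats::coef(m)[1]),
    ci_k = as.numeric(ci), n_webs = nw,
    sigma_res = stats::sigma(m),
    r2_marginal = suppressWarnings(summary(m)$r.squared),
    r2_conditional = suppressWarnings(summary(m)$r.squared),
    model = m, notes = character(0))
}

#' Predicted biomass gain under a power law
#'
#' For exponent `k`, multiplying prey biomass by `prey_fold` multiplies
#' predicted predator biomass by `prey_fold^k`; `biomass_gain()` expresses
#' this as a percentage increase. At k = 0.71, doubling prey biomass yields
#' about a 64% gain in predator biomass, and a five-fold prey increase an
#' approximately three-fold predator increase.
#'
#' @param k Power-law exponent.
#' @param prey_fold Multiplicative change in prey biomass (default 2).
#' @return `biomass_gain()`: percent increase in predator biomass;
#'   `predator_fold_change()`: the multiplicative factor `prey_fold^k`.
#' @export
#' @examples
#' biomass_gain(0.71)            # ~64 (%)
#' predator_fold_change(0.71, 5) # ~3-fold
biomass_gain <- function(k, prey_fold = 2) {
  (prey_fold^k - 1) * 100
}

#' @rdname biomass_gain
#' @export
predator_fold_change <- function(k, prey_fold = 5) {
  prey_fold^k
}
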
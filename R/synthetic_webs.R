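# Synthetic food-web generator: niche-ordered, layered, acyclic webs whose
# consumer biomasses are assigned bottom-up from the same power law the
# mixed model fits, with per-web random slope/intercept deviations. Parameter
# recovery on these webs is therefore a sharp test of the pipeline, not an
# approximation.

#' Configuration for the synthetic food-web generator
#'
#' Defaults emulate the structure of multi-ecosystem food-web collections:
#' three ecosystem types with tens of webs each, a few tens of nodes per
#' web spread over four trophic layers, lognormal body masses climbing
#' about two orders of magnitude per trophic level, and a log-log-linear
#' predator-prey biomass relation with per-web random slope and intercept
#' deviations plus lognormal residual scatter.
#'
#' @param n_webs Webs per ecosystem type.
#' @param ecosystems Character vector of ecosystem-type labels.
#' @param species_per_web Single count or `c(min, max)` range of nodes per
#'   web (sampled uniformly).
#' @param n_basal Number of basal resource nodes per web.
#' @param layer_fractions Fractions of consumers allocated to trophic
#'   layers 2, 3 and 4 (renormalised; each layer gets at least one node).
#' @param connectance_target Target link density L/S^2 used to set mean
#'   consumer generality.
#' @param k_bar,c_bar Generating mean exponent and normalisation (log10
#'   g/m^2 intercept) of the power law.
#' @param sigma_k,sigma_c Between-web SDs of the slope and intercept
#'   deviations.
#' @param rho Correlation of the slope and intercept deviations.
#' @param sigma_res Residual SD in log10 units (lognormal biomass scatter).
#' @param ppmr_effect,omnivory_effect Injected trait coefficients on log10
#'   predator biomass (default 0).
#' @param basal_biomass_range Width, in decades, of the log-uniform basal
#'   biomass distribution.
#' @param basal_biomass_centre_log10 Centre of that distribution (log10
#'   g/m^2).
#' @param ppmr_target_log10 Mean increase of log10 body mass per trophic
#'   level.
#' @param mass_scatter_log10 Lognormal scatter (log10 SD) of body masses
#'   around the trophic-level trend.
#' @param basal_mass_log10 Mean log10 body mass (g) of basal resources.
#' @param p_aggregate Probability that a consumer node is flagged as a
#'   coarse taxonomic aggregate.
#' @param adjust_vulnerability Whether the generating covariate is the
#'   vulnerability-adjusted available prey biomass (default `TRUE`,
#'   matching the default analysis).
#' @param seed Integer RNG seed; identical config + seed reproduce the
#'   dataset exactly.
#' @return Named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_webs = 30,
                             ecosystems = c("freshwater", "marine",
                                            "terrestrial"),
                             species_per_web = c(35, 45),
                             n_basal = 8,
                             layer_fractions = c(0.40, 0.35, 0.25),
                             connectance_target = 0.10,
                             k_bar = 0.75, c_bar = -0.5,
                             sigma_k = 0.05, sigma_c = 0.3, rho = 0,
                             sigma_res = 0.3,
                             ppmr_effect = 0, omnivory_effect = 0,
                             basal_biomass_range = 4,
                             basal_biomass_centre_log10 = 1,
                             ppmr_target_log10 = 2,
                             mass_scatter_log10 = 0.25,
                             basal_mass_log10 = -6,
                             p_aggregate = 0,
                             adjust_vulnerability = TRUE,
                             seed = 1) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  stopifnot(cfg$n_webs >= 0, length(cfg$ecosystems) >= 1,
            all(c(cfg$sigma_k, cfg$sigma_c, cfg$sigma_res,
                  cfg$mass_scatter_log10) >= 0),
            cfg$rho >= -1, cfg$rho <= 1,
            cfg$connectance_target > 0, cfg$connectance_target < 0.5,
            cfg$n_basal >= 1, cfg$p_aggregate >= 0, cfg$p_aggregate <= 1)
  cfg
}

#' Generate the topology of one synthetic web
#'
#' Builds a niche-ordered acyclic skeleton: `n_basal` basal nodes in layer
#' 1 and consumers spread over layers 2-4. Each consumer feeds on at least
#' one node of the layer directly below and samples further prey from all
#' lower layers (adjacent layer favoured 3:1), with mean generality set so
#' realised connectance approximates the target. At least three consumer
#' layers guarantee predators above the usual trophic-level cut-off.
#' Body masses and abundances are placeholders until
#' [assign_biomasses()] runs.
#'
#' @param config A [synthetic_config()].
#' @param web_id,ecosystem_type Labels for the generated web.
#' @param inject_loops If `TRUE`, adds an upward feeding link closing a
#'   2-cycle, for stress-testing the trophic-level solver (such skeletons
#'   cannot receive biomasses).
#' @return A `food_web` skeleton (body_mass 1, abundance 0) with a
#'   `"layer"` attribute.
#' @export
generate_topology <- function(config, web_id = "w1",
                              ecosystem_type = "freshwater",
                              inject_loops = FALSE) {
  S <- if (length(config$species_per_web) == 1) {
    config$species_per_web
  } else {
    sample(seq(config$species_per_web[1], config$species_per_web[2]), 1)
  }
  n_basal <- config$n_basal
  if (n_basal >= S - 2) {
    rlang::abort(sprintf(
      "web of %d nodes with %d basal resources leaves no room for three consumer layers",
      S, n_basal), class = "trophoscale_config_error")
  }
  n_cons <- S - n_basal
  fr <- config$layer_fractions / sum(config$layer_fractions)
  sizes <- pmax(1, round(fr * n_cons))
  while (sum(sizes) > n_cons) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
  while (sum(sizes) < n_cons) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1
  layer <- c(rep(1L, n_basal), rep(seq_along(sizes) + 1L, times = sizes))
  ids <- sprintf("n%03d", seq_len(S))

  g_target <- config$connectance_target * S^2 / n_cons
  if (g_target > S / 2) {
    rlang::abort(sprintf(
      "connectance target %.2f infeasible for %d nodes (%d consumers)",
      config$connectance_target, S, n_cons), class = "trophoscale_config_error")
  }

  links <- purrr::map_dfr(which(layer > 1L), function(i) {
    below <- which(layer < layer[i])
    adjacent <- which(layer == layer[i] - 1L)
    n_prey <- min(1 + stats::rpois(1, max(g_target - 1, 0)), length(below))
    first <- adjacent[sample.int(length(adjacent), 1)]
    rest <- setdiff(below, first)
    extra <- integer(0)
    if (n_prey > 1 && length(rest) > 0) {
      w <- ifelse(layer[rest] == layer[i] - 1L, 3, 1)
      extra <- rest[sample.int(length(rest), min(n_prey - 1, length(rest)),
                               prob = w)]
    }
    tibble::tibble(consumer_id = ids[i], resource_id = ids[c(first, extra)])
  })

  if (inject_loops) {
    top <- which(layer >= 3L)
    b <- top[sample.int(length(top), 1)]
    a_candidates <- links$resource_id[links$consumer_id == ids[b]]
    a_candidates <- a_candidates[a_candidates %in% ids[layer > 1L]]
    if (length(a_candidates) == 0) {
      mid <- ids[layer == 2L][1]
      links <- dplyr::bind_rows(links, tibble::tibble(
        consumer_id = ids[b], resource_id = mid))
      a_candidates <- mid
    }
    a <- a_candidates[1]
    links <- dplyr::bind_rows(links, tibble::tibble(
      consumer_id = a, resource_id = ids[b]))
  }

  nodes <- tibble::tibble(
    node_id = ids,
    taxon_name = sprintf("taxon_%s_%s", web_id, ids),
    body_mass = 1, abundance = 0,
    is_basal = layer == 1L,
    is_aggregate = layer > 1L &
      stats::runif(S) < config$p_aggregate)
  web <- food_web(web_id, ecosystem_type, nodes, links, validate = FALSE)
  attr(web, "layer") <- stats::setNames(layer, ids)
  web
}

#' Assign body masses, abundances and power-law biomasses to a skeleton
#'
#' Trophic levels are computed from the topology; log10 body mass rises by
#' `ppmr_target_log10` per trophic level with lognormal scatter. Basal
#' biomasses are drawn log-uniform over `basal_biomass_range` decades; then
#' each consumer, in niche order, receives biomass
#' `10^(c_i + trait terms + eps) * x^(k_i)` with `x` its (vulnerability-
#' adjusted) available prey biomass and `eps ~ Normal(0, sigma_res)`.
#' Abundance is biomass / body mass.
#'
#' @param skeleton Acyclic skeleton from [generate_topology()].
#' @param web_effects List with the per-web realised slope `k_i` and
#'   intercept `c_i`.
#' @param config A [synthetic_config()].
#' @return A complete, validated `food_web`.
#' @export
assign_biomasses <- function(skeleton, web_effects, config) {
  fl <- feeding_links(skeleton)
  g <- igraph::graph_from_data_frame(fl, directed = TRUE,
                                     vertices = skeleton$nodes$node_id)
  if (!igraph::is_dag(g)) {
    rlang::abort("assign_biomasses requires an acyclic skeleton",
                 class = "trophoscale_config_error")
  }
  ids <- skeleton$nodes$node_id
  S <- length(ids)
  tl <- compute_trophic_levels(skeleton)

  log10_mass <- config$basal_mass_log10 +
    config$ppmr_target_log10 * (tl - 1) +
    stats::rnorm(S, 0, config$mass_scatter_log10)
  mass <- stats::setNames(10^log10_mass, ids)

  deg <- compute_degree(skeleton)
  vul <- stats::setNames(deg$vulnerability, deg$node_id)
  prey <- prey_of(skeleton)

  omn <- compute_omnivory(skeleton, tl)
  ppmr <- vapply(ids, function(id) {
    p <- prey[[id]]
    if (length(p) == 0) return(0)
    log10(mass[id] / mean(mass[p]))
  }, numeric(1))

  is_basal <- skeleton$nodes$is_basal
  half <- config$basal_biomass_range / 2
  eps <- stats::rnorm(S, 0, config$sigma_res)
  basal_draw <- stats::runif(S, config$basal_biomass_centre_log10 - half,
                             config$basal_biomass_centre_log10 + half)
  biomass <- stats::setNames(rep(NA_real_, S), ids)
  for (i in seq_len(S)) {  # niche order: prey precede consumers
    id <- ids[i]
    if (is_basal[i]) {
      biomass[id] <- 10^basal_draw[i]
    } else {
      p <- prey[[id]]
      x <- if (config$adjust_vulnerability) {
        sum(biomass[p] / vul[p])
      } else sum(biomass[p])
      o <- if (is.na(omn[id])) 0 else omn[id]
      log10_y <- web_effects$c_i + web_effects$k_i * log10(x) +
        config$ppmr_effect * ppmr[[id]] + config$omnivory_effect * o +
        eps[i]
      biomass[id] <- 10^log10_y
    }
  }

  web <- skeleton
  web$nodes$body_mass <- unname(mass)
  web$nodes$abundance <- unname(biomass / mass)
  validate_food_web(web)
}

#' Generate a complete synthetic dataset
#'
#' Draws `n_webs` webs for each ecosystem type, each with its own realised
#' slope and intercept `(k_i, c_i) = (k_bar, c_bar) +` correlated normal
#' deviations, and records the truth table needed for parameter-recovery
#' tests. Per-web RNG substreams are derived from the master seed by
#' counter, so each web is reproducible independently of generation order.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_dataset` with elements `webs` (named
#'   list of `food_web`), `truth` (tibble `web_id, ecosystem_type, k_i,
#'   c_i, sigma_res`), and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  total <- config$n_webs * length(config$ecosystems)
  truth <- tibble::tibble(web_id = character(0),
                          ecosystem_type = character(0),
                          k_i = numeric(0), c_i = numeric(0),
                          sigma_res = numeric(0))
  webs <- list()
  if (total > 0) {
    set.seed(config$seed)
    subseeds <- sample.int(.Machine$integer.max - 1, total)
    idx <- 0
    for (eco in config$ecosystems) {
      for (i in seq_len(config$n_webs)) {
        idx <- idx + 1
        set.seed(subseeds[idx])
        web_id <- sprintf("%s_w%03d", eco, i)
        z <- stats::rnorm(2)
        c_i <- config$c_bar + config$sigma_c * z[1]
        k_i <- config$k_bar + config$sigma_k *
          (config$rho * z[1] + sqrt(1 - config$rho^2) * z[2])
        skel <- generate_topology(config, web_id = web_id,
                                  ecosystem_type = eco)
        webs[[web_id]] <- assign_biomasses(
          skel, list(k_i = k_i, c_i = c_i), config)
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          web_id = web_id, ecosystem_type = eco, k_i = k_i, c_i = c_i,
          sigma_res = config$sigma_res))
      }
    }
  }
  structure(list(webs = webs, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d webs (%s), k_bar = %.3f\n",
              length(x$webs),
              paste(unique(x$truth$ecosystem_type), collapse = "/"),
              x$config$k_bar))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the node/link CSV pair via [write_web_tables()] plus a
#' `truth.csv` with the per-web generating parameters.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @return Named character vector of file paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  paths <- write_web_tables(dataset$webs, dir)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(dataset$truth, truth_path, progress = FALSE)
  c(paths, truth = truth_path)
}
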
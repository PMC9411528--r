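# Builds the two analysis tables from webs + metrics:
#  - within-web: one record per retained predator (biomass vs the
#    vulnerability-adjusted total biomass of its prey)
#  - across-web: one record per retained web (biomass totals)
# applying the trophic-level, minimum-predator and biomass-range filters.

#' Pipeline configuration
#'
#' Collects the tunable filtering and aggregation options with their
#' defaults.
#'
#' @param tl_cutoff Predators must have prey-averaged trophic level strictly
#'   above this value (default 2.5; 3 is the usual sensitivity setting).
#' @param adjust_vulnerability Divide each prey node's biomass by its
#'   vulnerability before summing over a predator's prey (default `TRUE`).
#' @param min_predators Minimum number of predator records for a web to be
#'   retained (default 5).
#' @param min_x_range_decades Minimum within-web range (decades) of the
#'   log10 available-prey-biomass covariate (default 1).
#' @param exclude_aggregates_within Drop predators flagged as coarse
#'   taxonomic aggregates from the within-web records (default `TRUE`);
#'   aggregates are always kept for the across-web totals.
#' @param omnivory_denominator,prey_mass_mean Passed to [compute_metrics()].
#' @param across_prey_shared If `TRUE`, the across-web prey total uses
#'   vulnerability-shared biomass instead of counting each prey node once at
#'   full biomass (default `FALSE`).
#' @param mean_prey_mass_weighted If `TRUE`, the across-web mean prey body
#'   mass is abundance-weighted (default `FALSE`, plain mean).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(tl_cutoff = 2.5,
                            adjust_vulnerability = TRUE,
                            min_predators = 5,
                            min_x_range_decades = 1,
                            exclude_aggregates_within = TRUE,
                            omnivory_denominator = "population",
                            prey_mass_mean = "arithmetic",
                            across_prey_shared = FALSE,
                            mean_prey_mass_weighted = FALSE) {
  structure(list(
    tl_cutoff = tl_cutoff,
    adjust_vulnerability = adjust_vulnerability,
    min_predators = min_predators,
    min_x_range_decades = min_x_range_decades,
    exclude_aggregates_within = exclude_aggregates_within,
    omnivory_denominator = omnivory_denominator,
    prey_mass_mean = prey_mass_mean,
    across_prey_shared = across_prey_shared,
    mean_prey_mass_weighted = mean_prey_mass_weighted
  ), class = "pipeline_config")
}

#' Node standing-stock biomass
#'
#' Biomass of a node is its numerical abundance (individuals per m^2) times
#' its mean individual body mass (g dry weight), in g/m^2.
#'
#' @param body_mass,abundance Numeric vectors (recycled as usual).
#' @return Numeric vector of biomasses.
#' @export
#' @examples
#' node_biomass(0.5, 10)  # 5 g/m^2
node_biomass <- function(body_mass, abundance) {
  stopifnot(all(body_mass > 0), all(abundance >= 0))
  abundance * body_mass
}

web_biomass <- function(web) {
  stats::setNames(node_biomass(web$nodes$body_mass, web$nodes$abundance),
                  web$nodes$node_id)
}

#' Available prey biomass per predator
#'
#' For each consumer, sums the biomass of its prey nodes. When
#' `adjust_for_vulnerability` is `TRUE` (the default) each prey node's
#' biomass is first divided by its vulnerability — the number of consumers
#' feeding on it — so that a prey shared by several predators is split
#' equally among them and the shares over all its consumers sum exactly to
#' its biomass.
#'
#' @param web A [food_web()].
#' @param predator_id Optional single node id; if `NULL` the full named
#'   vector over all nodes with at least one prey is returned.
#' @param adjust_for_vulnerability Divide prey biomass by vulnerability.
#' @return Named numeric vector (g/m^2); nodes without prey get `NA`.
#' @export
available_prey_biomass <- function(web, predator_id = NULL,
                                   adjust_for_vulnerability = TRUE) {
  biomass <- web_biomass(web)
  deg <- compute_degree(web)
  vul <- stats::setNames(deg$vulnerability, deg$node_id)
  prey <- prey_of(web)
  shares <- function(p) {
    if (length(p) == 0) return(NA_real_)
    stopifnot(all(vul[p] >= 1))  # the predator itself consumes each prey
    if (adjust_for_vulnerability) sum(biomass[p] / vul[p]) else sum(biomass[p])
  }
  if (!is.null(predator_id)) {
    return(shares(prey[[predator_id]]))
  }
  out <- vapply(prey, shares, numeric(1))
  stats::setNames(out, web$nodes$node_id)
}

#' Select predators passing the trophic-level cut-off
#'
#' Predators are nodes whose prey-averaged trophic level exceeds
#' `tl_cutoff` (so they feed mostly on animal prey rather than basal
#' resources). For the within-web analysis, nodes flagged as coarse
#' taxonomic aggregates are additionally removed.
#'
#' @param web A [food_web()].
#' @param metrics Metrics table from [compute_metrics()] for this web.
#' @param tl_cutoff Trophic-level threshold (strict inequality).
#' @param exclude_aggregates Drop `is_aggregate` nodes.
#' @return Character vector of predator node ids.
#' @export
filter_predators <- function(web, metrics = compute_metrics(web),
                             tl_cutoff = 2.5, exclude_aggregates = FALSE) {
  keep <- metrics$trophic_level > tl_cutoff & metrics$generality >= 1
  if (exclude_aggregates) {
    agg <- stats::setNames(web$nodes$is_aggregate, web$nodes$node_id)
    keep <- keep & !agg[metrics$node_id]
  }
  metrics$node_id[keep]
}

#' Retain webs with enough predators and covariate spread
#'
#' A web is kept when it has at least `min_predators` predator records and
#' the available-prey-biomass covariate spans at least
#' `min_x_range_decades` orders of magnitude within the web.
#'
#' @param records Tibble of predator records with columns `web_id` and
#'   `log10_prey_biomass`.
#' @param min_predators Minimum record count per web.
#' @param min_x_range_decades Minimum range of `log10_prey_biomass`.
#' @return Character vector of retained web ids.
#' @export
filter_webs <- function(records, min_predators = 5, min_x_range_decades = 1) {
  if (nrow(records) == 0) return(character(0))
  summ <- records |>
    dplyr::group_by(.data$web_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      x_range = max(.data$log10_prey_biomass) - min(.data$log10_prey_biomass),
      .groups = "drop")
  summ$web_id[summ$n >= min_predators & summ$x_range >= min_x_range_decades]
}

# one predator record per qualifying node of one web (pre web-level filter)
web_predator_records <- function(web, config, exclude_aggregates) {
  metrics <- compute_metrics(web, denominator = config$omnivory_denominator,
                             prey_mass_mean = config$prey_mass_mean)
  preds <- filter_predators(web, metrics, tl_cutoff = config$tl_cutoff,
                            exclude_aggregates = exclude_aggregates)
  if (length(preds) == 0) return(NULL)
  biomass <- web_biomass(web)
  x <- available_prey_biomass(
    web, adjust_for_vulnerability = config$adjust_vulnerability)[preds]
  y <- biomass[preds]
  taxa <- stats::setNames(web$nodes$taxon_name, web$nodes$node_id)
  rec <- tibble::tibble(
    web_id = web$web_id,
    ecosystem_type = web$ecosystem_type,
    predator_id = preds,
    predator_taxon = unname(taxa[preds]),
    prey_biomass = unname(x),
    predator_biomass = unname(y),
    log10_prey_biomass = log10(unname(x)),
    log10_predator_biomass = log10(unname(y)),
    ppmr_log10 = metrics$ppmr_log10[match(preds, metrics$node_id)],
    omnivory = metrics$omnivory[match(preds, metrics$node_id)],
    trophic_level = metrics$trophic_level[match(preds, metrics$node_id)]
  )
  bad <- !(rec$prey_biomass > 0) | !(rec$predator_biomass > 0)
  if (any(bad)) {
    message(sprintf("web '%s': dropped %d predator record(s) with non-positive biomass (log10 undefined)",
                    web$web_id, sum(bad)))
    rec <- rec[!bad, ]
  }
  rec
}

#' Build the within-web predator record table
#'
#' One row per retained predator per retained web: its biomass (g/m^2), the
#' total (vulnerability-adjusted) biomass of its prey, both log10-
#' transformed, plus its trophic traits. Predators are filtered at the
#' trophic-level cut-off with aggregates removed; webs are then filtered on
#' minimum predator count and covariate range.
#'
#' @param webs List of [food_web()] objects.
#' @param config A [pipeline_config()].
#' @return Tibble of predator records.
#' @export
build_within_table <- function(webs, config = pipeline_config()) {
  if (inherits(webs, "food_web")) webs <- list(webs)
  records <- purrr::map_dfr(
    webs, web_predator_records, config = config,
    exclude_aggregates = config$exclude_aggregates_within)
  if (nrow(records) == 0) return(records)
  keep <- filter_webs(records, config$min_predators,
                      config$min_x_range_decades)
  dropped <- setdiff(unique(records$web_id), keep)
  if (length(dropped) > 0) {
    message(sprintf("build_within_table: dropped %d web(s) failing the min-predator or biomass-range filter",
                    length(dropped)))
  }
  records[records$web_id %in% keep, ]
}

#' Build the across-web summary table
#'
#' One row per retained web: the total biomass of its predators (trophic
#' level above the cut-off, aggregates included), the combined biomass of
#' the union of their prey nodes (each prey counted once at full biomass by
#' default), and the mean body mass over that prey set. Web retention uses
#' the same minimum-predator and covariate-range filter as the within-web
#' table but with aggregate predators included.
#'
#' @inheritParams build_within_table
#' @return Tibble with columns `web_id, ecosystem_type,
#'   total_predator_biomass, total_prey_biomass, mean_prey_body_mass,
#'   n_predators` plus their log10 transforms.
#' @export
build_across_table <- function(webs, config = pipeline_config()) {
  if (inherits(webs, "food_web")) webs <- list(webs)
  records <- purrr::map_dfr(webs, web_predator_records, config = config,
                            exclude_aggregates = FALSE)
  keep <- filter_webs(records, config$min_predators,
                      config$min_x_range_decades)
  rows <- purrr::map_dfr(webs, function(web) {
    if (!(web$web_id %in% keep)) return(NULL)
    metrics <- compute_metrics(web, denominator = config$omnivory_denominator,
                               prey_mass_mean = config$prey_mass_mean)
    preds <- filter_predators(web, metrics, tl_cutoff = config$tl_cutoff,
                              exclude_aggregates = FALSE)
    biomass <- web_biomass(web)
    prey <- prey_of(web)
    prey_union <- unique(unlist(prey[preds], use.names = FALSE))
    if (length(preds) == 0 || length(prey_union) == 0) {
      message(sprintf("build_across_table: web '%s' has an empty predator or prey set; excluded",
                      web$web_id))
      return(NULL)
    }
    deg <- compute_degree(web)
    vul <- stats::setNames(deg$vulnerability, deg$node_id)
    prey_total <- if (config$across_prey_shared) {
      sum(unlist(lapply(preds, function(p) {
        pp <- prey[[p]]
        sum(biomass[pp] / vul[pp])
      })))
    } else {
      sum(biomass[prey_union])
    }
    mass <- stats::setNames(web$nodes$body_mass, web$nodes$node_id)
    abund <- stats::setNames(web$nodes$abundance, web$nodes$node_id)
    mean_mass <- if (config$mean_prey_mass_weighted) {
      stats::weighted.mean(mass[prey_union], abund[prey_union])
    } else {
      mean(mass[prey_union])
    }
    tibble::tibble(
      web_id = web$web_id,
      ecosystem_type = web$ecosystem_type,
      total_predator_biomass = sum(biomass[preds]),
      total_prey_biomass = prey_total,
      mean_prey_body_mass = mean_mass,
      n_predators = length(preds)
    )
  })
  if (nrow(rows) == 0) return(rows)
  rows$log10_total_predator_biomass <- log10(rows$total_predator_biomass)
  rows$log10_total_prey_biomass <- log10(rows$total_prey_biomass)
  rows$log10_mean_prey_mass <- log10(rows$mean_prey_body_mass)
  rows
}
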
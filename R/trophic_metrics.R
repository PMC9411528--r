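# Per-node trophic metrics: prey-averaged trophic level, omnivory,
# generality / vulnerability, and predator-prey body mass ratio.
# Self-links (cannibalism) are excluded from every computation here.

feeding_links <- function(web) {
  web$links[!web$links$is_cannibal, c("consumer_id", "resource_id")]
}

prey_of <- function(web) {
  fl <- feeding_links(web)
  split(fl$resource_id, factor(fl$consumer_id, levels = web$nodes$node_id))
}

#' Compute prey-averaged trophic levels
#'
#' The trophic level of node i is defined as one plus the mean trophic level
#' of its prey, with basal resources (no prey) fixed at 1. Diet weights are
#' equal (1/generality) over each consumer's prey, so the vector TL solves
#' the linear system TL = 1 + D TL, where D is the row-stochastic diet
#' matrix. The system is solved exactly, which remains valid for webs with
#' feeding loops as long as every loop drains to a basal resource.
#'
#' @param web A [food_web()].
#' @return Named numeric vector of trophic levels (names are node ids).
#'   Basal nodes have TL exactly 1; any consumer has TL >= 2.
#' @export
#' @examples
#' web <- food_web("w", "marine",
#'   nodes = data.frame(node_id = c("A", "B", "C"), taxon_name = "t",
#'                      body_mass = 1, abundance = 1,
#'                      is_basal = c(TRUE, FALSE, FALSE), is_aggregate = FALSE),
#'   links = data.frame(consumer_id = c("B", "C"), resource_id = c("A", "B")))
#' compute_trophic_levels(web)  # A = 1, B = 2, C = 3
compute_trophic_levels <- function(web) {
  ids <- web$nodes$node_id
  n <- length(ids)
  fl <- feeding_links(web)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(fl) > 0) {
    gen <- table(fl$consumer_id)
    D[cbind(fl$consumer_id, fl$resource_id)] <-
      1 / as.numeric(gen[fl$consumer_id])
  }
  A <- diag(n) - D
  tl <- tryCatch(
    solve(A, rep(1, n)),
    error = function(e) {
      offenders <- unsolvable_components(web)
      rlang::abort(
        sprintf(
          "trophic levels undefined for web '%s': feeding loop(s) with no path to a basal resource involving node(s): %s",
          web$web_id, paste(offenders, collapse = ", ")),
        class = "trophoscale_tl_error")
    })
  stats::setNames(as.numeric(tl), ids)
}

# strongly connected components from which no basal node is reachable
unsolvable_components <- function(web) {
  fl <- feeding_links(web)
  g <- igraph::graph_from_data_frame(
    fl[, c("consumer_id", "resource_id")], directed = TRUE,
    vertices = data.frame(name = web$nodes$node_id))
  basal <- web$nodes$node_id[!(web$nodes$node_id %in% fl$consumer_id)]
  comp <- igraph::components(g, mode = "strong")
  bad <- character(0)
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2 && !any(fl$consumer_id == members &
                                    fl$resource_id == members)) next
    reach <- names(igraph::subcomponent(g, members[1], mode = "out"))
    if (!any(reach %in% basal)) bad <- c(bad, members)
  }
  if (length(bad) == 0) bad <- "<unidentified>"
  unique(bad)
}

#' Compute predator omnivory
#'
#' Omnivory of a consumer is the variance of the trophic levels of its prey
#' set, using the population denominator (number of prey): a consumer whose
#' prey all share one trophic level has omnivory 0, and a single-prey
#' specialist has omnivory 0. Basal nodes get `NA`.
#'
#' @param web A [food_web()].
#' @param trophic_levels Named TL vector from [compute_trophic_levels()]
#'   (computed if missing).
#' @param denominator `"population"` (divide by n, the default) or
#'   `"sample"` (divide by n - 1); the field convention treats the prey set
#'   as complete, hence population.
#' @return Named numeric vector (NA for nodes without prey).
#' @export
compute_omnivory <- function(web, trophic_levels = compute_trophic_levels(web),
                             denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  prey <- prey_of(web)
  out <- vapply(prey, function(p) {
    if (length(p) == 0) return(NA_real_)
    tls <- trophic_levels[p]
    if (anyNA(tls)) {
      rlang::abort("omnivory: prey with missing trophic level",
                   class = "trophoscale_internal_error")
    }
    if (length(p) == 1) return(0)
    v <- stats::var(tls)  # sample variance
    if (denominator == "population") v * (length(p) - 1) / length(p) else v
  }, numeric(1))
  stats::setNames(out, web$nodes$node_id)
}

#' Compute generality and vulnerability
#'
#' Generality is a consumer's number of prey nodes (out-degree over feeding
#' links); vulnerability is the number of consumer nodes feeding on a node
#' (in-degree). Self-links are excluded from both. Vulnerability counts all
#' consumers regardless of their biomass.
#'
#' @param web A [food_web()].
#' @return Tibble with columns `node_id`, `generality`, `vulnerability`.
#' @export
compute_degree <- function(web) {
  fl <- feeding_links(web)
  ids <- web$nodes$node_id
  gen <- table(factor(fl$consumer_id, levels = ids))
  vul <- table(factor(fl$resource_id, levels = ids))
  tibble::tibble(node_id = ids,
                 generality = as.integer(gen),
                 vulnerability = as.integer(vul))
}

#' Compute log10 predator-prey body mass ratio
#'
#' PPmR of a predator is its mean body mass divided by the unweighted
#' arithmetic mean of its prey's body masses, log10-transformed. Nodes
#' without prey get `NA`.
#'
#' @param web A [food_web()].
#' @param prey_mass_mean `"arithmetic"` (default) or `"geometric"` mean of
#'   prey body masses.
#' @return Named numeric vector of log10 mass ratios.
#' @export
compute_ppmr <- function(web, prey_mass_mean = c("arithmetic", "geometric")) {
  prey_mass_mean <- match.arg(prey_mass_mean)
  prey <- prey_of(web)
  mass <- stats::setNames(web$nodes$body_mass, web$nodes$node_id)
  out <- vapply(names(prey), function(id) {
    p <- prey[[id]]
    if (length(p) == 0) return(NA_real_)
    pm <- mass[p]
    pm <- pm[is.finite(pm) & pm > 0]
    if (length(pm) == 0) {
      message(sprintf("compute_ppmr: node '%s' has no prey with usable body mass; PPmR undefined", id))
      return(NA_real_)
    }
    mbar <- if (prey_mass_mean == "arithmetic") mean(pm) else exp(mean(log(pm)))
    log10(mass[id] / mbar)
  }, numeric(1))
  stats::setNames(out, web$nodes$node_id)
}

#' Compute all per-node trophic metrics for a web
#'
#' Convenience wrapper returning the tidy metrics table used by the
#' biomass pipeline.
#'
#' @param web A [food_web()].
#' @inheritParams compute_omnivory
#' @inheritParams compute_ppmr
#' @return Tibble with columns `web_id, node_id, trophic_level, omnivory,
#'   generality, vulnerability, ppmr_log10`.
#' @export
compute_metrics <- function(web, denominator = "population",
                            prey_mass_mean = "arithmetic") {
  tl <- compute_trophic_levels(web)
  deg <- compute_degree(web)
  tibble::tibble(
    web_id = web$web_id,
    node_id = web$nodes$node_id,
    trophic_level = as.numeric(tl),
    omnivory = as.numeric(compute_omnivory(web, tl, denominator = denominator)),
    generality = deg$generality,
    vulnerability = deg$vulnerability,
    ppmr_log10 = as.numeric(compute_ppmr(web, prey_mass_mean = prey_mass_mean))
  )
}
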
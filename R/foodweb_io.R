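#' Construct a food web
#'
#' A food web couples a node table (taxa with mean individual body mass and
#' numerical abundance) with a directed feeding-link table
#' (consumer -> resource) under a web identifier and an ecosystem-type label.
#'
#' @param web_id Single string identifying the web.
#' @param ecosystem_type One of `"freshwater"`, `"marine"`, `"terrestrial"`.
#' @param nodes Data frame with columns `node_id` (unique, character),
#'   `taxon_name`, `body_mass` (g dry weight, > 0), `abundance`
#'   (individuals per m^2, >= 0), `is_basal`, `is_aggregate` (logical).
#' @param links Data frame with columns `consumer_id`, `resource_id`, both
#'   referring to `nodes$node_id`. Self-links (cannibalism) are retained and
#'   flagged in the `is_cannibal` column; they are excluded from all trophic
#'   computations downstream.
#' @param validate Run [validate_food_web()] on the result (default `TRUE`).
#'
#' @return An object of class `food_web`: a list with elements `web_id`,
#'   `ecosystem_type`, `nodes` (tibble), `links` (tibble).
#' @export
#' @examples
#' web <- food_web(
#'   "w1", "freshwater",
#'   nodes = data.frame(
#'     node_id = c("A", "B", "C"), taxon_name = c("alga", "grazer", "fish"),
#'     body_mass = c(1e-6, 1e-3, 1), abundance = c(1e6, 1e3, 1),
#'     is_basal = c(TRUE, FALSE, FALSE), is_aggregate = FALSE
#'   ),
#'   links = data.frame(consumer_id = c("B", "C"), resource_id = c("A", "B"))
#' )
#' web
food_web <- function(web_id, ecosystem_type, nodes, links, validate = TRUE) {
  stopifnot(is.character(web_id) || is.factor(web_id), length(web_id) == 1)
  nodes <- tibble::as_tibble(nodes)
  links <- tibble::as_tibble(links)

  required_nodes <- c("node_id", "taxon_name", "body_mass", "abundance",
                      "is_basal", "is_aggregate")
  if (!("taxon_name" %in% names(nodes))) nodes$taxon_name <- nodes$node_id
  if (!("is_basal" %in% names(nodes))) nodes$is_basal <- NA
  if (!("is_aggregate" %in% names(nodes))) nodes$is_aggregate <- FALSE
  missing_cols <- setdiff(required_nodes, names(nodes))
  if (length(missing_cols) > 0) {
    abort_format(paste0("node table is missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  missing_link_cols <- setdiff(c("consumer_id", "resource_id"), names(links))
  if (length(missing_link_cols) > 0) {
    abort_format(paste0("link table is missing mandatory column(s): ",
                        paste(missing_link_cols, collapse = ", ")))
  }

  nodes$node_id <- as.character(nodes$node_id)
  nodes$is_basal <- as.logical(nodes$is_basal)
  nodes$is_aggregate <- as.logical(nodes$is_aggregate)
  links$consumer_id <- as.character(links$consumer_id)
  links$resource_id <- as.character(links$resource_id)
  links$is_cannibal <- links$consumer_id == links$resource_id
  links <- dplyr::distinct(links, .data$consumer_id, .data$resource_id,
                           .keep_all = TRUE)

  web <- structure(
    list(web_id = as.character(web_id),
         ecosystem_type = as.character(ecosystem_type),
         nodes = nodes[required_nodes],
         links = links[c("consumer_id", "resource_id", "is_cannibal")]),
    class = "food_web"
  )
  if (validate) web <- validate_food_web(web)
  web
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("<food_web> %s (%s): %d nodes, %d links (%d basal, %d aggregate)\n",
              x$web_id, x$ecosystem_type, nrow(x$nodes), nrow(x$links),
              sum(x$nodes$is_basal), sum(x$nodes$is_aggregate)))
  invisible(x)
}

#' @export
format.food_web <- function(x, ...) {
  sprintf("<food_web> %s (%d nodes, %d links)", x$web_id,
          nrow(x$nodes), nrow(x$links))
}

#' Validate a food web
#'
#' Checks the structural invariants: unique node ids, positive body masses,
#' non-negative abundances, links referencing known nodes, and consistency of
#' the `is_basal` flag with the link structure (a node is basal iff it has no
#' outgoing prey links, self-links excluded). Flag mismatches are repaired
#' from the link structure with a warning; structural violations raise a
#' classed validation error.
#'
#' @param web A `food_web`.
#' @return The (possibly repaired) `food_web`, invisibly classed as before.
#' @export
validate_food_web <- function(web) {
  nodes <- web$nodes
  links <- web$links

  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup) > 0) {
    abort_validation(sprintf("web '%s': duplicated node_id(s): %s",
                             web$web_id, paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.finite(nodes$body_mass)) || any(nodes$body_mass <= 0)) {
    bad <- nodes$node_id[!is.finite(nodes$body_mass) | nodes$body_mass <= 0]
    abort_validation(sprintf(
      "web '%s': non-positive or missing body_mass for node(s): %s (drop rows before construction, e.g. via read_web_tables())",
      web$web_id, paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(nodes$abundance)) || any(nodes$abundance < 0)) {
    bad <- nodes$node_id[!is.finite(nodes$abundance) | nodes$abundance < 0]
    abort_validation(sprintf("web '%s': negative or missing abundance for node(s): %s",
                             web$web_id, paste(bad, collapse = ", ")))
  }
  unknown <- setdiff(c(links$consumer_id, links$resource_id), nodes$node_id)
  if (length(unknown) > 0) {
    abort_validation(sprintf("web '%s': link(s) reference unknown node(s): %s",
                             web$web_id, paste(unknown, collapse = ", ")))
  }

  # basal <=> no outgoing prey links (self-links do not count as feeding)
  feeding <- links[!links$is_cannibal, ]
  has_prey <- nodes$node_id %in% feeding$consumer_id
  structural_basal <- !has_prey
  if (any(is.na(nodes$is_basal))) {
    nodes$is_basal[is.na(nodes$is_basal)] <-
      structural_basal[is.na(nodes$is_basal)]
  }
  mismatch <- nodes$is_basal != structural_basal
  if (any(mismatch)) {
    warning(sprintf(
      "web '%s': is_basal flag inconsistent with link structure for %d node(s) (%s); repaired from links",
      web$web_id, sum(mismatch),
      paste(utils::head(nodes$node_id[mismatch], 5), collapse = ", ")),
      call. = FALSE)
    nodes$is_basal <- structural_basal
  }
  if (!any(structural_basal)) {
    warning(sprintf("web '%s' has no basal node (every node has prey); trophic levels will be undefined",
                    web$web_id), call. = FALSE)
  }
  web$nodes <- nodes
  web
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "trophoscale_format_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "trophoscale_validation_error")
}

# canonical column dialect for node / link tables
.node_cols <- c("web_id", "ecosystem_type", "node_id", "taxon_name",
                "body_mass_g", "abundance_per_m2", "is_basal", "is_aggregate")
.link_cols <- c("web_id", "consumer_id", "resource_id")

#' Read food webs from node and link tables
#'
#' Ingests a multi-web dataset from two CSV files (or connections): a node
#' table with columns `web_id, ecosystem_type, node_id, taxon_name,
#' body_mass_g, abundance_per_m2, is_basal, is_aggregate` (booleans coded
#' 0/1) and a link table with `web_id, consumer_id, resource_id`. A mapping
#' (YAML file or named list) can rename columns of a foreign export to this
#' dialect, e.g. `columns: {body_mass_g: bodymass}`.
#'
#' Rows with non-positive body mass or missing abundance are dropped (with
#' their links) and the count reported via `message()`. Self-links are kept
#' but flagged. Links referencing unknown nodes raise a validation error.
#'
#' @param nodes_source,links_source File paths or connections readable by
#'   [readr::read_csv()].
#' @param mapping Optional path to a YAML file with a `columns:` block, or a
#'   named list mapping dialect column names to source column names.
#' @return Named list of [food_web()] objects, one per distinct `web_id`.
#' @export
read_web_tables <- function(nodes_source, links_source, mapping = NULL) {
  # base read.csv: strtod parsing is correctly rounded, so numeric text
  # written at full precision round-trips bit-exactly
  nodes <- tibble::as_tibble(utils::read.csv(nodes_source,
                                             stringsAsFactors = FALSE))
  links <- tibble::as_tibble(utils::read.csv(links_source,
                                             stringsAsFactors = FALSE))

  map <- read_column_mapping(mapping)
  nodes <- apply_column_mapping(nodes, map)
  links <- apply_column_mapping(links, map)

  miss_n <- setdiff(.node_cols, names(nodes))
  if (length(miss_n) > 0) {
    abort_format(paste0("nodes CSV is missing mandatory column(s): ",
                        paste(miss_n, collapse = ", ")))
  }
  miss_l <- setdiff(.link_cols, names(links))
  if (length(miss_l) > 0) {
    abort_format(paste0("links CSV is missing mandatory column(s): ",
                        paste(miss_l, collapse = ", ")))
  }

  nodes$node_id <- as.character(nodes$node_id)
  links$consumer_id <- as.character(links$consumer_id)
  links$resource_id <- as.character(links$resource_id)

  bad <- !is.finite(nodes$body_mass_g) | nodes$body_mass_g <= 0 |
    !is.finite(nodes$abundance_per_m2) | nodes$abundance_per_m2 < 0
  if (any(bad)) {
    message(sprintf("read_web_tables: dropped %d node row(s) with non-positive body mass or missing abundance",
                    sum(bad)))
    dropped <- nodes[bad, c("web_id", "node_id")]
    nodes <- nodes[!bad, ]
    drop_key <- paste(dropped$web_id, dropped$node_id)
    link_key_c <- paste(links$web_id, links$consumer_id)
    link_key_r <- paste(links$web_id, links$resource_id)
    links <- links[!(link_key_c %in% drop_key | link_key_r %in% drop_key), ]
  }

  web_ids <- unique(nodes$web_id)
  webs <- lapply(web_ids, function(w) {
    n <- nodes[nodes$web_id == w, ]
    l <- links[links$web_id == w, ]
    eco <- unique(n$ecosystem_type)
    if (length(eco) != 1) {
      abort_validation(sprintf("web '%s' has conflicting ecosystem_type labels: %s",
                               w, paste(eco, collapse = ", ")))
    }
    food_web(
      web_id = as.character(w), ecosystem_type = eco,
      nodes = tibble::tibble(
        node_id = n$node_id, taxon_name = n$taxon_name,
        body_mass = n$body_mass_g, abundance = n$abundance_per_m2,
        is_basal = as.logical(n$is_basal),
        is_aggregate = as.logical(n$is_aggregate)
      ),
      links = tibble::tibble(consumer_id = l$consumer_id,
                             resource_id = l$resource_id)
    )
  })
  stats::setNames(webs, web_ids)
}

read_column_mapping <- function(mapping) {
  if (is.null(mapping)) return(NULL)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  if (!is.null(mapping$columns)) mapping <- mapping$columns
  if (length(mapping) == 0) return(NULL)
  unlist(mapping)
}

apply_column_mapping <- function(df, map) {
  if (is.null(map)) return(df)
  for (canonical in names(map)) {
    src <- map[[canonical]]
    if (src %in% names(df) && !(canonical %in% names(df))) {
      names(df)[names(df) == src] <- canonical
    }
  }
  df
}

#' Write food webs to node and link tables
#'
#' Serialises a collection of webs back to the two-table CSV dialect read by
#' [read_web_tables()]. Numeric columns are written with full round-trip
#' precision, so `read_web_tables()` on the output reproduces the webs
#' field-for-field, and identical inputs yield byte-identical files.
#'
#' @param webs A `food_web` or list of them.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix; files are `<prefix>nodes.csv` and
#'   `<prefix>links.csv`.
#' @return Named character vector with elements `nodes` and `links` (paths).
#' @export
write_web_tables <- function(webs, dir, prefix = "") {
  if (inherits(webs, "food_web")) webs <- list(webs)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      rlang::abort(sprintf("cannot create output directory '%s'", dir),
                   class = "trophoscale_io_error")
    }
  }
  nodes <- purrr::map_dfr(webs, function(w) {
    tibble::tibble(
      web_id = w$web_id, ecosystem_type = w$ecosystem_type,
      node_id = w$nodes$node_id, taxon_name = w$nodes$taxon_name,
      body_mass_g = w$nodes$body_mass,
      abundance_per_m2 = w$nodes$abundance,
      is_basal = as.integer(w$nodes$is_basal),
      is_aggregate = as.integer(w$nodes$is_aggregate)
    )
  })
  links <- purrr::map_dfr(webs, function(w) {
    tibble::tibble(web_id = w$web_id,
                   consumer_id = w$links$consumer_id,
                   resource_id = w$links$resource_id)
  })
  if (nrow(nodes) == 0) {
    nodes <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(.node_cols)), .node_cols))
  }
  if (nrow(links) == 0) {
    links <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(.link_cols)), .link_cols))
  }
  paths <- c(nodes = file.path(dir, paste0(prefix, "nodes.csv")),
             links = file.path(dir, paste0(prefix, "links.csv")))
  readr::write_csv(nodes, paths[["nodes"]], progress = FALSE)
  readr::write_csv(links, paths[["links"]], progress = FALSE)
  paths
}
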
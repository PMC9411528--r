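# Fixture builders and independent oracles shared by the tests.
# The oracles deliberately avoid the package's linear-algebra path so they
# can cross-check it.

# small web from a compact spec: prey_list maps consumer -> prey ids
toy_web <- function(prey_list, masses = NULL, abundances = NULL,
                    web_id = "toy", eco = "freshwater", aggregates = character(0)) {
  ids <- sort(unique(c(names(prey_list), unlist(prey_list, use.names = FALSE))))
  if (is.null(masses)) masses <- setNames(rep(1, length(ids)), ids)
  if (is.null(abundances)) abundances <- setNames(rep(1, length(ids)), ids)
  links <- do.call(rbind, lapply(names(prey_list), function(cns) {
    if (length(prey_list[[cns]]) == 0) return(NULL)
    data.frame(consumer_id = cns, resource_id = prey_list[[cns]])
  }))
  if (is.null(links)) links <- data.frame(consumer_id = character(0),
                                          resource_id = character(0))
  suppressWarnings(food_web(
    web_id, eco,
    nodes = data.frame(node_id = ids, taxon_name = ids,
                       body_mass = as.numeric(masses[ids]),
                       abundance = as.numeric(abundances[ids]),
                       is_basal = NA, is_aggregate = ids %in% aggregates),
    links = links))
}

chain_web <- function(...) {
  toy_web(list(B = "A", C = "B"), ...)
}

# random acyclic web via niche ordering; independent of the package generator
random_dag_web <- function(n = 12, p = 0.25, web_id = "dag") {
  ids <- sprintf("v%02d", seq_len(n))
  links <- NULL
  for (i in 2:n) {
    prey <- which(stats::runif(i - 1) < p)
    if (length(prey) > 0) {
      links <- rbind(links, data.frame(consumer_id = ids[i],
                                       resource_id = ids[prey]))
    }
  }
  if (is.null(links)) links <- data.frame(consumer_id = ids[2],
                                          resource_id = ids[1])
  suppressWarnings(food_web(
    web_id, "marine",
    nodes = data.frame(node_id = ids, taxon_name = ids,
                       body_mass = 10^stats::runif(n, -6, 0),
                       abundance = 10^stats::runif(n, 0, 6),
                       is_basal = NA, is_aggregate = FALSE),
    links = links))
}

# oracle 1: recursive trophic levels in topological order (DAGs only)
tl_recursive <- function(web) {
  ids <- web$nodes$node_id
  fl <- web$links[!web$links$is_cannibal, ]
  prey <- split(fl$resource_id, factor(fl$consumer_id, levels = ids))
  tl <- setNames(rep(NA_real_, length(ids)), ids)
  visit <- function(id) {
    if (!is.na(tl[[id]])) return(tl[[id]])
    p <- prey[[id]]
    tl[[id]] <<- if (length(p) == 0) 1 else 1 + mean(vapply(p, visit, numeric(1)))
    tl[[id]]
  }
  for (id in ids) visit(id)
  tl
}

# oracle 2: fixed-point iteration from TL = 1 (handles feeding loops)
tl_fixed_point <- function(web, tol = 1e-13, max_iter = 100000) {
  ids <- web$nodes$node_id
  fl <- web$links[!web$links$is_cannibal, ]
  prey <- split(fl$resource_id, factor(fl$consumer_id, levels = ids))
  tl <- setNames(rep(1, length(ids)), ids)
  for (it in seq_len(max_iter)) {
    new <- vapply(ids, function(i) {
      p <- prey[[i]]
      if (length(p) == 0) 1 else 1 + mean(tl[p])
    }, numeric(1))
    if (max(abs(new - tl)) < tol) return(new)
    tl <- new
  }
  tl
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
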
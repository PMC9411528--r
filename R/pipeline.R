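# End-to-end orchestration: ingest -> metrics -> analysis tables -> fits,
# with per-stage record counts and optional CSV/JSON output. The pipeline
# is a pure function of its inputs and configuration; repeated runs on
# identical inputs produce identical output.

#' Run the full biomass-scaling pipeline
#'
#' Reads webs (from CSV files or an in-memory list), computes per-node
#' trophic metrics, builds the within- and across-web analysis tables, and
#' fits the within-web mixed model, the trait-augmented model, per-web OLS
#' slopes, the across-web ANCOVA and the prey body-mass diagnostic. Stage
#' counts are recorded so the effect of each filter is visible.
#'
#' @param nodes_csv,links_csv Paths to the node and link tables (see
#'   [read_web_tables()]); ignored when `webs` is given.
#' @param webs Optional named list of [food_web()] objects, bypassing I/O.
#' @param config A [pipeline_config()].
#' @param mapping Optional column mapping passed to [read_web_tables()].
#' @param prey_mass_outliers Web ids excluded from the prey body-mass
#'   diagnostic (a data annotation, e.g. webs naturally lacking fish).
#' @param out_dir Optional directory; when given, intermediate tables
#'   (`metrics.csv`, `within_table.csv`, `across_table.csv`,
#'   `per_web_slopes.csv`) and a numeric `report.json` are written there.
#' @return A `pipeline_report`: list with `status` (`"ok"` or
#'   `"empty-after-filters"`), `counts`, the two tables, and the fitted
#'   `scaling_fit` objects (`within`, `traits`, `per_web`, `across`,
#'   `prey_mass`).
#' @export
run_pipeline <- function(nodes_csv = NULL, links_csv = NULL, webs = NULL,
                         config = pipeline_config(), mapping = NULL,
                         prey_mass_outliers = character(),
                         out_dir = NULL) {
  if (is.null(webs)) {
    webs <- read_web_tables(nodes_csv, links_csv, mapping = mapping)
  }
  if (inherits(webs, "synthetic_dataset")) webs <- webs$webs

  metrics <- purrr::map_dfr(webs, compute_metrics,
                            denominator = config$omnivory_denominator,
                            prey_mass_mean = config$prey_mass_mean)
  within <- build_within_table(webs, config)
  across <- build_across_table(webs, config)

  counts <- list(
    n_webs_input = length(webs),
    n_within_webs = length(unique(within$web_id)),
    n_within_records = nrow(within),
    n_across_webs = nrow(across))

  fits <- list(within = NULL, traits = NULL, per_web = NULL,
               across = NULL, prey_mass = NULL)
  status <- "ok"
  if (counts$n_within_webs == 0 && counts$n_across_webs == 0) {
    status <- "empty-after-filters"
    message("run_pipeline: no webs survive the filters; no models fitted")
  } else {
    if (counts$n_within_webs >= 2) {
      fits$within <- fit_within_lme(within)
      fits$traits <- tryCatch(
        fit_trait_lme(within, base_fit = fits$within),
        error = function(e) {
          message("trait model skipped: ", conditionMessage(e)); NULL
        })
      fits$per_web <- fit_per_web_ols(within)
    }
    if (counts$n_across_webs >= 3) {
      fits$across <- tryCatch(
        fit_across_ancova(across),
        error = function(e) {
          message("across-web model skipped: ", conditionMessage(e)); NULL
        })
      fits$prey_mass <- tryCatch(
        fit_prey_mass_model(across, outlier_ids = prey_mass_outliers),
        error = function(e) {
          message("prey-mass model skipped: ", conditionMessage(e)); NULL
        })
    }
  }

  report <- structure(list(
    status = status, counts = counts, config = unclass(config),
    metrics = metrics, within_table = within, across_table = across,
    fits = fits,
    version = as.character(utils::packageVersion("trophoscale"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> status:", x$status, "\n")
  cat(sprintf("  webs: %d in, %d within-web, %d across-web\n",
              x$counts$n_webs_input, x$counts$n_within_webs,
              x$counts$n_across_webs))
  cat(sprintf("  within-web records: %d\n", x$counts$n_within_records))
  if (!is.null(x$fits$within)) {
    cat(sprintf("  within-web k_bar = %.3f (%.3f to %.3f)\n",
                x$fits$within$k_bar, x$fits$within$ci_k[1],
                x$fits$within$ci_k[2]))
  }
  if (!is.null(x$fits$across)) {
    cat(sprintf("  across-web k_bar = %.3f (%.3f to %.3f)\n",
                x$fits$across$k_bar, x$fits$across$ci_k[1],
                x$fits$across$ci_k[2]))
  }
  invisible(x)
}

# numeric view of a scaling_fit, safe for JSON serialisation
summarise_fit <- function(fit) {
  if (is.null(fit)) return(NULL)
  out <- list(kind = fit$kind, k_bar = fit$k_bar, c_bar = fit$c_bar,
              ci_k = fit$ci_k, sigma_k = fit$sigma_k,
              sigma_c = fit$sigma_c, rho = fit$rho,
              sigma_res = fit$sigma_res,
              r2_marginal = fit$r2_marginal,
              r2_conditional = fit$r2_conditional,
              notes = fit$notes)
  if (!is.null(fit$k_by_ecosystem)) {
    out$k_by_ecosystem <- as.data.frame(fit$k_by_ecosystem)
  }
  if (!is.null(fit$interaction_test)) {
    out$interaction_test <- as.data.frame(fit$interaction_test)
  }
  if (!is.null(fit$anova)) out$anova <- as.data.frame(fit$anova)
  if (!is.null(fit$model_comparison)) {
    out$model_comparison <- lapply(fit$model_comparison, function(x) {
      if (is.null(x)) NULL else as.data.frame(x)
    })
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write pipeline outputs to a directory
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  tables <- list(metrics = report$metrics,
                 within_table = report$within_table,
                 across_table = report$across_table,
                 per_web_slopes = report$fits$per_web)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]]) || nrow(tables[[nm]]) == 0) next
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, progress = FALSE)
    paths <- c(paths, p)
  }
  json <- list(
    status = report$status, counts = report$counts,
    config = report$config, version = report$version,
    fits = lapply(report$fits[c("within", "traits", "across", "prey_mass")],
                  summarise_fit))
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, jp))
}
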
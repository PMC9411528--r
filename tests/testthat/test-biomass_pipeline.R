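test_that("node biomass is abundance times body mass", {
  expect_equal(node_biomass(0.5, 10), 5)
  expect_equal(node_biomass(2, 0), 0)
  w <- random_dag_web(n = 10, p = 0.3)
  expect_equal(unname(trophoscale:::web_biomass(w)),
               w$nodes$abundance * w$nodes$body_mass)
})

test_that("available prey biomass shares each prey equally among its consumers", {
  # prey A (biomass 4) eaten only by P
  w1 <- toy_web(list(P = "A"), abundances = c(A = 4, P = 1))
  expect_equal(available_prey_biomass(w1, "P"), 4)
  # prey A eaten by P and Q: each receives half
  w2 <- toy_web(list(P = "A", Q = "A"), abundances = c(A = 4, P = 1, Q = 1))
  expect_equal(available_prey_biomass(w2, "P"), 2)
  expect_equal(available_prey_biomass(w2, "P",
                                      adjust_for_vulnerability = FALSE), 4)
})

test_that("vulnerability-adjusted shares conserve each consumed prey's biomass (property)", {
  set.seed(21)
  for (r in 1:8) {
    w <- random_dag_web(n = sample(10:30, 1), p = stats::runif(1, 0.15, 0.4))
    biomass <- trophoscale:::web_biomass(w)
    x <- available_prey_biomass(w)
    consumed <- unique(w$links$resource_id[!w$links$is_cannibal])
    total_shares <- sum(x, na.rm = TRUE)
    total_consumed <- sum(biomass[consumed])
    expect_equal(total_shares, total_consumed,
                 tolerance = 1e-12)
  }
})

test_that("predator filtering applies the trophic-level cut-off and is monotone in it", {
  w <- chain_web()
  m <- compute_metrics(w)
  expect_equal(filter_predators(w, m, tl_cutoff = 2.5), "C")
  set.seed(5)
  for (r in 1:5) {
    rw <- random_dag_web(n = 20, p = 0.35)
    rm_ <- compute_metrics(rw)
    s25 <- filter_predators(rw, rm_, tl_cutoff = 2.5)
    s30 <- filter_predators(rw, rm_, tl_cutoff = 3.0)
    expect_true(all(s30 %in% s25))
    # matches a brute-force scan of the TL table
    expect_setequal(s25, rm_$node_id[rm_$trophic_level > 2.5 &
                                       rm_$generality >= 1])
  }
})

test_that("aggregate predators are excluded only when requested", {
  w <- toy_web(list(B = "A", C = "B", D = "B"), aggregates = "D")
  m <- compute_metrics(w)
  expect_setequal(filter_predators(w, m, tl_cutoff = 2.5), c("C", "D"))
  expect_equal(filter_predators(w, m, tl_cutoff = 2.5,
                                exclude_aggregates = TRUE), "C")
})

test_that("webs with too few predators or too little biomass spread are dropped", {
  rec <- function(web_id, n, span) {
    tibble::tibble(web_id = web_id,
                   log10_prey_biomass = seq(0, span, length.out = n))
  }
  records <- dplyr::bind_rows(
    rec("ok", 6, 2),        # retained
    rec("few", 4, 2),       # dropped: fewer than five predators
    rec("narrow", 6, 0.5))  # dropped: < 1 decade of prey biomass
  expect_equal(filter_webs(records), "ok")
  # idempotent: filtering the retained records changes nothing
  kept <- records[records$web_id %in% filter_webs(records), ]
  expect_equal(filter_webs(kept), "ok")
})

test_that("within-web records carry log10 biomasses and traits for retained predators", {
  ds <- generate_dataset(synthetic_config(n_webs = 3, ecosystems = "marine",
                                          seed = 9))
  within <- quiet(build_within_table(ds$webs))
  expect_true(all(within$trophic_level > 2.5))
  expect_true(all(is.finite(within$log10_prey_biomass)))
  expect_true(all(is.finite(within$ppmr_log10)))
  expect_equal(within$log10_predator_biomass,
               log10(within$predator_biomass))
  # every retained web satisfies both web-level filters
  per_web <- dplyr::summarise(
    dplyr::group_by(within, web_id), n = dplyr::n(),
    span = max(log10_prey_biomass) - min(log10_prey_biomass))
  expect_true(all(per_web$n >= 5))
  expect_true(all(per_web$span >= 1))
})

test_that("rescaling all abundances by f shifts every record by exactly log10(f)", {
  ds <- generate_dataset(synthetic_config(n_webs = 2, ecosystems = "marine",
                                          seed = 13))
  f <- 7.3
  scaled <- lapply(ds$webs, function(w) {
    w$nodes$abundance <- w$nodes$abundance * f
    w
  })
  w0 <- quiet(build_within_table(ds$webs))
  w1 <- quiet(build_within_table(scaled))
  expect_equal(w1$log10_prey_biomass, w0$log10_prey_biomass + log10(f),
               tolerance = 1e-12)
  expect_equal(w1$log10_predator_biomass,
               w0$log10_predator_biomass + log10(f), tolerance = 1e-12)
})

test_that("across-web totals follow the stated aggregation rules", {
  # single qualifying predator: totals are its biomass and its prey sum
  w <- toy_web(list(B = "A", C = "B", D = "C", E = "D", P1 = c("C", "D"),
                    P2 = c("B", "C"), P3 = c("C", "E")),
               abundances = c(A = 1000, B = 100, C = 10, D = 5, E = 2,
                              P1 = 1, P2 = 1, P3 = 1))
  m <- compute_metrics(w)
  cfg <- pipeline_config(min_predators = 1, min_x_range_decades = 0)
  across <- quiet(build_across_table(list(w), cfg))
  preds <- filter_predators(w, m, 2.5)
  biomass <- trophoscale:::web_biomass(w)
  prey_union <- unique(unlist(trophoscale:::prey_of(w)[preds]))
  expect_equal(across$total_predator_biomass, sum(biomass[preds]))
  expect_equal(across$total_prey_biomass, sum(biomass[prey_union]))
  expect_equal(across$mean_prey_body_mass,
               mean(w$nodes$body_mass[w$nodes$node_id %in% prey_union]))
  # nodes that are both predator and prey contribute to both totals
  both <- intersect(preds, prey_union)
  expect_true(length(both) > 0)
})

test_that("across-web totals equal brute-force sums on a generated batch", {
  ds <- generate_dataset(synthetic_config(n_webs = 3, ecosystems = "terrestrial",
                                          seed = 17))
  across <- quiet(build_across_table(ds$webs))
  for (i in seq_len(nrow(across))) {
    w <- ds$webs[[across$web_id[i]]]
    m <- compute_metrics(w)
    preds <- m$node_id[m$trophic_level > 2.5 & m$generality >= 1]
    biomass <- trophoscale:::web_biomass(w)
    fl <- w$links[!w$links$is_cannibal, ]
    prey_union <- unique(fl$resource_id[fl$consumer_id %in% preds])
    expect_equal(across$total_predator_biomass[i], sum(biomass[preds]))
    expect_equal(across$total_prey_biomass[i], sum(biomass[prey_union]))
    expect_equal(across$n_predators[i], length(preds))
  }
})

test_that("predators whose biomass or prey biomass is zero are dropped with a message", {
  w <- toy_web(list(B = "A", C = "B", D = "C", E = "D"),
               abundances = c(A = 10, B = 5, C = 2, D = 0, E = 1))
  cfg <- pipeline_config(min_predators = 1, min_x_range_decades = 0)
  # D has biomass 0 (dropped as predator); E's only prey D has biomass 0
  expect_message(
    rec <- trophoscale:::web_predator_records(w, cfg, exclude_aggregates = TRUE),
    "non-positive biomass")
  expect_false(any(rec$predator_id %in% c("D", "E")))
})
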
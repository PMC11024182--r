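test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_genes = 20L)
  a <- simulate_homology_data(cfg)
  b <- simulate_homology_data(cfg)
  expect_equal(a$hits, b$hits)
  expect_equal(a$annotations, b$annotations)
  expect_equal(a$truth, b$truth)
  # written outputs are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_homology_data(cfg, dir = d1)
  simulate_homology_data(cfg, dir = d2)
  for (f in dir(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  s1 <- simulate_selection_table(cfg)
  s2 <- simulate_selection_table(cfg)
  expect_equal(s1$results, s2$results)
  e1 <- simulate_expression(sim_config(seed = 9, expr_n_set = 5L,
                                       expr_n_other = 3L))
  e2 <- simulate_expression(sim_config(seed = 9, expr_n_set = 5L,
                                       expr_n_other = 3L))
  expect_equal(e1$expr, e2$expr)
})

test_that("generated files round-trip through the parsers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, n_genes = 15L)
  sim <- simulate_homology_data(cfg, dir = dir)
  blast_files <- dir(dir, pattern = "^blast_", full.names = TRUE)
  expect_gt(length(blast_files), 30)
  hits <- purrr::map_dfr(blast_files, function(f) {
    read_blast_tabular(f, target_species = sub("^blast_(.*)\\.tsv$",
                                               "\\1", basename(f)))
  })
  expect_equal(nrow(hits), nrow(sim$hits))
  # scaled scores recomputed from the written bit scores match the
  # generator's intent (bit scores are written to one decimal)
  joined <- dplyr::inner_join(
    add_scaled_scores(select_best_hits(hits)),
    sim$hits, by = c("query_gene", "target_species"))
  expect_lt(max(abs(joined$scaled_score -
                      joined$max_score.y /
                        (joined$query_length.y +
                           joined$subject_length.y))), 1e-12)
  ann <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(ann), nrow(sim$annotations))
  nb <- extract_neighborhood(ann[ann$species_id == "hsapiens", ],
                             sim$truth$gene[1])
  expect_s3_class(nb, "neighborhood")
})

test_that("the noiseless limit recovers every planted stratum", {
  cfg <- sim_config(seed = 17, n_genes = 60L, score_sigma = 0,
                    synteny_p_within = 1)
  sim <- simulate_homology_data(cfg)
  dated <- date_genes(sim$hits, sim$annotations, sim$panel)
  cmp <- dplyr::inner_join(dated$records, sim$truth, by = "gene")
  expect_equal(cmp$earliest_ps, cmp$true_ps)
})

test_that("default noise still allows high-fidelity recovery", {
  sim <- simulate_homology_data(sim_config(seed = 19, n_genes = 60L))
  dated <- date_genes(sim$hits, sim$annotations, sim$panel)
  cmp <- dplyr::inner_join(dated$records, sim$truth, by = "gene")
  expect_gte(mean(cmp$earliest_ps == cmp$true_ps), 0.9)
  # exhaustive dating is never later than staged dating
  d2 <- date_genes(sim$hits, sim$annotations, sim$panel, staged = FALSE)
  j <- dplyr::inner_join(dated$records, d2$records, by = "gene",
                         suffix = c("_staged", "_exh"))
  expect_true(all(j$earliest_ps_exh <= j$earliest_ps_staged,
                  na.rm = TRUE))
})

test_that("synthetic homolog calls are prefixes of the proximity order", {
  # deterministic scores decaying with stratum distance: per species,
  # called genes must be exactly those at or before the species stratum
  sim <- simulate_homology_data(
    sim_config(seed = 23, n_genes = 40L, score_sigma = 0,
               spurious_rate = 0))
  best <- add_scaled_scores(select_best_hits(sim$hits))
  nv_species <- sim$panel$species$species_id[
    sim$panel$species$role == "non_vertebrate"]
  nv <- best[best$target_species %in% nv_species, ]
  calls <- call_homologs(nv, species_cutoffs(nv))
  joined <- dplyr::inner_join(calls, sim$truth,
                              by = c(query_gene = "gene")) |>
    dplyr::left_join(sim$panel$species[, c("species_id", "ps_index")],
                     by = c(target_species = "species_id"))
  # every positive call lies within the truth clade
  expect_true(all(joined$ps_index[joined$homolog] >=
                    joined$true_ps[joined$homolog]))
})

test_that("saturated and empty selection configs behave at the limits", {
  all_pos <- simulate_selection_table(
    sim_config(seed = 3, sel_n_genes = 12L, sel_frac_positive = 1))
  s <- summarize_selection(all_pos$results)
  expect_equal(s$n_significant, 12)
  none <- simulate_selection_table(
    sim_config(seed = 3, sel_n_genes = 12L, sel_frac_positive = 0))
  expect_equal(sum(none$truth$positive), 0)
})

test_that("expression generator honors its dimensions and truth table", {
  cfg <- sim_config(seed = 29, expr_donors = 4L, expr_regions = 10L,
                    expr_n_set = 6L, expr_n_other = 2L,
                    expr_effects = c(ctx_03 = 2))
  ex <- simulate_expression(cfg)
  expect_equal(dplyr::n_distinct(ex$expr$donor), 4)
  expect_equal(dplyr::n_distinct(ex$expr$region), 10)
  expect_equal(dplyr::n_distinct(ex$expr$gene), 8)
  expect_equal(ex$truth$d_true[ex$truth$region == "ctx_03"], 2)
  expect_equal(sum(ex$truth$d_true != 0), 1)
  expect_error(simulate_expression(sim_config(expr_donors = 1L)),
               "donors")
  expect_error(simulate_expression(
    sim_config(expr_effects = c(nowhere = 2))), "unknown effect")
  # a fully degenerate cohort is flagged by the test stage
  flat <- simulate_expression(sim_config(seed = 31, expr_n_set = 4L,
                                         expr_n_other = 0L,
                                         expr_sigma_region = 0,
                                         expr_sigma_gene = 0))
  expect_warning(region_vs_brain_tests(flat$expr, flat$gene_set),
                 "degenerate")
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(spurious_rate = 1.5), "probabilities")
  expect_error(sim_config(score_sigma = -1), "non-negative")
  expect_error(sim_config(ps_weights = rep(0, 20)), "weights")
})
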
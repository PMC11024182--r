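#' Default simulation configuration
#'
#' Bundles the parameters of the three synthetic-data generators. The
#' defaults encode the study conditions the pipeline was built around: a
#' 154-gene pathway whose genes spread over 20 phylostrata with the
#' published per-stratum proportions, per-gene best-hit scaled scores
#' that decay linearly with stratum distance from the planted stratum
#' plus Gaussian noise, flank-gene conservation that collapses outside
#' the truth clade, a branch-site table dominated by uniform nulls, and
#' a six-donor, 42-region expression matrix with planted regional
#' shifts.
#'
#' @param seed Integer seed; recorded in every generator output.
#' @param n_genes Number of simulated genes.
#' @param ps_weights Sampling weights for the planted stratum over
#'   `1..20` (default: the study's per-stratum gene counts).
#' @param score_base Expected scaled score at zero stratum distance.
#' @param score_decay Linear decay of the expected scaled score per
#'   stratum of distance from the planted stratum.
#' @param score_sigma Gaussian noise s.d. on scaled scores.
#' @param spurious_rate Probability that a species older than the
#'   planted stratum still yields a (weak) best hit.
#' @param spurious_mean Expected scaled score of such spurious hits.
#' @param synteny_p_within Per-flank-gene conservation probability in
#'   species that carry the gene.
#' @param synteny_p_outside Per-flank-gene chance conservation in
#'   species that do not.
#' @param sel_n_genes,sel_n_branches Size of the simulated branch-site
#'   table.
#' @param sel_frac_positive Fraction of genes with a planted positively
#'   selected branch.
#' @param sel_p_max Upper bound for planted raw P values.
#' @param expr_donors,expr_regions Expression matrix dimensions
#'   (42 regions: 34 cortical + 8 subcortical labels).
#' @param expr_n_set,expr_n_other Genes in / outside the query set.
#' @param expr_mu Baseline intensity.
#' @param expr_sigma_region Donor-by-region noise s.d. (the sampling
#'   unit of the region tests, so planted effects are expressed in this
#'   unit).
#' @param expr_sigma_gene Per-gene residual noise s.d.
#' @param expr_effects Named numeric vector of planted regional effects
#'   (Cohen's d units), e.g. `c(precentral = 3)`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       ps_weights = c(12, 15, 1, 9, 2, 3, 8, 3, 1, 2,
                                      5, 34, 12, 20, 10, 8, 2, 0, 5, 2),
                       score_base = 0.5,
                       score_decay = 0.02,
                       score_sigma = 0.005,
                       spurious_rate = 0.5,
                       spurious_mean = 0.08,
                       synteny_p_within = 0.9,
                       synteny_p_outside = 0.05,
                       sel_n_genes = 38L,
                       sel_n_branches = 23L,
                       sel_frac_positive = 0.13,
                       sel_p_max = 1e-6,
                       expr_donors = 6L,
                       expr_regions = 42L,
                       expr_n_set = 81L,
                       expr_n_other = 120L,
                       expr_mu = 0.5,
                       expr_sigma_region = 0.05,
                       expr_sigma_gene = 0.10,
                       expr_effects = c()) {
  cfg <- as.list(environment())
  probs <- c(synteny_p_within, synteny_p_outside, spurious_rate,
             sel_frac_positive)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0,1]")
  if (score_sigma < 0 || expr_sigma_region < 0 || expr_sigma_gene < 0) {
    abort("noise s.d. must be non-negative")
  }
  if (length(ps_weights) != 20 || all(ps_weights == 0)) {
    abort("ps_weights must give 20 non-all-zero weights")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Simulate homology-search inputs with planted gene ages
#'
#' Generates, for a species panel, the inputs of the dating pipeline:
#' per-species tabular BLAST best hits whose scaled scores are high for
#' species at or after each gene's planted stratum and low/absent
#' before it, and vertebrate gene-annotation tables whose flanking
#' windows are conserved (per flank gene, with the configured
#' probability) only where the gene exists. The reference species'
#' annotation includes a pseudogene inside each window so biotype
#' exclusion is exercised on every run.
#'
#' @param config A [sim_config()].
#' @param panel A [load_species_panel()] panel (default: the packaged
#'   39-species panel).
#' @param dir Optional directory; when given, per-species BLAST TSVs
#'   (`blast_<species>.tsv`), `annotations.tsv` and `truth.tsv` are
#'   written there.
#' @return List with `hits` (BLAST-hit tibble across species),
#'   `annotations` (vertebrate annotation tibble), `truth`
#'   (`gene`, `true_ps`), `panel`, `seed` and, when `dir` was given,
#'   `files`.
#' @export
simulate_homology_data <- function(config = sim_config(),
                                   panel = NULL, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel)) {
    panel <- load_species_panel(
      phylage_example("synthetic_species_panel.tsv"),
      phylage_example("synthetic_species_tree.nwk"))
  }
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("SG%03d", seq_len(n))
  true_ps <- sample(seq_len(20), n, replace = TRUE,
                    prob = config$ps_weights)
  truth <- tibble(gene = genes, true_ps = true_ps)

  sp <- panel$species
  grid <- tidyr::expand_grid(gene = genes,
                             species_id = sp$species_id) |>
    dplyr::left_join(truth, by = "gene") |>
    dplyr::left_join(sp[, c("species_id", "ps_index", "role")],
                     by = "species_id") |>
    dplyr::mutate(present = .data$ps_index >= .data$true_ps)

  m <- nrow(grid)
  grid$scaled <- ifelse(
    grid$present,
    pmax(0.02, config$score_base -
           config$score_decay * (grid$ps_index - grid$true_ps) +
           rnorm(m, 0, config$score_sigma)),
    ifelse(runif(m) < config$spurious_rate,
           pmax(0.01, rnorm(m, config$spurious_mean,
                            config$score_sigma)),
           NA_real_))
  hits <- grid |>
    dplyr::filter(!is.na(.data$scaled)) |>
    dplyr::mutate(
      query_length = sample(250:600, dplyr::n(), replace = TRUE),
      subject_length = sample(250:600, dplyr::n(), replace = TRUE),
      max_score = round(.data$scaled *
                          (.data$query_length + .data$subject_length), 1),
      evalue = signif(10 ^ pmax(-180, -200 * .data$scaled), 3),
      subject_accession = paste0("XP_", .data$species_id, "_",
                                 .data$gene)
    ) |>
    dplyr::transmute(query_gene = .data$gene,
                     target_species = .data$species_id,
                     .data$subject_accession, .data$evalue,
                     .data$max_score, .data$query_length,
                     .data$subject_length,
                     present = .data$present)

  annotations <- simulate_annotations(grid, panel, config)

  out <- list(hits = hits, annotations = annotations, truth = truth,
              panel = panel, seed = config$seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (s in unique(hits$target_species)) {
      f <- file.path(dir, paste0("blast_", s, ".tsv"))
      h <- hits[hits$target_species == s, ]
      readr::write_tsv(
        tibble(qseqid = h$query_gene, sseqid = h$subject_accession,
               pident = 50, length = pmin(h$query_length,
                                          h$subject_length),
               evalue = h$evalue, bitscore = h$max_score,
               qlen = h$query_length, slen = h$subject_length),
        f, col_names = FALSE, progress = FALSE)
      files <- c(files, f)
    }
    fa <- file.path(dir, "annotations.tsv")
    readr::write_tsv(annotations, fa, progress = FALSE)
    ft <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, ft, progress = FALSE)
    out$files <- c(files, fa, ft)
  }
  out
}

# vertebrate annotation tables: an 11-gene contig per gene per species
# carrying the focal gene, with flank symbols conserved per-gene with the
# configured probability; plus one pseudogene inside the reference window
simulate_annotations <- function(grid, panel, config) {
  ref_sp <- panel$species$species_id[which.max(panel$species$ps_index)]
  vgrid <- grid[grid$role == "vertebrate" & grid$present, ]
  slots <- c(-5:-1, 1:5)
  ann <- tidyr::expand_grid(
    vgrid[, c("gene", "species_id")], slot = slots) |>
    dplyr::mutate(
      conserved = runif(dplyr::n()) <
        ifelse(.data$species_id == ref_sp, 1, config$synteny_p_within),
      symbol = ifelse(.data$conserved,
                      paste0(.data$gene, "_F", .data$slot + 6L),
                      paste0("JNK_", .data$species_id, "_", .data$gene,
                             "_", .data$slot + 6L)),
      gene_id = paste0(.data$species_id, "_", .data$symbol),
      biotype = "protein_coding")
  focal <- vgrid |>
    dplyr::transmute(.data$gene, .data$species_id, slot = 0L,
                     conserved = TRUE, symbol = .data$gene,
                     gene_id = paste0(.data$species_id, "_", .data$gene),
                     biotype = "protein_coding")
  pseudo <- vgrid[vgrid$species_id == ref_sp, ] |>
    dplyr::transmute(.data$gene, .data$species_id, slot = 0L,
                     conserved = FALSE,
                     symbol = paste0(.data$gene, "_PS1"),
                     gene_id = paste0(.data$species_id, "_", .data$gene,
                                      "_ps"),
                     biotype = "pseudogene")
  dplyr::bind_rows(ann, focal, pseudo) |>
    dplyr::mutate(
      contig = paste0("ctg_", .data$gene),
      start = 1000L * (.data$slot + 6L) +
        ifelse(.data$biotype == "pseudogene", 400L, 0L),
      end = .data$start + 300L,
      strand = "+") |>
    dplyr::select("species_id", "contig", "gene_id", "symbol", "start",
                  "end", "strand", "biotype") |>
    dplyr::arrange(.data$species_id, .data$contig, .data$start)
}

#' Simulate a branch-site selection result table
#'
#' Null gene x branch tests draw raw P values uniformly on `[0, 1]` with
#' maximum dN/dS below or around 1; planted positives draw raw P at or
#' below `sel_p_max` with maximum dN/dS above 1. The planted truth is
#' returned alongside.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory for `selection.tsv` / `truth.tsv`.
#' @return List with `results` (schema of
#'   [read_selection_results()]), `truth` (`gene`, `branch`,
#'   `positive`), `seed`.
#' @export
simulate_selection_table <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- sprintf("G%03d", seq_len(config$sel_n_genes))
  branches <- sprintf("B%02d", seq_len(config$sel_n_branches))
  n_pos <- round(config$sel_frac_positive * length(genes))
  pos_genes <- sample(genes, n_pos)
  grid <- tidyr::expand_grid(gene = genes, branch = branches)
  pos_branch <- setNames(sample(branches, n_pos, replace = TRUE),
                         pos_genes)
  grid <- grid |>
    dplyr::mutate(
      positive = .data$gene %in% pos_genes &
        .data$branch == pos_branch[.data$gene],
      p_raw = ifelse(.data$positive,
                     runif(dplyr::n(), 0, config$sel_p_max),
                     runif(dplyr::n())),
      max_dnds = ifelse(.data$positive,
                        exp(runif(dplyr::n(), log(2), log(500))),
                        exp(rnorm(dplyr::n(), log(0.3), 0.8))),
      lrt = ifelse(.data$positive, runif(dplyr::n(), 15, 60),
                   runif(dplyr::n(), 0, 4)),
      complete = TRUE)
  results <- grid[, c("gene", "branch", "lrt", "p_raw", "max_dnds",
                      "complete")]
  truth <- grid[, c("gene", "branch", "positive")]
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(results, file.path(dir, "selection.tsv"),
                     progress = FALSE)
    readr::write_tsv(truth, file.path(dir, "selection_truth.tsv"),
                     progress = FALSE)
  }
  list(results = results, truth = truth, seed = config$seed)
}

#' Simulate a donor x region x gene expression matrix
#'
#' Gene intensities are `mu` plus a shared donor-by-region fluctuation
#' (s.d. `expr_sigma_region`), plus independent per-gene noise. For the
#' genes of the query set, planted regional effects shift the mean by
#' `d * expr_sigma_region` in the chosen regions, so the planted value
#' is the Cohen's d the region tests estimate from per-donor set means.
#'
#' @param config A [sim_config()]; `expr_effects` names the shifted
#'   regions.
#' @param dir Optional directory for `expression.tsv` /
#'   `expression_truth.tsv` and a `gene_set.gmt`.
#' @return List with `expr` (long tibble), `gene_set`, `truth`
#'   (`region`, `d_true`), `seed`.
#' @export
simulate_expression <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$expr_donors < 2) abort("need at least 2 donors")
  set.seed(config$seed + 2L)
  donors <- sprintf("donor%02d", seq_len(config$expr_donors))
  n_cort <- min(34L, config$expr_regions)
  regions <- c(sprintf("ctx_%02d", seq_len(n_cort)),
               if (config$expr_regions > n_cort)
                 sprintf("sub_%02d",
                         seq_len(config$expr_regions - n_cort)))
  set_genes <- sprintf("SET%03d", seq_len(config$expr_n_set))
  other <- if (config$expr_n_other > 0) {
    sprintf("BGD%03d", seq_len(config$expr_n_other))
  } else character(0)
  genes <- c(set_genes, other)

  effects <- config$expr_effects
  bad <- setdiff(names(effects), regions)
  if (length(bad) > 0) {
    abort(paste0("unknown effect region(s): ",
                 paste(bad, collapse = ", ")))
  }
  delta <- setNames(rep(0, length(regions)), regions)
  delta[names(effects)] <- effects * config$expr_sigma_region

  dr <- tidyr::expand_grid(donor = donors, region = regions) |>
    dplyr::mutate(u = rnorm(dplyr::n(), 0, config$expr_sigma_region))
  expr <- tidyr::expand_grid(dr, gene = genes) |>
    dplyr::mutate(
      value = config$expr_mu + .data$u +
        ifelse(.data$gene %in% set_genes,
               delta[.data$region], 0) +
        rnorm(dplyr::n(), 0, config$expr_sigma_gene)) |>
    dplyr::select("donor", "region", "gene", "value")
  truth <- tibble(region = regions,
                  d_true = unname(delta) / max(config$expr_sigma_region,
                                               .Machine$double.eps))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(expr, file.path(dir, "expression.tsv"),
                     progress = FALSE)
    readr::write_tsv(truth, file.path(dir, "expression_truth.tsv"),
                     progress = FALSE)
    write_gmt(list(query_set = set_genes),
              file.path(dir, "gene_set.gmt"))
  }
  list(expr = expr, gene_set = set_genes, truth = truth,
       seed = config$seed)
}
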
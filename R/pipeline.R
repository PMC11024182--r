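#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the fields understood by
#'   [run_pipeline()]: input paths (`panel`, `tree`, `blast_dir`,
#'   `annotations`, `selection`, `expression`, `gene_set`,
#'   `tissue_sets`, `background`), an `out_dir`, and a `params` block
#'   (`window`, `threshold_k`, `alpha`, `fdr_scope`, `boundaries`,
#'   `staged`, `seed`).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_fields <- c("panel", "tree", "blast_dir", "annotations",
                   "selection", "expression", "gene_set", "tissue_sets",
                   "background")
  for (f in intersect(path_fields, names(cfg))) {
    if (!grepl("^(/|[A-Za-z]:)", cfg[[f]])) {
      cfg[[f]] <- file.path(base, cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

default_params <- function() {
  list(window = 5L, threshold_k = 3L, alpha = 0.05,
       fdr_scope = "global", boundaries = c(3L, 10L), staged = TRUE,
       seed = 1L)
}

#' Run the dating / selection / expression pipeline
#'
#' Orchestrates the independent analysis stages over whichever inputs
#' the configuration provides, writing a report bundle into the output
#' directory: `gene_ages.tsv` plus `age_summary.json` and `cutoffs.tsv`
#' (age stage), `selection_annotated.tsv` plus `selection_summary.json`
#' (selection stage), `region_tests.tsv` and
#' `differential_stability.tsv` (expression stage),
#' `tissue_enrichment.tsv` (enrichment stage, when tissue sets are
#' given) and a `run.log` with ISO timestamps, the configuration hash,
#' the seed and every analysis parameter in effect. Stages with missing
#' inputs are skipped with a log entry; a failing stage is recorded and
#' the other stages' outputs are retained. Re-running an unchanged
#' configuration is idempotent.
#'
#' @param config A `pipeline_config`, a YAML path, or a plain list.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return A `phylage_run` list: per-stage results, `outputs` (paths),
#'   `skipped`, `failed`, `config_hash`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  params <- utils::modifyList(default_params(),
                              config$params %||% list())
  out_dir <- out_dir %||% config$out_dir %||%
    abort("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  given <- intersect(c("panel", "tree", "blast_dir", "annotations",
                       "selection", "expression", "gene_set",
                       "tissue_sets", "background"), names(config))
  absent <- given[!vapply(given, function(f) file.exists(config[[f]]),
                          logical(1))]
  if (length(absent) > 0) {
    abort(paste0("configured input path(s) do not exist: ",
                 paste(paste0(absent, " = ", unlist(config[absent])),
                       collapse = "; ")))
  }

  cfg_hash <- rlang::hash(list(config[given], params))
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                   paste0(...))
    log_lines <<- c(log_lines, line)
  }
  say("run start; config_hash=", cfg_hash, "; seed=", params$seed)
  say("params: window=", params$window, " threshold_k=",
      params$threshold_k, " alpha=", params$alpha, " fdr_scope=",
      params$fdr_scope, " boundaries=",
      paste(params$boundaries, collapse = "/"),
      " staged=", params$staged)

  run <- list(outputs = character(0), skipped = character(0),
              failed = character(0), config_hash = cfg_hash,
              seed = params$seed)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    run$outputs <<- c(run$outputs, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(c(list(config_hash = cfg_hash,
                                seed = params$seed), x),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    run$outputs <<- c(run$outputs, p)
    p
  }
  stage <- function(name, needs, fn) {
    if (!all(needs %in% names(config))) {
      say("stage ", name, ": skipped (missing input: ",
          paste(setdiff(needs, names(config)), collapse = ", "), ")")
      run$skipped <<- c(run$skipped, name)
      return(invisible(NULL))
    }
    say("stage ", name, ": start")
    res <- tryCatch(fn(), error = function(e) {
      say("stage ", name, ": FAILED (", conditionMessage(e), ")")
      run$failed <<- c(run$failed, name)
      NULL
    })
    if (!is.null(res)) say("stage ", name, ": done")
    res
  }

  run$age <- stage("age", c("panel", "tree", "blast_dir",
                            "annotations"), function() {
    panel <- load_species_panel(config$panel, config$tree)
    files <- dir(config$blast_dir, pattern = "\\.tsv$",
                 full.names = TRUE)
    if (length(files) == 0) abort("no BLAST tables in blast_dir")
    hits <- purrr::map_dfr(files, function(f) {
      read_blast_tabular(
        f, target_species = sub("^blast_", "",
                                tools::file_path_sans_ext(basename(f))))
    })
    ann <- readr::read_tsv(config$annotations, show_col_types = FALSE,
                           progress = FALSE)
    dated <- date_genes(hits, ann, panel,
                        threshold_k = params$threshold_k,
                        window = params$window, staged = params$staged,
                        boundaries = params$boundaries)
    write_gene_ages(dated$records, file.path(out_dir, "gene_ages.tsv"))
    run$outputs <<- c(run$outputs, file.path(out_dir, "gene_ages.tsv"))
    if (!is.null(dated$cutoffs)) emit(dated$cutoffs, "cutoffs.tsv")
    s <- dated$summary
    emit_json(list(total = s$total, n_unassigned = s$n_unassigned,
                   by_stratum = setNames(as.list(s$by_stratum$n),
                                         s$by_stratum$ps_index),
                   by_category = setNames(as.list(s$by_category$n),
                                          s$by_category$category)),
              "age_summary.json")
    dated
  })

  run$selection <- stage("selection", "selection", function() {
    res <- read_selection_results(config$selection)
    summ <- summarize_selection(res, alpha = params$alpha,
                                scope = params$fdr_scope)
    write_selection_results(summ,
                            file.path(out_dir,
                                      "selection_annotated.tsv"))
    run$outputs <<- c(run$outputs,
                      file.path(out_dir, "selection_annotated.tsv"))
    emit_json(list(n_significant = summ$n_significant,
                   n_tested = summ$n_tested,
                   n_excluded = summ$n_excluded,
                   alpha = summ$alpha, scope = summ$scope,
                   significant_genes = summ$significant_genes),
              "selection_summary.json")
    summ
  })

  run$expression <- stage("expression", c("expression", "gene_set"),
                          function() {
    expr <- read_expression_long(config$expression)
    sets <- read_gmt(config$gene_set)
    gene_set <- sets[[1]]
    tests <- region_vs_brain_tests(expr, gene_set)
    emit(as_tibble(tests), "region_tests.tsv")
    ds <- differential_stability(expr)
    emit(ds, "differential_stability.tsv")
    tf <- top_fraction(ds[ds$gene %in% gene_set, ], ds)
    emit(tf, "top_fraction.tsv")
    list(tests = tests, ds = ds, top_fraction = tf)
  })

  run$enrichment <- stage("enrichment", c("gene_set", "tissue_sets",
                                          "background"), function() {
    gene_set <- read_gmt(config$gene_set)[[1]]
    tissue <- read_gmt(config$tissue_sets)
    background <- readr::read_lines(config$background,
                                    progress = FALSE)
    enr <- tissue_enrichment(gene_set, tissue, background)
    emit(as_tibble(enr), "tissue_enrichment.tsv")
    enr
  })

  say("run end; outputs=", length(run$outputs), " skipped=",
      length(run$skipped), " failed=", length(run$failed))
  writeLines(log_lines, log_path)
  run$log <- log_path
  class(run) <- "phylage_run"
  run
}

#' @export
print.phylage_run <- function(x, ...) {
  cat("<phylage_run> hash ", x$config_hash, "\n  outputs: ",
      length(x$outputs), " file(s)", sep = "")
  if (length(x$skipped)) {
    cat("; skipped: ", paste(x$skipped, collapse = ", "), sep = "")
  }
  if (length(x$failed)) {
    cat("; FAILED: ", paste(x$failed, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}
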
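#' Read branch-site selection test results
#'
#' Loads per-gene, per-branch outputs of adaptive branch-site random
#' effects likelihood (aBSREL-style) tests from either a flat TSV or a
#' JSON file. The TSV needs columns `gene`, `branch`, `lrt`, `p_raw` and
#' `max_dnds`, plus an optional logical `complete` column; the JSON
#' layout is a top-level object mapping gene names to the familiar
#' `"branch attributes"` structure whose per-branch records carry
#' `"LRT"`, `"Uncorrected P-value"` and either `"Max dN/dS"` or a
#' `"Rate Distributions"` array of `[omega, weight]` pairs (the maximum
#' omega is taken).
#'
#' Rows from unfinished runs (`complete = FALSE`, or missing P values)
#' are kept but flagged, and every downstream summary excludes them from
#' both numerator and denominator.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return Tibble with columns `gene`, `branch`, `lrt`, `p_raw`,
#'   `max_dnds`, `complete`.
#' @export
read_selection_results <- function(path) {
  ext <- tolower(tools::file_ext(path))
  res <- if (ext == "json") {
    read_selection_json(path)
  } else {
    read_selection_tsv(path)
  }
  bad <- res$complete &
    (res$p_raw < 0 | res$p_raw > 1 | res$max_dnds < 0 | res$lrt < 0)
  if (any(bad, na.rm = TRUE)) {
    abort(paste0(path, ": invalid P/LRT/dN-dS value for gene ",
                 res$gene[which(bad)[1]]))
  }
  res
}

read_selection_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene", "branch", "lrt", "p_raw", "max_dnds")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"complete" %in% names(tab)) {
    tab$complete <- !is.na(tab$p_raw)
  }
  tab$complete <- tab$complete & !is.na(tab$p_raw)
  as_tibble(tab[c("gene", "branch", "lrt", "p_raw", "max_dnds",
                  "complete")])
}

read_selection_json <- function(path) {
  doc <- jsonlite::read_json(path)
  purrr::imap_dfr(doc, function(gene_doc, gene) {
    branches <- gene_doc[["branch attributes"]]
    if (!is.null(branches[["0"]])) branches <- branches[["0"]]
    if (is.null(branches)) {
      abort(paste0(path, ": gene ", gene, " lacks branch attributes"))
    }
    purrr::imap_dfr(branches, function(b, name) {
      p <- b[["Uncorrected P-value"]]
      dnds <- b[["Max dN/dS"]]
      if (is.null(dnds) && !is.null(b[["Rate Distributions"]])) {
        dnds <- max(vapply(b[["Rate Distributions"]],
                           function(rw) rw[[1]], numeric(1)))
      }
      tibble(gene = gene, branch = name,
             lrt = b[["LRT"]] %||% NA_real_,
             p_raw = p %||% NA_real_,
             max_dnds = dnds %||% NA_real_,
             complete = !is.null(p))
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment with a grouping policy
#'
#' Applies the Benjamini-Hochberg step-up false-discovery-rate
#' correction to raw P values. The default policy pools every
#' gene x branch test into one family; `"per_gene"` and `"per_branch"`
#' correct within genes or branches for sensitivity analyses.
#'
#' @param results Tibble with `p_raw` (and `gene`/`branch` for grouped
#'   policies), or a bare numeric vector of raw P values.
#' @param scope One of `"global"`, `"per_gene"`, `"per_branch"`.
#' @return The input with a `p_fdr` column (or the adjusted vector when
#'   a vector was given). Incomplete rows get `NA` and do not count
#'   towards the family size.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04))
#' @export
fdr_adjust <- function(results, scope = c("global", "per_gene",
                                          "per_branch")) {
  scope <- match.arg(scope)
  if (is.numeric(results)) {
    if (any(results < 0 | results > 1, na.rm = TRUE)) {
      abort("raw P values must lie in [0, 1]")
    }
    return(p.adjust(results, method = "BH"))
  }
  stopifnot("p_raw" %in% names(results))
  if (!"complete" %in% names(results)) results$complete <- TRUE
  ok <- results$complete & !is.na(results$p_raw)
  if (any(results$p_raw[ok] < 0 | results$p_raw[ok] > 1)) {
    abort("raw P values must lie in [0, 1]")
  }
  results$p_fdr <- NA_real_
  grp <- switch(scope,
                global = rep("all", nrow(results)),
                per_gene = results$gene,
                per_branch = results$branch)
  for (g in unique(grp[ok])) {
    sel <- ok & grp == g
    results$p_fdr[sel] <- p.adjust(results$p_raw[sel], method = "BH")
  }
  results
}

#' Classify selection regime from a maximum dN/dS value
#'
#' Maps the branch-site test's maximum dN/dS onto the selection regime
#' through the shifted-log transform `t = log(1 + dN/dS)`, whose neutral
#' point `t = log 2 = 0.693147181` corresponds to dN/dS = 1. Values
#' below the neutral point (within a small tolerance band, since exact
#' equality is measure-zero) indicate negative/purifying selection,
#' values above it positive selection.
#'
#' @param max_dnds Non-negative numeric vector.
#' @param tol Width of the neutral band around `log 2` (default 1e-9).
#' @return Factor with levels `negative`, `neutral`, `positive`.
#' @examples
#' classify_selection(c(0, 1, 10))
#' @export
classify_selection <- function(max_dnds, tol = 1e-9) {
  if (any(max_dnds < 0, na.rm = TRUE)) {
    abort("max_dnds must be non-negative")
  }
  t <- log1p(max_dnds)
  cls <- ifelse(is.na(t), NA_character_,
                ifelse(abs(t - log(2)) <= tol, "neutral",
                       ifelse(t < log(2), "negative", "positive")))
  factor(cls, levels = c("negative", "neutral", "positive"))
}

#' The dN/dS transform used for selection classification
#'
#' @param max_dnds Non-negative numeric vector.
#' @return `log(1 + max_dnds)`; equals `log 2` at neutrality.
#' @export
dnds_transform <- function(max_dnds) {
  if (any(max_dnds < 0, na.rm = TRUE)) {
    abort("max_dnds must be non-negative")
  }
  log1p(max_dnds)
}

#' Summarize significant selection across branches and nodes
#'
#' Applies the multiple-testing policy, lists per-branch significant
#' genes at the FDR threshold, and counts genes significant in at least
#' one branch or node. Incomplete runs are excluded from numerator and
#' denominator alike.
#'
#' @param results Tibble from [read_selection_results()], with or
#'   without a `p_fdr` column ([fdr_adjust()] is applied when absent).
#' @param alpha Significance threshold on the adjusted values
#'   (default 0.05).
#' @param scope FDR grouping policy, see [fdr_adjust()].
#' @return A `selection_summary` object: list with `by_branch` (tibble
#'   of per-branch counts and gene lists), `significant_genes`,
#'   `n_significant`, `n_tested`, `n_excluded`, `alpha`, `scope` and
#'   the annotated per-test `results`.
#' @export
summarize_selection <- function(results, alpha = 0.05,
                                scope = c("global", "per_gene",
                                          "per_branch")) {
  scope <- match.arg(scope)
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (!"p_fdr" %in% names(results)) {
    results <- fdr_adjust(results, scope)
  }
  if (!"complete" %in% names(results)) results$complete <- TRUE
  results$selection_class <- classify_selection(results$max_dnds)
  ok <- results[results$complete & !is.na(results$p_fdr), ]
  excluded_genes <- setdiff(results$gene, ok$gene)
  sig <- ok[ok$p_fdr < alpha, ]
  by_branch <- ok |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_significant = sum(.data$p_fdr < alpha),
      genes = list(sort(.data$gene[.data$p_fdr < alpha])),
      .groups = "drop")
  structure(
    list(by_branch = by_branch,
         significant_genes = sort(unique(sig$gene)),
         n_significant = length(unique(sig$gene)),
         n_tested = length(unique(ok$gene)),
         n_excluded = length(excluded_genes),
         excluded_genes = sort(excluded_genes),
         alpha = alpha, scope = scope, results = results),
    class = "selection_summary"
  )
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("<selection_summary> ", x$n_significant, " of ", x$n_tested,
      " genes significant in >= 1 branch/node (alpha = ", x$alpha,
      ", ", x$scope, " FDR)", sep = "")
  if (x$n_excluded > 0) {
    cat("; ", x$n_excluded, " incomplete gene(s) excluded", sep = "")
  }
  cat("\n")
  top <- x$by_branch[order(-x$by_branch$n_significant), ]
  top <- top[top$n_significant > 0, ]
  if (nrow(top) > 0) {
    cat("  busiest: ", top$branch[1], " (",
        paste(top$genes[[1]], collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Write an annotated selection table to TSV
#'
#' @param summary A `selection_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_results <- function(summary, path) {
  stopifnot(inherits(summary, "selection_summary"))
  readr::write_tsv(summary$results, path, progress = FALSE)
  invisible(path)
}
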
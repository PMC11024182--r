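#' Read a long-format expression matrix
#'
#' Expression data travels as a long TSV with one row per donor x region
#' x gene and a numeric `value` column (normalized mRNA intensity).
#' Missing measurements may be absent rows or `NA` values; both are
#' treated as masked.
#'
#' @param path TSV path with columns `donor`, `region`, `gene`, `value`.
#' @return Tibble with those four columns.
#' @export
read_expression_long <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("donor", "region", "gene", "value"), names(tab))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(tab[c("donor", "region", "gene", "value")])
}

#' Read / write GMT-style gene sets
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @return `write_gmt()`: `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Region-versus-whole-brain expression tests for a gene set
#'
#' For every brain region, compares the gene set's regional expression
#' against its whole-brain mean with a two-sided one-sample t test.
#' The sample unit is the per-donor gene-set mean: in each region the
#' sample holds one value per donor (the mean intensity of the gene set
#' in that region for that donor), and the null value `mu0` is the grand
#' mean of these per-donor means over all regions of the matrix. With
#' `n` donors the effect size is Cohen's d for one-sample designs,
#' `d = (mean - mu0) / sd`, which ties to the t statistic as
#' `|d| = |t| / sqrt(n)`. P values are corrected across the tested
#' regions with the Benjamini-Hochberg procedure.
#'
#' @param expr Long-format expression tibble (`donor`, `region`,
#'   `gene`, `value`).
#' @param gene_set Character vector of gene symbols; must intersect the
#'   matrix genes.
#' @param regions Regions to test (default: all regions in `expr`).
#'   `mu0` is always computed over all regions regardless.
#' @param mu0 Override the null value (rarely needed).
#' @return A tibble of class `region_tests` with columns `region`,
#'   `sample_n`, `mean`, `t`, `d`, `p`, `p_fdr`, `degenerate`;
#'   attributes `mu0` and `n_genes` record the null value and gene-set
#'   size used. Zero-variance samples whose mean differs from `mu0`
#'   leave `t` undefined and are flagged `degenerate` instead of being
#'   fabricated.
#' @export
region_vs_brain_tests <- function(expr, gene_set, regions = NULL,
                                  mu0 = NULL) {
  genes <- intersect(unique(expr$gene), gene_set)
  if (length(genes) == 0) abort("gene_set does not intersect the matrix")
  if (length(unique(expr$donor)) < 2) abort("need at least 2 donors")

  donor_means <- expr |>
    dplyr::filter(.data$gene %in% genes, !is.na(.data$value)) |>
    dplyr::group_by(.data$donor, .data$region) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  if (is.null(mu0)) mu0 <- mean(donor_means$m)
  if (is.null(regions)) regions <- sort(unique(donor_means$region))

  res <- donor_means |>
    dplyr::filter(.data$region %in% regions) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(sample_n = dplyr::n(), mean = mean(.data$m),
                     sd = sd(.data$m), .groups = "drop") |>
    dplyr::mutate(
      degenerate = .data$sample_n < 2 | .data$sd == 0,
      t = ifelse(.data$degenerate, NA_real_,
                 (.data$mean - mu0) / (.data$sd / sqrt(.data$sample_n))),
      d = ifelse(.data$degenerate, NA_real_,
                 (.data$mean - mu0) / .data$sd),
      p = ifelse(.data$degenerate, NA_real_,
                 2 * pt(-abs(.data$t), df = .data$sample_n - 1)),
      p_fdr = p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::select("region", "sample_n", "mean", "t", "d", "p", "p_fdr",
                  "degenerate")
  if (any(res$degenerate)) {
    warn(paste0("degenerate (zero-variance or single-donor) sample in: ",
                paste(res$region[res$degenerate], collapse = ", ")))
  }
  structure(res, mu0 = mu0, n_genes = length(genes),
            class = c("region_tests", class(res)))
}

#' Differential stability of regional expression profiles
#'
#' Scores, per gene, how reproducible its regional expression profile is
#' across donors: the Pearson correlation of the two donors' profiles
#' over their shared (jointly observed) regions, averaged over all donor
#' pairs. Pairs with fewer than `min_shared` shared regions, or with a
#' constant profile in either donor (correlation undefined), are skipped
#' and counted; a gene with no usable pair gets a missing score rather
#' than a fabricated one.
#'
#' @param expr Long-format expression tibble.
#' @param genes Genes to score (default: all genes in `expr`).
#' @param min_shared Minimum jointly observed regions per donor pair
#'   (default 3).
#' @return Tibble with `gene`, `ds` (in `[-1, 1]` or `NA`), `n_pairs`
#'   (donor pairs used) and `n_skipped`.
#' @export
differential_stability <- function(expr, genes = NULL, min_shared = 3) {
  if (is.null(genes)) genes <- unique(expr$gene)
  donors <- sort(unique(expr$donor))
  if (length(donors) < 2) abort("need at least 2 donors")
  regions <- sort(unique(expr$region))
  expr <- expr[expr$gene %in% genes, ]

  # region x donor x gene array; absent rows stay NA
  arr <- array(NA_real_,
               dim = c(length(regions), length(donors), length(genes)),
               dimnames = list(regions, donors, genes))
  arr[cbind(match(expr$region, regions), match(expr$donor, donors),
            match(expr$gene, genes))] <- expr$value

  pairs <- utils::combn(length(donors), 2)
  res <- purrr::map_dfr(genes, function(g) {
    m <- arr[, , g, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(donors))
    cors <- apply(pairs, 2, function(pr) {
      x <- m[, pr[1]]; y <- m[, pr[2]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_shared) return(NA_real_)
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
      cor(x[ok], y[ok])
    })
    tibble(gene = g, ds = if (all(is.na(cors))) NA_real_
                          else mean(cors, na.rm = TRUE),
           n_pairs = sum(!is.na(cors)), n_skipped = sum(is.na(cors)))
  })
  res
}

#' Fraction of a gene set in the top quantile of background stability
#'
#' Computes the share of a gene set whose differential-stability scores
#' sit at or above the background universe's upper-`quantile` threshold
#' (default: the top half, threshold = background median). Genes without
#' a defined score are excluded from numerator and denominator, and the
#' exclusion counts are reported.
#'
#' @param set_ds Tibble from [differential_stability()] for the gene
#'   set, or a named numeric vector of scores.
#' @param background_ds Same, for the background universe.
#' @param quantile Upper tail size defining "top" (default 0.5).
#' @return One-row tibble: `fraction`, `threshold`, `n_set_used`,
#'   `n_set_excluded`, `n_background`.
#' @export
top_fraction <- function(set_ds, background_ds, quantile = 0.5) {
  if (quantile <= 0 || quantile >= 1) abort("quantile must lie in (0, 1)")
  pull_ds <- function(x) if (is.data.frame(x)) x$ds else as.numeric(x)
  s <- pull_ds(set_ds); b <- pull_ds(background_ds)
  b <- b[!is.na(b)]
  if (length(b) == 0) abort("empty background")
  n_excl <- sum(is.na(s)); s <- s[!is.na(s)]
  if (length(s) == 0) abort("gene set empty after exclusions")
  thr <- stats::quantile(b, probs = 1 - quantile, names = FALSE,
                         type = 7)
  tibble(fraction = mean(s >= thr), threshold = thr,
         n_set_used = length(s), n_set_excluded = n_excl,
         n_background = length(b))
}

#' Hypergeometric tissue enrichment of a gene set
#'
#' For each tissue's differentially-expressed-gene set, tests whether
#' the overlap with the query gene set is larger than expected when
#' drawing without replacement from the background universe: the
#' upper-tail hypergeometric probability of the observed-or-larger
#' overlap, Bonferroni-corrected across tissues.
#'
#' @param gene_set Character vector; must be a subset of `background`.
#' @param tissue_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); genes outside the background are dropped.
#' @param background Character vector, the gene universe (canonically
#'   all protein-coding genes).
#' @param n_tissues Number of tests for the Bonferroni factor
#'   (default: `length(tissue_sets)`).
#' @return A tibble of class `enrichment_results`: `tissue`, `overlap`,
#'   `set_size`, `tissue_set_size`, `background_size`, `p_hyper`,
#'   `p_bonferroni`.
#' @export
tissue_enrichment <- function(gene_set, tissue_sets, background,
                              n_tissues = length(tissue_sets)) {
  outside <- setdiff(gene_set, background)
  if (length(outside) > 0) {
    abort(paste0("gene(s) outside the background universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  gene_set <- unique(gene_set)
  background <- unique(background)
  n_bg <- length(background)
  res <- purrr::imap_dfr(tissue_sets, function(ts, tissue) {
    ts <- intersect(unique(ts), background)
    k <- length(intersect(gene_set, ts))
    p <- phyper(k - 1, length(ts), n_bg - length(ts),
                length(gene_set), lower.tail = FALSE)
    tibble(tissue = tissue, overlap = k, set_size = length(gene_set),
           tissue_set_size = length(ts), background_size = n_bg,
           p_hyper = p, p_bonferroni = pmin(1, p * n_tissues))
  })
  structure(res, class = c("enrichment_results", class(res)))
}
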
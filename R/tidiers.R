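#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an age summary into per-stratum rows
#'
#' @param x An `age_summary`.
#' @param ... Unused.
#' @return Tibble with `ps_index`, `n`, `percent`, `category`.
#' @method tidy age_summary
#' @export
tidy.age_summary <- function(x, ...) {
  as_tibble(x$by_stratum)
}

#' One-row overview of an age summary
#'
#' @param x An `age_summary`.
#' @param ... Unused.
#' @return One-row tibble with totals and per-cohort counts and
#'   percentages.
#' @method glance age_summary
#' @export
glance.age_summary <- function(x, ...) {
  bc <- x$by_category
  tibble(
    total = x$total, n_unassigned = x$n_unassigned,
    n_ancient = bc$n[bc$category == "ancient"],
    n_medium_aged = bc$n[bc$category == "medium_aged"],
    n_modern = bc$n[bc$category == "modern"],
    pct_ancient = bc$percent[bc$category == "ancient"],
    pct_medium_aged = bc$percent[bc$category == "medium_aged"],
    pct_modern = bc$percent[bc$category == "modern"])
}

#' Tidy a selection summary into per-test rows
#'
#' @param x A `selection_summary`.
#' @param ... Unused.
#' @return The annotated per-test tibble (`gene`, `branch`, `p_raw`,
#'   `p_fdr`, `max_dnds`, `selection_class`, ...).
#' @method tidy selection_summary
#' @export
tidy.selection_summary <- function(x, ...) {
  as_tibble(x$results)
}

#' One-row overview of a selection summary
#'
#' @param x A `selection_summary`.
#' @param ... Unused.
#' @return One-row tibble with tested/significant/excluded counts, the
#'   significance share, alpha and the FDR scope.
#' @method glance selection_summary
#' @export
glance.selection_summary <- function(x, ...) {
  tibble(n_tested = x$n_tested, n_significant = x$n_significant,
         pct_significant = round(100 * x$n_significant / x$n_tested, 2),
         n_excluded = x$n_excluded, alpha = x$alpha, scope = x$scope)
}

#' Tidy region tests (drops the class, keeps the rows)
#'
#' @param x A `region_tests` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-region results.
#' @method tidy region_tests
#' @export
tidy.region_tests <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "region_tests")
  out
}

#' One-row overview of region tests
#'
#' @param x A `region_tests` tibble.
#' @param alpha Threshold on `p_fdr` (default 0.05).
#' @param ... Unused.
#' @return One-row tibble: regions tested, significant count, the null
#'   value `mu0` and the gene-set size used.
#' @method glance region_tests
#' @export
glance.region_tests <- function(x, alpha = 0.05, ...) {
  tibble(n_regions = nrow(x),
         n_significant = sum(x$p_fdr < alpha, na.rm = TRUE),
         n_degenerate = sum(x$degenerate),
         mu0 = attr(x, "mu0"), n_genes = attr(x, "n_genes"))
}
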
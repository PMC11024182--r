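#' Assign each gene its earliest phylostratum
#'
#' Combines per-species presence calls (ortholog calls in vertebrates,
#' homolog calls in non-vertebrates) into a per-gene earliest stratum and
#' age category.
#'
#' Under the staged search protocol (the default), the non-vertebrate
#' evidence for a gene only counts when the gene has an ortholog in the
#' proxy species of the two oldest vertebrate strata (the anchor strata,
#' by default the first two at or above the panel's vertebrate boundary:
#' jawless and jawed vertebrates). A gene without such an anchor is dated
#' by its earliest positive vertebrate call and flagged `staged_stop`,
#' mirroring a protocol that runs no non-vertebrate searches for those
#' genes. A gene with the anchor takes the earliest positive
#' non-vertebrate call, falling back to the earliest vertebrate call when
#' no non-vertebrate species passes its cutoff. Exhaustive mode simply
#' takes the minimum stratum over all positive calls.
#'
#' Presence gaps (a positive call at stratum 4 and 7 but not 5-6) do not
#' block assignment: the earliest positive call wins. A gene with no
#' positive call anywhere is returned with `status = "unassigned"` and a
#' missing stratum rather than a silent default.
#'
#' @param calls Tibble with columns `gene`, `species_id` and logical
#'   `call` (ortholog call for vertebrate species, homolog call for
#'   non-vertebrate species). Extra columns (scores, cutoffs, shared
#'   counts) are preserved in the per-gene evidence trail.
#' @param panel A [load_species_panel()] panel.
#' @param staged Apply the staged stopping rule (default `TRUE`); set
#'   `FALSE` for an exhaustive sensitivity analysis.
#' @param boundaries Age-category cut points, see [age_category()].
#' @return Tibble with one row per gene: `gene`, `earliest_ps`,
#'   `clade`, `category`, `status`, `staged_stop` and a list column
#'   `evidence` holding the per-species call trail.
#' @export
assign_phylostrata <- function(calls, panel, staged = TRUE,
                               boundaries = c(3L, 10L)) {
  stopifnot(inherits(panel, "species_panel"))
  needed <- c("gene", "species_id", "call")
  missing <- setdiff(needed, names(calls))
  if (length(missing) > 0) {
    abort(paste0("calls table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(calls$species_id), panel$species$species_id)
  if (length(unknown) > 0) {
    abort(paste0("species not in panel: ", paste(unknown, collapse = ", ")))
  }
  n_strata <- nrow(panel$strata)
  vb <- panel$vertebrate_boundary
  vert_ps <- sort(unique(
    panel$species$ps_index[panel$species$role == "vertebrate"]))
  anchor_ps <- head(vert_ps, 2)   # oldest two vertebrate strata

  joined <- calls |>
    dplyr::left_join(panel$species[, c("species_id", "ps_index", "role")],
                     by = "species_id")

  clade_of <- setNames(panel$strata$clade_name, panel$strata$ps_index)

  records <- joined |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(g, key) {
      vert <- g$ps_index[g$role == "vertebrate" & g$call]
      nonv <- g$ps_index[g$role == "non_vertebrate" & g$call]
      anchored <- any(anchor_ps %in% vert)
      if (staged) {
        if (!anchored) {
          ps <- if (length(vert)) min(vert) else NA_integer_
          stopf <- TRUE
        } else {
          ps <- if (length(nonv)) min(nonv) else min(vert)
          stopf <- FALSE
        }
      } else {
        all_pos <- c(vert, nonv)
        ps <- if (length(all_pos)) min(all_pos) else NA_integer_
        stopf <- FALSE
      }
      tibble(earliest_ps = as.integer(ps), staged_stop = stopf,
             evidence = list(g))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      status = ifelse(is.na(.data$earliest_ps), "unassigned", "assigned"),
      clade = unname(clade_of[as.character(.data$earliest_ps)]),
      category = ifelse(
        is.na(.data$earliest_ps), NA_character_,
        as.character(age_category(
          dplyr::coalesce(.data$earliest_ps, 1L), boundaries, n_strata)))
    ) |>
    dplyr::select("gene", "earliest_ps", "clade", "category", "status",
                  "staged_stop", "evidence")
  records
}

#' Summarize a gene-age table
#'
#' Tallies genes per phylostratum and per age cohort, with percentages
#' of the assigned total (rounded to one decimal for display).
#'
#' @param records Tibble with columns `gene` and `earliest_ps` (a
#'   `category` column is recomputed from `boundaries` if absent);
#'   unassigned genes (missing `earliest_ps`) are excluded and counted
#'   separately.
#' @param n_strata Number of strata on the scale (default 20).
#' @param boundaries Age-category cut points, see [age_category()].
#' @return An `age_summary` object: list with `by_stratum` (counts for
#'   every stratum, including empty ones), `by_category` (counts and
#'   percentages), `total` and `n_unassigned`.
#' @examples
#' ages <- readr::read_tsv(
#'   phylage_example("synthetic_gene_phylostrata.tsv"),
#'   show_col_types = FALSE
#' )
#' summarize_ages(ages)
#' @export
summarize_ages <- function(records, n_strata = 20L,
                           boundaries = c(3L, 10L)) {
  stopifnot(all(c("gene", "earliest_ps") %in% names(records)))
  if (nrow(records) == 0) abort("empty record set")
  n_unassigned <- sum(is.na(records$earliest_ps))
  assigned <- records[!is.na(records$earliest_ps), ]
  if (nrow(assigned) == 0) abort("no assigned genes to summarize")
  total <- nrow(assigned)
  cat_levels <- c("ancient", "medium_aged", "modern")
  category <- age_category(assigned$earliest_ps, boundaries, n_strata)

  by_stratum <- tibble(ps_index = seq_len(n_strata)) |>
    dplyr::left_join(
      dplyr::count(assigned, ps_index = .data$earliest_ps),
      by = "ps_index") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      percent = round(100 * .data$n / total, 1),
      category = age_category(.data$ps_index, boundaries, n_strata))

  by_category <- tibble(category = factor(cat_levels, cat_levels)) |>
    dplyr::left_join(dplyr::count(tibble(category = category),
                                  .data$category),
                     by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  percent = round(100 * .data$n / total, 1))

  structure(list(by_stratum = by_stratum, by_category = by_category,
                 total = total, n_unassigned = n_unassigned,
                 boundaries = boundaries),
            class = "age_summary")
}

#' @export
print.age_summary <- function(x, ...) {
  cat("<age_summary> ", x$total, " genes dated",
      if (x$n_unassigned > 0) paste0(" (+", x$n_unassigned, " unassigned)"),
      "\n", sep = "")
  df <- as.data.frame(x$by_category)
  cat(paste0("  ", format(df$category, width = 12),
             format(df$n, width = 5), "  (", df$percent, "%)",
             collapse = "\n"), "\n")
  invisible(x)
}

#' Write a gene-age table to TSV
#'
#' Flattens the evidence list column into a compact per-species summary
#' string so the table mirrors a supplementary gene-stratum sheet.
#'
#' @param records Tibble from [assign_phylostrata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_ages <- function(records, path) {
  out <- records
  if ("evidence" %in% names(out)) {
    out$evidence <- vapply(out$evidence, function(ev) {
      paste0(ev$species_id, ifelse(ev$call, "+", "-"), collapse = ",")
    }, character(1))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
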
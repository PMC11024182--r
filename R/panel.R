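#' Load and validate a species panel
#'
#' A species panel maps proxy species to phylostrata on a lineage-specific
#' scale (stratum 1 = oldest clade, e.g. cellular organisms; the highest
#' stratum holds the reference species). Panels pair a TSV table with a
#' rooted species tree whose tips cover every panel species.
#'
#' Validation enforces: unique species, a contiguous `1..K` stratum range,
#' every species present as a tree tip, roles consistent with the
#' vertebrate boundary, and stratum indices that increase monotonically
#' along the root-to-reference path of the tree (clades branching off
#' earlier must hold older strata). Branch lengths, if present in the
#' Newick file, are ignored: stratum assignment uses topology only.
#'
#' @param panel_table Path to a TSV with columns `species_id`, `ps_index`
#'   and `role` (`vertebrate`/`non_vertebrate`); optional `clade_name`
#'   and `approx_age_mya` columns are carried through.
#' @param tree Path to a Newick file, or an [ape::read.tree()] `phylo`
#'   object, whose tips include all panel species.
#' @param vertebrate_boundary First stratum regarded as vertebrate
#'   (default 11): vertebrate species must sit at or above it,
#'   non-vertebrates below it.
#' @return A `species_panel` object: a list with `species` (tibble),
#'   `strata` (tibble with one row per stratum), `tree` (`phylo`) and
#'   `vertebrate_boundary`.
#' @examples
#' panel <- load_species_panel(
#'   phylage_example("synthetic_species_panel.tsv"),
#'   phylage_example("synthetic_species_tree.nwk")
#' )
#' panel
#' @export
load_species_panel <- function(panel_table, tree, vertebrate_boundary = 11) {
  tab <- readr::read_tsv(panel_table, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("species_id", "ps_index", "role")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("panel table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"clade_name" %in% names(tab)) tab$clade_name <- NA_character_
  if (!"approx_age_mya" %in% names(tab)) tab$approx_age_mya <- NA_real_

  if (anyDuplicated(tab$species_id)) {
    abort(paste0("duplicate species in panel: ",
                 paste(unique(tab$species_id[duplicated(tab$species_id)]),
                       collapse = ", ")))
  }
  tab$ps_index <- as.integer(tab$ps_index)
  k <- max(tab$ps_index)
  if (min(tab$ps_index) != 1L || !all(seq_len(k) %in% tab$ps_index)) {
    abort("phylostratum indices must form a contiguous 1..K range")
  }
  bad_role <- !tab$role %in% c("vertebrate", "non_vertebrate")
  if (any(bad_role)) {
    abort(paste0("unknown role for: ",
                 paste(tab$species_id[bad_role], collapse = ", ")))
  }
  inconsistent <- (tab$role == "vertebrate") !=
    (tab$ps_index >= vertebrate_boundary)
  if (any(inconsistent)) {
    abort(paste0("role inconsistent with the vertebrate boundary (PS >= ",
                 vertebrate_boundary, ") for: ",
                 paste(tab$species_id[inconsistent], collapse = ", ")))
  }

  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("malformed Newick tree")
  }
  absent <- setdiff(tab$species_id, tree$tip.label)
  if (length(absent) > 0) {
    abort(paste0("species absent from tree: ",
                 paste(absent, collapse = ", ")))
  }
  tree$edge.length <- NULL
  check_path_monotonic(tab, tree)

  strata <- tab |>
    dplyr::group_by(.data$ps_index) |>
    dplyr::summarise(
      clade_name = .data$clade_name[1],
      approx_age_mya = .data$approx_age_mya[1],
      proxy_species = list(.data$species_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ps_index)

  structure(
    list(species = as_tibble(tab[c("species_id", "ps_index", "clade_name",
                                   "approx_age_mya", "role")]),
         strata = strata, tree = tree,
         vertebrate_boundary = as.integer(vertebrate_boundary)),
    class = "species_panel"
  )
}

# Stratum indices must be non-decreasing along the root-to-reference path:
# walking from the root towards the deepest-stratum tip, each subtree that
# branches off may only contain strata at most as new as those ahead.
check_path_monotonic <- function(tab, tree) {
  if (length(tree$tip.label) < 3) return(invisible(TRUE))
  ps_of <- setNames(tab$ps_index, tab$species_id)
  ref <- tab$species_id[which.max(tab$ps_index)]
  ref_tip <- match(ref, tree$tip.label)
  # node path from root to the reference tip
  path <- integer(0)
  node <- ref_tip
  parent <- tree$edge[, 1][match(node, tree$edge[, 2])]
  while (!is.na(parent)) {
    path <- c(parent, path)
    node <- parent
    parent <- tree$edge[, 1][match(node, tree$edge[, 2])]
  }
  subtrees <- lapply(path, function(nd) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    on_path <- kids %in% c(path, ref_tip)
    tips <- unlist(lapply(kids[!on_path], function(k) {
      if (k <= length(tree$tip.label)) tree$tip.label[k]
      else ape::extract.clade(tree, k)$tip.label
    }))
    ps_of[intersect(tips, names(ps_of))]
  })
  subtrees <- subtrees[lengths(subtrees) > 0]
  fail <- function() {
    abort("stratum indices are not monotone along the root-to-reference path")
  }
  # a clade branching off the backbone must hold exactly one stratum,
  # and strata must not decrease walking from the root to the reference
  if (any(vapply(subtrees, function(s) length(unique(s)) > 1,
                 logical(1)))) {
    fail()
  }
  seq_ps <- vapply(subtrees, function(s) s[[1]], numeric(1))
  if (is.unsorted(seq_ps)) fail()
  invisible(TRUE)
}

#' @export
print.species_panel <- function(x, ...) {
  cat("<species_panel> ", nrow(x$species), " species, ",
      nrow(x$strata), " phylostrata (vertebrates at PS >= ",
      x$vertebrate_boundary, ")\n", sep = "")
  print(x$species, n = 6)
  invisible(x)
}

#' Write a species panel back to TSV
#'
#' Inverse of the table half of [load_species_panel()]; reloading the
#' written file against the same tree reproduces the panel.
#'
#' @param panel A `species_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_species_panel <- function(panel, path) {
  stopifnot(inherits(panel, "species_panel"))
  readr::write_tsv(panel$species, path, progress = FALSE)
  invisible(path)
}

#' Age category of a phylostratum
#'
#' Bins stratum indices into the three age cohorts used for downstream
#' annotation: strata up to `boundaries[1]` are "ancient", strata up to
#' `boundaries[2]` are "medium_aged", the rest are "modern". The default
#' cut points (3 and 10) put cellular organisms through opisthokonta in
#' the ancient cohort, holozoa through olfactores in the medium-aged
#' cohort, and all vertebrate strata in the modern cohort.
#'
#' @param ps_index Integer vector of stratum indices in `1..n_strata`.
#' @param boundaries Length-2 increasing integer vector of upper cut
#'   points for the ancient and medium-aged cohorts.
#' @param n_strata Total number of strata on the scale (default 20).
#' @return Factor with levels `ancient`, `medium_aged`, `modern`.
#' @examples
#' age_category(c(2, 7, 12))
#' @export
age_category <- function(ps_index, boundaries = c(3L, 10L), n_strata = 20L) {
  if (length(boundaries) != 2 || boundaries[1] >= boundaries[2] ||
      boundaries[2] >= n_strata) {
    abort("boundaries must be two increasing cut points below n_strata")
  }
  ps_index <- as.integer(ps_index)
  if (any(is.na(ps_index) | ps_index < 1 | ps_index > n_strata)) {
    abort(paste0("ps_index outside 1..", n_strata))
  }
  cut(ps_index, breaks = c(0, boundaries, n_strata),
      labels = c("ancient", "medium_aged", "modern"))
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
phylage_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "phylage"))
  } else {
    path <- system.file("extdata", file, package = "phylage")
    if (identical(path, "")) abort(paste0("no packaged file '", file, "'"))
    path
  }
}
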
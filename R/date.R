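#' Date a set of genes from BLAST hits and annotations
#'
#' Composes the full dating pipeline on in-memory tables: best-hit
#' selection, scaled scores, per-species cutoffs and homolog calls for
#' the non-vertebrate panel species; microsynteny comparison against the
#' reference species and combined hit-plus-synteny ortholog calls for
#' the vertebrate species; then earliest-stratum assignment under the
#' staged (or exhaustive) protocol.
#'
#' @param hits BLAST-hit tibble in the schema of
#'   [read_blast_tabular()], covering any number of target species.
#' @param annotations Gene-annotation tibble (vertebrate species,
#'   including the reference species) in the schema of
#'   [extract_neighborhood()], with a `species_id` column.
#' @param panel A [load_species_panel()] panel.
#' @param threshold_k Minimum shared flank genes for synteny
#'   conservation (default 3).
#' @param window Flank genes per side (default 5).
#' @param staged Staged stopping rule, see [assign_phylostrata()].
#' @param boundaries Age-category cut points.
#' @param symbol_map Optional cross-species symbol alias map.
#' @return List with `records` ([assign_phylostrata()] output),
#'   `summary` ([summarize_ages()]), `cutoffs`, `calls` and `synteny`
#'   (per gene x vertebrate species comparison table).
#' @export
date_genes <- function(hits, annotations, panel, threshold_k = 3,
                       window = 5, staged = TRUE,
                       boundaries = c(3L, 10L), symbol_map = NULL) {
  stopifnot(inherits(panel, "species_panel"))
  sp <- panel$species
  best <- add_scaled_scores(select_best_hits(hits))
  best <- dplyr::left_join(best, sp[, c("species_id", "role")],
                           by = c(target_species = "species_id"))
  if (any(is.na(best$role))) {
    abort(paste0("hits for species not in panel: ",
                 paste(unique(best$target_species[is.na(best$role)]),
                       collapse = ", ")))
  }

  # non-vertebrates: scaled score above the species-specific mean cutoff
  nv <- best[best$role == "non_vertebrate", ]
  nv_calls <- NULL
  cutoffs <- NULL
  if (nrow(nv) > 0) {
    cutoffs <- species_cutoffs(nv)
    nv_calls <- call_homologs(nv, cutoffs) |>
      dplyr::transmute(gene = .data$query_gene,
                       species_id = .data$target_species,
                       call = .data$homolog,
                       scaled_score = .data$scaled_score,
                       cutoff = .data$cutoff)
  }

  # vertebrates: best hit present AND conserved microsynteny
  ref_sp <- sp$species_id[which.max(sp$ps_index)]
  vert_sp <- sp$species_id[sp$role == "vertebrate"]
  ann_ref <- annotations[annotations$species_id == ref_sp, ]
  ann_by_sp <- split(annotations, annotations$species_id)
  genes <- sort(unique(c(best$query_gene, ann_ref$symbol[
    ann_ref$biotype == "protein_coding"])))
  genes <- intersect(genes, c(best$query_gene))

  vbest <- best[best$role == "vertebrate", ]
  hit_key <- paste(vbest$query_gene, vbest$target_species)

  synteny <- purrr::map_dfr(genes, function(g) {
    if (!any(ann_ref$symbol == g | ann_ref$gene_id == g)) return(NULL)
    ref_nb <- extract_neighborhoods(ann_ref, g, window)
    # reference may itself carry duplicated loci; use the first as frame
    ref_nb <- ref_nb[[1]]
    purrr::map_dfr(setdiff(vert_sp, ref_sp), function(s) {
      ann_s <- ann_by_sp[[s]]
      if (is.null(ann_s) ||
          !any(ann_s$symbol == g | ann_s$gene_id == g)) {
        return(tibble(gene = g, species_id = s, shared_count = 0L,
                      conserved = FALSE, threshold_k = threshold_k))
      }
      nbs <- extract_neighborhoods(ann_s, g, window)
      cnt <- max(vapply(nbs, function(nb) {
        shared_flank_count(ref_nb, nb, symbol_map)
      }, integer(1)))
      tibble(gene = g, species_id = s, shared_count = cnt,
             conserved = synteny_conserved(cnt, threshold_k, 2 * window),
             threshold_k = threshold_k)
    })
  })

  vert_calls <- synteny |>
    dplyr::mutate(
      hit = paste(.data$gene, .data$species_id) %in% hit_key,
      call = call_ortholog(.data$hit, .data$conserved))
  ref_calls <- tibble(
    gene = genes, species_id = ref_sp,
    shared_count = NA_integer_, conserved = NA, threshold_k = threshold_k,
    hit = TRUE,
    call = genes %in% ann_ref$symbol[ann_ref$biotype == "protein_coding"])

  calls <- dplyr::bind_rows(
    nv_calls,
    dplyr::select(vert_calls, "gene", "species_id", "call",
                  "shared_count"),
    dplyr::select(ref_calls, "gene", "species_id", "call"))

  records <- assign_phylostrata(calls, panel, staged = staged,
                                boundaries = boundaries)
  list(records = records,
       summary = summarize_ages(records, nrow(panel$strata), boundaries),
       cutoffs = cutoffs, calls = calls, synteny = synteny)
}
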
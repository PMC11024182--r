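#' Read tabular protein-BLAST output
#'
#' Parses the tab-separated BLAST output dialect (`-outfmt 6`, or
#' `-outfmt 7` with `#` comment lines) extended with query and subject
#' sequence lengths. Required columns, by name in a header comment or
#' supplied via `col_names`, are `qseqid`, `sseqid`, `evalue`, `bitscore`,
#' `qlen` and `slen`; a `staxid`/`species` column, when present, is mapped
#' to `target_species`.
#'
#' @param path Path to the tabular file.
#' @param col_names Column names, in file order, when the file carries no
#'   header. Defaults to the extended outfmt-6 order
#'   `qseqid sseqid pident length evalue bitscore qlen slen`.
#' @param target_species Species identifier to attach to every hit when
#'   the file has no species column (one file per target proteome, the
#'   usual layout).
#' @return A tibble of hits with columns `query_gene`, `target_species`,
#'   `subject_accession`, `evalue`, `max_score`, `query_length`,
#'   `subject_length`.
#' @export
read_blast_tabular <- function(path,
                               col_names = c("qseqid", "sseqid", "pident",
                                             "length", "evalue", "bitscore",
                                             "qlen", "slen"),
                               target_species = NA_character_) {
  lines <- readr::read_lines(path, progress = FALSE)
  header <- grep("^#\\s*Fields:", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) abort(paste0("empty BLAST file: ", path))
  if (length(header) > 0) {
    col_names <- strsplit(sub("^#\\s*Fields:\\s*", "", header[1]),
                          "\\s*,\\s*")[[1]]
    col_names <- gsub("[^a-z0-9]+", "_", tolower(col_names))
    aliases <- c(query_acc_ver = "qseqid", query_id = "qseqid",
                 subject_acc_ver = "sseqid", subject_id = "sseqid",
                 bit_score = "bitscore", query_length = "qlen",
                 subject_length = "slen", subject_tax_id = "staxid")
    hit <- match(col_names, names(aliases))
    col_names[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  tab <- readr::read_tsv(I(body), col_names = col_names,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("qseqid", "sseqid", "evalue", "bitscore", "qlen", "slen")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0) {
      abort(paste0(path, ": non-numeric ", col, " in data row ", bad[1]))
    }
    v
  }
  hits <- tibble(
    query_gene = tab$qseqid,
    target_species = if ("staxid" %in% names(tab)) tab$staxid
                     else if ("species" %in% names(tab)) tab$species
                     else target_species,
    subject_accession = tab$sseqid,
    evalue = num("evalue"),
    max_score = num("bitscore"),
    query_length = as.integer(num("qlen")),
    subject_length = as.integer(num("slen"))
  )
  bad <- which(hits$max_score < 0 | hits$evalue < 0 |
                 hits$query_length < 1 | hits$subject_length < 1)
  if (length(bad) > 0) {
    abort(paste0(path, ": invalid score/length in data row ", bad[1]))
  }
  hits
}

#' Best hit per gene and target species
#'
#' Selects, within each `query_gene` x `target_species` group, the hit
#' with the lowest E-value; E-value ties are broken by the highest max
#' score, remaining ties by the lexicographically smallest subject
#' accession so the choice is deterministic. Groups are dropped silently
#' when empty (a gene with no hit in a species simply yields no row).
#'
#' @param hits Tibble of hits as returned by [read_blast_tabular()].
#' @return One-row-per-group tibble of best hits.
#' @examples
#' hits <- tibble::tibble(
#'   query_gene = "OXTR", target_species = "csavignyi",
#'   subject_accession = c("A", "B"), evalue = c(1e-50, 1e-10),
#'   max_score = c(80, 95), query_length = 431L, subject_length = 364L
#' )
#' select_best_hits(hits)
#' @export
select_best_hits <- function(hits) {
  stopifnot(all(c("query_gene", "target_species", "subject_accession",
                  "evalue", "max_score") %in% names(hits)))
  hits |>
    dplyr::group_by(.data$query_gene, .data$target_species) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$max_score),
                   .data$subject_accession, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Length-scaled max score
#'
#' Normalizes a BLAST max score (best-HSP bit score) by the summed
#' lengths of the aligned proteins, making scores comparable across
#' proteins of different length: `max_score / (subject_length +
#' query_length)`. The published worked example divides a max score of
#' 92.8 by 364 + 431 residues, giving 0.1167296.
#'
#' @param max_score Non-negative numeric vector of bit scores.
#' @param subject_length,query_length Positive integer vectors of protein
#'   lengths in residues.
#' @return Numeric vector of scaled scores.
#' @examples
#' scaled_max_score(92.8, 364, 431)
#' @export
scaled_max_score <- function(max_score, subject_length, query_length) {
  if (any(subject_length < 1) || any(query_length < 1)) {
    abort("sequence lengths must be >= 1 residue")
  }
  if (any(max_score < 0)) abort("max_score must be non-negative")
  max_score / (subject_length + query_length)
}

#' Attach scaled scores to a best-hit table
#'
#' @param best_hits Tibble from [select_best_hits()].
#' @return The input with a `scaled_score` column.
#' @export
add_scaled_scores <- function(best_hits) {
  dplyr::mutate(best_hits,
                scaled_score = scaled_max_score(.data$max_score,
                                                .data$subject_length,
                                                .data$query_length))
}

#' Species-specific homology cutoffs
#'
#' Averages per-gene scaled scores within each target species to obtain
#' that species' homology cutoff. Only genes with a hit contribute (one
#' best-hit score per gene); a gene absent from a species neither raises
#' nor lowers the cutoff.
#'
#' @param scores Tibble with columns `query_gene`, `target_species` and
#'   `scaled_score`, one row per gene x species.
#' @return Tibble with `target_species`, `cutoff` and `n_genes`.
#' @export
species_cutoffs <- function(scores) {
  stopifnot(all(c("query_gene", "target_species", "scaled_score")
                %in% names(scores)))
  dup <- scores |>
    dplyr::count(.data$target_species, .data$query_gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate gene entries for species ",
                 dup$target_species[1], " (", dup$query_gene[1],
                 "); pass best hits only"))
  }
  if (nrow(scores) == 0) abort("no scores to average")
  scores |>
    dplyr::group_by(.data$target_species) |>
    dplyr::summarise(cutoff = mean(.data$scaled_score),
                     n_genes = dplyr::n(), .groups = "drop")
}

#' Call putative homologs against species cutoffs
#'
#' A hit is a putative homolog when its scaled score lies strictly above
#' the species-specific cutoff (a score exactly at the cutoff is not a
#' call).
#'
#' @param scores Tibble with `query_gene`, `target_species`,
#'   `scaled_score`.
#' @param cutoffs Tibble from [species_cutoffs()], or a single numeric
#'   cutoff when `scores` holds one species.
#' @return `scores` with `cutoff` and logical `homolog` columns.
#' @examples
#' call_homologs(
#'   tibble::tibble(query_gene = "OXTR", target_species = "csavignyi",
#'                  scaled_score = 0.1167296),
#'   tibble::tibble(target_species = "csavignyi", cutoff = 0.2098398)
#' )
#' @export
call_homologs <- function(scores, cutoffs) {
  if (is.numeric(cutoffs)) {
    sp <- unique(scores$target_species)
    if (length(sp) != 1) {
      abort("a bare numeric cutoff needs a single-species score table")
    }
    cutoffs <- tibble(target_species = sp, cutoff = cutoffs)
  }
  missing <- setdiff(unique(scores$target_species),
                     cutoffs$target_species)
  if (length(missing) > 0) {
    abort(paste0("no cutoff for species: ",
                 paste(missing, collapse = ", ")))
  }
  scores |>
    dplyr::left_join(dplyr::select(cutoffs, "target_species", "cutoff"),
                     by = "target_species") |>
    dplyr::mutate(homolog = .data$scaled_score > .data$cutoff)
}

#' Write a per-species cutoff table
#'
#' @param cutoffs Tibble from [species_cutoffs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  readr::write_tsv(cutoffs, path, progress = FALSE)
  invisible(path)
}
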
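# shared in-code fixtures: small panels, annotation contigs, hit tables

packaged_panel <- function() {
  load_species_panel(phylage_example("synthetic_species_panel.tsv"),
                     phylage_example("synthetic_species_tree.nwk"))
}

# minimal panel: one species per stratum, k strata, ladder tree
toy_panel <- function(k = 4, boundary = 3) {
  sp <- paste0("sp", seq_len(k))
  tab <- tibble::tibble(
    species_id = sp, ps_index = seq_len(k),
    role = ifelse(seq_len(k) >= boundary, "vertebrate", "non_vertebrate"))
  nwk <- sp[k]
  for (i in rev(seq_len(k - 1))) nwk <- paste0("(", sp[i], ",", nwk, ")")
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ptab <- file.path(dir, "panel.tsv")
  ptree <- file.path(dir, "tree.nwk")
  readr::write_tsv(tab, ptab)
  writeLines(paste0(nwk, ";"), ptree)
  load_species_panel(ptab, ptree, vertebrate_boundary = boundary)
}

# one-contig annotation table: symbols in order, all protein_coding
# unless biotype overrides are given by position
ann_contig <- function(symbols, species = "spA", contig = "c1",
                       biotype = NULL) {
  n <- length(symbols)
  bt <- rep("protein_coding", n)
  if (!is.null(biotype)) bt[seq_along(biotype)] <- biotype
  tibble::tibble(
    species_id = species, contig = contig,
    gene_id = paste0(species, "_", symbols, "_", seq_len(n)),
    symbol = symbols, start = 1000L * seq_len(n),
    end = 1000L * seq_len(n) + 500L, strand = "+", biotype = bt)
}

hit_row <- function(gene, species, evalue = 1e-30, score = 100,
                    acc = "ACC1", qlen = 400L, slen = 400L) {
  tibble::tibble(query_gene = gene, target_species = species,
                 subject_accession = acc, evalue = evalue,
                 max_score = score, query_length = qlen,
                 subject_length = slen)
}

# independent step-up oracle for the Benjamini-Hochberg adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# exhaustive upper-tail hypergeometric by enumeration of overlaps
hyper_oracle <- function(k, set_size, tissue_size, background) {
  js <- k:min(set_size, tissue_size)
  sum(choose(tissue_size, js) *
        choose(background - tissue_size, set_size - js)) /
    choose(background, set_size)
}
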
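write_blast <- function(rows, dir, header = NULL) {
  path <- file.path(dir, "hits.tsv")
  writeLines(c(header, rows), path)
  path
}

test_that("tabular BLAST output parses with correct field mapping", {
  dir <- withr::local_tempdir()
  path <- write_blast(c(
    "OXTR\tXP_1\t35.2\t210\t1e-20\t92.8\t431\t364",
    "OXTR\tXP_2\t30.0\t180\t1e-10\t60.1\t431\t300",
    "OXT\tXP_3\t40.0\t100\t2e-30\t120.0\t125\t140"), dir)
  hits <- read_blast_tabular(path, target_species = "csavignyi")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_gene, c("OXTR", "OXTR", "OXT"))
  expect_equal(hits$max_score[1], 92.8)
  expect_equal(hits$query_length[1], 431L)
  expect_equal(hits$subject_length[1], 364L)
  expect_equal(unique(hits$target_species), "csavignyi")
})

test_that("commented output (outfmt 7) is parsed via its Fields header", {
  dir <- withr::local_tempdir()
  path <- write_blast(
    "OXTR\tXP_1\t1e-20\t92.8\t431\t364",
    dir,
    header = c("# BLASTP 2.13.0+", "# Query: OXTR",
               paste("# Fields: query id, subject id, evalue,",
                     "bit score, query length, subject length"),
               "# 1 hits found"))
  hits <- read_blast_tabular(path)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$max_score, 92.8)
  expect_equal(hits$subject_length, 364L)
})

test_that("defective files are rejected with the offending row named", {
  dir <- withr::local_tempdir()
  bad <- write_blast(c("OXTR\tXP_1\t35\t210\t1e-20\t-5\t431\t364"), dir)
  expect_error(read_blast_tabular(bad), "row 1")
  bad <- write_blast(c("OXTR\tXP_1\t35\t210\t1e-20\tNOTNUM\t431\t364"),
                     dir)
  expect_error(read_blast_tabular(bad), "non-numeric")
  bad <- write_blast("OXTR\tXP_1\t1e-20", dir)
  expect_error(read_blast_tabular(bad,
                                  col_names = c("qseqid", "sseqid",
                                                "evalue")),
               "missing required column")
  empty <- file.path(dir, "empty.tsv")
  writeLines(character(0), empty)
  expect_error(read_blast_tabular(empty), "empty")
})

test_that("best-hit selection minimizes E-value with deterministic ties", {
  h <- dplyr::bind_rows(
    hit_row("g", "sp", evalue = 1e-50, score = 80, acc = "B"),
    hit_row("g", "sp", evalue = 1e-10, score = 200, acc = "A"))
  expect_equal(select_best_hits(h)$evalue, 1e-50)
  # E-value tie: highest max score wins
  h <- dplyr::bind_rows(
    hit_row("g", "sp", evalue = 1e-20, score = 50.1, acc = "A"),
    hit_row("g", "sp", evalue = 1e-20, score = 92.8, acc = "B"))
  expect_equal(select_best_hits(h)$max_score, 92.8)
  # full tie: smallest accession wins
  h <- dplyr::bind_rows(
    hit_row("g", "sp", acc = "XP_9"), hit_row("g", "sp", acc = "XP_1"))
  expect_equal(select_best_hits(h)$subject_accession, "XP_1")
  # empty input: no rows, not an error
  expect_equal(nrow(select_best_hits(h[0, ])), 0)
  # groups are independent
  h <- dplyr::bind_rows(
    hit_row("g1", "spA", evalue = 1e-5), hit_row("g1", "spB", 1e-9),
    hit_row("g2", "spA", evalue = 1e-7))
  expect_equal(nrow(select_best_hits(h)), 3)
})

test_that("scaled max score reproduces the worked normalization", {
  expect_equal(sprintf("%.7f", scaled_max_score(92.8, 364, 431)),
               "0.1167296")
  expect_equal(scaled_max_score(0, 100, 200), 0)
  expect_equal(scaled_max_score(100, 100, 100), 0.5)
  expect_error(scaled_max_score(10, 0, 100), "length")
  expect_error(scaled_max_score(-1, 10, 10), "non-negative")
})

test_that("scaled score is monotone in score and anti-monotone in length", {
  set.seed(11)
  for (i in 1:50) {
    s <- runif(1, 10, 500); ql <- sample(50:900, 1)
    sl <- sample(50:900, 1)
    base <- scaled_max_score(s, sl, ql)
    expect_gt(scaled_max_score(s + 1, sl, ql), base)
    expect_lt(scaled_max_score(s, sl + 10, ql), base)
    expect_lt(scaled_max_score(s, sl, ql + 10), base)
  }
})

test_that("species cutoffs are per-species means of per-gene scores", {
  sc <- tibble::tibble(query_gene = c("a", "b"),
                       target_species = "sp",
                       scaled_score = c(0.2, 0.3))
  expect_equal(species_cutoffs(sc)$cutoff, 0.25)
  expect_equal(species_cutoffs(sc)$n_genes, 2L)
  one <- sc[1, ]; one$scaled_score <- 0.4
  expect_equal(species_cutoffs(one)$cutoff, 0.4)
  expect_error(species_cutoffs(sc[0, ]), "no scores")
  dup <- dplyr::bind_rows(sc, sc[1, ])
  expect_error(species_cutoffs(dup), "duplicate")
})

test_that("cutoffs are bounded by their inputs and permutation-invariant", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    sc <- tibble::tibble(query_gene = paste0("g", 1:n),
                         target_species = "sp",
                         scaled_score = runif(n, 0, 0.6))
    cut <- species_cutoffs(sc)$cutoff
    expect_gte(cut, min(sc$scaled_score))
    expect_lte(cut, max(sc$scaled_score))
    perm <- sc[sample(n), ]
    expect_equal(species_cutoffs(perm)$cutoff, cut)
  }
})

test_that("homolog calls use a strict above-cutoff rule", {
  cut <- tibble::tibble(target_species = "csavignyi",
                        cutoff = 0.2098398)
  sc <- function(v) tibble::tibble(query_gene = "g",
                                   target_species = "csavignyi",
                                   scaled_score = v)
  expect_false(call_homologs(sc(0.1167296), cut)$homolog)
  expect_true(call_homologs(sc(0.3), cut)$homolog)
  # a score exactly at the cutoff is not a call
  expect_false(call_homologs(sc(0.2098398), cut)$homolog)
  expect_error(call_homologs(sc(0.3),
                             tibble::tibble(target_species = "other",
                                            cutoff = 0.2)),
               "no cutoff")
})

test_that("raising a score never flips a homolog call to false", {
  set.seed(31)
  cut <- tibble::tibble(target_species = "sp", cutoff = 0.25)
  for (i in 1:100) {
    v <- runif(1, 0, 0.6)
    lo <- call_homologs(tibble::tibble(query_gene = "g",
                                       target_species = "sp",
                                       scaled_score = v), cut)$homolog
    hi <- call_homologs(tibble::tibble(query_gene = "g",
                                       target_species = "sp",
                                       scaled_score = v + runif(1, 0, 0.3)),
                        cut)$homolog
    expect_true(!lo || hi)
  }
})
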
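expr_from_samples <- function(samples) {
  # samples: named list region -> numeric vector (one value per donor)
  purrr::imap_dfr(samples, function(v, r) {
    tibble::tibble(donor = paste0("d", seq_along(v)), region = r,
                   gene = "G1", value = v)
  })
}

test_that("a centered sample gives t = 0, d = 0, p = 1", {
  expr <- expr_from_samples(list(r1 = c(1, 2, 3)))
  rt <- region_vs_brain_tests(expr, "G1", mu0 = 2)
  expect_equal(rt$t, 0)
  expect_equal(rt$d, 0)
  expect_equal(rt$p, 1)
})

test_that("t and p match the closed form and a stock t-test oracle", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    mu0 <- rnorm(1)
    rt <- region_vs_brain_tests(expr_from_samples(list(r = x)), "G1",
                                mu0 = mu0)
    tt <- t.test(x, mu = mu0)
    expect_equal(rt$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(rt$p, tt$p.value, tolerance = 1e-9)
    expect_equal(rt$p, 2 * pt(-abs(rt$t), n - 1), tolerance = 1e-12)
    expect_equal(abs(rt$d), abs(rt$t) / sqrt(n), tolerance = 1e-9)
    expect_equal(sign(rt$t), sign(rt$mean - mu0))
  }
})

test_that("the size-six design links the published t and d pairs", {
  pairs <- tibble::tribble(
    ~region,            ~t,      ~d,
    "pars_opercularis",  4.29,  1.75,
    "posterior_cing",    4.38,  1.79,
    "precentral",        7.29,  2.98,
    "superior_frontal",  4.08,  1.67,
    "thalamus",        -17.11,  6.98,
    "pallidum",         -5.79,  2.36,
    "hippocampus",      -4.35,  1.77,
    "brainstem",       -11.61,  4.74,
    "accumbens",         6.87,  1.81)   # documented outlier pair
  implied <- abs(pairs$t) / sqrt(6)
  consistent <- abs(implied - pairs$d) < 0.015
  expect_equal(sum(consistent), 8)
  expect_false(consistent[pairs$region == "accumbens"])
})

test_that("zero-variance samples are flagged, never fabricated", {
  expr <- expr_from_samples(list(flat = c(2, 2, 2), ok = c(1, 2, 4)))
  expect_warning(rt <- region_vs_brain_tests(expr, "G1"), "degenerate")
  flat <- rt[rt$region == "flat", ]
  expect_true(flat$degenerate)
  expect_true(is.na(flat$t))
  expect_false(rt$degenerate[rt$region == "ok"])
  expect_error(region_vs_brain_tests(
    tibble::tibble(donor = "d1", region = "r", gene = "G1", value = 1),
    "G1"), "2 donors")
  expect_error(region_vs_brain_tests(expr, "ZZZ"), "intersect")
})

test_that("planted regional shifts are detected and estimated", {
  hits <- tops <- logical(60); d_hat <- numeric(60)
  for (i in seq_len(60)) {
    ex <- simulate_expression(
      sim_config(seed = 100 + i, expr_n_set = 20L, expr_n_other = 0L,
                 expr_effects = c(ctx_05 = 3)))
    rt <- suppressWarnings(region_vs_brain_tests(ex$expr, ex$gene_set))
    row <- rt[rt$region == "ctx_05", ]
    hits[i] <- isTRUE(row$p_fdr < 0.05)
    tops[i] <- rt$region[which.min(rt$p)] == "ctx_05"
    d_hat[i] <- row$d
  }
  # the shifted region dominates the ranking and survives correction in
  # a solid share of cohorts despite only six donors
  expect_gte(mean(tops), 0.75)
  expect_gte(mean(hits), 1 / 3)
  expect_lt(abs(mean(d_hat) - 3) / 3, 0.4)
})

test_that("differential stability hits its algebraic anchors", {
  base <- tibble::tibble(region = paste0("r", 1:5),
                         value = c(1, 3, 2, 5, 4))
  same <- dplyr::bind_rows(
    dplyr::mutate(base, donor = "d1", gene = "G"),
    dplyr::mutate(base, donor = "d2", gene = "G"))
  expect_equal(differential_stability(same)$ds, 1)
  flipped <- dplyr::bind_rows(
    dplyr::mutate(base, donor = "d1", gene = "G"),
    dplyr::mutate(base, donor = "d2", gene = "G",
                  value = 6 - value))
  expect_equal(differential_stability(flipped)$ds, -1)
})

test_that("constant profiles are skipped and surfaced as missing", {
  expr <- dplyr::bind_rows(
    tibble::tibble(donor = "d1", region = paste0("r", 1:4), gene = "G",
                   value = 2),
    tibble::tibble(donor = "d2", region = paste0("r", 1:4), gene = "G",
                   value = c(1, 2, 3, 4)))
  ds <- differential_stability(expr)
  expect_true(is.na(ds$ds))
  expect_equal(ds$n_skipped, 1L)
})

test_that("independent profiles center differential stability at zero", {
  set.seed(82)
  expr <- tidyr::expand_grid(donor = paste0("d", 1:6),
                             region = paste0("r", 1:42),
                             gene = paste0("g", 1:1000))
  expr$value <- rnorm(nrow(expr))
  ds <- differential_stability(expr)
  expect_lt(abs(mean(ds$ds)), 0.02)
  expect_true(all(ds$ds >= -1 & ds$ds <= 1))
})

test_that("top-fraction scoring is exact at its extremes", {
  bg <- tibble::tibble(gene = paste0("g", 1:100),
                       ds = seq(0.01, 1, length.out = 100))
  top_half <- bg[bg$ds > stats::median(bg$ds), ]
  bottom_half <- bg[bg$ds < stats::median(bg$ds), ]
  expect_equal(top_fraction(top_half, bg)$fraction, 1.0)
  expect_equal(top_fraction(bottom_half, bg)$fraction, 0.0)
  # random subsets sit near one half
  set.seed(83)
  fr <- vapply(1:50, function(i) {
    top_fraction(bg[sample(100, 30), ], bg)$fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 3 * sqrt(0.25 / 30) / sqrt(50))
  # exclusions are reported, degenerate inputs refused
  with_na <- dplyr::bind_rows(top_half,
                              tibble::tibble(gene = "x", ds = NA))
  expect_equal(top_fraction(with_na, bg)$n_set_excluded, 1L)
  expect_error(top_fraction(tibble::tibble(gene = "x", ds = NA), bg),
               "empty")
  expect_error(top_fraction(top_half, bg[0, ]), "background")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # worked case: background 10, set 5, tissue set 4, full overlap
  enr <- tissue_enrichment(paste0("g", 1:5),
                           list(t1 = paste0("g", 2:5)),
                           paste0("g", 1:10), n_tissues = 1)
  expect_equal(enr$overlap, 4L)
  expect_equal(enr$p_hyper, 6 / 252, tolerance = 1e-12)
  # no overlap with a tiny tissue set: probability near one
  enr0 <- tissue_enrichment(paste0("g", 1:5),
                            list(t1 = paste0("g", 9:10)),
                            paste0("g", 1:10))
  expect_equal(enr0$overlap, 0L)
  expect_gt(enr0$p_hyper, 0.95)
  # tissue set equal to the background: overlap is forced, p = 1
  enr1 <- tissue_enrichment(paste0("g", 1:5),
                            list(t1 = paste0("g", 1:10)),
                            paste0("g", 1:10))
  expect_equal(enr1$p_hyper, 1)
  expect_error(tissue_enrichment(c("g1", "alien"), list(t = "g1"),
                                 paste0("g", 1:5)), "outside")
  # Bonferroni uses the declared number of tissues, capped at one
  enr30 <- tissue_enrichment(paste0("g", 1:5),
                             list(t1 = paste0("g", 2:5)),
                             paste0("g", 1:10), n_tissues = 30)
  expect_equal(enr30$p_bonferroni, pmin(1, enr30$p_hyper * 30))
})

test_that("enrichment agrees with the enumeration oracle on small universes", {
  for (n_bg in c(6, 9, 12)) {
    bg <- paste0("g", seq_len(n_bg))
    for (set_size in c(2, 4)) {
      for (tissue_size in c(1, 3, n_bg)) {
        gs <- bg[seq_len(set_size)]
        ts <- bg[seq_len(tissue_size)]
        enr <- tissue_enrichment(gs, list(t = ts), bg, n_tissues = 1)
        expect_equal(enr$p_hyper,
                     hyper_oracle(enr$overlap, set_size, tissue_size,
                                  n_bg),
                     tolerance = 1e-12)
      }
    }
  }
})
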
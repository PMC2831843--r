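test_that("composition excludes N bases from the frequency denominator", {
  gs <- GeneSet(data.frame(gene_id = "g", sequence = "AATT"))
  comp <- composition(gs)
  expect_equal(unname(comp$f), c(.5, 0, 0, .5))

  gsn <- GeneSet(data.frame(gene_id = "g", sequence = "AANN"))
  compn <- composition(gsn)
  expect_equal(unname(compn$f["A"]), 1)
  expect_equal(compn$N, 4L)  # N bases still count toward total length
})

test_that("expected_count reproduces closed-form and Monte-Carlo values", {
  # single gene, L = 10, f = 0.25, k = 3: exact value by the per-gene formula
  comp1 <- genome_composition(c(A = .25, C = .25, G = .25, T = .25),
                              N = 10, n = 1, lengths = 10)
  expect_equal(expected_count(comp1, "A", 3), 0.076171875)
  # independent Monte-Carlo oracle over random length-10 sequences
  mc <- mc_expected_count(0.25, L = 10, k = 3, n_sim = 3e5, seed = 4)
  se <- sqrt(0.076171875 / 3e5)  # run counts are near-Poisson at this scale
  expect_lt(abs(mc - 0.076171875), 4 * se)

  # the GC-70%, 1.8 Mb regime: E for A_8 is close to 0.3
  comp70 <- composition_from_gc(0.70, N = 1.8e6, n = 2000)
  expect_equal(round(expected_count(comp70, "A", 8), 1), 0.3)

  # degenerate compositions
  expect_equal(expected_count(genome_composition(
    c(A = 0, C = .5, G = .5, T = 0), 1000, 2), "A", 5), 0)
  expect_warning(expected_count(genome_composition(
    c(A = 1, C = 0, G = 0, T = 0), 100, 1, lengths = 100), "A", 5),
    "degenerate")
})

test_that("per-gene and aggregate expectation forms agree at genome scale", {
  gs <- make_null_geneset(c(A = .3, C = .2, G = .2, T = .3), 100,
                          lengths = function(n) sample(200:1500, n, TRUE),
                          seed = 8)
  comp <- composition(gs)
  for (k in c(2, 5, 8)) {
    pg <- expected_count(comp, "A", k, method = "per_gene")
    ag <- expected_count(comp, "A", k, method = "aggregate")
    expect_lt(abs(pg - ag) / pg, 1e-6)
  }
})

test_that("z_score matches the binomial-approximation arithmetic", {
  expect_equal(z_score(0.3, 0.3, 1.8e6), 0)
  expect_equal(z_score(2, 0.3, 1.8e6), 1.7 / sqrt(0.3 * (1 - 0.3 / 1.8e6)),
               tolerance = 1e-12)
  expect_equal(round(z_score(2, 0.3, 1.8e6), 2), 3.1)
  # strictly increasing in O at fixed E
  zs <- z_score(0:10, 2, 1e5)
  expect_true(all(diff(zs) > 0))
  # binomial and Poisson variance forms agree when q is tiny
  expect_equal(z_score(5, 2, 1e6), z_score(5, 2, variance = "poisson"),
               tolerance = 1e-4)
  expect_error(z_score(1, 0, 1e6), "untestable")
})

test_that("significance cut-offs come from the inverse normal CDF", {
  expect_equal(round(z_critical(), 2), 1.64)
  expect_equal(round(z_critical(two_sided = TRUE), 2), 1.96)
})

test_that("census calls overrepresentation of planted tracts and flags untestable cells", {
  bg <- make_null_geneset(c(A = .25, C = .25, G = .25, T = .25), 500,
                          lengths = 400, seed = 12)
  planted <- plant_hts(bg, base = "A", k = 7, seed = 13)
  cen <- census(planted, k_max = 10)
  a7 <- cen[cen$base == "A" & cen$k == 7, ]
  expect_equal(a7$call, "over")
  expect_gt(a7$Z, 10)

  # high-GC genome: long poly(A) cells have E below the floor -> untestable,
  # so underrepresentation cannot be called there
  hi_gc <- make_null_geneset(c(A = .15, C = .35, G = .35, T = .15), 100,
                             lengths = 500, seed = 14)
  cen_gc <- census(hi_gc, k_max = 10)
  a8 <- cen_gc[cen_gc$base == "A" & cen_gc$k == 8, ]
  expect_lt(a8$E, 0.05)
  expect_equal(a8$call, "untestable")
})

test_that("census is additive over gene sets with identical composition", {
  gs1 <- make_null_geneset(c(A = .25, C = .25, G = .25, T = .25), 50,
                           lengths = 300, seed = 15)
  # second set: per-gene shuffles of the first -> identical composition and lengths
  shuf <- withr::with_seed(16, vapply(gs1$genes$sequence, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1)))
  gs2 <- GeneSet(data.frame(gene_id = paste0("s", seq_along(shuf)),
                            sequence = unname(shuf)))
  both <- GeneSet(data.frame(
    gene_id = c(gs1$genes$gene_id, gs2$genes$gene_id),
    sequence = c(gs1$genes$sequence, gs2$genes$sequence)))
  c1 <- census(gs1, k_max = 8); c2 <- census(gs2, k_max = 8)
  cb <- census(both, k_max = 8)
  expect_equal(cb$O, c1$O + c2$O)
  expect_equal(cb$E, c1$E + c2$E, tolerance = 1e-9)
})

test_that("grouped census localizes planted signal to the labelled group", {
  bg <- make_null_geneset(c(A = .25, C = .25, G = .25, T = .25), 200,
                          lengths = 400, seed = 17)
  genes <- bg$genes
  genes$group_label <- rep(c("regulatory", "other"), each = 100)
  reg <- GeneSet(genes[genes$group_label == "regulatory",
                       c("gene_id", "sequence", "group_label")])
  reg_planted <- plant_hts(reg, base = "A", k = 7, seed = 18)
  merged <- genes
  merged$sequence[merged$group_label == "regulatory"] <-
    reg_planted$genes$sequence
  gs <- GeneSet(merged[, c("gene_id", "sequence", "group_label")])
  gc <- grouped_census(gs, k_max = 8)
  a7 <- gc[gc$base == "A" & gc$k == 7, ]
  expect_equal(a7$call[a7$group_label == "regulatory"], "over")
  expect_true(a7$call[a7$group_label == "other"] != "over")

  # a degenerate one-gene group yields untestable cells without crashing
  tiny <- GeneSet(data.frame(gene_id = c("a", "b"),
                             sequence = c("ACGTACGTAC", strrep("ACGT", 100)),
                             group_label = c("tiny", "big")))
  gt <- grouped_census(tiny, k_max = 8)
  expect_true(all(gt$call[gt$group_label == "tiny" & gt$E < 0.05] == "untestable"))
})

test_that("group Z-score comparison gives exact small-sample Wilcoxon p-values", {
  # shifted toy case: all C(4,2) rank splits enumerable
  res <- compare_group_zscores(c(5, 6, 0, 1), rep(c("bact", "arch"), each = 2),
                               groups = c("bact", "arch"),
                               alternative = "greater")
  expect_equal(res$p.value, 1 / 6)
  # identical distributions: no evidence of shift in either direction
  same <- compare_group_zscores(c(1, 2, 3, 1, 2, 3),
                                rep(c("a", "b"), each = 3),
                                groups = c("a", "b"))
  expect_gt(same$p.value, 0.3)
  expect_error(compare_group_zscores(1:3, c("a", "a", "a"),
                                     groups = c("a", "b")),
               "at least one")
})
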
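test_that("relative location is the exact midpoint over gene length", {
  expect_equal(relative_location(1, 5, 100), 0.03)
  expect_equal(relative_location(1, 7, 7), 4 / 7)
  expect_equal(relative_location(100, 100, 100), 1)  # upper bound attained
  expect_error(relative_location(5, 3, 100), "first")
  expect_error(relative_location(1, 101, 100), "first")
  # half-integer midpoints are kept exact
  expect_equal(relative_location(1, 6, 10), 0.35)
})

test_that("rl stays in (0,1] and histograms conserve record counts", {
  gs <- make_null_geneset(c(A = .3, C = .2, G = .2, T = .3), 50,
                          lengths = 300, seed = 44)
  runs <- run_positions(scan_runs(gs), gs)
  expect_true(all(runs$rl > 0 & runs$rl <= 1))
  h <- position_histogram(runs$rl)
  expect_equal(nrow(h), 20L)
  expect_equal(sum(h$count), nrow(runs))
})

test_that("uniform pseudo-null is seed-reproducible with mean 1/2", {
  a <- uniform_pseudo_null(1e5, seed = 5)
  b <- uniform_pseudo_null(1e5, seed = 5)
  expect_identical(a, b)
  expect_lt(abs(mean(a) - 0.5), 3 * sqrt(1 / 12 / 1e5))
})

test_that("ladder test gives exact small-sample p-values and is one-sided 5'-ward", {
  expect_equal(ladder_test(c(0.1, 0.2), c(0.8, 0.9)), 1 / 6)
  expect_gte(ladder_test(c(.2, .4, .6), c(.2, .4, .6)), 0.5)
})

test_that("ladder test agrees with exhaustive rank enumeration (n <= 10)", {
  withr::with_seed(55, {
    for (i in 1:200) {
      nx <- sample(2:5, 1); ny <- sample(2:5, 1)
      v <- sample(1:1000, nx + ny) / 1000  # tie-free
      x <- v[1:nx]; y <- v[(nx + 1):(nx + ny)]
      expect_equal(ladder_test(x, y), enum_wilcoxon_less(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("enrichment table statistics follow the cross-product and Fisher contracts", {
  # 30/100 observed vs 10/100 expected in the 5' window
  er <- enrichment_table_stats(30, 70, 10, 90)
  expect_equal(er$OR, (30 * 90) / (70 * 10))
  expect_equal(round(er$OR, 3), 3.857)
  expect_lt(er$p, 0.001)
  expect_true(er$ci95[1] > 1)

  # all-or-nothing 3+3 table: one-sided Fisher p is exactly 1/20
  er2 <- enrichment_table_stats(3, 0, 0, 3)
  expect_equal(er2$p, 0.05)
  expect_true(is.finite(er2$OR))  # Haldane correction keeps OR finite
})

test_that("Fisher p agrees with hypergeometric enumeration for tables up to n = 50", {
  withr::with_seed(66, {
    for (i in 1:200) {
      a <- sample(0:15, 1); b <- sample(0:15, 1)
      c_ <- sample(0:10, 1); d <- sample(0:10, 1)
      if (a + b == 0 || c_ + d == 0) next
      er <- enrichment_table_stats(a, b, c_, d)
      expect_equal(er$p, enum_fisher_greater(a, b, c_, d), tolerance = 1e-10)
    }
  })
})

test_that("first-fraction enrichment detects 5'-planted runs and stays null on uniform ones", {
  bg <- make_null_geneset(c(A = 0, C = .5, G = .5, T = 0), 500,
                          lengths = 600, seed = 70)
  five_p <- plant_hts(bg, base = "A", k = 7, position_law = "five_prime_beta",
                      seed = 71)
  rl5 <- run_positions(attr(five_p, "planted"), five_p)$rl
  er <- first_fraction_enrichment(rl5, seed = 72)
  expect_gt(er$OR, 2)
  expect_gt(er$ci95[1], 1)
  expect_lt(er$p, 1e-6)

  unif <- plant_hts(bg, base = "A", k = 7, position_law = "uniform", seed = 73)
  rlu <- run_positions(attr(unif, "planted"), unif)$rl
  eru <- first_fraction_enrichment(rlu, seed = 74)
  expect_true(eru$ci95[1] <= 1 && eru$ci95[2] >= 1)
  expect_equal(eru$obs_in + eru$obs_out, 500L)
})

test_that("codon usage fractions and preference flags", {
  gs <- GeneSet(data.frame(gene_id = "g", sequence = "AAAAAGAAA"))
  cu <- codon_usage(gs, c("AAA", "AAG"))
  expect_equal(cu$usage, 2 / 3)
  expect_true(cu$preferred)

  # zero AAA, five AAG: usage 0 and strong (>70%) preference for AAG
  gs2 <- GeneSet(data.frame(gene_id = "g",
                            sequence = paste(rep("AAG", 5), collapse = "")))
  cu2 <- codon_usage(gs2, c("AAA", "AAG"))
  expect_equal(cu2$usage, 0)
  expect_true(cu2$strong)

  gs3 <- GeneSet(data.frame(gene_id = "g", sequence = "CCCCCC"))
  expect_error(codon_usage(gs3, c("AAA", "AAG")), "absent")
})

test_that("codon position test detects planted 5' vs 3' codon placement", {
  # AAA near the start, AAG near the end of each gene
  withr::with_seed(80, {
    mk <- function() {
      mid <- paste(sample(c("CCG", "GGC", "CGC", "GCG"), 60, TRUE), collapse = "")
      paste0("ATG", "AAA", mid, "AAG", "TGA")
    }
    gs <- GeneSet(data.frame(gene_id = paste0("g", 1:200),
                             sequence = vapply(1:200, function(i) mk(), character(1))))
  })
  expect_lt(codon_position_test(gs, "AAA", "AAG"), 1e-3)
  # codons at identical relative positions carry no signal
  gs_same <- GeneSet(data.frame(gene_id = c("a", "b"),
                                sequence = c("AAACCC", "AAGCCC")))
  expect_gte(codon_position_test(gs_same, "AAA", "AAG"), 0.5)
})

test_that("residue terminal test flags planted C-terminal bias", {
  # all lysines at the last residue: extreme C-terminal signal
  seqs <- vapply(1:60, function(i)
    paste0(paste(rep("GGC", 20), collapse = ""), "AAA"), character(1))
  gs <- GeneSet(data.frame(gene_id = paste0("g", 1:60), sequence = seqs))
  rp <- residue_positions(gs)
  expect_lt(residue_terminal_test(rp, "K", "C", seed = 90), 1e-10)
  # the same data carries no N-terminal signal
  expect_gt(residue_terminal_test(rp, "K", "N", seed = 91), 0.5)
  expect_error(residue_terminal_test(rp, "W", "C"), "no residues")
})

test_that("uniform placements give near-unit odds ratios at large n", {
  rl <- uniform_pseudo_null(1e5, seed = 92)
  er <- first_fraction_enrichment(rl, seed = 93)
  expect_lt(abs(log(er$OR)), 0.1)
})
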
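# Independent oracles used across test files. Each re-derives a quantity by a
# route disjoint from the implementation under test.

# Maximal-run oracle via greedy regex matching: "A+" matches are exactly the
# maximal runs of A, with start and length from the match positions.
regex_runs <- function(sequence, gene_id = "gene") {
  out <- lapply(c("A", "C", "G", "T"), function(b) {
    m <- gregexpr(paste0(b, "+"), sequence)[[1]]
    if (m[1] == -1L) return(NULL)
    k <- attr(m, "match.length")
    data.frame(gene_id = gene_id, base = b, k = as.integer(k),
               start = as.integer(m), end = as.integer(m) + as.integer(k) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

# Lookaround form of the oracle for a single (base, k): counts matches of
# (?<!b)b{k}(?!b).
regex_count_exact <- function(sequence, base, k) {
  pat <- sprintf("(?<!%s)%s{%d}(?!%s)", base, base, k, base)
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# Exhaustive Wilcoxon rank-sum oracle (tie-free inputs): enumerates all
# C(n, nx) assignments of the combined ranks to sample x and returns
# P(rank sum <= observed) for alternative "x stochastically smaller".
enum_wilcoxon_less <- function(x, y) {
  n <- length(x) + length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  obs <- sum(r[seq_along(x)])
  sums <- combn(n, length(x), FUN = sum)
  mean(sums <= obs)
}

# Hypergeometric enumeration oracle for the one-sided ("greater") Fisher
# exact test on a 2x2 table rbind(c(a, b), c(c, d)): conditional on the
# margins, P(top-left cell >= a) by direct combinatorial summation.
enum_fisher_greater <- function(a, b, c, d) {
  m1 <- a + b; n_tot <- a + b + c + d; c1 <- a + c
  lo <- max(0, c1 - (n_tot - m1)); hi <- min(m1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(m1, x) * choose(n_tot - m1, c1 - x), numeric(1))
  sum(probs[(lo:hi) >= a]) / sum(probs)
}

# Monte-Carlo oracle for the expected number of maximal runs of exactly k
# bases `base` in i.i.d. sequences of length L with frequency f.
mc_expected_count <- function(f, L, k, base = "A", n_sim = 2e5, seed = 1) {
  withr::with_seed(seed, {
    probs <- c(f, rep((1 - f) / 3, 3))
    mat <- matrix(sample(c(base, setdiff(c("A", "C", "G", "T"), base)),
                         n_sim * L, replace = TRUE, prob = probs),
                  nrow = n_sim)
    is_b <- mat == base
    # window logic, not run-length encoding: a maximal run of exact length k
    # starts at j iff positions j..j+k-1 match and both flanks (when inside
    # the sequence) do not
    total <- 0
    for (j in seq_len(L - k + 1)) {
      v <- is_b[, j]
      for (l in seq_len(k - 1)) v <- v & is_b[, j + l]
      if (j > 1) v <- v & !is_b[, j - 1]
      if (j + k <= L) v <- v & !is_b[, j + k]
      total <- total + sum(v)
    }
    total / n_sim
  })
}

# Small deterministic gene sets used by several files.
toy_geneset <- function() {
  GeneSet(data.frame(
    gene_id = c("g1", "g2", "g3"),
    sequence = c("ATGAAAAAACGTACGTACGTTGA", "ATGCCCGGGTTTAAATAA", "ATGANNTGGTAA"),
    group_label = c("regulatory functions", "regulatory functions", NA)),
    genome_id = "toy")
}

random_sequence <- function(L, with_n = FALSE) {
  alpha <- c("A", "C", "G", "T", if (with_n) "N")
  prob <- if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alpha, L, replace = TRUE, prob = prob), collapse = "")
}
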
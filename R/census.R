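#' Nucleotide composition of a gene set
#'
#' Frequencies are computed over A/C/G/T positions only: `N` bases count
#' toward total length `N` but are excluded from the frequency denominator,
#' so `sum(f) == 1` whenever at least one unambiguous base is present.
#'
#' @param gs a [GeneSet].
#' @return A `GenomeComposition`: list with `f` (named frequencies for
#'   A, C, G, T), `gc` (G+C fraction), `N` (total nt including N bases),
#'   `n` (gene count) and `lengths` (per-gene nt lengths, used for exact
#'   boundary terms in [expected_count]).
#' @export
composition <- function(gs) {
  validate_geneset(gs)
  all <- paste(gs$genes$sequence, collapse = "")
  cnt <- vapply(c("A", "C", "G", "T"), function(b)
    nchar(all) - nchar(gsub(b, "", all, fixed = TRUE)), numeric(1))
  denom <- sum(cnt)
  if (denom == 0) stop("no unambiguous bases in gene set")
  genome_composition(f = cnt / denom, N = gs$N, n = gs$n,
                     lengths = gs$genes$length)
}

#' Construct a GenomeComposition directly
#'
#' Used when only aggregate quantities are known (e.g. reproducing a
#' published figure from its stated GC content and total coding length).
#'
#' @param f named numeric vector of frequencies for `A`, `C`, `G`, `T`;
#'   must sum to 1 within 1e-9.
#' @param N total coding length in nt.
#' @param n number of coding genes.
#' @param lengths optional per-gene lengths; when absent, [expected_count]
#'   falls back to the aggregate closed form in `N` and `n`.
#' @return A `GenomeComposition`.
#' @export
genome_composition <- function(f, N, n, lengths = NULL) {
  f <- f[c("A", "C", "G", "T")]
  if (any(is.na(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("frequencies must be named A/C/G/T, non-negative, and sum to 1")
  stopifnot(N >= n, n >= 1)
  structure(list(f = f, gc = unname(f["G"] + f["C"]), N = N, n = n,
                 lengths = lengths),
            class = "GenomeComposition")
}

#' Composition for a given GC content with A/T and G/C split equally
#'
#' @param gc G+C fraction in `[0,1]`.
#' @inheritParams genome_composition
#' @return A `GenomeComposition` with `f_G = f_C = gc/2`,
#'   `f_A = f_T = (1-gc)/2`.
#' @export
composition_from_gc <- function(gc, N, n, lengths = NULL) {
  stopifnot(gc >= 0, gc <= 1)
  genome_composition(c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2),
                     N = N, n = n, lengths = lengths)
}

#' @export
print.GenomeComposition <- function(x, ...) {
  cat("GenomeComposition: N =", x$N, "nt, n =", x$n, "genes, GC =",
      round(100 * x$gc, 1), "%\n")
  print(round(x$f, 4))
  invisible(x)
}

#' Expected number of maximal runs under the composition null
#'
#' Under the null model, each position carries base `i` independently with
#' probability `f_i`. The expected number of maximal runs of exactly `k`
#' bases `i` in a gene of length `L` is
#' `(L - k - 1) * f^k * (1-f)^2 + 2 * f^k * (1-f)` for `L >= k+1`
#' (interior runs need two non-matching flanks; runs touching either gene
#' boundary need one), `f^k` for `L == k`, and 0 for `L < k`. Summing over
#' genes gives the aggregate closed form
#' `E = (N - n*(k+1)) * f^k * (1-f)^2 + 2*n * f^k * (1-f)`,
#' which is used when per-gene lengths are unavailable.
#'
#' @param comp a `GenomeComposition`.
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param k exact run length, `k >= 1`.
#' @param method `"per_gene"` (exact boundary terms, requires `lengths`) or
#'   `"aggregate"`; default uses per-gene lengths when available. The two
#'   differ only through genes shorter than `k+1`, negligible at genome
#'   scale.
#' @return Expected count `E` (numeric scalar).
#' @examples
#' comp <- composition_from_gc(0.70, N = 1.8e6, n = 2000)
#' expected_count(comp, "A", 8)  # ~0.33, the "close to 0.3" regime
#' @export
expected_count <- function(comp, base, k,
                           method = c("auto", "per_gene", "aggregate")) {
  stopifnot(inherits(comp, "GenomeComposition"), base %in% names(comp$f), k >= 1)
  method <- match.arg(method)
  f <- unname(comp$f[base])
  if (f >= 1) warning("f = 1 is degenerate: every gene is one long run")
  if (f == 0) return(0)
  if (method == "auto")
    method <- if (is.null(comp$lengths)) "aggregate" else "per_gene"
  if (method == "per_gene") {
    if (is.null(comp$lengths)) stop("per-gene method needs gene lengths")
    L <- comp$lengths
    interior <- sum(pmax(L - k - 1, 0)) * f^k * (1 - f)^2
    boundary <- 2 * sum(L >= k + 1) * f^k * (1 - f)
    whole <- sum(L == k) * f^k
    interior + boundary + whole
  } else {
    (comp$N - comp$n * (k + 1)) * f^k * (1 - f)^2 + 2 * comp$n * f^k * (1 - f)
  }
}

#' Z-score for over/under-representation of a run count
#'
#' The observed count `O` is compared to its expectation `E` under a binomial
#' null with `M = N` trial sites and per-site maximal-run probability
#' `q = E/N`: `Z = (O - E) / sqrt(N*q*(1-q))`. Since `q` is tiny in practice
#' this is numerically close to the Poisson form `(O - E)/sqrt(E)`, which is
#' exposed as an option.
#'
#' @param O observed count.
#' @param E expected count (must be > 0).
#' @param N total coding length (trial sites); required for
#'   `variance = "binomial"`.
#' @param variance `"binomial"` (default) or `"poisson"`.
#' @return Z (numeric); positive means overrepresented.
#' @export
z_score <- function(O, E, N = NULL, variance = c("binomial", "poisson")) {
  variance <- match.arg(variance)
  if (any(E <= 0)) stop("Z-score undefined for E <= 0 (untestable cell)")
  if (variance == "binomial") {
    if (is.null(N)) stop("N required for binomial variance")
    q <- E / N
    (O - E) / sqrt(N * q * (1 - q))
  } else {
    (O - E) / sqrt(E)
  }
}

#' Census of homopolymeric tracts against the composition null
#'
#' For each base and run length `k` in `[k_min, k_max]`, counts observed
#' maximal runs, computes the expected count under the composition-based
#' binomial null and the Z-score, and classifies the cell:
#' * `over`: `Z > z_over` (one-sided 5% critical value 1.64 by default);
#' * `under`: `Z < -z_over` and `E` at or above the untestable floor;
#' * `untestable`: `E < e_floor` — with a tiny expectation even `O = 0`
#'   cannot attain significance, so underrepresentation is undetectable
#'   (e.g. long poly(A) tracts in a high-GC genome);
#' * `ns`: otherwise.
#' The column `sig_two_sided` additionally marks `|Z| > z_two` (the 1.96
#' display cut-off used alongside one-sided calls).
#'
#' @param gs a [GeneSet].
#' @param k_min,k_max run-length range (defaults 1 and 20).
#' @param bases which bases to census.
#' @param z_over one-sided critical Z for over/under calls (default
#'   [z_critical()] = 1.64).
#' @param z_two two-sided display cut-off (default 1.96).
#' @param e_floor untestable floor on `E` (default 0.05).
#' @param variance variance form passed to [z_score].
#' @param p_adjust optional method for [stats::p.adjust] applied to the
#'   one-sided p-values across cells (`NULL`, the default, matches the
#'   uncorrected analysis).
#' @return data.frame with one row per (base, k): `genome_id`, `base`, `k`,
#'   `f`, `gc`, `N`, `n`, `O`, `E`, `Z`, `p`, `call`, `sig_two_sided`.
#' @export
census <- function(gs, k_min = 1L, k_max = 20L, bases = c("A", "C", "G", "T"),
                   z_over = z_critical(), z_two = z_critical(two_sided = TRUE),
                   e_floor = 0.05, variance = c("binomial", "poisson"),
                   p_adjust = NULL) {
  validate_geneset(gs)
  variance <- match.arg(variance)
  comp <- composition(gs)
  m <- run_count_matrix(gs, k_cap = max(60L, k_max + 1L))
  ks <- seq.int(k_min, k_max)
  grid <- expand.grid(base = bases, k = ks, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$base, bases), grid$k), ]
  O <- mapply(function(b, k) m[b, as.character(k)], grid$base, grid$k)
  E <- mapply(function(b, k) expected_count(comp, b, k), grid$base, grid$k)
  Z <- ifelse(E > 0, z_score(O, pmax(E, .Machine$double.xmin), comp$N,
                             variance = variance), NA_real_)
  Z[E <= 0] <- NA_real_
  p <- stats::pnorm(Z, lower.tail = FALSE)
  if (!is.null(p_adjust)) p <- stats::p.adjust(p, method = p_adjust)
  call <- ifelse(E < e_floor, "untestable",
                 ifelse(Z > z_over, "over",
                        ifelse(Z < -z_over, "under", "ns")))
  data.frame(genome_id = gs$genome_id, base = grid$base, k = grid$k,
             f = unname(comp$f[grid$base]), gc = comp$gc,
             N = comp$N, n = comp$n,
             O = as.integer(O), E = E, Z = Z, p = p, call = call,
             sig_two_sided = !is.na(Z) & abs(Z) > z_two,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Census stratified by gene group label
#'
#' Runs [census] within each group of labelled genes (composition, observed
#' and expected counts and Z-scores are all computed inside the subset), the
#' analysis used for functional role categories. Genes without a label are
#' skipped.
#'
#' @inheritParams census
#' @return data.frame as [census] with a leading `group_label` column.
#' @export
grouped_census <- function(gs, k_min = 1L, k_max = 20L,
                           bases = c("A", "C", "G", "T"), ...) {
  validate_geneset(gs)
  g <- gs$genes[!is.na(gs$genes$group_label), ]
  if (nrow(g) == 0L) stop("no labelled genes in gene set")
  out <- lapply(split(g, g$group_label), function(sub) {
    sgs <- GeneSet(sub[, c("gene_id", "sequence", "group_label")],
                   genome_id = gs$genome_id)
    cbind(group_label = sub$group_label[1],
          census(sgs, k_min = k_min, k_max = k_max, bases = bases, ...),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Compare per-genome Z-scores between two groups of genomes
#'
#' One-sided Wilcoxon rank-sum test on per-genome Z-scores for a fixed
#' (base, k) cell, e.g. bacterial vs archaeal genomes, or mammalian-pathogen
#' vs other genomes.
#'
#' @param z numeric vector of per-genome Z-scores.
#' @param group vector (same length) of group labels.
#' @param groups length-2 character: the two groups compared, in order.
#' @param alternative `"greater"` tests that `groups[1]` has larger Z
#'   (stronger overrepresentation) than `groups[2]`; `"less"` the reverse.
#' @return list with `p.value`, `statistic` and the group sizes.
#' @export
compare_group_zscores <- function(z, group, groups = unique(group),
                                  alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(z) == length(group), length(groups) == 2L)
  x <- z[group == groups[1]]
  y <- z[group == groups[2]]
  if (!length(x) || !length(y)) stop("both groups need at least one genome")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       n = c(length(x), length(y)), groups = groups,
       alternative = alternative)
}

#' Critical Z value for significance calls
#'
#' @param alpha significance level (default 0.05).
#' @param two_sided if `TRUE`, the two-sided cut-off (`1.96` at 5%);
#'   otherwise the one-sided cut-off (`1.64`) used for over/under calls.
#' @return numeric critical value from the inverse normal CDF.
#' @export
z_critical <- function(alpha = 0.05, two_sided = FALSE) {
  stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
}
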
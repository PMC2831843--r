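#' Relative location of a feature within its gene or protein
#'
#' Defined as the feature midpoint divided by the host length:
#' `rl = ((first + last)/2) / L`, computed exactly (the midpoint may be a
#' half-integer) and always in `(0, 1]`. Values near 0 indicate placement at
#' the 5' end (or N-terminus).
#'
#' @param first,last 1-based inclusive start and end positions,
#'   `1 <= first <= last <= L`.
#' @param L gene length in nt (or protein length in residues). All three
#'   arguments are vectorized.
#' @return numeric vector of relative locations.
#' @examples
#' relative_location(1, 5, 100)  # 0.03
#' @export
relative_location <- function(first, last, L) {
  if (any(first < 1 | last < first | last > L))
    stop("need 1 <= first <= last <= L")
  ((first + last) / 2) / L
}

#' Relative locations for a run table
#'
#' Joins a run table from [scan_runs] to gene lengths and computes each
#' run's relative location.
#'
#' @param runs data.frame with `gene_id`, `start`, `end` (from [scan_runs]).
#' @param gs the [GeneSet] the runs came from.
#' @return `runs` with added columns `L` and `rl`.
#' @export
run_positions <- function(runs, gs) {
  validate_geneset(gs)
  idx <- match(runs$gene_id, gs$genes$gene_id)
  if (anyNA(idx)) stop("run table refers to gene ids absent from the gene set")
  runs$L <- gs$genes$length[idx]
  runs$rl <- relative_location(runs$start, runs$end, runs$L)
  runs
}

#' Uniform pseudo relative locations
#'
#' Draws the uniform null dataset that observed relative locations are
#' compared against; by construction it is given the same size as the
#' observed dataset.
#'
#' @param n number of draws.
#' @param seed optional integer seed (reproducible draws).
#' @return numeric vector of `n` i.i.d. Uniform(0,1) values.
#' @export
uniform_pseudo_null <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, stats::runif(n))
}

#' One-sided Wilcoxon ladder test for 5' positional bias
#'
#' Tests whether tracts of length `k` sit closer to the 5' end than tracts
#' one base shorter: alternative "`rl_k` stochastically smaller than
#' `rl_km1`". Exact enumeration is used when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' mid-ranks, tie-corrected variance and continuity correction.
#'
#' @param rl_k relative locations of the longer tracts.
#' @param rl_km1 relative locations of the one-base-shorter tracts (or any
#'   reference set, e.g. a uniform pseudo-null).
#' @return one-sided p-value.
#' @export
ladder_test <- function(rl_k, rl_km1) {
  if (!length(rl_k) || !length(rl_km1)) stop("both samples must be non-empty")
  n <- length(rl_k) + length(rl_km1)
  ties <- anyDuplicated(c(rl_k, rl_km1)) > 0
  wt <- suppressWarnings(stats::wilcox.test(rl_k, rl_km1, alternative = "less",
                                            exact = n <= 20 && !ties,
                                            correct = TRUE))
  wt$p.value
}

#' First-fraction (5' 10%) enrichment against a uniform pseudo-null
#'
#' Counts observed relative locations in the first `threshold` fraction of
#' genes, draws an equal-size uniform pseudo-null, and compares the two in a
#' 2x2 table. The odds ratio is the cross-product
#' `OR = (obs_in * exp_out) / (obs_out * exp_in)`; an OR of 2.3 means the
#' feature is 2.3-fold more likely to occur in the first 10% of a coding
#' gene than expected under uniform placement. The 95% CI uses the log-OR
#' normal approximation (Haldane-Anscombe 0.5 correction when a cell is
#' zero); the p-value is a one-sided Fisher exact test on the uncorrected
#' table.
#'
#' @param rl observed relative locations in `(0, 1]`.
#' @param threshold fraction of the gene defining the 5' window (default
#'   0.10).
#' @param seed optional seed for the pseudo-null.
#' @param B number of pseudo-null draws; with `B > 1` the expected cells are
#'   the rounded mean over draws (the default single draw mirrors the
#'   one-draw design of the original analysis).
#' @return object of class `EnrichmentResult`: list with `threshold`,
#'   `obs_in`, `obs_out`, `exp_in`, `exp_out`, `OR`, `ci95`, `p`, `n`.
#' @export
first_fraction_enrichment <- function(rl, threshold = 0.10, seed = NULL, B = 1L) {
  if (!length(rl)) stop("no observed relative locations")
  stopifnot(threshold > 0, threshold < 1, B >= 1)
  n <- length(rl)
  obs_in <- sum(rl <= threshold)
  exp_in_draws <- with_seed(seed,
    vapply(seq_len(B), function(b) sum(stats::runif(n) <= threshold), numeric(1)))
  exp_in <- as.integer(round(mean(exp_in_draws)))
  enrichment_table_stats(obs_in, n - obs_in, exp_in, n - exp_in,
                         threshold = threshold)
}

#' Enrichment statistics from an explicit 2x2 table
#'
#' The table compares observed counts inside/outside the 5' window against
#' pseudo-null counts. Odds ratio is the cross-product
#' `(obs_in * exp_out) / (obs_out * exp_in)` with a Haldane-Anscombe 0.5
#' correction applied to all cells when any cell is zero (for the OR and CI
#' only); the one-sided Fisher exact p-value uses the uncorrected counts.
#'
#' @param obs_in,obs_out observed counts inside/outside the window.
#' @param exp_in,exp_out pseudo-null counts inside/outside the window.
#' @param threshold window fraction recorded in the result.
#' @return An `EnrichmentResult` (see [first_fraction_enrichment]).
#' @export
enrichment_table_stats <- function(obs_in, obs_out, exp_in, exp_out,
                                   threshold = 0.10) {
  stopifnot(obs_in >= 0, obs_out >= 0, exp_in >= 0, exp_out >= 0)
  tab <- matrix(c(obs_in, obs_out, exp_in, exp_out), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  hald <- if (any(tab == 0)) 0.5 else 0
  a <- obs_in + hald; b <- obs_out + hald; c_ <- exp_in + hald; d <- exp_out + hald
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(threshold = threshold, obs_in = obs_in, obs_out = obs_out,
                 exp_in = exp_in, exp_out = exp_out, OR = or, ci95 = ci,
                 p = p, n = obs_in + obs_out),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("First %.0f%% enrichment: %d/%d observed vs %d/%d expected\n",
              100 * x$threshold, x$obs_in, x$n, x$exp_in, x$n))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), one-sided Fisher p = %.3g\n",
              x$OR, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Synonymous codon usage for a two-codon pair
#'
#' Fraction of in-frame occurrences of `pair[1]` among occurrences of the
#' pair, e.g. AAA vs AAG for lysine. A codon is "preferred" at usage > 50%;
#' the stricter > 70% flag marks strong preference.
#'
#' @param gs a [GeneSet].
#' @param pair character vector of two synonymous codons.
#' @return list with `usage` (fraction of `pair[1]`), `counts` (named), and
#'   logical flags `preferred` (`usage > 0.5`) and `strong` (either codon
#'   above 70%).
#' @export
codon_usage <- function(gs, pair = c("AAA", "AAG")) {
  stopifnot(length(pair) == 2L, all(nchar(pair) == 3L))
  hits <- scan_codons(gs, pair)
  counts <- c(sum(hits$codon == pair[1]), sum(hits$codon == pair[2]))
  names(counts) <- pair
  if (sum(counts) == 0L) stop("codon pair absent from gene set")
  usage <- counts[[1]] / sum(counts)
  list(usage = usage, counts = counts,
       preferred = usage > 0.5,
       strong = max(usage, 1 - usage) > 0.7)
}

#' Positional comparison of two codons
#'
#' Tests whether in-frame occurrences of `codon_a` sit closer to the 5' end
#' of coding genes than those of `codon_b` (e.g. AAA vs AAG). Relative
#' locations use the codon's nt span with the same midpoint convention as
#' tracts; records are pooled across genes.
#'
#' @param gs a [GeneSet].
#' @param codon_a,codon_b 3-mers to compare.
#' @return one-sided Wilcoxon p-value for "`codon_a` closer to 5'".
#' @export
codon_position_test <- function(gs, codon_a, codon_b) {
  hits <- scan_codons(gs, c(codon_a, codon_b))
  rl_a <- with(hits[hits$codon == codon_a, ],
               relative_location(start_nt, start_nt + 2L, L))
  rl_b <- with(hits[hits$codon == codon_b, ],
               relative_location(start_nt, start_nt + 2L, L))
  if (!length(rl_a) || !length(rl_b)) stop("both codons must occur in the gene set")
  ladder_test(rl_a, rl_b)
}

#' Terminal-bias test for an amino acid
#'
#' Compares the relative locations (`residue_index / protein_length`) of one
#' amino acid, pooled over genes, against an equal-size uniform pseudo-null.
#' Direction `"C"` tests for C-terminal bias (observed locations
#' stochastically larger than uniform), `"N"` for N-terminal bias.
#'
#' @param residues data.frame from [residue_positions].
#' @param amino_acid 1-letter code.
#' @param direction `"C"` or `"N"`.
#' @param seed optional seed for the pseudo-null.
#' @return one-sided Wilcoxon p-value.
#' @export
residue_terminal_test <- function(residues, amino_acid, direction = c("C", "N"),
                                  seed = NULL) {
  direction <- match.arg(direction)
  sub <- residues[residues$amino_acid == amino_acid, ]
  if (!nrow(sub)) stop("no residues of type ", amino_acid)
  rl <- sub$residue_index / sub$protein_length
  null <- uniform_pseudo_null(length(rl), seed = seed)
  if (direction == "C") ladder_test(null, rl) else ladder_test(rl, null)
}

#' Positional histogram in 20 windows of 5% gene length
#'
#' @param rl relative locations in `(0, 1]`.
#' @param bins number of equal windows (default 20).
#' @return data.frame with `bin` (1-based), `lower`, `upper`, `count` and
#'   `freq`; counts sum to `length(rl)`.
#' @export
position_histogram <- function(rl, bins = 20L) {
  stopifnot(bins >= 1, all(rl > 0 & rl <= 1))
  idx <- pmin(ceiling(rl * bins), bins)
  counts <- tabulate(idx, nbins = bins)
  data.frame(bin = seq_len(bins),
             lower = (seq_len(bins) - 1) / bins,
             upper = seq_len(bins) / bins,
             count = counts,
             freq = counts / max(1L, length(rl)))
}
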
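---
title: "Methods: homopolymeric tract census, positional bias and reversion frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homopolymeric tract census, positional bias and reversion frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htract)
```

## Why homopolymeric tracts

A homopolymeric tract (HT) is a maximal run of one nucleotide — `AAAAAA`
flanked by non-A bases or a gene boundary. Tracts inside coding genes are
hotspots for slipped-strand mispairing during replication: single-base
insertions or deletions arise orders of magnitude more often there than
point mutations do elsewhere, and an indel in a coding tract usually shifts
the reading frame. A tract near the 5' end of a gene therefore acts as a
reversible ON/OFF switch for the whole protein — the mutational engine of
phase variation in many bacteria (the *Listeria monocytogenes* virulence
gene *inlA*, with its 5' poly(A) tract, is the classic model locus).

This package implements the three quantitative questions that follow from
that biology, for any set of coding sequences supplied as FASTA:

1. **Census** — are tracts of a given base and length more or less frequent
   than nucleotide composition alone predicts?
2. **Position** — do tracts (and the codons/amino acids that could mimic
   them) sit closer to the 5' end of genes than uniform placement predicts?
3. **Rate** — how often do frameshifts in a tract revert, as measured by a
   selective plating assay?

Because the original genome-scale analyses depend on downloading and
curating on the order of a hundred genomes, the package also ships
first-class synthetic generators that emulate the relevant data-generating
processes, so each statistical stage can be validated against known truth.

## The run-expectation model

### Scanner conventions

`find_runs()` reports every maximal run with its exact length `k` and
1-based inclusive coordinates. Three conventions matter and are shared by
the expectation model:

* a run of 8 A's is one A~8~, never also an A~7~ (no sub-run counting);
* a run touching position 1 or position `L` needs only one non-matching
  flank to be maximal;
* `N` bases break runs, are never reported as runs, and are excluded from
  composition denominators (they still count toward total length). Rationale:
  finished genomes contain almost no `N`s, and an `N` must never be allowed
  to extend or join runs.

### Expected counts

Under the null model, positions are i.i.d. with base frequencies
$f_A, f_C, f_G, f_T$ estimated from the coding genes themselves. For a gene
of length $L$, the expected number of maximal runs of exactly $k$ bases $i$
is

$$E_{\text{gene}} = (L-k-1)\,f_i^k(1-f_i)^2 + 2\,f_i^k(1-f_i), \qquad L \ge k+1,$$

with the two terms covering interior runs (two non-matching flanks) and
boundary-touching runs (one flank). A gene with $L = k$ contributes
$f_i^k$; shorter genes contribute nothing. Summing over a genome with $n$
genes and $\sum L = N$ gives the aggregate closed form

$$E = (N - n(k+1))\,f_i^k(1-f_i)^2 + 2n\,f_i^k(1-f_i).$$

`expected_count()` uses the per-gene sum whenever gene lengths are
available and the closed form otherwise; at genome scale the two differ
only through genes shorter than $k+1$ and agree to a relative $10^{-6}$ in
our tests. The model was validated two ways: an independent Monte-Carlo
oracle (window logic over simulated sequences, no run-length encoding)
reproduces the exact per-gene value $E = 0.076171875$ for
$L=10, f=0.25, k=3$, and the canonical genome-scale check value — a 70% GC
genome with 1.8 Mb of coding sequence has an expected poly(A)~8~ count of

```{r}
comp <- composition_from_gc(0.70, N = 1.8e6, n = 2000)
expected_count(comp, "A", 8)
```

i.e. "close to 0.3": with fewer than one expected tract, *under*representation
of such cells is statistically invisible, which is why the census flags cells
with `E < 0.05` as `untestable` rather than calling them.

### Z-scores and calls

Significance uses the normal approximation to the binomial with $M = N$
trial sites and per-site probability $q = E/N$:

$$Z = \frac{O - E}{\sqrt{N q (1-q)}}.$$

Since $q \ll 1$, this is numerically the Poisson form $(O-E)/\sqrt{E}$
(both are implemented; binomial is the default). Calls use the one-sided 5%
critical value $Z > 1.64$ for overrepresentation and $Z < -1.64$ for
underrepresentation, with $|Z| > 1.96$ reported as the two-sided display
cut-off; both come from `qnorm` via `z_critical()`. No multiple-testing
correction is applied across the base × length grid by default, matching
standard practice for this census (a Benjamini–Hochberg option exists via
`p_adjust`).

A statistical subtlety, documented here because it shapes the calibration
results: for short runs the binomial variance overstates the true variance
of maximal-run counts (two same-base runs cannot sit closer than $k+2$
positions, inducing negative local covariance of order $(2k+3)q$). The Z
statistic is therefore *conservative* for small $k$ — on simulated null
genomes the per-cell over-call rate at $Z > 1.64$ is about 3.5% rather than
5%, and cell counts never stray anywhere near the nominal 3-SD envelope.
We keep the binomial form because it is the field's convention for this
census and errs on the cautious side.

## Positional statistics

The relative location of any feature is its midpoint over the host length,

$$rl = \frac{(first + last)/2}{L} \in (0, 1],$$

computed without rounding (midpoints may be half-integers). Codons use
their nt span within the gene — not the codon index — so one convention
serves tracts, codons and (with `residue_index/protein_length`) amino
acids; the difference is a $1/L$-order effect.

Three tests probe 5' bias:

* **Ladder test** (`ladder_test`): one-sided Wilcoxon rank-sum comparing
  $rl$ of length-$k$ tracts against length-$(k-1)$ tracts — the "do longer
  tracts sit closer to the 5' end?" question. Exact enumeration is used for
  combined $n \le 20$ without ties; otherwise the normal approximation with
  mid-ranks, tie-corrected variance and continuity correction (rl values
  tie heavily for short genes, hence the correction).
* **First-10% enrichment** (`first_fraction_enrichment`): observed $rl$
  values are compared against an equal-size uniform pseudo-null in a 2×2
  table. The odds ratio is the plain cross-product — an OR of 2.3 means the
  tract is 2.3-fold more likely to fall in the first 10% of its gene than
  uniform placement predicts — with a log-OR normal 95% CI
  (Haldane–Anscombe 0.5 correction when a cell is zero) and a one-sided
  Fisher exact p on the uncorrected counts. The pseudo-null is one `runif`
  draw by default (the original design); a `B > 1` resampling mode averages
  the expected cells over draws for stability.
* **Terminal tests** (`residue_terminal_test`, `codon_position_test`):
  pooled residue or codon positions against a uniform pseudo-null or
  against a synonymous codon (AAA vs AAG, TTT vs TTC — the control for
  whether tract placement merely reflects lysine/phenylalanine placement or
  codon usage).

All pooled tests weight records, not genomes, since cross-genome analyses
pool the raw records.

## Reversion frequencies from plating counts

The plating estimator mirrors the translational-fusion assay: grow a
culture, plate a diluted aliquot non-selectively for total counts, plate
another selectively for revertants, and confirm a sample of colonies by
sequencing. With `CFU` the mean non-selective colony count, `VP` the plated
volume (ml) and `DF` the dilution factor,

$$OCD = \frac{CFU \cdot DF}{VP}, \qquad
  RD = \frac{TC \cdot (R/CS) \cdot DF}{VP}, \qquad
  FR = \frac{RD}{OCD},$$

where `TC` counts *large* colonies only (the > 8 px / < 9 px pixel
classifier separates true revertants from slow-growing background), `CS` of
them are sequenced and `R` confirm. Replicates are summarized by the
arithmetic mean of per-replicate frequencies (median also reported). When
no replicate yields a confirmed revertant, `detection_limit()` reports the
frequency a single revertant would have implied:
$1 / \sum_\text{reps} OCD \cdot VP / DF_{sel}$ cells screened.
`fold_vs_reference()` compares an estimated frequency against a reference
(e.g. an average point-mutation frequency of $4.5 \times 10^{-10}$;
$5.5\times10^{-7} / 4.5\times10^{-10} \approx 1222$, i.e. about 1,000-fold
at one significant figure).

## What the synthetic generators emulate — and what they do not

`make_null_geneset()` draws i.i.d. bases at a chosen composition: exactly
the null hypothesis of the census, nothing more. Real coding sequences have
codon structure, ORF grammar, and GC gradients; none of that is simulated,
so a passing calibration says the *statistics* are correct under their own
null, not that real genomes are i.i.d.

`plant_hts()` overwrites `k` bases with a run whose midpoint follows either
a uniform law or a Beta($\alpha$, $\beta$) law — Beta(1, 9) (mean 0.1) is
the default 5'-skewed choice, selected to resemble the strong observed 5'
clustering while remaining a one-parameter-family stand-in. Flanking bases
are forced to a different nucleotide so every planted run is maximal and
recoverable at its exact coordinates; gene length is preserved. Planting
positions use the run midpoint precisely because that is the statistic
under test downstream.

`simulate_plating()` models a *frequency* (per-cell proportion of
revertants), not a Luria–Delbrück per-generation rate: revertant cells are
Poisson($\varphi \cdot$ culture size), plated subsamples are binomial in
the plated fraction, colony sizes come from a two-component law (small
$\le 8$ px, large $\ge 9$ px) with Poisson background contamination in both
components, and sequencing confirmation draws hypergeometrically from the
large colonies. Defaults — $2.5\times10^{10}$ cells in 5 ml, `DF_total`
$10^6$, `DF_sel` 10, `VP` 0.1 ml, triplicates, 10 colonies sequenced when
more than 20 are present — reproduce the order of magnitude of the real
assay (a few hundred total-count colonies, tens of selective colonies at
$\varphi = 5\times10^{-7}$). Jackpot (fluctuation) effects are deliberately
absent; the estimator being validated is itself a frequency estimator.

All generators take a single integer seed and are bit-reproducible;
seed-dependent steps inside analyses (pseudo-nulls) accept their own seed
and record it in pipeline report headers together with a config hash.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout.
* Exact rational midpoint before division in `rl`; no rounding.
* `GeneSet` validation is strict by default (ambiguity codes other than `N`
  are errors); a lenient mode maps them to `N`. How the original gene files
  handled ambiguity codes is unknowable from the outside, so both modes are
  explicit.
* The untestable floor `E < 0.05` prevents "under" calls that no data could
  support; it is configurable.
* Ties in Wilcoxon tests: mid-ranks with tie-corrected variance (exact
  enumeration is only used in tie-free small samples).
* `fisher.test` p-values are computed on integer tables; with `B > 1`
  pseudo-null resampling, expected cells are rounded means.
* Degenerate inputs fail loudly: empty gene sets, `f_i = 1` compositions
  (warned as degenerate), genes too short to host a planted run, `TC > 0`
  with `CS = 0`, detection limits in the presence of revertants.

## Problem sizes used in the validation suite

The package's own test suite validates each stage at sizes chosen to give
the relevant cells useful expectations while staying desk-scale: scanner
equivalence against a greedy-regex oracle on 10,000 random sequences;
Wilcoxon agreement with exhaustive rank enumeration for every configuration
with combined $n \le 10$; Fisher agreement with hypergeometric enumeration
for all 2×2 tables with total $\le 16$ plus random tables to total 50; null
calibration over 2,000 simulated genomes of 50 × 1,200 nt at GC 50% (cells
up to $k = 5$ reach $E \ge 20$); positional-bias recovery with 500 planted
genes per set and CI calibration over 50 seeds; and reversion-estimator
recovery at $\varphi \in \{10^{-8}, 5\times10^{-7}, 10^{-5}\}$ over 100
simulated triplicate experiments each.

## Known limitations

* Only mononucleotide repeats are modelled; SSRs of period ≥ 2 need a
  different expectation model.
* The census null conditions only on mononucleotide composition; GC-skew
  gradients or codon bias within genes are not corrected for.
* Sequences are scanned as given (coding strand, 5'→3'); no
  reverse-complement scanning.
* Cross-genome comparisons treat pooled records as independent;
  phylogenetic non-independence of genomes is outside scope.
* The reversion module estimates frequencies, not mutation rates; if rates
  are needed, a fluctuation-analysis package should be used on the raw
  counts instead.
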
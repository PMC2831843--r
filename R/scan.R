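#' Find maximal mononucleotide runs in one sequence
#'
#' A homopolymeric tract (HT) of exact length `k` is a run of a single
#' nucleotide flanked on both sides by a different base or by a sequence
#' boundary. Runs are maximal and do not overlap: a run of 8 A's is reported
#' once as an A_8, never additionally as A_7 or shorter sub-runs. `N` bases
#' never form or extend a run; they break runs like any non-matching base,
#' and no run is reported for N itself.
#'
#' Runs touching position 1 or the last position of the gene need only one
#' non-matching flank and count as maximal; the composition-null expectation
#' model ([expected_count]) uses the same boundary convention.
#'
#' @param sequence character scalar over `{A,C,G,T,N}` (a gene's coding
#'   sequence, 5' to 3').
#' @param gene_id id recorded with each run.
#' @param k_min smallest run length to report (default 1).
#' @param k_max retained for interface symmetry with the census range; runs
#'   longer than `k_max` are still reported with their true length so that
#'   run lengths partition the non-N positions of the gene.
#' @return data.frame with columns `gene_id`, `base`, `k`, `start`, `end`
#'   (1-based inclusive nt coordinates), ordered by `start`.
#' @examples
#' find_runs("AAACGTTTTTTT")  # A_3, C_1, G_1, T_7
#' @export
find_runs <- function(sequence, gene_id = "gene", k_min = 1L, k_max = 20L) {
  stopifnot(length(sequence) == 1L, k_min >= 1L, k_max >= k_min)
  if (is.na(sequence) || !nzchar(sequence)) stop("empty sequence")
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  k <- r$lengths
  end <- cumsum(k)
  start <- end - k + 1L
  keep <- r$values != "N" & k >= k_min
  data.frame(gene_id = gene_id,
             base = r$values[keep],
             k = as.integer(k[keep]),
             start = as.integer(start[keep]),
             end = as.integer(end[keep]),
             stringsAsFactors = FALSE)
}

#' Scan all genes of a GeneSet for maximal runs
#'
#' @param gs a [GeneSet].
#' @inheritParams find_runs
#' @return data.frame as in [find_runs] with a leading `genome_id` column,
#'   genes in set order.
#' @export
scan_runs <- function(gs, k_min = 1L, k_max = 20L) {
  validate_geneset(gs)
  runs <- lapply(seq_len(gs$n), function(i)
    find_runs(gs$genes$sequence[i], gs$genes$gene_id[i], k_min = k_min, k_max = k_max))
  out <- do.call(rbind, runs)
  cbind(genome_id = gs$genome_id, out, stringsAsFactors = FALSE)
}

# Fast per-(base,k) run counts for a whole GeneSet; genes are concatenated
# with a separator so boundary maximality is preserved, then one rle pass.
# Returns a 4 x k_cap integer matrix (rows A,C,G,T); runs longer than k_cap
# are tallied in the last column of the companion attribute "overflow".
run_count_matrix <- function(gs, k_cap = 30L) {
  seqs <- gs$genes$sequence
  all <- paste(seqs, collapse = "|")
  r <- rle(strsplit(all, "", fixed = TRUE)[[1]])
  keep <- r$values %in% c("A", "C", "G", "T")
  b <- r$values[keep]
  k <- pmin(r$lengths[keep], k_cap)
  m <- matrix(0L, nrow = 4L, ncol = k_cap,
              dimnames = list(c("A", "C", "G", "T"), as.character(seq_len(k_cap))))
  tab <- table(factor(b, levels = c("A", "C", "G", "T")), factor(k, levels = seq_len(k_cap)))
  m[] <- as.integer(tab)
  m
}

#' Count maximal runs of one base and exact length
#'
#' @param gs a [GeneSet].
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param k exact run length in nt.
#' @return integer: number of maximal runs of exactly `k` `base`s summed over
#'   all genes.
#' @export
count_runs <- function(gs, base, k) {
  stopifnot(base %in% c("A", "C", "G", "T"), k >= 1)
  # k_cap strictly above k so clamping of longer runs cannot inflate the count
  m <- run_count_matrix(gs, k_cap = max(30L, k + 1L))
  as.integer(m[base, as.character(k)])
}

#' Find in-frame occurrences of a codon
#'
#' The reading frame is fixed by nt 1 of the coding sequence; trailing 1-2 nt
#' that do not complete a codon are ignored. Overlapping out-of-frame matches
#' are not reported.
#'
#' @param sequence coding sequence (character scalar).
#' @param codon 3-mer over `{A,C,G,T}`.
#' @param gene_id id recorded with each hit.
#' @return data.frame with `gene_id`, `codon`, `codon_index` (1-based,
#'   in-frame) and `start_nt` (`= 3*(codon_index-1)+1`).
#' @export
find_codons <- function(sequence, codon, gene_id = "gene") {
  stopifnot(nchar(codon) == 3L, length(sequence) == 1L)
  if (nchar(sequence) < 3L) stop("sequence shorter than one codon")
  idx <- which(codon_vector(sequence) == codon)
  data.frame(gene_id = rep(gene_id, length(idx)),
             codon = rep(codon, length(idx)),
             codon_index = idx, start_nt = 3L * (idx - 1L) + 1L,
             stringsAsFactors = FALSE)
}

# split a sequence into its in-frame codons, dropping trailing 1-2 nt
codon_vector <- function(sequence) {
  nc <- nchar(sequence) %/% 3L
  if (nc == 0L) return(character(0))
  starts <- 3L * (seq_len(nc) - 1L) + 1L
  substring(sequence, starts, starts + 2L)
}

#' Scan a GeneSet for in-frame codon occurrences
#'
#' @param gs a [GeneSet].
#' @param codons character vector of 3-mers.
#' @return pooled data.frame as in [find_codons], plus `L` (gene length in
#'   nt) for relative-location computation.
#' @export
scan_codons <- function(gs, codons) {
  validate_geneset(gs)
  out <- lapply(seq_len(gs$n), function(i) {
    cv <- codon_vector(gs$genes$sequence[i])
    hits <- lapply(codons, function(cd) {
      idx <- which(cv == cd)
      if (!length(idx)) return(NULL)
      data.frame(gene_id = gs$genes$gene_id[i], codon = cd,
                 codon_index = idx, start_nt = 3L * (idx - 1L) + 1L,
                 L = gs$genes$length[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), codon = character(0),
                      codon_index = integer(0), start_nt = integer(0),
                      L = integer(0))
  out
}

#' Translate a coding sequence (standard genetic code)
#'
#' The full CDS is translated literally (no start-codon special casing);
#' trailing 1-2 nt are ignored; a terminal stop codon is dropped. Codons
#' containing `N` translate to `X`. A stop codon before the final codon flags
#' the gene as carrying an internal stop; such genes are excluded from
#' residue-position analyses downstream.
#'
#' @param sequence coding sequence, length >= 3.
#' @return list with `aa` (character vector of 1-letter residues, terminal
#'   stop removed) and `internal_stop` (logical).
#' @export
translate_cds <- function(sequence) {
  cv <- codon_vector(sequence)
  if (!length(cv)) stop("sequence shorter than one codon")
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[cv])
  aa[is.na(aa)] <- "X"  # codons containing N
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  list(aa = aa, internal_stop = any(aa == "*"))
}

#' Residue positions for all stop-free genes of a GeneSet
#'
#' Translates each gene and reports one row per residue. Genes with an
#' internal stop codon are flagged and excluded (their ids are returned in
#' the `"excluded"` attribute).
#'
#' @param gs a [GeneSet].
#' @return data.frame with `gene_id`, `amino_acid` (1-letter), `residue_index`
#'   (1-based) and `protein_length` (residues, terminal stop not counted);
#'   attribute `excluded` lists internal-stop gene ids.
#' @export
residue_positions <- function(gs) {
  validate_geneset(gs)
  excluded <- character(0)
  rows <- vector("list", gs$n)
  for (i in seq_len(gs$n)) {
    tr <- translate_cds(gs$genes$sequence[i])
    if (tr$internal_stop) {
      excluded <- c(excluded, gs$genes$gene_id[i])
      next
    }
    pl <- length(tr$aa)
    rows[[i]] <- data.frame(gene_id = gs$genes$gene_id[i],
                            amino_acid = tr$aa,
                            residue_index = seq_len(pl),
                            protein_length = pl,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), amino_acid = character(0),
                      residue_index = integer(0), protein_length = integer(0))
  attr(out, "excluded") <- excluded
  out
}
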
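#' Construct a gene set
#'
#' A `GeneSet` is an ordered collection of coding-sequence records for one
#' genome (or one group of genes). Each record carries a unique `gene_id`, an
#' upper-case nucleotide sequence over `{A,C,G,T,N}` and an optional free-text
#' `group_label` (e.g. a functional role category). The total coding length
#' `N` and the gene count `n` are derived from the records and revalidated on
#' construction.
#'
#' @param genes data.frame with columns `gene_id`, `sequence` and optionally
#'   `group_label`. Sequences are normalized: upper-cased and `U` mapped to `T`.
#' @param genome_id character scalar identifying the genome.
#' @param ambiguity how to treat IUPAC ambiguity codes other than `N`:
#'   `"error"` rejects them (strict mode), `"to_n"` maps them to `N`.
#' @return An object of class `GeneSet`: a list with elements `genome_id`,
#'   `genes` (data.frame with `gene_id`, `sequence`, `length`, `group_label`),
#'   `n` (gene count) and `N` (total nt).
#' @examples
#' gs <- GeneSet(data.frame(gene_id = c("g1", "g2"),
#'                          sequence = c("ATGAAAAAATGA", "atgacgt")),
#'               genome_id = "toy")
#' gs$N  # 19
#' @export
GeneSet <- function(genes, genome_id = "genome", ambiguity = c("error", "to_n")) {
  ambiguity <- match.arg(ambiguity)
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stop("'genes' must be a non-empty data.frame")
  if (!all(c("gene_id", "sequence") %in% names(genes)))
    stop("'genes' must have columns 'gene_id' and 'sequence'")
  gene_id <- as.character(genes$gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  seqs <- normalize_sequence(as.character(genes$sequence), ambiguity = ambiguity)
  if (any(!nzchar(seqs))) stop("empty sequence for gene_id: ",
                               paste(gene_id[!nzchar(seqs)], collapse = ", "))
  group_label <- if ("group_label" %in% names(genes))
    as.character(genes$group_label) else rep(NA_character_, length(seqs))
  out <- list(
    genome_id = as.character(genome_id)[1],
    genes = data.frame(gene_id = gene_id,
                       sequence = seqs,
                       length = nchar(seqs),
                       group_label = group_label,
                       stringsAsFactors = FALSE),
    n = length(seqs),
    N = sum(nchar(seqs))
  )
  class(out) <- "GeneSet"
  out
}

# Upper-case, map U->T; ambiguity codes other than N rejected or mapped to N.
normalize_sequence <- function(x, ambiguity = c("error", "to_n")) {
  ambiguity <- match.arg(ambiguity)
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    if (ambiguity == "error")
      stop("non-ACGTN characters in ", sum(bad),
           " sequence(s); use ambiguity = \"to_n\" to map them to N")
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$genome_id, "': ", x$n, " genes, ", x$N, " nt total\n", sep = "")
  nlab <- sum(!is.na(x$genes$group_label))
  if (nlab > 0) cat("  ", nlab, " genes carry a group label\n", sep = "")
  invisible(x)
}

#' Validate a GeneSet's internal invariants
#'
#' Checks that `N` and `n` match the records, ids are unique, and sequences
#' are normalized. Called by functions that accept externally constructed
#' objects.
#'
#' @param gs a `GeneSet`.
#' @return `gs`, invisibly; stops on violation.
#' @export
validate_geneset <- function(gs) {
  stopifnot(inherits(gs, "GeneSet"))
  g <- gs$genes
  if (gs$n != nrow(g) || gs$N != sum(g$length) || any(g$length != nchar(g$sequence)))
    stop("GeneSet invariants violated: N/n/lengths inconsistent with records")
  if (anyDuplicated(g$gene_id)) stop("GeneSet has duplicate gene_id")
  if (any(grepl("[^ACGTN]", g$sequence))) stop("GeneSet sequences not normalized to ACGTN")
  invisible(gs)
}

#' Read coding sequences from a multi-FASTA file
#'
#' Reads one record per gene. Sequences are normalized (upper case, `U` to
#' `T`); ambiguity codes other than `N` are rejected in strict mode or mapped
#' to `N`. An optional TSV sidecar with header `gene_id<TAB>group_label`
#' attaches free-text group labels (e.g. role categories) by `gene_id`.
#'
#' @param path FASTA file path.
#' @param labels optional path to the label TSV.
#' @param genome_id identifier for the resulting set; defaults to the file
#'   base name.
#' @inheritParams GeneSet
#' @return A [GeneSet].
#' @export
read_gene_fasta <- function(path, labels = NULL, genome_id = NULL,
                            ambiguity = c("error", "to_n")) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  genes <- data.frame(gene_id = ids, sequence = as.character(ss),
                      stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, header = TRUE, sep = "\t",
                             colClasses = "character")
    if (!all(c("gene_id", "group_label") %in% names(lab)))
      stop("label file must have columns gene_id and group_label")
    genes$group_label <- lab$group_label[match(genes$gene_id, lab$gene_id)]
  }
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fna|fasta)$", "", basename(path), ignore.case = TRUE)
  GeneSet(genes, genome_id = genome_id, ambiguity = ambiguity)
}

#' Write a GeneSet to FASTA
#'
#' Round-trip guarantee: `read_gene_fasta(write_gene_fasta(gs, f))` reproduces
#' ids, sequences and record order exactly (group labels live in the sidecar
#' TSV, not in FASTA).
#'
#' @param gs a [GeneSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(gs, path) {
  validate_geneset(gs)
  ss <- Biostrings::DNAStringSet(gs$genes$sequence)
  names(ss) <- gs$genes$gene_id
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Write gene group labels to a TSV sidecar
#'
#' @param gs a [GeneSet]; genes without a label are omitted.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_labels <- function(gs, path) {
  validate_geneset(gs)
  g <- gs$genes[!is.na(gs$genes$group_label), c("gene_id", "group_label")]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
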
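# Local-seed helper: run code under a fixed RNG state without disturbing the
# caller's stream. NULL seed = use (and advance) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Binomial draw tolerant of astronomically large size (cell counts); falls
# back to the Poisson limit when size exceeds integer range and p is tiny.
rbinom_large <- function(n, size, prob) {
  if (size <= .Machine$integer.max) return(stats::rbinom(n, size, prob))
  if (size * prob < 1e6) return(stats::rpois(n, size * prob))
  round(stats::rnorm(n, size * prob, sqrt(size * prob * (1 - prob))))
}

#' Generate a composition-matched null gene set
#'
#' Bases are drawn i.i.d. from the given composition, the null model under
#' which run counts are binomially distributed — the reference condition for
#' calibrating the census statistics.
#'
#' @param comp a `GenomeComposition` (only `f` is used) or a named numeric
#'   vector of frequencies for `A`, `C`, `G`, `T` summing to 1.
#' @param n_genes number of genes.
#' @param lengths gene length law: a single length recycled to all genes, a
#'   vector of length `n_genes`, or a function `function(n)` returning `n`
#'   lengths (all in nt, >= 1).
#' @param seed integer seed; identical seeds give identical gene sets.
#' @param genome_id id for the resulting [GeneSet].
#' @return A [GeneSet] with gene ids `g00001, g00002, ...`.
#' @export
make_null_geneset <- function(comp, n_genes, lengths = 900L, seed = NULL,
                              genome_id = "null_genome") {
  f <- if (inherits(comp, "GenomeComposition")) comp$f else comp[c("A", "C", "G", "T")]
  if (any(is.na(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("composition must give non-negative A/C/G/T frequencies summing to 1")
  stopifnot(n_genes >= 1)
  with_seed(seed, {
    L <- if (is.function(lengths)) lengths(n_genes) else rep_len(lengths, n_genes)
    L <- as.integer(round(L))
    if (any(L < 1)) stop("gene lengths must be >= 1 nt")
    bases <- sample(c("A", "C", "G", "T"), sum(L), replace = TRUE, prob = f)
    ends <- cumsum(L)
    starts <- ends - L + 1L
    seqs <- vapply(seq_len(n_genes), function(i)
      paste(bases[starts[i]:ends[i]], collapse = ""), character(1))
    GeneSet(data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                       sequence = seqs, stringsAsFactors = FALSE),
            genome_id = genome_id)
  })
}

#' Plant maximal homopolymeric tracts at controlled within-gene positions
#'
#' Overwrites `k` bases of each gene with a run of `base`, forcing both
#' flanking positions to a different base so the planted run is maximal and
#' recovered with exactly length `k` by [find_runs]. Gene length is
#' unchanged. The run midpoint's relative location follows the chosen law:
#' `"uniform"`, or `"five_prime_beta"` — a Beta(alpha, beta) draw, with the
#' defaults Beta(1, 9) (mean 0.1) emulating the strong 5' clustering seen in
#' real genomes.
#'
#' @param gs a [GeneSet]; every gene must be longer than `k + 2`.
#' @param base run base.
#' @param k run length in nt.
#' @param count_per_gene number of runs planted per gene (placements are
#'   re-drawn on overlap; must fit the gene).
#' @param position_law `"uniform"` or `"five_prime_beta"`.
#' @param alpha,beta shape parameters of the Beta law (only used for
#'   `"five_prime_beta"`).
#' @param seed integer seed.
#' @return A [GeneSet] with the planted sequences; attribute `planted` holds
#'   a data.frame of the planted runs (`gene_id`, `base`, `k`, `start`,
#'   `end`).
#' @export
plant_hts <- function(gs, base = "A", k = 7L, count_per_gene = 1L,
                      position_law = c("uniform", "five_prime_beta"),
                      alpha = 1, beta = 9, seed = NULL) {
  validate_geneset(gs)
  position_law <- match.arg(position_law)
  stopifnot(base %in% c("A", "C", "G", "T"), k >= 1, count_per_gene >= 0,
            alpha > 0, beta > 0)
  short <- gs$genes$length <= k + 2L
  if (any(short))
    stop(sum(short), " gene(s) too short to host a maximal k=", k, " run")
  flank <- if (base == "A") "C" else "A"
  draw_rl <- function(n) {
    if (position_law == "uniform") stats::runif(n) else stats::rbeta(n, alpha, beta)
  }
  planted <- vector("list", gs$n)
  genes <- gs$genes
  with_seed(seed, {
    for (i in seq_len(gs$n)) {
      if (count_per_gene == 0L) next
      L <- genes$length[i]
      ch <- strsplit(genes$sequence[i], "", fixed = TRUE)[[1]]
      occupied <- rep(FALSE, L)
      starts <- integer(0)
      for (j in seq_len(count_per_gene)) {
        for (try in 1:200) {
          rl <- draw_rl(1)
          # midpoint rl -> start; keep one flank inside the gene on each side
          s <- as.integer(round(rl * L - (k - 1) / 2))
          s <- min(max(s, 2L), L - k)
          span <- (s - 1L):(s + k)  # run plus both flanks
          if (!any(occupied[span])) break
          if (try == 200) stop("could not place ", count_per_gene,
                               " non-overlapping runs in gene of length ", L)
        }
        occupied[span] <- TRUE
        ch[s:(s + k - 1L)] <- base
        ch[s - 1L] <- flank
        ch[s + k] <- flank
        starts <- c(starts, s)
      }
      genes$sequence[i] <- paste(ch, collapse = "")
      planted[[i]] <- data.frame(gene_id = genes$gene_id[i], base = base,
                                 k = k, start = starts, end = starts + k - 1L,
                                 stringsAsFactors = FALSE)
    }
  })
  out <- GeneSet(genes[, c("gene_id", "sequence", "group_label")],
                 genome_id = gs$genome_id)
  attr(out, "planted") <- do.call(rbind, planted)
  out
}

#' Simulate selective-plating experiments for reversion-frequency estimation
#'
#' Emulates the translational-fusion plating assay: a culture of
#' `culture_size` cells in `culture_volume` ml contains
#' `Poisson(true_freq * culture_size)` revertant cells. A volume `VP` of a
#' `DF_total`-fold dilution is plated non-selectively (colony count `CFU`
#' estimates total density) and a volume `VP` of a `DF_sel`-fold dilution is
#' plated selectively. Revertant colonies are large; a background of
#' slow-growing non-revertant colonies (mostly small, occasionally large)
#' exercises the pixel-size classifier and the sequencing-confirmation step.
#' Of the large colonies, `CS` are sequenced (all when fewer than 20,
#' otherwise `cs_cap`) and `R` of those are confirmed revertants.
#'
#' @param true_freq true per-cell revertant frequency `phi` in `[0, 1]`.
#' @param culture_size cells per culture (may exceed integer range).
#' @param culture_volume culture volume in ml (default 5).
#' @param DF_total dilution factor for the non-selective (total count) plate.
#' @param VP volume plated in ml (both plate types).
#' @param DF_sel dilution factor for the selective plate.
#' @param replicates number of biological replicates.
#' @param bg_small,bg_large Poisson means of small and large non-revertant
#'   background colonies per selective plate.
#' @param cs_cap colonies sequenced when more than 20 large colonies are
#'   present (default 10).
#' @param seed integer seed; identical seeds reproduce the table exactly.
#' @return data.frame with one row per replicate: `replicate`, `CFU`,
#'   `DF_total`, `VP`, `DF_sel`, `TC` (total large colonies), `CS`, `R`, and
#'   list-column `colony_sizes` (pixel sizes of all selective-plate
#'   colonies). Suitable for [reversion_frequency] and [write_plating_tsv].
#' @export
simulate_plating <- function(true_freq, culture_size, culture_volume = 5,
                             DF_total = 1e6, VP = 0.1, DF_sel = 10,
                             replicates = 3L, bg_small = 10, bg_large = 1,
                             cs_cap = 10L, seed = NULL) {
  stopifnot(true_freq >= 0, true_freq <= 1, culture_size >= 1,
            VP > 0, DF_total >= 1, DF_sel >= 1, replicates >= 1)
  with_seed(seed, {
    rows <- vector("list", replicates)
    frac_total <- VP / (culture_volume * DF_total)
    frac_sel <- VP / (culture_volume * DF_sel)
    for (r in seq_len(replicates)) {
      n_rev <- stats::rpois(1, true_freq * culture_size)
      CFU <- rbinom_large(1, culture_size, frac_total)
      rev_colonies <- rbinom_large(1, n_rev, frac_sel)
      n_small <- stats::rpois(1, bg_small)
      n_big_bg <- stats::rpois(1, bg_large)
      # two-component size law: small colonies <= 8 px, large >= 9 px
      sizes <- c(9L + stats::rpois(rev_colonies + n_big_bg, 5),
                 pmin(8L, 1L + stats::rpois(n_small, 3)))
      TC <- rev_colonies + n_big_bg
      CS <- if (TC < 20L) TC else as.integer(cs_cap)
      # sequencing draws CS large colonies without replacement
      R <- if (TC > 0L) stats::rhyper(1, m = rev_colonies, n = n_big_bg, k = CS) else 0L
      rows[[r]] <- data.frame(replicate = r, CFU = CFU, DF_total = DF_total,
                              VP = VP, DF_sel = DF_sel, TC = TC, CS = CS,
                              R = R, stringsAsFactors = FALSE)
      rows[[r]]$colony_sizes <- list(as.integer(sizes))
    }
    do.call(rbind, rows)
  })
}

#' Write a plating-experiment table to TSV
#'
#' Colony sizes are packed as a comma-separated list in one column;
#' [read_plating_tsv] unpacks them.
#'
#' @param plating data.frame as returned by [simulate_plating].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plating_tsv <- function(plating, path) {
  out <- plating
  out$colony_sizes <- vapply(plating$colony_sizes, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plating-experiment table from TSV
#'
#' @param path TSV written by [write_plating_tsv] (columns `replicate`,
#'   `CFU`, `DF_total`, `VP`, `DF_sel`, `TC`, `CS`, `R`, `colony_sizes`).
#' @return data.frame with `colony_sizes` unpacked to an integer
#'   list-column.
#' @export
read_plating_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("replicate", "CFU", "DF_total", "VP", "DF_sel", "TC", "CS", "R")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("plating table missing column(s): ",
                         paste(miss, collapse = ", "))
  x$colony_sizes <- if ("colony_sizes" %in% names(x))
    lapply(strsplit(as.character(x$colony_sizes), ","),
           function(v) as.integer(v[nzchar(v)]))
  else rep(list(integer(0)), nrow(x))
  x
}
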
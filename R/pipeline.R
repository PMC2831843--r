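# 32-bit polynomial rolling hash of the canonicalized config, for
# provenance headers (collision resistance is not a goal).
config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]  # analysis params only
  s <- paste(names(config),
             vapply(config, function(v) paste(format(v), collapse = ","), character(1)),
             sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build a pipeline run configuration
#'
#' Collects the knobs shared by the pipeline stages. Defaults mirror the
#' standard analysis: run lengths 1-20, all four bases, 5' window 10%,
#' one-sided critical Z 1.64 and two-sided display cut-off 1.96.
#'
#' @param fasta path to the coding-gene FASTA (scan/census/position stages).
#' @param labels optional path to the gene-group label TSV.
#' @param plating optional path to a plating TSV (reversion stage).
#' @param out_dir output directory for stage reports (created if missing).
#' @param k_min,k_max run-length range.
#' @param bases bases to census.
#' @param threshold 5' window fraction for enrichment.
#' @param z_over,z_two critical Z values.
#' @param seed integer seed used by all stochastic steps (pseudo-nulls).
#' @param B pseudo-null resamples for enrichment.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(fasta = NULL, labels = NULL, plating = NULL,
                       out_dir = ".", k_min = 1L, k_max = 20L,
                       bases = c("A", "C", "G", "T"), threshold = 0.10,
                       z_over = z_critical(), z_two = z_critical(two_sided = TRUE),
                       seed = 1L, B = 1L) {
  stopifnot(k_min >= 1, k_max >= k_min, threshold > 0, threshold < 1)
  structure(list(fasta = fasta, labels = labels, plating = plating,
                 out_dir = out_dir, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), bases = bases,
                 threshold = threshold, z_over = z_over, z_two = z_two,
                 seed = as.integer(seed), B = as.integer(B)),
            class = "RunConfig")
}

# One provenance line per report: stage, seed, config hash.
write_report <- function(df, config, stage, filename) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  path <- file.path(config$out_dir, filename)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# htract %s seed=%d config=%s", stage, config$seed,
                     config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_geneset <- function(config) {
  if (is.null(config$fasta)) stop("config has no input FASTA")
  read_gene_fasta(config$fasta, labels = config$labels)
}

#' Pipeline stage: scan runs, codons and residues
#'
#' Writes `runs.tsv` (maximal runs with relative locations), `codons.tsv`
#' (in-frame AAA/AAG/TTT/TTC hits) and `residues.tsv` (residue positions of
#' stop-free genes) to the configured output directory.
#'
#' @param config a [run_config].
#' @return invisibly, a list of the three tables.
#' @export
run_scan <- function(config) {
  gs <- load_geneset(config)
  runs <- run_positions(scan_runs(gs, k_min = config$k_min, k_max = config$k_max), gs)
  codons <- scan_codons(gs, c("AAA", "AAG", "TTT", "TTC"))
  residues <- residue_positions(gs)
  write_report(runs, config, "scan", "runs.tsv")
  write_report(codons, config, "scan", "codons.tsv")
  write_report(residues, config, "scan", "residues.tsv")
  message(sprintf("scan: %d genes, %d runs, %d codon hits, %d residues (%d gene(s) excluded for internal stops)",
                  gs$n, nrow(runs), nrow(codons), nrow(residues),
                  length(attr(residues, "excluded"))))
  invisible(list(runs = runs, codons = codons, residues = residues))
}

#' Pipeline stage: composition-null census
#'
#' Writes `census.tsv` (per base and run length: frequencies, GC, N, n,
#' observed and expected counts, Z, call) and, when group labels are
#' present, `census_by_group.tsv`.
#'
#' @param config a [run_config].
#' @return invisibly, a list with `census` and (possibly `NULL`)
#'   `by_group`.
#' @export
run_census <- function(config) {
  gs <- load_geneset(config)
  cen <- census(gs, k_min = config$k_min, k_max = config$k_max,
                bases = config$bases, z_over = config$z_over,
                z_two = config$z_two)
  write_report(cen, config, "census", "census.tsv")
  by_group <- NULL
  if (any(!is.na(gs$genes$group_label))) {
    by_group <- grouped_census(gs, k_min = config$k_min, k_max = config$k_max,
                               bases = config$bases, z_over = config$z_over,
                               z_two = config$z_two)
    write_report(by_group, config, "census", "census_by_group.tsv")
  }
  invisible(list(census = cen, by_group = by_group))
}

#' Pipeline stage: positional-bias analyses
#'
#' Writes `histograms.tsv` (20-window relative-location histograms per base
#' and run length), `ladder.tsv` (one-sided Wilcoxon p for each k vs k-1)
#' and `enrichment.tsv` (first-fraction odds ratios with CIs and Fisher p).
#' Cells with no observed runs are emitted with `NA` statistics.
#'
#' @param config a [run_config].
#' @param k_range run lengths analysed positionally (default 5:9, the
#'   informative range for 5' clustering).
#' @return invisibly, a list of the three tables.
#' @export
run_position <- function(config, k_range = 5:9) {
  gs <- load_geneset(config)
  runs <- run_positions(scan_runs(gs, k_min = 1L), gs)
  hist_rows <- list(); ladder_rows <- list(); enrich_rows <- list()
  for (b in config$bases) {
    for (k in k_range) {
      rl <- runs$rl[runs$base == b & runs$k == k]
      rl_prev <- runs$rl[runs$base == b & runs$k == k - 1L]
      if (length(rl)) {
        h <- position_histogram(rl)
        hist_rows[[paste(b, k)]] <- cbind(base = b, k = k, h)
        er <- first_fraction_enrichment(rl, threshold = config$threshold,
                                        seed = config$seed + k, B = config$B)
        enrich_rows[[paste(b, k)]] <- data.frame(
          base = b, k = k, threshold = er$threshold, n = er$n,
          obs_in = er$obs_in, exp_in = er$exp_in, OR = er$OR,
          ci_lo = er$ci95[1], ci_hi = er$ci95[2], p = er$p)
      } else {
        enrich_rows[[paste(b, k)]] <- data.frame(
          base = b, k = k, threshold = config$threshold, n = 0L,
          obs_in = NA_integer_, exp_in = NA_integer_, OR = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_)
      }
      ladder_rows[[paste(b, k)]] <- data.frame(
        base = b, k = k, n_k = length(rl), n_km1 = length(rl_prev),
        p = if (length(rl) && length(rl_prev)) ladder_test(rl, rl_prev) else NA_real_)
    }
  }
  hist_tab <- do.call(rbind, hist_rows)
  ladder_tab <- do.call(rbind, ladder_rows)
  enrich_tab <- do.call(rbind, enrich_rows)
  write_report(hist_tab, config, "position", "histograms.tsv")
  write_report(ladder_tab, config, "position", "ladder.tsv")
  write_report(enrich_tab, config, "position", "enrichment.tsv")
  invisible(list(histograms = hist_tab, ladder = ladder_tab,
                 enrichment = enrich_tab))
}

#' Pipeline stage: reversion-frequency estimation
#'
#' Reads the configured plating TSV and writes `reversion.tsv` with
#' per-replicate OCD, RD and FR plus the mean/median FR and, when no
#' replicate had a confirmed revertant, the detection limit.
#'
#' @param config a [run_config].
#' @return invisibly, the [reversion_frequency] estimate.
#' @export
run_reversion <- function(config) {
  if (is.null(config$plating)) stop("config has no plating table")
  plating <- read_plating_tsv(config$plating)
  est <- reversion_frequency(plating)
  out <- est$replicates
  out$mean_FR <- est$mean_FR
  out$median_FR <- est$median_FR
  out$detection_limit <- est$detection_limit
  write_report(out, config, "reversion", "reversion.tsv")
  invisible(est)
}
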
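#' Classify selective-plate colonies by pixel size
#'
#' Colonies larger than 8 px are "large" (mostly true revertants); colonies
#' smaller than 9 px are "small" (mostly slow-growing non-revertants). The
#' two rules coincide on integers, so the partition is complete and
#' exclusive.
#'
#' @param sizes integer vector of colony sizes in pixels.
#' @return named integer vector `c(large = ..., small = ...)`.
#' @examples
#' classify_colonies(c(9, 12, 8, 3))  # 2 large, 2 small
#' @export
classify_colonies <- function(sizes) {
  if (length(sizes) && (any(sizes < 0) || any(sizes != round(sizes))))
    stop("colony sizes must be non-negative integers")
  c(large = sum(sizes > 8), small = sum(sizes <= 8))
}

#' Original cell density from non-selective plate counts
#'
#' `OCD = CFU * DF / VP`, in cells per ml of undiluted culture.
#'
#' @param CFU average number of colonies per non-selective plate.
#' @param VP volume plated in ml (> 0).
#' @param DF dilution factor of the plated suspension.
#' @return cells/ml (vectorized).
#' @export
original_cell_density <- function(CFU, VP, DF) {
  if (any(VP <= 0)) stop("VP must be > 0")
  if (any(DF < 1)) stop("DF must be >= 1")
  CFU * DF / VP
}

#' Confirmed-revertant density from selective plate counts
#'
#' Total large colonies are scaled by the sequencing-confirmed fraction:
#' `RD = TC * (R / CS) * DF / VP`, in confirmed revertants per ml of
#' undiluted culture. Small colonies are excluded throughout (they are
#' predominantly slow-growing non-revertants).
#'
#' @param TC total large colonies on the selective plate.
#' @param CS number of large colonies sequenced (>= 1 whenever `TC > 0`).
#' @param R sequenced colonies confirmed as revertants (`0 <= R <= CS`).
#' @param VP volume plated in ml.
#' @param DF dilution factor of the selective plating.
#' @return revertants/ml (vectorized); 0 where `TC == 0`.
#' @export
revertant_density <- function(TC, CS, R, VP, DF) {
  if (any(VP <= 0)) stop("VP must be > 0")
  if (any(TC > 0 & CS < 1)) stop("CS must be >= 1 when TC > 0")
  if (any(R > CS) || any(R < 0)) stop("need 0 <= R <= CS")
  ifelse(TC == 0, 0, TC * (R / CS) * DF / VP)
}

#' Reversion-frequency estimates from a plating table
#'
#' For each replicate, computes the original cell density (OCD), the
#' confirmed-revertant density (RD) and the reversion frequency
#' `FR = RD / OCD`; the experiment-level estimate is the arithmetic mean of
#' replicate frequencies (the median is also reported).
#'
#' @param plating data.frame with columns `replicate`, `CFU`, `DF_total`,
#'   `VP`, `DF_sel`, `TC`, `CS`, `R` ([simulate_plating] /
#'   [read_plating_tsv] schema).
#' @return object of class `ReversionEstimate`: list with `replicates`
#'   (data.frame adding `OCD`, `RD`, `FR`), `mean_FR`, `median_FR`, and
#'   `detection_limit` (the one-revertant frequency bound, reported when no
#'   replicate had a confirmed revertant, `NA` otherwise).
#' @export
reversion_frequency <- function(plating) {
  need <- c("CFU", "DF_total", "VP", "DF_sel", "TC", "CS", "R")
  miss <- setdiff(need, names(plating))
  if (length(miss)) stop("plating table missing column(s): ",
                         paste(miss, collapse = ", "))
  OCD <- original_cell_density(plating$CFU, plating$VP, plating$DF_total)
  if (any(OCD <= 0)) stop("OCD must be > 0 (no colonies on total-count plates?)")
  RD <- revertant_density(plating$TC, plating$CS, plating$R,
                          plating$VP, plating$DF_sel)
  FR <- RD / OCD
  reps <- cbind(plating[setdiff(names(plating), "colony_sizes")],
                OCD = OCD, RD = RD, FR = FR)
  dl <- if (all(plating$R == 0)) detection_limit(plating) else NA_real_
  structure(list(replicates = reps,
                 mean_FR = mean(FR),
                 median_FR = stats::median(FR),
                 detection_limit = dl),
            class = "ReversionEstimate")
}

#' @export
print.ReversionEstimate <- function(x, ...) {
  cat("Reversion frequency over", nrow(x$replicates), "replicate(s):\n")
  print(format(x$replicates[, c("replicate", "OCD", "RD", "FR")], digits = 3),
        row.names = FALSE)
  cat(sprintf("  mean FR = %.3g, median FR = %.3g\n", x$mean_FR, x$median_FR))
  if (!is.na(x$detection_limit))
    cat(sprintf("  no confirmed revertants: frequency below ~%.2g\n",
                x$detection_limit))
  invisible(x)
}

#' Detection limit when no revertants are observed
#'
#' With zero confirmed revertants across all replicates, the frequency is
#' bounded by what a single revertant colony would have implied:
#' `1 / sum(cells screened)`, where each replicate screens
#' `OCD * VP / DF_sel` cells on its selective plate.
#'
#' @param plating data.frame as for [reversion_frequency], with `R == 0` in
#'   every replicate.
#' @return upper bound on the reversion frequency.
#' @export
detection_limit <- function(plating) {
  if (any(plating$R > 0))
    stop("detection limit is only defined when no replicate has confirmed revertants")
  OCD <- original_cell_density(plating$CFU, plating$VP, plating$DF_total)
  screened <- OCD * plating$VP / plating$DF_sel
  1 / sum(screened)
}

#' Fold difference of a reversion frequency over a reference frequency
#'
#' @param FR estimated reversion frequency.
#' @param reference reference frequency (> 0), e.g. an average point-mutation
#'   frequency.
#' @param sig_figs optional number of significant figures to round the fold
#'   ratio to (e.g. 1 for an order-of-magnitude statement).
#' @return fold ratio `FR / reference`.
#' @examples
#' fold_vs_reference(5.5e-7, 4.5e-10, sig_figs = 1)  # 1000
#' @export
fold_vs_reference <- function(FR, reference, sig_figs = NULL) {
  if (any(reference <= 0)) stop("reference frequency must be > 0")
  out <- FR / reference
  if (!is.null(sig_figs)) out <- signif(out, sig_figs)
  out
}
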
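#' Normalized mutant-cell frequency per cell type
#'
#' For every cell type with strictly more than `min_cells` genotyped cells
#' (genotype `MUT` or `WT`), computes the mutant fraction
#' `n_MUT / (n_MUT + n_WT)`. In the default `"per_patient"` mode the
#' fraction is computed within each patient (patients with at least one
#' genotyped cell of the type) and averaged across patients, so no single
#' patient dominates; `"pooled"` computes one fraction over all genotyped
#' cells. The mode used is stamped in attribute `"normalization"`.
#'
#' @param cells cell table with columns `cell_type`, `genotype`, and
#'   (for per-patient mode) `patient`
#' @param min_cells analysis floor: cell types with `<= min_cells` genotyped
#'   cells are omitted (default 100; the rule is strictly greater than)
#' @param mode `"per_patient"` (default) or `"pooled"`
#' @return `data.frame`: `cell_type`, `frequency`, `n_genotyped`,
#'   `n_patients`
#' @export
normalized_mutant_frequency <- function(cells, min_cells = 100L,
                                        mode = c("per_patient", "pooled")) {
  mode <- match.arg(mode)
  g <- cells[cells$genotype %in% c("MUT", "WT"), , drop = FALSE]
  counts <- table(g$cell_type)
  keep <- names(counts)[counts > min_cells]
  if (length(keep) == 0L) {
    warning("no cell type exceeds the genotyped-cell floor")
    out <- data.frame(cell_type = character(0), frequency = numeric(0),
                      n_genotyped = integer(0), n_patients = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "normalization") <- mode
    return(out)
  }
  rows <- lapply(keep, function(ty) {
    gt <- g[g$cell_type == ty, , drop = FALSE]
    if (mode == "pooled") {
      freq <- mean(gt$genotype == "MUT")
      npat <- length(unique(gt$patient))
    } else {
      per_pat <- tapply(gt$genotype == "MUT", gt$patient, mean)
      per_pat <- per_pat[!is.na(per_pat)]
      freq <- mean(per_pat)
      npat <- length(per_pat)
    }
    data.frame(cell_type = ty, frequency = unname(freq),
               n_genotyped = nrow(gt), n_patients = npat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normalization") <- mode
  out
}

bin_pseudotime <- function(t, n_bins) {
  rng <- range(t)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(t, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  list(bin = bin, centers = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

#' Genotype-ratio curves along pseudotime
#'
#' Splits the lineage's cells into `n_bins` equal-width pseudotime bins and
#' computes, per bin, the ratio of mutant (and of wild-type) cells to all
#' lineage cells in the bin (`denominator = "all"`, including unassigned
#' cells, the default) or to genotyped cells only (`"assigned"`). The
#' per-bin standard error is the binomial `sqrt(p (1 - p) / n)` and the
#' confidence band half-width is `1.96 * SE`. Bins with fewer than
#' `min_per_bin` cells are masked. Values are stored on the linear scale;
#' log-scaling is a plotting choice.
#'
#' @param cells cell table with `cell_type`, `genotype`, `pseudotime`
#' @param lineage cell-type label selecting the lineage
#' @param n_bins number of equal-width bins (default 20)
#' @param min_per_bin mask bins with fewer cells (default 10)
#' @param denominator `"all"` or `"assigned"`
#' @return `data.frame` of class `binned_curve`: `genotype`, `bin_center`,
#'   `ratio`, `se`, `band`, `n`, `masked`
#' @export
genotype_ratio_along_pseudotime <- function(cells, lineage, n_bins = 20L,
                                            min_per_bin = 10L,
                                            denominator = c("all",
                                                            "assigned")) {
  denominator <- match.arg(denominator)
  lin <- cells[cells$cell_type == lineage & !is.na(cells$pseudotime), ,
               drop = FALSE]
  if (nrow(lin) == 0L)
    stop(sprintf("no cells with pseudotime in lineage '%s'", lineage),
         call. = FALSE)
  if (denominator == "assigned")
    lin <- lin[lin$genotype %in% c("MUT", "WT"), , drop = FALSE]
  bp <- bin_pseudotime(lin$pseudotime, n_bins)
  rows <- lapply(c("MUT", "WT"), function(gt) {
    n <- tabulate(bp$bin, nbins = n_bins)
    k <- tabulate(bp$bin[lin$genotype == gt], nbins = n_bins)
    ratio <- ifelse(n > 0, k / n, NA_real_)
    se <- ifelse(n > 0, sqrt(ratio * (1 - ratio) / n), NA_real_)
    data.frame(genotype = gt, bin_center = bp$centers, ratio = ratio,
               se = se, band = 1.96 * se, n = n,
               masked = n < min_per_bin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("binned_curve", class(out))
  out
}

#' Module-score curves along pseudotime, by group
#'
#' Per group and equal-width pseudotime bin: the mean of a per-cell score
#' column, its standard error `sd / sqrt(n)`, and a `1.96 * SE` band. Bins
#' with fewer than `min_per_bin` cells are masked.
#'
#' @param cells cell table with `pseudotime`, the score column, and the
#'   grouping column
#' @param score_col name of the per-cell score column
#' @param group_col name of the grouping column (e.g. disease status);
#'   `NULL` treats all cells as one group
#' @param n_bins,min_per_bin binning parameters as in
#'   [genotype_ratio_along_pseudotime()]
#' @return `data.frame` of class `binned_curve`: `group`, `bin_center`,
#'   `mean`, `se`, `band`, `n`, `masked`
#' @export
score_along_pseudotime <- function(cells, score_col, group_col = NULL,
                                   n_bins = 20L, min_per_bin = 10L) {
  if (!score_col %in% names(cells))
    stop(sprintf("score column '%s' is missing", score_col), call. = FALSE)
  cells <- cells[!is.na(cells$pseudotime), , drop = FALSE]
  grp <- if (is.null(group_col)) rep("all", nrow(cells))
         else as.character(cells[[group_col]])
  bp <- bin_pseudotime(cells$pseudotime, n_bins)
  rows <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    n <- tabulate(bp$bin[sel], nbins = n_bins)
    s <- cells[[score_col]][sel]
    b <- bp$bin[sel]
    mu <- vapply(seq_len(n_bins), function(i)
      if (n[i] > 0) mean(s[b == i]) else NA_real_, numeric(1))
    se <- vapply(seq_len(n_bins), function(i)
      if (n[i] > 1) stats::sd(s[b == i]) / sqrt(n[i])
      else if (n[i] == 1) 0 else NA_real_, numeric(1))
    data.frame(group = g, bin_center = bp$centers, mean = mu, se = se,
               band = 1.96 * se, n = n, masked = n < min_per_bin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("binned_curve", class(out))
  out
}
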
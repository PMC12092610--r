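#' Filter transcriptome reads lacking barcode tags
#'
#' Removes reads missing the cell-barcode (CB) or molecular-barcode (UB)
#' tag; only reads carrying both identify a molecule in a cell. Removal
#' counts are reported in attribute `"tag_filter_stats"`.
#'
#' @param reads `data.frame` with columns `cell_barcode`, `umi`,
#'   `base_at_variant`; absent tags are `NA` (or literal `"."` on disk)
#' @return the retained reads
#' @export
filter_tagged_reads <- function(reads) {
  cb_missing <- is.na(reads$cell_barcode) | reads$cell_barcode == "."
  ub_missing <- is.na(reads$umi) | reads$umi == "."
  out <- reads[!cb_missing & !ub_missing, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tag_filter_stats") <- c(
    n_input = nrow(reads),
    n_no_cb = sum(cb_missing),
    n_no_ub = sum(ub_missing),
    n_removed = sum(cb_missing | ub_missing),
    n_retained = nrow(out))
  out
}

#' Consensus base of one molecule (cell, UMI) with a 75% rule
#'
#' When all reads of a molecule agree, that base is the consensus. When they
#' disagree, the most common base wins only if it accounts for at least
#' `threshold` (default 0.75) of the molecule's reads; otherwise the
#' molecule is `DISCARDED`. With `strict = TRUE` the comparison is strictly
#' greater than the threshold (so exactly 3 of 4 reads no longer suffices).
#' A consensus that is neither allele (`OTHER`) cannot support a genotype
#' and is reported as `DISCARDED`. An empty group is `DISCARDED`.
#'
#' @param bases character vector of per-read bases (`"WT"`, `"MUT"`,
#'   `"OTHER"`) for one (cell, UMI)
#' @param threshold consensus share required when reads disagree
#' @param strict use `>` instead of `>=` at the threshold
#' @return `"WT"`, `"MUT"` or `"DISCARDED"`
#' @export
consensus_base_per_umi <- function(bases, threshold = 0.75, strict = FALSE) {
  if (length(bases) == 0L) return("DISCARDED")
  tab <- table(bases)
  top <- names(tab)[which.max(tab)]
  share <- max(tab) / length(bases)
  ok <- length(tab) == 1L ||
    (if (strict) share > threshold else share >= threshold)
  if (!ok || !top %in% c("WT", "MUT")) return("DISCARDED")
  top
}

#' Hemizygous cell genotypes from per-UMI transcriptome consensi
#'
#' Applies the same hemizygous calling contract as
#' [call_cell_genotypes()], with per-UMI consensus bases in place of
#' amplicon UMI calls.
#'
#' @param consensi `data.frame` with columns `cell_barcode` and `call`
#'   (`"WT"`/`"MUT"`; `DISCARDED` molecules must already be excluded)
#' @return per-cell genotype `data.frame` (see [call_cell_genotypes()])
#' @export
genotype_cells_from_transcriptome <- function(consensi) {
  call_cell_genotypes(consensi)
}

#' Run the transcriptome-read variant caller
#'
#' Tag-filters the reads, forms per-(cell, UMI) consensus bases under the
#' 75% rule, discards unresolved molecules, and calls hemizygous per-cell
#' genotypes.
#'
#' @param reads tagged-read `data.frame` (`cell_barcode`, `umi`,
#'   `base_at_variant`)
#' @param threshold consensus share (default 0.75)
#' @param strict use `>` instead of `>=` at the threshold
#' @return list with `umi_consensus` (`cell_barcode`, `umi`, `n_reads`,
#'   `call`, including `DISCARDED` rows) and `cell_genotypes`
#' @export
genotype_sniffer <- function(reads, threshold = 0.75, strict = FALSE) {
  reads <- filter_tagged_reads(reads)
  stats_tags <- attr(reads, "tag_filter_stats")
  if (nrow(reads) == 0L) {
    cons <- data.frame(cell_barcode = character(0), umi = character(0),
                       n_reads = integer(0), call = character(0),
                       stringsAsFactors = FALSE)
    return(list(umi_consensus = cons,
                cell_genotypes = call_cell_genotypes(
                  data.frame(cell_barcode = character(0),
                             call = character(0)))))
  }
  key <- paste(reads$cell_barcode, reads$umi, sep = "\r")
  groups <- split(reads$base_at_variant, key)
  calls <- vapply(groups, consensus_base_per_umi, character(1),
                  threshold = threshold, strict = strict)
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  cons <- data.frame(
    cell_barcode = vapply(parts, `[[`, character(1), 1L),
    umi = vapply(parts, `[[`, character(1), 2L),
    n_reads = lengths(groups), call = unname(calls),
    stringsAsFactors = FALSE)
  rownames(cons) <- NULL
  kept <- cons[cons$call != "DISCARDED", , drop = FALSE]
  cells <- genotype_cells_from_transcriptome(kept)
  attr(cells, "tag_filter_stats") <- stats_tags
  attr(cells, "n_discarded_umis") <- sum(cons$call == "DISCARDED")
  list(umi_consensus = cons, cell_genotypes = cells)
}
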
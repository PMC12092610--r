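#' Default UMI-collapsing distance threshold
#'
#' The edit-distance radius used to define UMI "matches" during collapsing:
#' `ceiling(0.1 * umi_length)`, i.e. 2 bases for a 12-base UMI.
#'
#' @param umi_length UMI length in bases (>= 1)
#' @return integer threshold
#' @export
default_umi_threshold <- function(umi_length) {
  if (!is.numeric(umi_length) || length(umi_length) != 1L ||
      is.na(umi_length) || umi_length < 1)
    stop("umi_length must be a single positive number", call. = FALSE)
  as.integer(ceiling(0.1 * umi_length))
}

#' Collapse UMIs within one cell barcode by Levenshtein distance
#'
#' Pairwise Levenshtein (full edit) distances are computed between all UMIs
#' of a cell; pairs at distance <= `threshold` are "matches". Greedily, the
#' UMI with the greatest number of matches among the surviving set absorbs
#' its matched partners (which map to it as canonical and leave further
#' consideration); the process repeats with the next-highest-match UMI until
#' no survivor has a match. Ties on match count are broken by higher total
#' read count, then lexicographically. Unmatched UMIs map to themselves.
#'
#' @param umi_counts named integer vector: read count per UMI (names are the
#'   UMI sequences, unique)
#' @param threshold maximum edit distance defining a match (>= 0)
#' @return named character vector mapping every input UMI to its canonical
#'   UMI (a total map; collapsing the canonical set again is a no-op)
#' @export
collapse_umis <- function(umi_counts, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  umis <- names(umi_counts)
  if (is.null(umis) || any(!nzchar(umis)) || anyDuplicated(umis))
    stop("umi_counts must be named by unique, non-empty UMIs", call. = FALSE)
  n <- length(umis)
  canon <- stats::setNames(umis, umis)
  if (n <= 1L || threshold == 0) return(canon)
  adj <- utils::adist(umis) <= threshold
  diag(adj) <- FALSE
  active <- rep(TRUE, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    mc <- rowSums(adj[idx, idx, drop = FALSE])
    if (max(mc) == 0L) break
    best <- idx[mc == max(mc)]
    if (length(best) > 1L) {
      rc <- umi_counts[best]
      best <- best[rc == max(rc)]
      if (length(best) > 1L) best <- best[order(umis[best])][1L]
    }
    absorbed <- idx[adj[best, idx]]
    canon[umis[absorbed]] <- umis[best]
    active[c(best, absorbed)] <- FALSE
  }
  canon
}

#' Per-UMI mutant/wild-type consensus from amplicon reads
#'
#' Tallies wild-type and mutant locus bases per (cell barcode, canonical
#' UMI). Bases matching neither allele (`OTHER`) count toward neither tally
#' but are reported. A UMI is called `MUT` when mutant reads outnumber
#' wild-type reads, `WT` for the converse, and `AMBIGUOUS` when the two
#' tallies are equal and positive; ambiguous UMIs are excluded from
#' cell-level genotyping. UMIs with no informative (WT/MUT) read are dropped
#' and counted in attribute `"n_uninformative"`.
#'
#' @param reads `data.frame` with columns `cell_barcode`, `umi` (canonical),
#'   `locus_base`
#' @return `data.frame`: `cell_barcode`, `umi`, `n_wt_reads`, `n_mut_reads`,
#'   `n_other_reads`, `call`
#' @export
genotype_umis <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(cell_barcode = character(0), umi = character(0),
                      n_wt_reads = integer(0), n_mut_reads = integer(0),
                      n_other_reads = integer(0), call = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(reads$cell_barcode, reads$umi, sep = "\r")
  n_wt <- tapply(reads$locus_base == "WT", key, sum)
  n_mut <- tapply(reads$locus_base == "MUT", key, sum)
  n_other <- tapply(!reads$locus_base %in% c("WT", "MUT"), key, sum)
  keys <- names(n_wt)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    cell_barcode = vapply(parts, `[[`, character(1), 1L),
    umi = vapply(parts, `[[`, character(1), 2L),
    n_wt_reads = as.integer(n_wt), n_mut_reads = as.integer(n_mut),
    n_other_reads = as.integer(n_other), stringsAsFactors = FALSE)
  out$call <- ifelse(out$n_mut_reads > out$n_wt_reads, "MUT",
                     ifelse(out$n_wt_reads > out$n_mut_reads, "WT",
                            "AMBIGUOUS"))
  uninformative <- out$n_wt_reads == 0L & out$n_mut_reads == 0L
  n_unf <- sum(uninformative)
  out <- out[!uninformative, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_uninformative") <- n_unf
  out
}

#' Hemizygous per-cell genotype calls from UMI consensi
#'
#' Applies the hemizygous calling rule: a cell with at least one mutant UMI
#' is `MUT`; otherwise, at least one wild-type UMI makes it `WT`; a cell
#' with neither is `UNASSIGNED`. Because the locus is hemizygous, a cell
#' with both mutant and wild-type evidence is a conflict that can only arise
#' through error; mutant takes precedence (a true mutant cell yields
#' wild-type reads only through error at the amplified locus, the rarer
#' direction) and the number of such conflicted cells is reported in
#' attribute `"n_conflicted"` and per cell in column `conflicted`.
#'
#' @param consensi output of [genotype_umis()]; `AMBIGUOUS` rows are
#'   excluded internally if present
#' @return `data.frame`: `cell_barcode`, `n_wt_umis`, `n_mut_umis`,
#'   `genotype`, `conflicted`
#' @export
call_cell_genotypes <- function(consensi) {
  consensi <- consensi[consensi$call %in% c("WT", "MUT"), , drop = FALSE]
  if (nrow(consensi) == 0L) {
    out <- data.frame(cell_barcode = character(0), n_wt_umis = integer(0),
                      n_mut_umis = integer(0), genotype = character(0),
                      conflicted = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_conflicted") <- 0L
    return(out)
  }
  n_wt <- tapply(consensi$call == "WT", consensi$cell_barcode, sum)
  n_mut <- tapply(consensi$call == "MUT", consensi$cell_barcode, sum)
  out <- data.frame(
    cell_barcode = names(n_wt),
    n_wt_umis = as.integer(n_wt), n_mut_umis = as.integer(n_mut),
    stringsAsFactors = FALSE)
  out$genotype <- ifelse(out$n_mut_umis >= 1L, "MUT",
                         ifelse(out$n_wt_umis >= 1L, "WT", "UNASSIGNED"))
  out$conflicted <- out$n_mut_umis >= 1L & out$n_wt_umis >= 1L
  rownames(out) <- NULL
  attr(out, "n_conflicted") <- sum(out$conflicted)
  out
}

#' Split reads into fixed-size chunks
#'
#' Reads are processed in groups of `chunk_size` (default 125,000); the
#' concatenation of the chunks equals the input, and downstream genotyping
#' is invariant to the chunking because reads are re-grouped by cell barcode
#' after the per-chunk pass.
#'
#' @param reads read `data.frame`
#' @param chunk_size maximum rows per chunk (>= 1)
#' @return list of `data.frame` chunks
#' @export
chunk_reads <- function(reads, chunk_size = 125000L) {
  if (chunk_size < 1L) stop("chunk_size must be >= 1", call. = FALSE)
  n <- nrow(reads)
  if (n == 0L) return(list(reads))
  grp <- ceiling(seq_len(n) / chunk_size)
  lapply(split(seq_len(n), grp), function(i) reads[i, , drop = FALSE])
}

#' Run the full GoT genotyping algorithm on amplicon reads
#'
#' Drops reads with `N` in barcode or UMI (ambiguous molecule identity),
#' processes reads in chunks, re-keys by cell barcode, collapses UMIs within
#' each cell at the edit-distance threshold (default
#' `ceiling(0.1 * umi_length)`), tallies per-UMI mutant/wild-type reads,
#' removes ambiguous UMIs, and applies the hemizygous per-cell rule.
#'
#' @param reads amplicon read `data.frame` (`cell_barcode`, `umi`,
#'   `locus_base`), e.g. from [simulate_amplicon_reads()] or
#'   [read_fastq_pair()]
#' @param umi_threshold `"auto"` (the default rule) or a fixed integer
#' @param chunk_size reads per processing chunk
#' @return list with `umi_consensus` (per-UMI table) and `cell_genotypes`
#'   (per-cell table, see [call_cell_genotypes()])
#' @export
genotype_got <- function(reads, umi_threshold = "auto",
                         chunk_size = 125000L) {
  keep <- !grepl("N", reads$cell_barcode, fixed = TRUE) &
    !grepl("N", reads$umi, fixed = TRUE)
  n_dropped_n <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  if (identical(umi_threshold, "auto")) {
    umi_len <- if (nrow(reads)) nchar(reads$umi[1L]) else 12L
    umi_threshold <- default_umi_threshold(umi_len)
  }
  chunks <- chunk_reads(reads, chunk_size)
  # per-chunk pass tabulates (cell, umi, base); merge re-keys by barcode
  tallies <- do.call(rbind, c(lapply(chunks, function(ch) {
    if (nrow(ch) == 0L) return(NULL)
    stats::aggregate(cbind(n = rep(1L, nrow(ch))) ~
                       cell_barcode + umi + locus_base, data = ch, FUN = sum)
  }), list(make.row.names = FALSE)))
  if (is.null(tallies) || nrow(tallies) == 0L) {
    cons <- genotype_umis(reads)
    res <- call_cell_genotypes(cons)
    return(list(umi_consensus = cons, cell_genotypes = res))
  }
  per_cell <- split(tallies, tallies$cell_barcode)
  cons_list <- lapply(per_cell, function(tc) {
    umi_reads <- tapply(tc$n, tc$umi, sum)
    map <- if (length(umi_reads) > 1L)
      collapse_umis(stats::setNames(as.integer(umi_reads),
                                    names(umi_reads)), umi_threshold)
    else stats::setNames(names(umi_reads), names(umi_reads))
    tc$umi <- unname(map[tc$umi])
    tc
  })
  merged <- do.call(rbind, c(cons_list, list(make.row.names = FALSE)))
  expanded <- merged[rep(seq_len(nrow(merged)), merged$n),
                     c("cell_barcode", "umi", "locus_base")]
  cons <- genotype_umis(expanded)
  cells <- call_cell_genotypes(cons)
  attr(cells, "n_reads_dropped_N") <- n_dropped_n
  attr(cells, "umi_threshold") <- umi_threshold
  list(umi_consensus = cons, cell_genotypes = cells)
}
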
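#' Group receptor chains into clones
#'
#' Cells sharing an identical CDR3 nucleotide sequence (mode `"cdr3nt"`,
#' default) or an identical CDR3 plus V and J gene calls
#' (`"cdr3nt_vj"`) share a clone. Only productive chains are used. A cell
#' is represented by its primary chain — `TRB` for T cells, `IGH` for B
#' cells; if a cell carries several productive primary-locus chains, the
#' chain with the larger supporting `umi_count` defines the clone, ties
#' broken by lexicographic CDR3. Clone frequencies are relative to the
#' cells retained in the table.
#'
#' @param chains AIRR-style `data.frame` (`cell_id`, `locus`, `productive`,
#'   `cdr3`, `v_call`, `j_call`, optional `umi_count`)
#' @param mode clone definition, `"cdr3nt"` or `"cdr3nt_vj"`
#' @param locus primary chain locus to group on (`"TRB"` or `"IGH"`)
#' @return a list of class `clone_table`: `clones` (`clone_id`, `cdr3`,
#'   `n_cells`, `frequency`) and `cell_map` (`cell_id`, `clone_id`)
#' @export
group_clones <- function(chains, mode = c("cdr3nt", "cdr3nt_vj"),
                         locus = c("TRB", "IGH")) {
  mode <- match.arg(mode)
  locus <- match.arg(locus)
  ch <- chains[chains$productive & chains$locus == locus, , drop = FALSE]
  if (nrow(ch) == 0L)
    return(structure(list(
      clones = data.frame(clone_id = character(0), cdr3 = character(0),
                          n_cells = integer(0), frequency = numeric(0),
                          stringsAsFactors = FALSE),
      cell_map = data.frame(cell_id = character(0), clone_id = character(0),
                            stringsAsFactors = FALSE)),
      class = "clone_table"))
  if (is.null(ch$umi_count)) ch$umi_count <- 1L
  # primary chain per cell: most UMIs, then lexicographic CDR3
  ch <- ch[order(ch$cell_id, -ch$umi_count, ch$cdr3), , drop = FALSE]
  ch <- ch[!duplicated(ch$cell_id), , drop = FALSE]
  key <- if (mode == "cdr3nt") ch$cdr3
         else paste(ch$cdr3, ch$v_call, ch$j_call, sep = "|")
  sizes <- sort(table(key), decreasing = TRUE)
  clone_id <- stats::setNames(sprintf("clone%05d", seq_along(sizes)),
                              names(sizes))
  clones <- data.frame(
    clone_id = unname(clone_id[names(sizes)]), cdr3 = names(sizes),
    n_cells = as.integer(sizes),
    frequency = as.integer(sizes) / nrow(ch), stringsAsFactors = FALSE)
  cell_map <- data.frame(cell_id = ch$cell_id,
                         clone_id = unname(clone_id[key]),
                         stringsAsFactors = FALSE)
  rownames(clones) <- rownames(cell_map) <- NULL
  structure(list(clones = clones, cell_map = cell_map),
            class = "clone_table")
}

#' Shannon entropy of a clone frequency distribution
#'
#' `H(P) = -sum(p_i * log2(p_i))`, in bits. Maximal (`log2 n`) for a
#' uniform distribution, zero for a single clone. The input must be a
#' proper distribution; it is not silently renormalized.
#'
#' @param p clone frequencies, all > 0 and summing to 1 (within 1e-9)
#' @return entropy in bits
#' @export
shannon_entropy <- function(p) {
  if (length(p) == 0L || any(p <= 0))
    stop("clone frequencies must be positive", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("clone frequencies must sum to 1 (no silent renormalization)",
         call. = FALSE)
  -sum(p * log2(p))
}

#' Gini index of clone sizes
#'
#' The standard inequality index on the clone-size distribution,
#' `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`: 0 for perfectly even clones,
#' approaching 1 under extreme clonal dominance. Computed via the sorted
#' form `G = 2 sum(i x_(i)) / (n sum(x)) - (n + 1)/n`.
#'
#' @param sizes clone sizes (>= 1)
#' @return Gini index in `[0, 1)`
#' @export
gini_index <- function(sizes) {
  if (length(sizes) == 0L) stop("no clone sizes given", call. = FALSE)
  if (any(sizes < 1)) stop("clone sizes must be >= 1", call. = FALSE)
  n <- length(sizes)
  x <- sort(as.numeric(sizes))
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Clone-expansion class per clone size
#'
#' `singleton` (1 cell), `small` (2-5), `medium` (6-20), `expanded`
#' (strictly more than 20 cells sharing a CDR3). Only the `> 20` boundary
#' of the expanded class is analysis-fixed; the interior boundaries are
#' plotting conventions.
#'
#' @param sizes clone sizes (>= 1)
#' @return factor with levels `singleton`, `small`, `medium`, `expanded`
#' @export
classify_expansion <- function(sizes) {
  if (any(sizes < 1)) stop("clone sizes must be >= 1", call. = FALSE)
  cut(sizes, breaks = c(0, 1, 5, 20, Inf),
      labels = c("singleton", "small", "medium", "expanded"))
}

#' Somatic-hypermutation category of a mutation frequency
#'
#' `germline` (frequency exactly 0), `low` (0 < frequency <= 3%), `high`
#' (frequency > 3%).
#'
#' @param mutation_frequency per-sequence mutation frequencies in `[0, 1]`
#' @return factor with levels `germline`, `low`, `high`
#' @export
classify_shm <- function(mutation_frequency) {
  if (any(is.na(mutation_frequency)) || any(mutation_frequency < 0) ||
      any(mutation_frequency > 1))
    stop("mutation frequency must be in [0, 1]", call. = FALSE)
  cut(mutation_frequency, breaks = c(-Inf, 0, 0.03, Inf),
      labels = c("germline", "low", "high"))
}

ISOTYPE_MAP <- c(IGHM = "IgM", IGHD = "IgD",
                 IGHG1 = "IgG1", IGHG2 = "IgG2", IGHG3 = "IgG3",
                 IGHG4 = "IgG4", IGHA1 = "IgA1", IGHA2 = "IgA2",
                 IGHE = "IgE")

#' Isotype frequency table per cell subtype
#'
#' Maps heavy-chain constant-region gene calls to antibody isotypes
#' (IGHM -> IgM, IGHG1-4 -> IgG1-4, IGHA1/2 -> IgA1/2, IGHD -> IgD,
#' IGHE -> IgE; anything else is counted as `unknown`) and tabulates
#' per-subtype isotype frequencies, each row summing to 1.
#'
#' @param chains AIRR-style `data.frame` with `cell_id` and `c_call`
#'   (heavy chains)
#' @param subtypes named character vector: subtype label per `cell_id`
#' @return matrix subtype x isotype of frequencies; raw counts in attribute
#'   `"counts"`
#' @export
isotype_table <- function(chains, subtypes) {
  ch <- chains[chains$cell_id %in% names(subtypes), , drop = FALSE]
  iso <- ISOTYPE_MAP[ch$c_call]
  iso[is.na(iso)] <- "unknown"
  st <- subtypes[ch$cell_id]
  counts <- table(st, iso)
  freq <- sweep(unclass(counts), 1, pmax(rowSums(counts), 1), "/")
  attr(freq, "counts") <- unclass(counts)
  freq
}

#' V (and J) gene usage frequencies with a between-group test
#'
#' Tabulates per-group gene-call usage frequencies (each group summing to
#' 1) and, when two or more groups are present, reports a chi-square test
#' of homogeneity of usage between groups.
#'
#' @param chains AIRR-style `data.frame`
#' @param groups character vector, one group label per chain row
#' @param gene_col which call to tabulate (`"v_call"` or `"j_call"`)
#' @return list: `frequencies` (group x gene matrix), `counts`,
#'   `chisq_statistic`, `p_value` (NA with a single group)
#' @export
vdj_usage <- function(chains, groups, gene_col = c("v_call", "j_call")) {
  gene_col <- match.arg(gene_col)
  counts <- table(groups, chains[[gene_col]])
  freq <- sweep(unclass(counts), 1, pmax(rowSums(counts), 1), "/")
  stat <- NA_real_; p <- NA_real_
  if (nrow(counts) >= 2L && ncol(counts) >= 2L) {
    ct <- suppressWarnings(stats::chisq.test(counts))
    stat <- unname(ct$statistic); p <- ct$p.value
  } else if (nrow(counts) >= 2L && ncol(counts) == 1L) {
    stat <- 0; p <- 1  # a single gene: usage is identical by construction
  }
  list(frequencies = freq, counts = unclass(counts),
       chisq_statistic = stat, p_value = p)
}

#' Per-patient repertoire summary
#'
#' Groups productive chains into clones within each patient and reports
#' clonality statistics: number of clones, Shannon entropy (bits), Gini
#' index, and the count of expanded clones (> 20 cells).
#'
#' @param chains AIRR-style `data.frame` with a `cell_id` column
#' @param patients named character vector: patient per `cell_id`
#' @param locus primary locus (`"TRB"` or `"IGH"`)
#' @param mode clone definition passed to [group_clones()]
#' @return `data.frame`: `patient`, `n_cells`, `n_clones`,
#'   `shannon_entropy`, `gini_index`, `n_expanded`
#' @export
repertoire_summary <- function(chains, patients, locus = c("TRB", "IGH"),
                               mode = c("cdr3nt", "cdr3nt_vj")) {
  locus <- match.arg(locus); mode <- match.arg(mode)
  ch <- chains[chains$cell_id %in% names(patients), , drop = FALSE]
  pat <- patients[ch$cell_id]
  rows <- lapply(sort(unique(pat)), function(p) {
    ct <- group_clones(ch[pat == p, , drop = FALSE], mode = mode,
                       locus = locus)
    sizes <- ct$clones$n_cells
    if (length(sizes) == 0L)
      return(data.frame(patient = p, n_cells = 0L, n_clones = 0L,
                        shannon_entropy = NA_real_, gini_index = NA_real_,
                        n_expanded = 0L, stringsAsFactors = FALSE))
    data.frame(patient = p, n_cells = sum(sizes),
               n_clones = length(sizes),
               shannon_entropy = shannon_entropy(ct$clones$frequency),
               gini_index = gini_index(sizes),
               n_expanded = sum(classify_expansion(sizes) == "expanded"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
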
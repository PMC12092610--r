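#' Cell quality-control filter
#'
#' Excludes low-quality cells: fewer than `min_genes` detected genes
#' (potential fragments), more than `max_genes` (potential doublets), or a
#' mitochondrial read fraction above `max_mito_frac`. Defaults are the
#' standard 500 / 6000 genes and 5% mitochondrial bounds. Removal counts per
#' criterion are attached as attribute `"qc_stats"`. The filter is
#' idempotent.
#'
#' @param counts genes x cells count matrix (`dgCMatrix` or base matrix)
#'   with gene names and cell barcodes as dimnames
#' @param min_genes,max_genes detected-gene bounds (cells strictly below
#'   `min_genes` or strictly above `max_genes` are removed)
#' @param max_mito_frac maximum mitochondrial read fraction (cells strictly
#'   above are removed)
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#' @return the filtered count matrix
#' @export
qc_filter <- function(counts, min_genes = 500L, max_genes = 6000L,
                      max_mito_frac = 0.05, mito_prefix = "MT-") {
  if (is.null(dim(counts)) || ncol(counts) == 0L || nrow(counts) == 0L)
    stop("counts must be a non-empty genes x cells matrix", call. = FALSE)
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  low <- detected < min_genes
  high <- detected > max_genes
  mt <- mito_frac > max_mito_frac
  keep <- !(low | high | mt)
  out <- counts[, keep, drop = FALSE]
  attr(out, "qc_stats") <- c(
    n_input = ncol(counts), n_low_genes = sum(low), n_high_genes = sum(high),
    n_high_mito = sum(mt), n_removed = sum(!keep), n_retained = sum(keep))
  out
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common library size (default 10,000) and
#' applies `log1p`: `value = ln(1 + count / library_size * scale)`. Columns
#' of `expm1(result)` each sum to `scale`.
#'
#' @param counts genes x cells count matrix; every retained cell must have a
#'   positive library size
#' @param scale target library size
#' @return normalized matrix (sparse if the input was)
#' @export
normalize_log <- function(counts, scale = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib <= 0))
    stop("cells with zero library size present; run qc_filter first",
         call. = FALSE)
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale / lib)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
  } else {
    out <- log1p(sweep(counts, 2, scale / lib, "*"))
  }
  out
}

#' Derive subtype signatures from reference expression profiles
#'
#' For each reference subtype, genes are ranked by the contrast between
#' their mean expression in that subtype and their mean across all other
#' subtypes (descending; ties broken by gene name), and the top `top_k`
#' (default 250) most subtype-specific genes form the signature.
#'
#' @param reference gene x subtype matrix (or data.frame) of mean expression
#' @param top_k signature size per subtype
#' @return a list of class `signature_set`: one character vector of genes
#'   per subtype, with the reference universe size in attribute
#'   `"universe_size"` and the universe itself in `"universe"`
#' @export
derive_subtype_signatures <- function(reference, top_k = 250L) {
  reference <- as.matrix(reference)
  if (ncol(reference) < 2L)
    stop("at least two reference subtypes are required", call. = FALSE)
  if (top_k > nrow(reference)) {
    warning("top_k exceeds the reference gene universe; truncating")
    top_k <- nrow(reference)
  }
  genes <- rownames(reference)
  sigs <- lapply(colnames(reference), function(st) {
    contrast <- reference[, st] -
      rowMeans(reference[, colnames(reference) != st, drop = FALSE])
    ord <- order(-contrast, genes)
    genes[ord][seq_len(top_k)]
  })
  names(sigs) <- colnames(reference)
  structure(sigs, class = "signature_set",
            universe_size = nrow(reference), universe = genes)
}

#' One-sided Fisher's exact test for marker/signature overlap
#'
#' Tests enrichment of the overlap between a cluster's marker genes and a
#' subtype signature against a gene universe, via the one-sided
#' (`greater`) Fisher's exact test on the 2x2 table (overlap, markers only,
#' signature only, neither).
#'
#' @param markers character vector of cluster marker genes
#' @param signature character vector of signature genes
#' @param universe_size size of the gene universe containing both sets
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#' @return the p-value
#' @export
fisher_overlap <- function(markers, signature, universe_size,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (universe_size < 1L) stop("empty gene universe", call. = FALSE)
  markers <- unique(markers); signature <- unique(signature)
  n11 <- length(intersect(markers, signature))
  n12 <- length(markers) - n11
  n21 <- length(signature) - n11
  n22 <- universe_size - n11 - n12 - n21
  if (n22 < 0)
    stop("marker and signature sets exceed the stated universe", call. = FALSE)
  stats::fisher.test(matrix(c(n11, n21, n12, n22), nrow = 2L),
                     alternative = alternative)$p.value
}

#' Assign a subtype identity to each cluster by marker overlap
#'
#' Each cluster is labeled with the subtype whose signature overlaps its
#' marker set most significantly (smallest one-sided Fisher p); ties are
#' broken by larger overlap, then subtype name order, and flagged
#' ambiguous. All candidate p-values are attached as attribute
#' `"p_matrix"`.
#'
#' @param marker_sets named list: marker gene vector per cluster (each
#'   non-empty)
#' @param signatures a [derive_subtype_signatures()] result (or named list
#'   of gene vectors)
#' @param universe_size gene universe size; defaults to the signature set's
#' @return `data.frame`: `cluster`, `subtype`, `p_value`, `overlap`,
#'   `ambiguous`
#' @export
assign_cluster_identity <- function(marker_sets, signatures,
                                    universe_size =
                                      attr(signatures, "universe_size")) {
  stopifnot(length(marker_sets) > 0, length(signatures) > 0)
  if (any(lengths(marker_sets) == 0L))
    stop("every cluster needs at least one marker gene", call. = FALSE)
  subtypes <- names(signatures)
  pm <- matrix(NA_real_, nrow = length(marker_sets),
               ncol = length(subtypes),
               dimnames = list(names(marker_sets), subtypes))
  ov <- pm
  for (cl in names(marker_sets)) {
    for (st in subtypes) {
      pm[cl, st] <- fisher_overlap(marker_sets[[cl]], signatures[[st]],
                                   universe_size)
      ov[cl, st] <- length(intersect(marker_sets[[cl]], signatures[[st]]))
    }
  }
  res <- lapply(names(marker_sets), function(cl) {
    p <- pm[cl, ]
    cand <- which(p == min(p))
    amb <- FALSE
    if (length(cand) > 1L) {
      o <- ov[cl, cand]
      cand <- cand[o == max(o)]
      if (length(cand) > 1L) amb <- TRUE
      cand <- cand[order(subtypes[cand])][1L]
    }
    data.frame(cluster = cl, subtype = subtypes[cand],
               p_value = unname(p[cand]), overlap = unname(ov[cl, cand]),
               ambiguous = amb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "p_matrix") <- pm
  out
}

#' Control-binned gene module score
#'
#' Scores each cell for a gene module as the mean normalized expression of
#' the module genes minus the mean of an expression-matched control set:
#' genes are binned into `n_bins` by average expression across cells, and
#' for each module gene up to `n_ctrl` control genes are drawn (without
#' replacement within its bin; genes recur freely across bins) from the
#' gene's bin. The control set is the union of the draws. Deterministic
#' under a fixed `seed`; the caller's RNG state is untouched.
#'
#' @param expr normalized genes x cells matrix
#' @param module character vector of module genes (genes absent from `expr`
#'   are dropped with a warning)
#' @param n_bins number of average-expression bins (default 24)
#' @param n_ctrl control genes drawn per module gene (default 100)
#' @param seed RNG seed for the control draw
#' @return named numeric vector: score per cell
#' @export
module_score <- function(expr, module, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  present <- module %in% rownames(expr)
  if (!all(present))
    warning(sprintf("%d module gene(s) absent from the matrix; dropped",
                    sum(!present)))
  module <- module[present]
  if (length(module) == 0L)
    stop("module is empty after filtering against the matrix", call. = FALSE)
  avg <- Matrix::rowMeans(expr)
  n_bins <- min(n_bins, nrow(expr))
  bins <- if (n_bins == 1L) rep(1L, nrow(expr))
          else as.integer(cut(rank(avg, ties.method = "first"),
                              breaks = n_bins))
  names(bins) <- rownames(expr)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(module, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      sample(pool, min(n_ctrl, length(pool)))
    }), use.names = FALSE))
  })
  mod_mean <- Matrix::colMeans(expr[module, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl, , drop = FALSE])
  mod_mean - ctrl_mean
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test between group A and group B
#' cells, Bonferroni adjustment across tested genes, and a log fold change
#' `log(mean(expm1(A)) + 1) - log(mean(expm1(B)) + 1)` (natural log by
#' default). A gene is flagged differentially expressed when its unadjusted
#' p-value is below `p_threshold` and its log fold change exceeds
#' `lfc_threshold` (`direction = "up"`, used for marker derivation) or its
#' absolute value does (`direction = "both"`). Genes constant across both
#' groups get p = 1.
#'
#' @param expr normalized genes x cells matrix
#' @param cells_a,cells_b barcodes (or column indices) of the two groups
#' @param p_threshold unadjusted p-value cut for the DE flag (default 0.05)
#' @param lfc_threshold log fold-change cut for the DE flag (default 0.1)
#' @param direction `"up"` or `"both"`
#' @param log_base base of the reported fold change (default `exp(1)`)
#' @return `data.frame`: `gene`, `log_fc`, `p_value`, `p_adjusted`, `is_de`
#' @export
differential_expression <- function(expr, cells_a, cells_b,
                                    p_threshold = 0.05,
                                    lfc_threshold = 0.1,
                                    direction = c("up", "both"),
                                    log_base = exp(1)) {
  direction <- match.arg(direction)
  if (length(cells_a) == 0L || length(cells_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  a <- as.matrix(expr[, cells_a, drop = FALSE])
  b <- as.matrix(expr[, cells_b, drop = FALSE])
  genes <- rownames(expr)
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (max(x, y) == min(x, y)) return(1)
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = FALSE)$p.value
  }, numeric(1))
  lfc <- (log(rowMeans(expm1(a)) + 1) - log(rowMeans(expm1(b)) + 1)) /
    log(log_base)
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  is_de <- p < p_threshold &
    (if (direction == "up") lfc > lfc_threshold
     else abs(lfc) > lfc_threshold)
  data.frame(gene = genes, log_fc = unname(lfc), p_value = p,
             p_adjusted = p_adj, is_de = is_de, stringsAsFactors = FALSE)
}

#' Derive per-cluster marker genes by one-vs-rest differential expression
#'
#' Runs [differential_expression()] for each cluster against all other
#' cells and keeps the up-regulated genes passing the DE thresholds.
#'
#' @param expr normalized genes x cells matrix
#' @param clusters named cluster labels per cell (names = barcodes), or an
#'   unnamed vector aligned with columns
#' @param ... passed to [differential_expression()]
#' @return named list: marker gene vector per cluster
#' @export
cluster_markers <- function(expr, clusters, ...) {
  if (is.null(names(clusters))) names(clusters) <- colnames(expr)
  clusters <- clusters[colnames(expr)]
  out <- lapply(sort(unique(clusters)), function(cl) {
    de <- differential_expression(expr, names(clusters)[clusters == cl],
                                  names(clusters)[clusters != cl], ...)
    de$gene[de$is_de]
  })
  names(out) <- sort(unique(clusters))
  out
}
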
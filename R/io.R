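# Interchange formats: FASTQ pair, MatrixMarket counts, commented TSVs.
# Every writer is paired with a reader that parses its output losslessly.

TSV_SCHEMA_VERSION <- "1"

#' Write a table as tab-separated values with a commented schema header
#'
#' @param df data.frame
#' @param path output path
#' @param comment optional extra comment text (generation parameters)
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("#gotcells tsv schema=%s", TSV_SCHEMA_VERSION)
  if (!is.null(comment)) hdr <- paste0(hdr, " ", comment)
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' Literal `"."` fields are read as `NA`.
#' @param path input path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Write a paired amplicon FASTQ (R1 = barcode + UMI, R2 = amplicon)
#'
#' Read 1 carries the cell barcode concatenated with the UMI; read 2 is the
#' wild-type or mutant amplicon context according to each read's locus
#' base. Qualities are constant dummies; the pipeline never uses them.
#'
#' @param reads amplicon read `data.frame` (`read_id`, `cell_barcode`,
#'   `umi`, `locus_base`)
#' @param r1_path,r2_path output FASTQ paths
#' @param locus a [locus_spec()]
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path, locus = locus_spec()) {
  r1 <- paste0(reads$cell_barcode, reads$umi)
  r2 <- ifelse(reads$locus_base == "MUT", locus$mut_context,
               locus$wt_context)
  ids <- reads$read_id %||% sprintf("read%07d", seq_len(nrow(reads)))
  for (side in list(list(seq = r1, path = r1_path),
                    list(seq = r2, path = r2_path))) {
    x <- Biostrings::DNAStringSet(side$seq)
    names(x) <- ids
    q <- Biostrings::PhredQuality(strrep("I", nchar(side$seq)))
    Biostrings::writeXStringSet(x, side$path, format = "fastq",
                                qualities = q)
  }
  invisible(c(r1_path, r2_path))
}

#' Read a paired amplicon FASTQ into an amplicon read table
#'
#' Read 1 is split into the cell barcode (first `barcode_length` bases) and
#' the UMI (next `umi_length`); read 2's base at the locus variant offset is
#' classified against the expected wild-type and mutant alleles (anything
#' else is `OTHER`).
#'
#' @param r1_path,r2_path FASTQ paths, records paired in order
#' @param locus a [locus_spec()]
#' @param barcode_length,umi_length read-1 layout
#' @return `data.frame`: `read_id`, `cell_barcode`, `umi`, `locus_base`
#' @export
read_fastq_pair <- function(r1_path, r2_path, locus = locus_spec(),
                            barcode_length = 16L, umi_length = 12L) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2))
    stop(sprintf("unpaired FASTQ records: %d in R1 vs %d in R2",
                 length(r1), length(r2)), call. = FALSE)
  need <- barcode_length + umi_length
  bad <- which(Biostrings::width(r1) < need)
  if (length(bad))
    stop(sprintf("R1 record %d is shorter than barcode+UMI (%d bases)",
                 bad[1L], need), call. = FALSE)
  r1c <- as.character(r1)
  base <- substr(as.character(r2), locus$variant_offset,
                 locus$variant_offset)
  locus_base <- ifelse(base == locus$mut_base, "MUT",
                       ifelse(base == locus$wt_base, "WT", "OTHER"))
  ids <- names(r1) %||% sprintf("read%07d", seq_along(r1))
  data.frame(
    read_id = sub(" .*", "", ids),
    cell_barcode = substr(r1c, 1L, barcode_length),
    umi = substr(r1c, barcode_length + 1L, need),
    locus_base = locus_base, stringsAsFactors = FALSE)
}

#' Write a count matrix as MatrixMarket plus gene and barcode TSVs
#'
#' @param counts genes x cells matrix with dimnames
#' @param mtx_path,genes_path,barcodes_path output paths
#' @export
write_count_matrix <- function(counts, mtx_path, genes_path,
                               barcodes_path) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, mtx_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(mtx_path)
}

#' Read a MatrixMarket count matrix with gene and barcode lists
#'
#' @param mtx_path,genes_path,barcodes_path input paths
#' @return genes x cells `dgCMatrix` with dimnames
#' @export
read_count_matrix <- function(mtx_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop(sprintf(
      "matrix dimensions %d x %d do not match %d genes / %d barcodes",
      nrow(m), ncol(m), length(genes), length(barcodes)), call. = FALSE)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("empty count matrix", call. = FALSE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Read gene sets from a two-column TSV (set_name, gene)
#'
#' @param path input TSV
#' @return named list of gene vectors
#' @export
read_gene_sets <- function(path) {
  df <- read_tsv(path)
  split(df$gene, df$set_name)
}

#' Bundled gene-module definitions
#'
#' The module gene lists shipped with the package: the 10 HLA class II
#' genes, the 3 alarmin-related S100A genes, and the 12 T-cell exhaustion
#' genes used for module scoring.
#'
#' @return named list of gene vectors
#' @export
module_definitions <- function() {
  read_gene_sets(system.file("extdata", "module_definitions.tsv",
                             package = "gotcells", mustWork = TRUE))
}

#' Materialize a simulated cohort bundle on disk
#'
#' Writes every component of a [simulate_cohort()] bundle in its
#' interchange format: amplicon FASTQ pair, tagged-read TSV, MatrixMarket
#' counts with gene/barcode lists, metadata, reference profiles, receptor
#' chains, and the ground truth (for validation only).
#'
#' @param bundle a [simulate_cohort()] result
#' @param config the [sim_config()] used
#' @param dir output directory (created if needed)
#' @return named character vector of paths
#' @export
write_cohort <- function(bundle, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(
    r1 = file.path(dir, "amplicon_R1.fastq"),
    r2 = file.path(dir, "amplicon_R2.fastq"),
    tagged = file.path(dir, "tagged_reads.tsv"),
    mtx = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    reference = file.path(dir, "reference_profiles.tsv"),
    repertoire = file.path(dir, "receptor_chains.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    clone_truth = file.path(dir, "clone_truth.tsv"),
    markers = file.path(dir, "marker_truth.tsv"),
    config = file.path(dir, "sim_config.json"))
  seed_comment <- sprintf("seed=%d", config$seed)
  write_fastq_pair(bundle$amplicon_reads, p[["r1"]], p[["r2"]],
                   config$locus)
  write_tsv(bundle$tagged_reads, p[["tagged"]], seed_comment)
  write_count_matrix(bundle$counts, p[["mtx"]], p[["genes"]],
                     p[["barcodes"]])
  write_tsv(bundle$metadata, p[["metadata"]], seed_comment)
  ref <- data.frame(gene = rownames(bundle$reference),
                    bundle$reference, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(ref, p[["reference"]], seed_comment)
  write_tsv(bundle$repertoire, p[["repertoire"]], seed_comment)
  write_tsv(bundle$truth, p[["truth"]], seed_comment)
  write_tsv(bundle$clone_truth, p[["clone_truth"]], seed_comment)
  write_tsv(bundle$markers, p[["markers"]], seed_comment)
  writeLines(sim_config_json(config), p[["config"]])
  p
}

#' Serialize a simulation configuration to JSON
#' @param config a [sim_config()]
#' @return JSON string
#' @export
sim_config_json <- function(config) {
  x <- unclass(config)
  x$locus <- unclass(x$locus)
  # named atomic vectors must become objects, not arrays, to keep names
  for (f in c("cell_type_proportions", "mutant_fraction_by_type",
              "b_subtype_proportions"))
    x[[f]] <- as.list(x[[f]])
  x$shm_by_subtype <- lapply(x$shm_by_subtype, as.list)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a simulation configuration from JSON
#' @param path JSON path written by [sim_config_json()]
#' @return a [sim_config()]
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  locus <- locus_spec(wt_context = x$locus$wt_context,
                      variant_offset = x$locus$variant_offset,
                      mut_base = x$locus$mut_base)
  shm <- lapply(x$shm_by_subtype, function(v) unlist(v))
  sim_config(
    n_patients = x$n_patients,
    n_cells_per_patient = x$n_cells_per_patient,
    cell_type_proportions = unlist(x$cell_type_proportions),
    mutant_fraction_by_type = unlist(x$mutant_fraction_by_type),
    nk_pseudotime_decay = x$nk_pseudotime_decay,
    amplicon_capture_rate = x$amplicon_capture_rate,
    transcriptome_capture_rate = x$transcriptome_capture_rate,
    reads_per_umi_mean = x$reads_per_umi_mean,
    per_base_error_rate = x$per_base_error_rate,
    umi_error_rate = x$umi_error_rate,
    barcode_length = x$barcode_length,
    umi_length = x$umi_length,
    umis_per_cell_mean = x$umis_per_cell_mean,
    missing_tag_rate = x$missing_tag_rate,
    clone_size_alpha = x$clone_size_alpha,
    shm_by_subtype = shm,
    b_subtype_proportions = unlist(x$b_subtype_proportions),
    marker_fold_change = x$marker_fold_change,
    n_genes = x$n_genes,
    markers_per_type = x$markers_per_type,
    mean_library_size = x$mean_library_size,
    seed = x$seed, locus = locus)
}
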
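#' Run the full genotyping and analysis pipeline on a simulated cohort
#'
#' Orchestrates every stage end to end: cohort simulation (written to
#' `out_dir/sim/` in interchange formats), amplicon genotyping from the
#' FASTQ pair, transcriptome-read genotyping from the tagged-read table,
#' cell QC / normalization / signature-based cluster annotation / module
#' scoring, assembly of the per-cell table, genotype-fraction and
#' trajectory curves, and repertoire statistics. All randomness derives
#' from the configuration seed, split deterministically per stage, so
#' reruns with the same configuration are byte-identical; a JSON manifest
#' records package version, seed, parameters and input checksums.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param seed optional integer overriding `config$seed`
#' @param top_k signature size used for cluster annotation (capped at the
#'   reference universe)
#' @param min_cells_frequency analysis floor of
#'   [normalized_mutant_frequency()]
#' @param n_bins pseudotime bins for trajectory curves
#' @return (invisibly) a list with the principal tables: `cells`,
#'   `got_genotypes`, `sniffer_genotypes`, `cluster_identity`,
#'   `mutant_frequency`, `nk_curve`, `repertoire_t`, `repertoire_b`,
#'   `isotypes`, `manifest`
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, top_k = 250L,
                         min_cells_frequency = 100L, n_bins = 20L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    cfg <- unclass(config)
    cfg$seed <- as.integer(seed)
    config <- structure(cfg, class = "sim_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out_dir, "sim")

  bundle <- simulate_cohort(config, out_dir = sim_dir)
  paths <- bundle$paths

  # --- amplicon genotyping (from the written FASTQ pair) ---------------
  amp_reads <- read_fastq_pair(paths[["r1"]], paths[["r2"]], config$locus,
                               config$barcode_length, config$umi_length)
  got <- genotype_got(amp_reads)
  write_tsv(got$umi_consensus, file.path(out_dir, "got_umi_consensus.tsv"))
  write_tsv(got$cell_genotypes, file.path(out_dir, "got_cell_genotypes.tsv"))

  # --- transcriptome-read genotyping -----------------------------------
  sniff <- genotype_sniffer(read_tsv(paths[["tagged"]]))
  write_tsv(sniff$cell_genotypes,
            file.path(out_dir, "sniffer_cell_genotypes.tsv"))

  # --- QC, normalization, cluster annotation, module scores ------------
  counts <- read_count_matrix(paths[["mtx"]], paths[["genes"]],
                              paths[["barcodes"]])
  counts <- qc_filter(counts)
  expr <- normalize_log(counts)
  metadata <- read_tsv(paths[["metadata"]])
  rownames(metadata) <- metadata$barcode
  metadata <- metadata[colnames(expr), , drop = FALSE]

  ref_df <- read_tsv(paths[["reference"]])
  reference <- as.matrix(ref_df[, -1, drop = FALSE])
  rownames(reference) <- ref_df$gene
  universe <- intersect(rownames(expr), rownames(reference))
  sigs <- derive_subtype_signatures(reference[universe, , drop = FALSE],
                                    top_k = min(top_k, length(universe)))
  clusters <- stats::setNames(metadata$cluster, metadata$barcode)
  mk <- cluster_markers(expr[universe, , drop = FALSE], clusters)
  mk <- mk[lengths(mk) > 0L]
  ident <- assign_cluster_identity(mk, sigs)
  write_tsv(ident, file.path(out_dir, "cluster_identity.tsv"))
  type_of_cluster <- stats::setNames(ident$subtype, ident$cluster)

  score_cols <- list()
  for (st in names(sigs)) {
    score_cols[[paste0("score_", st)]] <-
      module_score(expr, sigs[[st]][seq_len(min(50L, length(sigs[[st]])))],
                   seed = config$seed + 10L)
  }

  # --- per-cell table ---------------------------------------------------
  geno <- stats::setNames(got$cell_genotypes$genotype,
                          got$cell_genotypes$cell_barcode)
  cells <- data.frame(
    barcode = metadata$barcode, patient = metadata$patient,
    cluster = metadata$cluster,
    cell_type = unname(type_of_cluster[metadata$cluster]),
    pseudotime = metadata$pseudotime,
    genotype = ifelse(is.na(geno[metadata$barcode]), "UNASSIGNED",
                      geno[metadata$barcode]),
    stringsAsFactors = FALSE)
  for (nm in names(score_cols))
    cells[[nm]] <- unname(score_cols[[nm]][cells$barcode])
  write_tsv(cells, file.path(out_dir, "cells.tsv"))

  # --- trajectory summaries --------------------------------------------
  freq <- normalized_mutant_frequency(cells,
                                      min_cells = min_cells_frequency)
  write_tsv(freq, file.path(out_dir, "mutant_frequency.tsv"),
            sprintf("normalization=%s", attr(freq, "normalization")))
  nk_curve <- NULL
  if ("NK" %in% cells$cell_type) {
    nk_curve <- genotype_ratio_along_pseudotime(cells, "NK",
                                                n_bins = n_bins)
    write_tsv(nk_curve, file.path(out_dir, "nk_genotype_curve.tsv"))
  }

  # --- repertoire -------------------------------------------------------
  chains <- read_tsv(paths[["repertoire"]])
  patients <- stats::setNames(cells$patient, cells$barcode)
  rep_t <- repertoire_summary(chains, patients, locus = "TRB")
  rep_b <- repertoire_summary(chains, patients, locus = "IGH")
  write_tsv(rep_t, file.path(out_dir, "repertoire_trb.tsv"))
  write_tsv(rep_b, file.path(out_dir, "repertoire_igh.tsv"))
  subtype_labels <- stats::setNames(cells$cell_type, cells$barcode)
  b_chains <- chains[chains$locus == "IGH" & chains$productive, ,
                     drop = FALSE]
  isotypes <- isotype_table(b_chains, subtype_labels)
  write_tsv(as.data.frame.matrix(isotypes),
            file.path(out_dir, "isotype_table.tsv"))

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    package = "gotcells",
    version = as.character(utils::packageVersion("gotcells")),
    seed = config$seed,
    parameters = jsonlite::fromJSON(sim_config_json(config)),
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(unname(paths))), basename(unname(paths)))),
    n_cells_simulated = nrow(bundle$truth),
    n_cells_qc_retained = ncol(expr),
    n_cells_got_genotyped = nrow(got$cell_genotypes),
    n_cells_sniffer_genotyped = nrow(sniff$cell_genotypes))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))

  invisible(list(cells = cells, got_genotypes = got$cell_genotypes,
                 sniffer_genotypes = sniff$cell_genotypes,
                 cluster_identity = ident, mutant_frequency = freq,
                 nk_curve = nk_curve, repertoire_t = rep_t,
                 repertoire_b = rep_b, isotypes = isotypes,
                 manifest = manifest))
}
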
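#' Targeted-locus specification
#'
#' Describes the amplicon that spans the variant: the wild-type and mutant
#' sequence contexts of read 2 and the 1-based offset of the variant base
#' within them. The genotyper classifies each read 2 by the base observed at
#' `variant_offset`: the wild-type allele, the mutant allele, or anything
#' else (`OTHER`).
#'
#' The default models a hemizygous X-linked T>C missense variant in a 60-nt
#' amplicon, with the variant at position 31.
#'
#' @param wt_context wild-type amplicon sequence (read 2)
#' @param variant_offset 1-based position of the variant within read 2
#' @param mut_base mutant allele at that position
#' @return an object of class `locus_spec`
#' @export
locus_spec <- function(wt_context = NULL, variant_offset = 31L, mut_base = "C") {
  if (is.null(wt_context)) {
    # fixed synthetic amplicon context; variant base T at position 31
    wt_context <- paste0(
      "ACGGATTCCAGTGTCAAGGCTGTTACCCTA", "T",
      "GACGTTCTGAAGAACTTGGTTCTGGGATC"
    )
  }
  variant_offset <- as.integer(variant_offset)
  wt_base <- substr(wt_context, variant_offset, variant_offset)
  if (variant_offset < 1L || variant_offset > nchar(wt_context))
    config_stop("variant_offset", "outside the amplicon context")
  if (identical(wt_base, mut_base))
    config_stop("mut_base", "equals the wild-type base at the variant offset")
  mut_context <- wt_context
  substr(mut_context, variant_offset, variant_offset) <- mut_base
  structure(
    list(wt_context = wt_context, mut_context = mut_context,
         variant_offset = variant_offset, wt_base = wt_base,
         mut_base = mut_base),
    class = "locus_spec"
  )
}

#' Simulation configuration for a synthetic genotyping cohort
#'
#' Bundles every tunable of the cohort simulator. Defaults emulate the study
#' design the pipeline targets: nine patients carrying a hemizygous somatic
#' mutation whose mutant fraction is high in myeloid cells, intermediate and
#' declining along pseudotime in NK cells, and zero in T and B cells; an
#' amplicon assay capturing ~17% of cells and transcriptome reads covering
#' ~5%; PCR duplication with occasional 1-edit UMI corruption; a
#' marker-structured count matrix; power-law clone sizes; and B-cell
#' subtype-dependent somatic hypermutation.
#'
#' @param n_patients number of patients
#' @param n_cells_per_patient cells per patient
#' @param cell_type_proportions named fractions per cell type, summing to 1
#' @param mutant_fraction_by_type named mutant-cell fraction per cell type,
#'   each in `[0, 1]`; for the NK lineage this is the fraction at
#'   pseudotime 0
#' @param nk_pseudotime_decay decline rate (logit units per unit pseudotime)
#'   of the NK mutant probability
#' @param amplicon_capture_rate probability a cell is captured by the
#'   genotyping amplicon (default 0.17)
#' @param transcriptome_capture_rate probability a cell has transcriptome
#'   reads covering the variant (default 0.05)
#' @param reads_per_umi_mean mean extra PCR duplicates per molecule; each UMI
#'   emits `1 + Poisson(reads_per_umi_mean)` reads
#' @param per_base_error_rate probability a read reports the opposite allele
#' @param umi_error_rate probability a duplicate read carries a one-edit
#'   UMI corruption
#' @param barcode_length,umi_length cell-barcode and UMI lengths (16, 12)
#' @param umis_per_cell_mean mean number of captured molecules per captured
#'   cell; every captured cell emits at least one
#' @param missing_tag_rate fraction of transcriptome reads lacking a CB or
#'   UB tag
#' @param clone_size_alpha power-law (zeta) exponent of the clone-size
#'   distribution, > 1
#' @param shm_by_subtype named list of `c(mean, dispersion)` of the beta
#'   distribution of per-sequence mutation frequency per B subtype
#' @param b_subtype_proportions named fractions of B subtypes
#' @param marker_fold_change expression fold change of a marker gene in its
#'   own cell type
#' @param n_genes genes in the simulated count matrix
#' @param markers_per_type marker genes planted per cell type
#' @param mean_library_size mean total UMI count per cell
#' @param seed integer seed; together with the configuration it fully
#'   determines every simulated output
#' @param locus a [locus_spec()]
#' @return an object of class `sim_config`
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 9L,
                       n_cells_per_patient = 1000L,
                       cell_type_proportions = c(T = 0.50, B = 0.15,
                                                 Mono = 0.20, NK = 0.10,
                                                 DC = 0.05),
                       mutant_fraction_by_type = c(T = 0, B = 0, Mono = 0.4,
                                                   NK = 0.2, DC = 0.4),
                       nk_pseudotime_decay = 2,
                       amplicon_capture_rate = 0.17,
                       transcriptome_capture_rate = 0.05,
                       reads_per_umi_mean = 3,
                       per_base_error_rate = 0.01,
                       umi_error_rate = 0.05,
                       barcode_length = 16L,
                       umi_length = 12L,
                       umis_per_cell_mean = 1.5,
                       missing_tag_rate = 0.05,
                       clone_size_alpha = 2.5,
                       shm_by_subtype = list(
                         naive_B = c(mean = 0, dispersion = 40),
                         memory_B = c(mean = 0.02, dispersion = 40),
                         plasmablast = c(mean = 0.06, dispersion = 40)),
                       b_subtype_proportions = c(naive_B = 0.50,
                                                 memory_B = 0.35,
                                                 plasmablast = 0.15),
                       marker_fold_change = 4,
                       n_genes = 2000L,
                       markers_per_type = 25L,
                       mean_library_size = 3000,
                       seed = 1L,
                       locus = locus_spec()) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_cells_per_patient = as.integer(n_cells_per_patient),
    cell_type_proportions = cell_type_proportions,
    mutant_fraction_by_type = mutant_fraction_by_type,
    nk_pseudotime_decay = nk_pseudotime_decay,
    amplicon_capture_rate = amplicon_capture_rate,
    transcriptome_capture_rate = transcriptome_capture_rate,
    reads_per_umi_mean = reads_per_umi_mean,
    per_base_error_rate = per_base_error_rate,
    umi_error_rate = umi_error_rate,
    barcode_length = as.integer(barcode_length),
    umi_length = as.integer(umi_length),
    umis_per_cell_mean = umis_per_cell_mean,
    missing_tag_rate = missing_tag_rate,
    clone_size_alpha = clone_size_alpha,
    shm_by_subtype = shm_by_subtype,
    b_subtype_proportions = b_subtype_proportions,
    marker_fold_change = marker_fold_change,
    n_genes = as.integer(n_genes),
    markers_per_type = as.integer(markers_per_type),
    mean_library_size = mean_library_size,
    seed = as.integer(seed),
    locus = locus
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1L) config_stop("n_patients", "must be >= 1")
  if (cfg$n_cells_per_patient < 1L)
    config_stop("n_cells_per_patient", "must be >= 1")
  p <- cfg$cell_type_proportions
  if (is.null(names(p)) || any(!nzchar(names(p))))
    config_stop("cell_type_proportions", "must be a named vector")
  check_fraction(p, "cell_type_proportions")
  if (abs(sum(p) - 1) > 1e-9)
    config_stop("cell_type_proportions", "must sum to 1 (within 1e-9)")
  m <- cfg$mutant_fraction_by_type
  check_fraction(m, "mutant_fraction_by_type")
  if (!all(names(p) %in% names(m)))
    config_stop("mutant_fraction_by_type",
                "must name every cell type in cell_type_proportions")
  if (!is.numeric(cfg$nk_pseudotime_decay) || cfg$nk_pseudotime_decay < 0)
    config_stop("nk_pseudotime_decay", "must be a rate >= 0")
  check_fraction(cfg$amplicon_capture_rate, "amplicon_capture_rate")
  check_fraction(cfg$transcriptome_capture_rate, "transcriptome_capture_rate")
  check_fraction(cfg$per_base_error_rate, "per_base_error_rate")
  check_fraction(cfg$umi_error_rate, "umi_error_rate")
  check_fraction(cfg$missing_tag_rate, "missing_tag_rate")
  if (cfg$reads_per_umi_mean <= 0)
    config_stop("reads_per_umi_mean", "must be positive")
  if (cfg$umis_per_cell_mean < 1)
    config_stop("umis_per_cell_mean", "must be >= 1 (every captured cell emits a molecule)")
  if (cfg$barcode_length < 1L) config_stop("barcode_length", "must be >= 1")
  if (cfg$umi_length < 1L) config_stop("umi_length", "must be >= 1")
  if (cfg$clone_size_alpha <= 1)
    config_stop("clone_size_alpha", "power-law exponent must be > 1")
  bp <- cfg$b_subtype_proportions
  check_fraction(bp, "b_subtype_proportions")
  if (abs(sum(bp) - 1) > 1e-9)
    config_stop("b_subtype_proportions", "must sum to 1")
  if (!all(names(bp) %in% names(cfg$shm_by_subtype)))
    config_stop("shm_by_subtype", "must name every B subtype")
  for (s in names(cfg$shm_by_subtype)) {
    v <- cfg$shm_by_subtype[[s]]
    if (length(v) < 2L || v[["mean"]] < 0 || v[["mean"]] > 1 || v[["dispersion"]] <= 0)
      config_stop("shm_by_subtype",
                  sprintf("subtype '%s' needs mean in [0,1] and dispersion > 0", s))
  }
  if (cfg$marker_fold_change <= 0)
    config_stop("marker_fold_change", "must be positive")
  if (cfg$n_genes < 10L) config_stop("n_genes", "must be >= 10")
  if (cfg$markers_per_type * length(p) + 13L > cfg$n_genes)
    config_stop("markers_per_type", "marker genes exceed the gene universe")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cohort simulation configuration\n")
  cat(sprintf("  %d patients x %d cells, seed %d\n",
              x$n_patients, x$n_cells_per_patient, x$seed))
  cat("  cell types:",
      paste(sprintf("%s=%.2f", names(x$cell_type_proportions),
                    x$cell_type_proportions), collapse = " "), "\n")
  cat("  mutant fractions:",
      paste(sprintf("%s=%.2f", names(x$mutant_fraction_by_type),
                    x$mutant_fraction_by_type), collapse = " "), "\n")
  cat(sprintf("  capture: amplicon %.2f, transcriptome %.2f\n",
              x$amplicon_capture_rate, x$transcriptome_capture_rate))
  invisible(x)
}
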
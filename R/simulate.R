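#' Simulate per-cell ground truth for a cohort
#'
#' Draws, per patient, cell types from the configured proportions, a
#' pseudotime in `[0, 1]` for every cell, and a true genotype. For the NK
#' lineage the mutant probability declines along pseudotime on the logit
#' scale: `p(t) = plogis(qlogis(p0) - decay * t)`, where `p0` is the
#' configured NK mutant fraction; all other lineages use their configured
#' fraction as a constant probability. B cells additionally receive a B
#' subtype driving somatic-hypermutation levels downstream.
#'
#' @param config a [sim_config()]
#' @return a `data.frame` with one row per cell: `barcode`, `patient`,
#'   `cell_type`, `b_subtype` (NA outside the B lineage), `pseudotime`,
#'   `genotype` (`"MUT"`/`"WT"`); marker-gene membership is attached as
#'   attribute `"markers"` once counts are simulated
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_total <- config$n_patients * config$n_cells_per_patient
    types <- names(config$cell_type_proportions)
    cell_type <- sample(types, n_total, replace = TRUE,
                        prob = config$cell_type_proportions)
    patient <- rep(sprintf("P%02d", seq_len(config$n_patients)),
                   each = config$n_cells_per_patient)
    barcode <- rand_dna_unique(n_total, config$barcode_length)
    pseudotime <- stats::runif(n_total)
    p_mut <- config$mutant_fraction_by_type[cell_type]
    nk <- cell_type == "NK"
    if (any(nk)) {
      p0 <- config$mutant_fraction_by_type[["NK"]]
      p_mut[nk] <- stats::plogis(stats::qlogis(p0) -
                                   config$nk_pseudotime_decay * pseudotime[nk])
      if (p0 == 0) p_mut[nk] <- 0
    }
    genotype <- ifelse(stats::runif(n_total) < p_mut, "MUT", "WT")
    b_subtype <- rep(NA_character_, n_total)
    bcell <- cell_type == "B"
    if (any(bcell)) {
      b_subtype[bcell] <- sample(names(config$b_subtype_proportions),
                                 sum(bcell), replace = TRUE,
                                 prob = config$b_subtype_proportions)
    }
    data.frame(barcode = barcode, patient = patient, cell_type = cell_type,
               b_subtype = b_subtype, pseudotime = pseudotime,
               genotype = genotype, stringsAsFactors = FALSE)
  })
}

#' Simulate targeted amplicon reads for a cohort
#'
#' Each cell is captured with probability `amplicon_capture_rate`. A captured
#' cell emits `1 + Poisson(umis_per_cell_mean - 1)` molecules (UMIs), and
#' each molecule emits `1 + Poisson(reads_per_umi_mean)` reads, so every
#' captured molecule is observed at least once. Duplicate reads (beyond the
#' first of a molecule) carry a one-substitution UMI corruption with
#' probability `umi_error_rate`; each read reports the opposite allele with
#' probability `per_base_error_rate`.
#'
#' @param truth ground-truth table from [simulate_ground_truth()]
#' @param config a [sim_config()]
#' @return a `data.frame` of amplicon reads: `read_id`, `cell_barcode`,
#'   `umi`, `locus_base` (`"WT"`/`"MUT"`); the set of captured barcodes is
#'   attached as attribute `"captured_barcodes"`
#' @export
simulate_amplicon_reads <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- nrow(truth)
    cap <- stats::runif(n) < config$amplicon_capture_rate
    ncap <- sum(cap)
    if (ncap == 0L) {
      out <- data.frame(read_id = character(0), cell_barcode = character(0),
                        umi = character(0), locus_base = character(0),
                        stringsAsFactors = FALSE)
      attr(out, "captured_barcodes") <- character(0)
      return(out)
    }
    n_umis <- 1L + stats::rpois(ncap, config$umis_per_cell_mean - 1)
    mol_cell <- rep(truth$barcode[cap], n_umis)
    mol_geno <- rep(truth$genotype[cap], n_umis)
    n_mol <- length(mol_cell)
    mol_umi <- rand_dna(n_mol, config$umi_length)
    n_reads <- stats::rpois(n_mol, config$reads_per_umi_mean) + 1L
    read_cell <- rep(mol_cell, n_reads)
    read_umi <- rep(mol_umi, n_reads)
    read_geno <- rep(mol_geno, n_reads)
    total <- length(read_cell)
    is_dup <- sequence(n_reads) > 1L
    corrupt <- is_dup & stats::runif(total) < config$umi_error_rate
    read_umi[corrupt] <- corrupt_one_base(read_umi[corrupt], config$umi_length)
    flip <- stats::runif(total) < config$per_base_error_rate
    locus_base <- ifelse(xor(read_geno == "MUT", flip), "MUT", "WT")
    out <- data.frame(
      read_id = sprintf("read%07d", seq_len(total)),
      cell_barcode = read_cell, umi = read_umi, locus_base = locus_base,
      stringsAsFactors = FALSE)
    attr(out, "captured_barcodes") <- truth$barcode[cap]
    out
  })
}

#' Simulate transcriptome reads covering the variant position
#'
#' Emulates the tagged-read table a transcriptome variant caller consumes:
#' cells are covered with probability `transcriptome_capture_rate`; covered
#' cells emit molecules and PCR duplicates as in
#' [simulate_amplicon_reads()]; a fraction `missing_tag_rate` of reads lack
#' their cell-barcode (CB) or molecular-barcode (UB) tag, recorded as `NA`.
#'
#' @inheritParams simulate_amplicon_reads
#' @return a `data.frame`: `cell_barcode`, `umi` (either may be `NA`),
#'   `base_at_variant` (`"WT"`/`"MUT"`)
#' @export
simulate_tagged_reads <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    n <- nrow(truth)
    cap <- stats::runif(n) < config$transcriptome_capture_rate
    ncap <- sum(cap)
    if (ncap == 0L) {
      return(data.frame(cell_barcode = character(0), umi = character(0),
                        base_at_variant = character(0),
                        stringsAsFactors = FALSE))
    }
    n_umis <- 1L + stats::rpois(ncap, config$umis_per_cell_mean - 1)
    mol_cell <- rep(truth$barcode[cap], n_umis)
    mol_geno <- rep(truth$genotype[cap], n_umis)
    mol_umi <- rand_dna(length(mol_cell), config$umi_length)
    n_reads <- stats::rpois(length(mol_cell), config$reads_per_umi_mean) + 1L
    read_cell <- rep(mol_cell, n_reads)
    read_umi <- rep(mol_umi, n_reads)
    read_geno <- rep(mol_geno, n_reads)
    total <- length(read_cell)
    flip <- stats::runif(total) < config$per_base_error_rate
    base <- ifelse(xor(read_geno == "MUT", flip), "MUT", "WT")
    drop_tag <- stats::runif(total) < config$missing_tag_rate
    which_tag <- stats::runif(total) < 0.5
    read_cell[drop_tag & which_tag] <- NA_character_
    read_umi[drop_tag & !which_tag] <- NA_character_
    data.frame(cell_barcode = read_cell, umi = read_umi,
               base_at_variant = base, stringsAsFactors = FALSE)
  })
}

#' Simulate a marker-structured UMI count matrix and reference profiles
#'
#' Genes carry lognormal baseline abundances; each cell type has a planted
#' set of marker genes whose abundance is multiplied by
#' `marker_fold_change` in cells of that type. Thirteen mitochondrial genes
#' (prefix `MT-`) receive a per-cell mitochondrial fraction drawn from a
#' beta distribution with mean ~3%, so a realistic minority of cells exceeds
#' the 5% QC bound. Counts are Poisson draws around the per-cell rate, with
#' library sizes lognormal around `mean_library_size`.
#'
#' A reference mean-expression profile per cell type (the analogue of sorted
#' bulk profiles used to derive subtype signatures) is returned alongside,
#' computed from the same generative abundances with mild lognormal
#' perturbation.
#'
#' @inheritParams simulate_amplicon_reads
#' @return a list: `counts` (genes x cells `dgCMatrix`), `reference` (gene x
#'   cell-type mean-expression matrix), `markers` (`data.frame` gene,
#'   cell_type)
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    n_cells <- nrow(truth)
    types <- names(config$cell_type_proportions)
    n_mito <- 13L
    mito_genes <- sprintf("MT-G%02d", seq_len(n_mito))
    n_nuc <- config$n_genes - n_mito
    nuc_genes <- sprintf("GENE%04d", seq_len(n_nuc))
    genes <- c(nuc_genes, mito_genes)

    marker_idx <- matrix(
      seq_len(config$markers_per_type * length(types)),
      ncol = length(types))
    colnames(marker_idx) <- types
    markers <- data.frame(
      gene = nuc_genes[as.vector(marker_idx)],
      cell_type = rep(types, each = config$markers_per_type),
      stringsAsFactors = FALSE)

    base_ab <- stats::rlnorm(n_nuc, meanlog = 0, sdlog = 1)
    # per-type abundance profiles (markers up-regulated in their own type)
    prof <- matrix(base_ab, nrow = n_nuc, ncol = length(types))
    colnames(prof) <- types
    for (ty in types) prof[marker_idx[, ty], ty] <-
      prof[marker_idx[, ty], ty] * config$marker_fold_change
    prof <- sweep(prof, 2, colSums(prof), "/")

    lib <- stats::rlnorm(n_cells, meanlog = log(config$mean_library_size),
                         sdlog = 0.25)
    mito_frac <- stats::rbeta(n_cells, 2, 60)
    mito_ab <- stats::rlnorm(n_mito, meanlog = 0, sdlog = 0.5)
    mito_ab <- mito_ab / sum(mito_ab)

    counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells,
                     dimnames = list(genes, truth$barcode))
    for (ty in types) {
      idx <- which(truth$cell_type == ty)
      if (!length(idx)) next
      lam_nuc <- outer(prof[, ty], lib[idx] * (1 - mito_frac[idx]))
      lam_mito <- outer(mito_ab, lib[idx] * mito_frac[idx])
      counts[seq_len(n_nuc), idx] <- stats::rpois(length(lam_nuc), lam_nuc)
      counts[n_nuc + seq_len(n_mito), idx] <-
        stats::rpois(length(lam_mito), lam_mito)
    }
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")

    ref <- matrix(0, nrow = n_nuc, ncol = length(types),
                  dimnames = list(nuc_genes, types))
    for (ty in types) ref[, ty] <- prof[, ty] * config$mean_library_size *
      stats::rlnorm(n_nuc, meanlog = 0, sdlog = 0.1)
    list(counts = counts, reference = ref, markers = markers)
  })
}

#' Draw clone sizes from a truncated zeta (discrete power-law) distribution
#'
#' @param n number of draws
#' @param alpha exponent (> 1)
#' @param max_size truncation point (largest representable clone)
#' @return integer vector of sizes >= 1
#' @export
rzeta_trunc <- function(n, alpha, max_size) {
  if (alpha <= 1) config_stop("clone_size_alpha", "power-law exponent must be > 1")
  k <- seq_len(max(1L, as.integer(max_size)))
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

#' Maximum-likelihood exponent of a truncated zeta distribution
#'
#' Fits the exponent of a discrete power law truncated at `max_size` by
#' direct likelihood maximization; used to validate simulated repertoires.
#'
#' @param sizes observed sizes (>= 1)
#' @param max_size truncation used when generating
#' @return fitted exponent
#' @export
fit_powerlaw_alpha <- function(sizes, max_size = max(sizes)) {
  stopifnot(length(sizes) > 0, all(sizes >= 1))
  k <- seq_len(max(1L, as.integer(max_size)))
  sl <- sum(log(sizes))
  nll <- function(a) a * sl + length(sizes) * log(sum(k^(-a)))
  stats::optimize(nll, c(1.01, 60))$minimum
}

#' Simulate an AIRR-style receptor-chain table
#'
#' T cells receive one TRB chain each; B cells one IGH chain. Clone sizes
#' are drawn per patient and lineage from a truncated zeta law with exponent
#' `clone_size_alpha`; cells are assigned to clones, all members sharing one
#' CDR3 nucleotide sequence and V/J calls from a small fixed catalogue.
#' Per-sequence mutation frequency is drawn from a beta distribution with
#' subtype-specific mean and dispersion (`shm_by_subtype`); a zero mean
#' yields exact zeros (germline). Isotype (constant-region) weights are
#' subtype-dependent, skewed to IgG in plasmablasts. ~97% of chains are
#' productive.
#'
#' @inheritParams simulate_amplicon_reads
#' @return a `data.frame` in AIRR-style columns: `cell_id`, `locus`,
#'   `productive`, `cdr3`, `cdr3_aa`, `v_call`, `j_call`, `c_call`,
#'   `umi_count`, `mu_freq`; true clone assignment is attached as attribute
#'   `"clone_truth"` (`data.frame` cell_id, clone_id, clone_size)
#' @export
simulate_repertoire <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    v_cat <- list(
      TRB = list(v = c("TRBV5-1", "TRBV7-2", "TRBV9", "TRBV19", "TRBV20-1",
                       "TRBV28"),
                 j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-7"),
                 c = c("TRBC1", "TRBC2")),
      IGH = list(v = c("IGHV1-2", "IGHV1-69", "IGHV3-23", "IGHV3-30",
                       "IGHV4-34", "IGHV5-51"),
                 j = c("IGHJ3", "IGHJ4", "IGHJ6"),
                 c = NULL))
    iso_weights <- list(
      naive_B = c(IGHM = 0.8, IGHD = 0.2),
      memory_B = c(IGHM = 0.35, IGHG1 = 0.25, IGHG2 = 0.15, IGHA1 = 0.25),
      plasmablast = c(IGHG1 = 0.45, IGHG3 = 0.20, IGHA1 = 0.20, IGHM = 0.15))

    rows <- list()
    clone_truth <- list()
    for (pat in unique(truth$patient)) {
      for (lineage in c("T", "B")) {
        cells <- truth[truth$patient == pat & truth$cell_type == lineage, ]
        nc <- nrow(cells)
        if (nc == 0L) next
        locus <- if (lineage == "T") "TRB" else "IGH"
        sizes <- integer(0)
        while (sum(sizes) < nc)
          sizes <- c(sizes, rzeta_trunc(max(16L, nc %/% 4L),
                                        config$clone_size_alpha, nc))
        sizes <- sizes[cumsum(sizes) - sizes < nc]   # clones that start in range
        sizes[length(sizes)] <- nc - sum(sizes[-length(sizes)])
        clone_of <- rep(seq_along(sizes), sizes)[seq_len(nc)]
        clone_of <- sample(clone_of)                 # random cell-to-clone map
        n_clones <- length(sizes)
        cdr3_len <- 3L * sample(12L:15L, n_clones, replace = TRUE)
        cdr3 <- vapply(cdr3_len, function(L)
          paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = ""), character(1))
        vg <- sample(v_cat[[locus]]$v, n_clones, replace = TRUE)
        jg <- sample(v_cat[[locus]]$j, n_clones, replace = TRUE)
        clone_ids <- sprintf("%s_%s_cl%04d", pat, locus, seq_len(n_clones))

        if (lineage == "T") {
          cg <- sample(v_cat$TRB$c, nc, replace = TRUE)
          mu <- rep(0, nc)
        } else {
          subt <- cells$b_subtype
          cg <- vapply(subt, function(s)
            sample(names(iso_weights[[s]]), 1L,
                   prob = iso_weights[[s]]), character(1))
          mu <- vapply(subt, function(s) {
            par <- config$shm_by_subtype[[s]]
            m <- par[["mean"]]; d <- par[["dispersion"]]
            if (m == 0) 0 else stats::rbeta(1, m * d, (1 - m) * d)
          }, numeric(1))
        }
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAStringSet(cdr3), no.init.codon = TRUE))
        rows[[paste(pat, lineage)]] <- data.frame(
          cell_id = cells$barcode, locus = locus,
          productive = stats::runif(nc) < 0.97,
          cdr3 = cdr3[clone_of], cdr3_aa = aa[clone_of],
          v_call = vg[clone_of], j_call = jg[clone_of], c_call = cg,
          umi_count = 1L + stats::rpois(nc, 2),
          mu_freq = mu, stringsAsFactors = FALSE)
        tab <- table(clone_of)
        clone_truth[[paste(pat, lineage)]] <- data.frame(
          cell_id = cells$barcode, clone_id = clone_ids[clone_of],
          clone_size = as.integer(tab[as.character(clone_of)]),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    attr(out, "clone_truth") <-
      do.call(rbind, c(clone_truth, list(make.row.names = FALSE)))
    out
  })
}

#' Simulate a complete cohort bundle
#'
#' Runs every generator under one root seed (split deterministically per
#' stage) and returns all inputs the downstream pipeline consumes together
#' with the ground truth. When `out_dir` is given, every component is also
#' written to disk in its interchange format (FASTQ pair, MatrixMarket
#' matrix with gene/barcode TSVs, tab-separated tables).
#'
#' @param config a [sim_config()]
#' @param out_dir optional directory to materialize the bundle in
#' @return a list with elements `truth`, `amplicon_reads`, `tagged_reads`,
#'   `counts`, `reference`, `markers`, `metadata`, `repertoire`,
#'   `clone_truth`, and (when written) `paths`
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_ground_truth(config)
  amplicon <- simulate_amplicon_reads(truth, config)
  tagged <- simulate_tagged_reads(truth, config)
  cts <- simulate_counts(truth, config)
  rep_tab <- simulate_repertoire(truth, config)
  metadata <- data.frame(
    barcode = truth$barcode, patient = truth$patient,
    cluster = paste0("cluster_",
                     match(truth$cell_type,
                           names(config$cell_type_proportions))),
    pseudotime = truth$pseudotime, stringsAsFactors = FALSE)
  bundle <- list(
    truth = truth, amplicon_reads = amplicon, tagged_reads = tagged,
    counts = cts$counts, reference = cts$reference, markers = cts$markers,
    metadata = metadata, repertoire = rep_tab,
    clone_truth = attr(rep_tab, "clone_truth"))
  if (!is.null(out_dir)) bundle$paths <- write_cohort(bundle, config, out_dir)
  bundle
}
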
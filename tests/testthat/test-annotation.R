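make_counts <- function(detected, n_genes = 7000L, mito_counts = 0L,
                        base = 1L) {
  # one cell per element of `detected`, with exactly that many detected
  # genes, plus a mitochondrial gene with the given counts
  n_cells <- length(detected)
  m <- matrix(0L, nrow = n_genes + 1L, ncol = n_cells,
              dimnames = list(c(sprintf("G%05d", seq_len(n_genes)), "MT-1"),
                              sprintf("cell%03d", seq_len(n_cells))))
  for (i in seq_len(n_cells)) m[seq_len(detected[i]), i] <- base
  m["MT-1", ] <- mito_counts
  m
}

test_that("QC removes fragments, doublets and high-mitochondrial cells at the printed bounds", {
  m <- make_counts(c(499L, 500L, 6000L, 6001L))
  kept <- qc_filter(m)
  expect_identical(colnames(kept), c("cell002", "cell003"))
  s <- attr(kept, "qc_stats")
  expect_identical(unname(s[c("n_low_genes", "n_high_genes")]), c(1L, 1L))

  # 19 mito reads over 381 nuclear (5% exactly) is kept; above 5% removed
  m2 <- make_counts(c(600L, 600L), mito_counts = c(0L, 0L))
  m2["MT-1", 1] <- 31L   # 31 / (600 + 31) ~ 4.9% -> kept
  m2["MT-1", 2] <- 40L   # 40 / 640 = 6.25% -> removed
  kept2 <- qc_filter(m2)
  expect_identical(colnames(kept2), "cell001")

  expect_error(qc_filter(m[, 0, drop = FALSE]), "non-empty")
})

test_that("QC is idempotent and matches a direct predicate oracle", {
  set.seed(19)
  n <- 200
  det <- sample(c(300:700, 5800:6200), n, replace = TRUE)
  mito <- sample(0:40, n, replace = TRUE)
  m <- make_counts(det, mito_counts = mito)
  kept <- qc_filter(m)
  total <- det + mito
  # detected genes include the mito gene when expressed
  det_all <- det + (mito > 0)
  oracle <- det_all >= 500 & det_all <= 6000 & mito / total <= 0.05
  expect_identical(colnames(kept), colnames(m)[oracle])
  twice <- qc_filter(kept)
  expect_identical(colnames(twice), colnames(kept))
  expect_equal(twice, kept, ignore_attr = TRUE)
})

test_that("normalization matches ln(1 + count/library * scale) and inverts to the scale", {
  m <- matrix(c(0, 5, 5, 10), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- normalize_log(m)
  expect_identical(norm["g1", "c1"], 0)
  expect_equal(norm["g2", "c1"], log1p(1e4))  # single expressed gene
  set.seed(3)
  r <- matrix(rpois(600, 5) + 1L, nrow = 30,
              dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:20)))
  n2 <- normalize_log(r)
  expect_equal(unname(colSums(expm1(n2))), rep(1e4, 20), tolerance = 1e-6)
  sp <- normalize_log(Matrix::Matrix(r, sparse = TRUE))
  expect_equal(as.matrix(sp), n2, tolerance = 1e-12,
               ignore_attr = "class")
  r2 <- r; r2[, 1] <- 0L
  expect_error(normalize_log(r2), "zero library")
})

test_that("subtype signatures rank genes by one-vs-rest contrast", {
  ref <- matrix(c(10, 0, 0,
                  5, 5, 5,
                  0, 8, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gFlat", "gB"),
                                c("A", "B", "C")))
  sig <- derive_subtype_signatures(ref, top_k = 2L)
  expect_identical(sig$A[1], "gA")
  expect_identical(sig$B[1], "gB")
  expect_false("gFlat" %in% sig$A[1])

  set.seed(23)
  r <- matrix(rexp(100 * 4), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), LETTERS[1:4]))
  sig2 <- derive_subtype_signatures(r, top_k = 10L)
  for (st in LETTERS[1:4]) {
    contrast <- r[, st] - rowMeans(r[, colnames(r) != st])
    oracle <- rownames(r)[order(-contrast, rownames(r))][1:10]
    expect_identical(sig2[[st]], oracle)
  }
  expect_warning(derive_subtype_signatures(r, top_k = 500L), "truncating")
})

test_that("overlap enrichment equals exhaustive hypergeometric enumeration", {
  # disjoint sets: zero overlap gives the maximal one-sided p of 1
  expect_equal(fisher_overlap(paste0("m", 1:10), paste0("s", 1:10), 20), 1)
  u <- paste0("g", 1:15)
  expect_equal(fisher_overlap(u, u, 15), 1)
  p <- fisher_overlap(c("g1", "g2", "g3", "g9", "g10"),
                      c("g1", "g2", "g3", "g4", "g5"), 30)
  expect_equal(p, hyper_tail_oracle(3, 5, 30, 5), tolerance = 1e-12)
  expect_error(fisher_overlap("a", "b", 0), "universe")
})

test_that("cluster identity assignment picks the most enriched subtype", {
  genes <- paste0("g", 1:200)
  sigs <- structure(list(A = genes[1:30], B = genes[31:60]),
                    class = "signature_set", universe_size = 200L)
  res <- assign_cluster_identity(list(cl1 = genes[1:30],
                                      cl2 = genes[35:55]), sigs)
  expect_identical(res$subtype[res$cluster == "cl1"], "A")
  expect_identical(res$subtype[res$cluster == "cl2"], "B")
  expect_false(any(res$ambiguous))

  # identical signatures force a deterministic, flagged tie
  sigs2 <- structure(list(Z = genes[1:30], A = genes[1:30]),
                     class = "signature_set", universe_size = 200L)
  res2 <- assign_cluster_identity(list(cl = genes[1:20]), sigs2)
  expect_identical(res2$subtype, "A")
  expect_true(res2$ambiguous)

  # invariance to cluster order
  ms <- list(cl1 = genes[1:30], cl2 = genes[35:55])
  r1 <- assign_cluster_identity(ms, sigs)
  r2 <- assign_cluster_identity(rev(ms), sigs)
  expect_identical(r1[order(r1$cluster), ]$subtype,
                   r2[order(r2$cluster), ]$subtype)
  expect_error(assign_cluster_identity(list(cl = character(0)), sigs),
               "marker")
})

test_that("noisy planted clusters are assigned to their source subtype", {
  set.seed(31)
  genes <- sprintf("g%04d", 1:500)
  sigs <- structure(
    lapply(0:4, function(i) genes[i * 40 + 1:40]),
    names = paste0("S", 1:5), class = "signature_set",
    universe_size = 500L)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    for (s in 1:5) {
      markers <- unique(c(sample(sigs[[s]], 32),
                          sample(genes, 8)))  # ~20% noise
      res <- assign_cluster_identity(list(cl = markers), sigs)
      hits <- hits + (res$subtype == paste0("S", s))
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("module scores are shift-invariant, order-invariant and centered", {
  set.seed(41)
  expr <- matrix(rexp(300 * 50), nrow = 300,
                 dimnames = list(sprintf("g%03d", 1:300),
                                 sprintf("c%02d", 1:50)))
  mod <- rownames(expr)[sample(300, 12)]
  s1 <- module_score(expr, mod, seed = 7L)
  s_shift <- module_score(expr + 5, mod, seed = 7L)
  expect_equal(s1, s_shift, tolerance = 1e-12)
  s_perm <- module_score(expr[sample(300), ], rev(mod), seed = 7L)
  expect_equal(s1, s_perm, tolerance = 1e-12)
  # module = all genes with a single bin and exhaustive control: exact zero
  s0 <- module_score(expr, rownames(expr), n_bins = 1L, n_ctrl = 1000L,
                     seed = 1L)
  expect_equal(unname(s0), rep(0, 50), tolerance = 1e-12)
  expect_error(suppressWarnings(module_score(expr, c("nope1", "nope2"))),
               "empty")
  expect_warning(module_score(expr, c(mod, "nope")), "absent")
  expect_identical(module_score(expr, mod, seed = 3L),
                   module_score(expr, mod, seed = 3L))
})

test_that("a planted module shift is recovered by the score", {
  set.seed(51)
  deltas <- replicate(15, {
    expr <- matrix(rnorm(3000 * 60, mean = 2), nrow = 3000,
                   dimnames = list(sprintf("g%04d", 1:3000),
                                   sprintf("c%03d", 1:60)))
    mod <- sample(rownames(expr), 10)
    half <- sprintf("c%03d", 1:30)
    expr[mod, half] <- expr[mod, half] + 0.6
    s <- module_score(expr, mod, seed = 2L)
    mean(s[half]) - mean(s[setdiff(colnames(expr), half)])
  })
  se <- sd(deltas) / sqrt(length(deltas))
  # the control pool can include module genes (binned matching does not
  # exclude them), attenuating the recovered shift by ~ |module| / |pool|
  attenuation <- 0.6 * 10 / 1000
  expect_lt(abs(mean(deltas) - 0.6), 3 * se + attenuation)
})

test_that("differential expression behaves at the null and detects a planted gene", {
  set.seed(61)
  expr <- matrix(rnorm(100 * 60, mean = 1), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("c%03d", 1:60)))
  a <- colnames(expr)[1:30]; b <- colnames(expr)[31:60]
  # identical groups by construction: zero fold changes
  same <- cbind(expr[, a], expr[, a])
  colnames(same) <- sprintf("d%03d", 1:60)
  de0 <- differential_expression(same, colnames(same)[1:30],
                                 colnames(same)[31:60])
  expect_true(all(abs(de0$log_fc) < 1e-12))
  # constant gene: p = 1
  expr["g001", ] <- 3
  de <- differential_expression(expr, a, b)
  expect_identical(de$p_value[de$gene == "g001"], 1)
  # planted strong gene is flagged
  expr["g002", a] <- expr["g002", a] + log(4)
  de2 <- differential_expression(expr, a, b)
  expect_true(de2$is_de[de2$gene == "g002"])
  expect_lt(de2$p_adjusted[de2$gene == "g002"], 0.05)
  # direction switch flags down-regulation only in "both" mode
  de_ab <- differential_expression(expr, b, a, direction = "both")
  expect_true(de_ab$is_de[de_ab$gene == "g002"])
})

test_that("cluster markers recover planted marker genes", {
  cfg <- quick_config(seed = 25L, marker_fold_change = 6)
  truth <- simulate_ground_truth(cfg)
  cts <- simulate_counts(truth, cfg)
  expr <- normalize_log(cts$counts)
  clusters <- setNames(truth$cell_type, truth$barcode)
  mk <- cluster_markers(expr, clusters)
  planted <- split(cts$markers$gene, cts$markers$cell_type)
  for (ty in names(planted)) {
    expect_gt(length(intersect(mk[[ty]], planted[[ty]])) /
                length(planted[[ty]]), 0.8)
  }
})
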
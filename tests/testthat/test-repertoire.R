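chain_df <- function(cell_id, cdr3, locus = "TRB", productive = TRUE,
                     v_call = "TRBV9", j_call = "TRBJ1-1",
                     c_call = "TRBC1", umi_count = 1L, mu_freq = 0) {
  data.frame(cell_id = cell_id, locus = locus, productive = productive,
             cdr3 = cdr3, cdr3_aa = "X", v_call = v_call, j_call = j_call,
             c_call = c_call, umi_count = umi_count, mu_freq = mu_freq,
             stringsAsFactors = FALSE)
}

test_that("cells with identical CDR3 share a clone; distinct CDR3s are singletons", {
  ch <- chain_df(c("a", "b", "c"), rep("TGTGCA", 3))
  ct <- group_clones(ch)
  expect_identical(ct$clones$n_cells, 3L)
  expect_identical(length(unique(ct$cell_map$clone_id)), 1L)

  ch2 <- chain_df(c("a", "b", "c"), c("AAA", "CCC", "GGG"))
  ct2 <- group_clones(ch2)
  expect_identical(ct2$clones$n_cells, rep(1L, 3))
  expect_equal(sum(ct2$clones$frequency), 1)
})

test_that("clone grouping ignores unproductive chains and respects VJ mode", {
  ch <- rbind(chain_df(c("a", "b"), c("AAA", "AAA")),
              chain_df("c", "AAA", productive = FALSE))
  expect_identical(group_clones(ch)$clones$n_cells, 2L)
  ch3 <- rbind(chain_df("a", "AAA", v_call = "TRBV9"),
               chain_df("b", "AAA", v_call = "TRBV19"))
  expect_identical(group_clones(ch3, mode = "cdr3nt")$clones$n_cells, 2L)
  expect_identical(group_clones(ch3, mode = "cdr3nt_vj")$clones$n_cells,
                   rep(1L, 2))
})

test_that("multi-chain cells resolve by UMI support, then lexicographic CDR3", {
  ch <- rbind(chain_df("a", "CCC", umi_count = 5L),
              chain_df("a", "AAA", umi_count = 2L),
              chain_df("b", "TTT", umi_count = 3L),
              chain_df("b", "GGG", umi_count = 3L))
  ct <- group_clones(ch)
  cdr_of <- setNames(ct$clones$cdr3, ct$clones$clone_id)
  map <- setNames(cdr_of[ct$cell_map$clone_id], ct$cell_map$cell_id)
  expect_identical(unname(map["a"]), "CCC")  # more UMIs wins
  expect_identical(unname(map["b"]), "GGG")  # tie -> lexicographic
})

test_that("clone grouping is invariant to row order and recovers planted partitions", {
  cfg <- sim_config(n_patients = 1L, n_cells_per_patient = 1000L, seed = 33L)
  truth <- simulate_ground_truth(cfg)
  rep_tab <- simulate_repertoire(truth, cfg)
  planted <- attr(rep_tab, "clone_truth")
  ct <- group_clones(rep_tab, locus = "TRB")
  t_cells <- truth$barcode[truth$cell_type == "T"]
  planted_t <- planted[planted$cell_id %in% t_cells, ]
  got <- setNames(ct$cell_map$clone_id, ct$cell_map$cell_id)
  prod_cells <- intersect(planted_t$cell_id, names(got))
  # same partition: planted clone labels map 1:1 onto recovered labels
  tab <- table(planted_t[match(prod_cells, planted_t$cell_id), "clone_id"],
               got[prod_cells])
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_true(all(colSums(tab > 0) == 1L))
  perm <- rep_tab[sample(nrow(rep_tab)), ]
  ct2 <- group_clones(perm, locus = "TRB")
  expect_identical(ct$clones, ct2$clones)
})

test_that("Shannon entropy matches closed forms and rejects bad input", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1, 0)), "positive")
})

test_that("entropy is maximal exactly at the uniform distribution", {
  set.seed(81)
  for (n in 2:8) {
    h_max <- shannon_entropy(rep(1 / n, n))
    expect_equal(h_max, log2(n))
    for (i in 1:10) {
      p <- rexp(n); p <- p / sum(p)
      if (max(abs(p - 1 / n)) > 1e-6) expect_lt(shannon_entropy(p), h_max)
    }
  }
})

test_that("Gini matches the pairwise-difference oracle and its limits", {
  expect_equal(gini_index(rep(7, 12)), 0)
  expect_equal(gini_index(c(1, 1, 1, 97)), gini_oracle(c(1, 1, 1, 97)),
               tolerance = 1e-12)
  set.seed(82)
  for (i in 1:40) {
    sizes <- sample(1:200, sample(2:60, 1), replace = TRUE)
    expect_equal(gini_index(sizes), gini_oracle(sizes), tolerance = 1e-10)
  }
  # one dominant clone among n: G -> (n-1)/n as the clone grows
  n <- 10
  expect_lt(abs(gini_index(c(rep(1, n - 1), 1e7)) - (n - 1) / n), 1e-5)
  expect_error(gini_index(numeric(0)), "no clone")
  expect_error(gini_index(c(1, 0.5)), ">= 1")
})

test_that("expansion classes use the strict >20 boundary", {
  cls <- classify_expansion(c(1, 2, 5, 6, 20, 21, 100))
  expect_identical(as.character(cls),
                   c("singleton", "small", "small", "medium", "medium",
                     "expanded", "expanded"))
})

test_that("SHM categories follow the printed boundaries exactly", {
  cls <- classify_shm(c(0, 0.001, 0.03, 0.031, 1))
  expect_identical(as.character(cls),
                   c("germline", "low", "low", "high", "high"))
  expect_error(classify_shm(-0.1), "\\[0, 1\\]")
  expect_error(classify_shm(1.5), "\\[0, 1\\]")
})

test_that("isotype tables map constant genes and normalize per subtype", {
  ch <- chain_df(sprintf("c%d", 1:6), "AAA", locus = "IGH",
                 c_call = c("IGHG1", "IGHM", "IGHM", "IGHA1", "IGHM",
                            "IGHX"))
  subt <- setNames(c("pb", "naive", "naive", "pb", "naive", "pb"),
                   sprintf("c%d", 1:6))
  tab <- isotype_table(ch, subt)
  expect_equal(tab["naive", "IgM"], 1)
  expect_equal(sum(tab["pb", ]), 1)
  expect_equal(tab["pb", "unknown"], 1 / 3)
  counts <- attr(tab, "counts")
  expect_identical(unname(counts["pb", "IgG1"]), 1L)
})

test_that("V gene usage sums to one per group and detects planted shifts", {
  ch <- chain_df(sprintf("c%d", 1:4), "AAA", v_call = rep("TRBV9", 4))
  res <- vdj_usage(ch, groups = c("x", "x", "y", "y"))
  expect_equal(unname(res$frequencies[, "TRBV9"]), c(1, 1))
  expect_equal(res$chisq_statistic, 0)

  set.seed(83)
  detect <- vapply(1:10, function(i) {
    va <- sample(paste0("V", 1:6), 1000, replace = TRUE)
    vb <- sample(paste0("V", 1:6), 1000, replace = TRUE,
                 prob = c(3, 1, 1, 1, 1, 1))
    ch2 <- chain_df(sprintf("c%d", 1:2000), "AAA", v_call = c(va, vb))
    vdj_usage(ch2, rep(c("a", "b"), each = 1000))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.95)
})

test_that("an all-singleton repertoire has maximal entropy, zero Gini, no expansion", {
  ch <- chain_df(sprintf("c%d", 1:32), sprintf("CDR%02d", 1:32))
  ct <- group_clones(ch)
  expect_equal(shannon_entropy(ct$clones$frequency), log2(32))
  expect_equal(gini_index(ct$clones$n_cells), 0)
  expect_identical(sum(classify_expansion(ct$clones$n_cells) == "expanded"),
                   0L)
})

test_that("per-patient repertoire summaries carry the clonality statistics", {
  cfg <- sim_config(n_patients = 3L, n_cells_per_patient = 500L, seed = 35L)
  truth <- simulate_ground_truth(cfg)
  rep_tab <- simulate_repertoire(truth, cfg)
  pats <- setNames(truth$patient, truth$barcode)
  summ <- repertoire_summary(rep_tab, pats, locus = "TRB")
  expect_identical(summ$patient, sort(unique(truth$patient)))
  expect_true(all(summ$shannon_entropy <= log2(summ$n_clones) + 1e-9))
  expect_true(all(summ$gini_index >= 0 & summ$gini_index < 1))
})
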
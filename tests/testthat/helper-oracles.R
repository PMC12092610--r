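# Independent oracles, deliberately coded without reference to the package
# implementation paths they check.

# Levenshtein distance by straightforward dynamic programming.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- c(i, rep(0L, length(y)))
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

# Brute-force greedy UMI collapsing: enumerate all pairwise distances,
# repeatedly let the surviving UMI with most matches absorb its matched
# partners (ties: more reads, then alphabetical), until no survivor has a
# match.
collapse_oracle <- function(umi_counts, threshold) {
  umis <- names(umi_counts)
  n <- length(umis)
  canon <- setNames(umis, umis)
  if (n <= 1 || threshold == 0) return(canon)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- lev_dp(umis[i], umis[j])
  match_mat <- d <= threshold
  diag(match_mat) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    counts <- sapply(seq_len(n), function(i)
      if (alive[i]) sum(match_mat[i, ] & alive) else -1L)
    if (max(counts) <= 0) break
    cand <- which(counts == max(counts))
    if (length(cand) > 1) {
      cand <- cand[umi_counts[cand] == max(umi_counts[cand])]
      if (length(cand) > 1) cand <- cand[which.min(rank(umis[cand]))]
    }
    winner <- cand[1]
    partners <- which(match_mat[winner, ] & alive)
    canon[umis[partners]] <- umis[winner]
    alive[c(winner, partners)] <- FALSE
  }
  canon
}

# Random UMI instance with planted near-duplicates so collapsing actually
# happens: a few parents plus mutated copies.
random_umi_instance <- function(max_umis = 20L, umi_len = 12L) {
  n_parent <- sample(1:4, 1)
  parents <- unique(replicate(n_parent, paste(
    sample(c("A", "C", "G", "T"), umi_len, replace = TRUE),
    collapse = "")))
  umis <- parents
  for (p in parents) {
    k <- sample(0:4, 1)
    for (i in seq_len(k)) {
      m <- p
      for (e in seq_len(sample(1:3, 1))) {
        pos <- sample(umi_len, 1)
        substr(m, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
      umis <- c(umis, m)
    }
  }
  umis <- unique(umis)[seq_len(min(max_umis, length(unique(umis))))]
  setNames(sample(1:20, length(umis), replace = TRUE), umis)
}

# O(n^2) pairwise-difference Gini.
gini_oracle <- function(sizes) {
  n <- length(sizes)
  sum(abs(outer(sizes, sizes, "-"))) / (2 * n^2 * mean(sizes))
}

# One-sided enrichment p for the overlap of two sets in a finite universe,
# by exhaustive hypergeometric enumeration with binomial coefficients:
# P(overlap >= k) when a set of size K is drawn from a universe of N
# containing M marked elements.
hyper_tail_oracle <- function(k, M, N, K) {
  kk <- max(0, K + M - N):min(K, M)
  probs <- choose(M, kk) * choose(N - M, K - kk) / choose(N, K)
  sum(probs[kk >= k])
}

# Majority-vote per-UMI genotype call with equal-vote removal.
majority_oracle <- function(bases) {
  nm <- sum(bases == "MUT"); nw <- sum(bases == "WT")
  if (nm > nw) "MUT" else if (nw > nm) "WT" else "AMBIGUOUS"
}

# 75%-threshold consensus rule, written directly from the counts.
consensus_oracle <- function(n_mut, n_wt, n_other, threshold = 0.75,
                             strict = FALSE) {
  counts <- c(MUT = n_mut, WT = n_wt, OTHER = n_other)
  total <- sum(counts)
  if (total == 0) return("DISCARDED")
  if (sum(counts > 0) == 1) {
    b <- names(counts)[counts > 0]
    return(if (b %in% c("MUT", "WT")) b else "DISCARDED")
  }
  top <- names(counts)[which.max(counts)]
  share <- max(counts) / total
  pass <- if (strict) share > threshold else share >= threshold
  if (pass && top %in% c("MUT", "WT")) top else "DISCARDED"
}

# Small noise-free configuration used across module tests.
quick_config <- function(...) {
  sim_config(n_patients = 2L, n_cells_per_patient = 250L,
             per_base_error_rate = 0, umi_error_rate = 0,
             missing_tag_rate = 0, n_genes = 600L, mean_library_size = 800,
             ...)
}
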
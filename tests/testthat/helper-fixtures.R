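# Shared fixtures and independent oracles for the test suite.

# A tiny 3-gene, two-group table with paired baselines, built in code.
toy_annotation <- function() {
  data.frame(
    sample_id = c("A_r1_t0", "A_r2_t0", "A_r1_t1", "A_r2_t1",
                  "B_r1_t0", "B_r2_t0", "B_r1_t1", "B_r2_t1"),
    group = rep(c("A", "B"), each = 4),
    time = rep(c(0, 0, 1, 1), 2),
    replicate_id = rep(c("r1", "r2"), 4),
    role = rep(c("baseline", "baseline", "post", "post"), 2),
    stringsAsFactors = FALSE)
}

toy_table <- function(values = NULL) {
  ann <- toy_annotation()
  if (is.null(values)) {
    values <- matrix(5, 3, 8, dimnames = list(paste0("g", 1:3),
                                              ann$sample_id))
    values["g1", c("A_r1_t1", "A_r2_t1")] <- 6   # +1 in A only
    values["g2", c("B_r1_t1", "B_r2_t1")] <- 4   # -1 in B only
  }
  expression_table(values, ann)
}

# Random differential profile with known dimensions; differentials drawn
# wide enough to hit all three ternary levels at theta = 1.5.
random_profile <- function(n_genes, times = c(1, 6, 24),
                           groups = c("A", "B"), sd = 1.2, seed = 1) {
  set.seed(seed)
  vals <- array(rnorm(n_genes * length(groups) * length(times), 0, sd),
                dim = c(n_genes, length(groups), length(times)),
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), groups,
                                as.character(times)))
  structure(list(values = vals, genes = rownames(vals), groups = groups,
                 times = times, baseline_mode = "group_mean"),
            class = "differential_profile")
}

# Independent brute-force oracle: per-gene tally of a pattern histogram,
# discretizing with plain comparisons and counting with a loop.
oracle_histogram <- function(D, theta) {
  cut <- log2(theta)
  n <- rep(0L, 27L)
  for (g in seq_len(nrow(D))) {
    d <- D[g, ]
    if (any(is.na(d))) next
    digits <- ifelse(d >= cut, 0L, ifelse(d <= -cut, 2L, 1L))
    idx <- digits[1] * 9L + digits[2] * 3L + digits[3]
    n[idx + 1L] <- n[idx + 1L] + 1L
  }
  n
}

# Independent brute-force oracle: double-loop pairwise tally of the
# comparative pattern-count matrix from two index assignments.
oracle_compact <- function(idx_ref, idx_cmp, K) {
  counts <- matrix(0L, K, K)
  for (g in names(idx_ref)) {
    i <- idx_ref[[g]]; j <- idx_cmp[[g]]
    if (is.na(i) || is.na(j)) next
    counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + 1L
  }
  counts
}

# Permutation oracle for the two-proportion test: permute pooled group
# labels, i.e. draw the group-A success count from the conditional
# hypergeometric null, and compare absolute proportion differences.
oracle_permutation_p <- function(x1, n1, x2, n2, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  obs <- abs(x1 / n1 - x2 / n2)
  d <- rhyper(n_perm, m = x1 + x2, n = n1 + n2 - x1 - x2, k = n1)
  mean(abs(d / n1 - (x1 + x2 - d) / n2) >= obs - 1e-12)
}

expect_compact_valid <- function(m) {
  expect_s3_class(m, "compact")
  expect_equal(sum(m$counts), m$total_genes)
  expect_equal(sum(m$counts), nrow(m$assignment))
  expect_true(all(m$counts >= 0L))
}
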
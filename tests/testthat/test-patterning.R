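test_that("discretization respects inclusive boundaries and monotonicity", {
  sch <- discretization_scheme(1.75)
  expect_equal(discretize_value(1.0, sch), 1)        # 2-fold up > 1.75
  expect_equal(discretize_value(0.2, discretization_scheme(1.5)), 0)
  expect_equal(discretize_value(-log2(1.6), discretization_scheme(1.5)), -1)
  # boundary maps to the stronger level, both signs
  expect_equal(discretize_value(log2(1.5), discretization_scheme(1.5)), 1)
  expect_equal(discretize_value(-log2(1.5), discretization_scheme(1.5)), -1)
  expect_error(discretize_value(NaN, sch), "non-finite")

  # level is monotone non-increasing in rank as d increases
  d <- seq(-3, 3, by = 0.01)
  lv <- discretize_value(d, discretization_scheme(c(1.5, 3)))
  expect_true(all(diff(lv) >= 0))
  expect_equal(sort(unique(lv)), -2:2)
})

test_that("pattern codes use the canonical base-L index", {
  expect_equal(pattern_of(c(1, 1, 1))$index, 0L)
  expect_equal(pattern_of(c(0, 0, 0))$index, 13L)
  expect_equal(pattern_of(c(-1, -1, -1))$index, 26L)
  expect_equal(pattern_of(c(1, 0, -1))$label, "+0-")
  expect_true(is.na(pattern_of(c(1, NA, 0))$index))

  # bijection: enumerate visits each index exactly once, and re-encoding
  # each pattern's ranks reproduces its index (full-enumeration oracle)
  sch <- discretization_scheme(1.5)
  pats <- enumerate_patterns(sch, 3)
  expect_equal(pats$index, 0:26)
  expect_equal(anyDuplicated(pats$label), 0L)
  ranks <- attr(pats, "ranks")
  for (i in seq_len(nrow(pats)))
    expect_equal(sum(ranks[i, ] * c(9, 3, 1)), pats$index[i])

  # mirror: negating differentials maps index i to (L^T - 1) - i
  set.seed(4)
  for (k in 1:25) {
    d <- runif(3, -2, 2)
    expect_equal(pattern_of(-d)$index, 26L - pattern_of(d)$index)
  }
})

test_that("pattern enumeration covers L^T patterns in canonical order", {
  expect_equal(nrow(enumerate_patterns(discretization_scheme(1.5), 3)), 27L)
  one <- enumerate_patterns(discretization_scheme(1.5), 1)
  expect_equal(one$label, c("+", "0", "-"))
  expect_equal(nrow(enumerate_patterns(discretization_scheme(c(1.5, 4)), 2)),
               25L)
  # up block first, null pattern centered, down block last
  pats <- enumerate_patterns(discretization_scheme(1.5), 3)
  expect_equal(pats$label[1], "+++")
  expect_equal(pats$label[14], "000")
  expect_equal(pats$label[27], "---")
})

test_that("pattern histogram equals the brute-force per-gene tally", {
  prof <- random_profile(500, seed = 21)
  sch <- discretization_scheme(1.5)
  hist <- pattern_histogram(prof, "A", sch)
  D <- prof$values[, "A", ]
  expect_equal(unname(hist$counts), oracle_histogram(D, 1.5))
  # conservation including undefined genes
  prof$values[5, "A", 2] <- NA
  hist2 <- pattern_histogram(prof, "A", sch)
  expect_equal(sum(hist2$counts) + length(hist2$undefined), 500L)
  expect_equal(hist2$undefined, prof$genes[5])
  # counts match membership sizes
  for (i in names(hist2$members))
    expect_equal(length(hist2$members[[i]]),
                 unname(hist2$counts[as.integer(i) + 1L]))
})

test_that("histogram serializes with labels, counts, and members", {
  prof <- random_profile(40, seed = 3)
  hist <- pattern_histogram(prof, "B")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_histogram(hist, path)
  back <- read.delim(path, colClasses = c("integer", "character", "integer",
                                          "character"))
  expect_equal(nrow(back), 27L)
  expect_equal(back$count, unname(hist$counts))
  expect_equal(sum(back$count), 40L)
})

test_that("gene ordering is pattern-major, magnitude tie-broken, stable", {
  prof <- random_profile(100, seed = 8)
  hist <- pattern_histogram(prof, "A")
  ord <- order_genes_by_pattern(hist, prof)
  expect_setequal(ord, prof$genes)
  idx <- hist$index[ord]
  expect_true(all(diff(idx) >= 0))
  # within a pattern, max |d| is non-increasing
  D <- abs(prof$values[, "A", ])
  maxd <- apply(D, 1, max)[ord]
  for (i in unique(idx))
    expect_true(all(diff(maxd[idx == i]) <= 1e-12))
  # permutation invariance
  perm <- sample(prof$genes)
  prof2 <- prof
  prof2$values <- prof$values[perm, , , drop = FALSE]
  prof2$genes <- perm
  ord2 <- order_genes_by_pattern(pattern_histogram(prof2, "A"), prof2)
  expect_identical(ord, ord2)
})
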
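test_that("COMPACT matrix equals the brute-force pairwise tally", {
  prof <- random_profile(500, seed = 31)
  sch <- discretization_scheme(1.5)
  m <- compact(prof, reference = "A", comparison = "B", scheme = sch)
  expect_compact_valid(m)
  expect_equal(dim(m$counts), c(27L, 27L))

  idx_ref <- compactr:::pattern_index_matrix(prof$values[, "A", ], sch)
  idx_cmp <- compactr:::pattern_index_matrix(prof$values[, "B", ], sch)
  expect_equal(unname(m$counts), oracle_compact(as.list(idx_ref),
                                                as.list(idx_cmp), 27L))
  expect_equal(sum(m$counts), 500L)
})

test_that("identical patterns put all mass on the diagonal", {
  idx <- c(g1 = 5L, g2 = 20L)
  m <- build_compact(idx, idx, discretization_scheme(1.5), T = 3)
  expect_equal(sum(diag(m$counts)), 2L)
  expect_equal(sum(m$counts) - sum(diag(m$counts)), 0L)
  expect_equal(cell_genes(m, 5, 5), "g1")
  expect_equal(cell_genes(m, 0, 0), character(0))
})

test_that("transposition swaps roles exactly and is an involution", {
  prof <- random_profile(200, seed = 32)
  ab <- compact(prof, reference = "A", comparison = "B")
  ba <- compact(prof, reference = "B", comparison = "A")
  tab <- t(ab)
  expect_equal(tab$counts, ba$counts)
  expect_equal(tab$reference_group, "B")
  expect_equal(diag(tab$counts), diag(ab$counts))
  back <- t(tab)
  expect_equal(back$counts, ab$counts)
  expect_equal(back$assignment, ab$assignment)
})

test_that("undefined or unshared genes are dropped with a report", {
  idx_a <- c(g1 = 1L, g2 = NA_integer_, g3 = 3L, g4 = 4L)
  idx_b <- c(g1 = 2L, g2 = 5L, g3 = NA_integer_, g5 = 0L)
  m <- build_compact(idx_a, idx_b, discretization_scheme(1.5), T = 3)
  expect_equal(m$total_genes, 1L)
  expect_setequal(m$dropped$undefined, c("g2", "g3"))
  expect_equal(m$dropped$ref_only, "g4")
  expect_equal(m$dropped$cmp_only, "g5")
  expect_error(build_compact(c(a = 1L), c(b = 2L),
                             discretization_scheme(1.5), T = 3),
               "empty gene intersection")
})

test_that("section partition yields 9 disjoint exhaustive sections", {
  prof <- random_profile(100, seed = 33)
  m <- compact(prof, reference = "A", comparison = "B")
  part <- section_partition(m, basis_time = 1)
  expect_length(part$sections, 9L)
  sizes <- vapply(part$sections, nrow, 1L)
  expect_true(all(sizes == 81L))
  expect_equal(sum(sizes), 729L)
  expect_equal(part$central, "e")
  # each cell in exactly one section
  tally <- matrix(0L, 27, 27)
  for (cells in part$sections) tally[cells] <- tally[cells] + 1L
  expect_true(all(tally == 1L))
  # c and g hold opposite first-time-point regulation
  ids <- part$ids
  expect_equal(ids[1, 27], "c")   # up in reference, down in comparison
  expect_equal(ids[27, 1], "g")
  expect_equal(ids[14, 14], "e")
  expect_error(section_partition(m, basis_time = 4), "basis_time")
})

test_that("masking hides cells without deleting them, composing by union", {
  prof <- random_profile(300, seed = 34)
  m <- compact(prof, reference = "A", comparison = "B")
  masked <- mask_cells(m, sections = "e")
  expect_equal(sum(masked$mask), 81L)
  expect_equal(sum(!masked$mask), 648L)
  expect_equal(masked$counts, m$counts)  # counts untouched
  # idempotent for the same rule; union for new rules
  expect_equal(mask_cells(masked, sections = "e")$mask, masked$mask)
  both <- mask_cells(masked, sections = "a")
  expect_equal(sum(both$mask), 162L)
  expect_error(mask_cells(m, sections = "z"), "unknown section")

  # min_count above the max hides everything
  all_hidden <- mask_cells(m, min_count = max(m$counts) + 1L)
  expect_true(all(all_hidden$mask))
  expect_false(any(unmask(all_hidden)$mask))

  # masked cells refuse access unless explicitly allowed
  cellpos <- which(masked$mask & masked$counts > 0, arr.ind = TRUE)[1, ]
  expect_error(cell_genes(masked, cellpos[1] - 1L, cellpos[2] - 1L),
               "masked")
  expect_silent(cell_genes(masked, cellpos[1] - 1L, cellpos[2] - 1L,
                           allow_masked = TRUE))
})

test_that("gene classification matches matrix position semantics", {
  sch <- discretization_scheme(1.5)
  null_p <- pattern_of(c(0, 0, 0), sch)
  up1 <- pattern_of(c(1, 0, 0), sch)
  up2 <- pattern_of(c(1, 1, 0), sch)
  expect_equal(classify_gene(null_p, up1), "novel")
  expect_equal(classify_gene(up1, null_p), "missing")
  expect_equal(classify_gene(up1, up1), "common")
  expect_equal(classify_gene(up2, up1), "altered")
  expect_equal(classify_gene(null_p, null_p), "unresponsive")

  prof <- random_profile(200, seed = 35)
  m <- compact(prof, reference = "A", comparison = "B")
  cls <- classify_genes(m)
  a <- m$assignment
  expect_equal(unname(cls[a$ref == a$cmp & a$ref != 13L]),
               rep("common", sum(a$ref == a$cmp & a$ref != 13L)))
  expect_true(all(cls[a$ref == 13L & a$cmp != 13L] == "novel"))
  expect_true(all(cls[a$cmp == 13L & a$ref != 13L] == "missing"))
  # conservation: union over all unmasked cells recovers every gene
  genes <- unlist(lapply(0:26, function(i) lapply(0:26, function(j)
    cell_genes(m, i, j))))
  expect_setequal(genes, a$gene)
})

test_that("threshold sweep conserves genes and sparsifies monotonically", {
  prof <- random_profile(400, seed = 36)
  sweep <- threshold_sweep(prof, "A", "B")
  expect_equal(nrow(sweep$summary), 7L)
  expect_equal(sweep$summary$threshold, c(1.5, 1.75, 2, 2.5, 3, 3.5, 4))
  for (m in sweep$matrices) expect_equal(sum(m$counts), 400L)
  expect_true(all(diff(sweep$summary$null_in_both) >= 0))
  # genes contributing to non-null cells never increase with threshold
  expect_true(all(diff(400 - sweep$summary$null_in_both) <= 0))
  expect_error(threshold_sweep(prof, "A", "B", numeric(0)), "empty")
  expect_error(threshold_sweep(prof, "A", "B", c(1.5, 0.9)), "> 1")

  # a 2-fold gene is null-in-both at theta 4 but non-null at 1.5
  prof$values[1, , ] <- 0
  prof$values[1, "A", 1] <- 1.0
  s2 <- threshold_sweep(prof, "A", "B", c(1.5, 4))
  a15 <- s2$matrices[["1.5"]]$assignment
  a40 <- s2$matrices[["4"]]$assignment
  g <- prof$genes[1]
  expect_false(a15$ref[a15$gene == g] == 13L)
  expect_equal(a40$ref[a40$gene == g], 13L)
  expect_equal(a40$cmp[a40$gene == g], 13L)
})

test_that("cluster cross-tabulation matches a brute-force tally", {
  prof <- random_profile(200, seed = 37)
  m <- compact(prof, reference = "A", comparison = "B")
  set.seed(38)
  labels <- setNames(sample(c("M1", "M2", "M3"), 180, replace = TRUE),
                     sample(prof$genes, 180))
  tab <- cross_tabulate_clusters(m, labels)
  expect_equal(sum(tab), 200L)
  expect_equal(sum(tab[, "unlabeled"]), 20L)
  # brute force
  for (k in sample(nrow(m$assignment), 25)) {
    g <- m$assignment$gene[k]
    row <- paste0(m$assignment$ref[k], "|", m$assignment$cmp[k])
    col <- if (g %in% names(labels)) labels[[g]] else "unlabeled"
    manual <- sum(m$assignment$gene %in% names(which(labels == labels[g])) &
                    paste0(m$assignment$ref, "|", m$assignment$cmp) == row)
    if (col == "unlabeled")
      manual <- sum(!(m$assignment$gene %in% names(labels)) &
                      paste0(m$assignment$ref, "|", m$assignment$cmp) == row)
    expect_equal(unname(tab[row, col]), manual)
  }
  expect_error(cross_tabulate_clusters(m, setNames("M1", "absent_gene")),
               "no gene shared")
})

test_that("magnitude split partitions a cell exhaustively", {
  prof <- random_profile(50, seed = 39)
  # force three genes into one common cell with controlled magnitudes
  prof$values[1:3, "A", ] <- rep(c(1.0, 1.0, 2.0), 3)
  prof$values[1:3, "B", ] <- rep(c(2.0, 1.0, 0.9), 3)
  prof$values[1:3, "A", 1] <- c(0.9, 1.0, 2.0)
  prof$values[1:3, "B", 1] <- c(2.0, 1.0, 0.9)
  m <- compact(prof, reference = "A", comparison = "B")
  cell <- c(m$assignment$ref[m$assignment$gene == prof$genes[1]],
            m$assignment$cmp[m$assignment$gene == prof$genes[1]])
  split <- split_by_magnitude(m, cell, factor = 1.5)
  genes <- cell_genes(m, cell[1], cell[2], allow_masked = TRUE)
  expect_setequal(unlist(split), genes)
  expect_equal(sum(lengths(split)), length(genes))
  expect_true(prof$genes[1] %in% split$stronger_in_cmp)
  expect_true(prof$genes[2] %in% split$comparable)
  expect_true(prof$genes[3] %in% split$stronger_in_ref)
  expect_error(split_by_magnitude(m, cell, factor = 1), "> 1")
})
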
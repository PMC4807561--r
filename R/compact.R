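#' Build a comparative pattern-count (COMPACT) matrix
#'
#' The central constructor of the package. Each gene's time-series of average
#' log2 differentials versus baseline is discretized into regulation levels
#' and collated into a pattern vector per condition; `compact()` then
#' cross-tabulates the (reference-pattern, comparison-pattern) pairs over all
#' genes into an L^T x L^T count matrix. Rows are indexed by the reference
#' condition's pattern, columns by the comparison condition's pattern: cell
#' (i, j) counts the genes with pattern i in the reference group and pattern
#' j in the comparison group. The diagonal holds genes with a common
#' response; off-diagonal cells hold genes whose temporal response differs
#' between conditions.
#'
#' @param x An [expression_table()] or a `differential_profile` from
#'   [compute_differential()].
#' @param reference,comparison Group labels for the reference (rows) and
#'   comparison (columns) conditions.
#' @param threshold Fold-change discretization threshold (> 1); ignored when
#'   `scheme` is supplied.
#' @param scheme A [discretization_scheme()]; defaults to the ternary scheme
#'   at `threshold`.
#' @param baseline_mode Passed to [compute_differential()] when `x` is an
#'   expression table.
#' @param ... Passed between methods.
#' @return An object of class `compact`: list with `counts` (L^T x L^T
#'   integer matrix, dimnames are pattern labels), `assignment` (data frame
#'   gene/ref/cmp of 0-based pattern indices), `mask` (logical matrix, `TRUE`
#'   = hidden), `scheme`, `T`, `times`, `reference_group`,
#'   `comparison_group`, `total_genes`, `dropped` (genes undefined in either
#'   condition), and `profile` (the differential profile, kept for
#'   magnitude-based drill-down).
#' @examples
#' sim <- simulate_compact_data(simulation_config(n_genes = 50, seed = 1))
#' m <- compact(sim$expression, reference = "carbohydrate",
#'              comparison = "ethanol")
#' summary(m)
#' @export
compact <- function(x, ...) UseMethod("compact")

#' @rdname compact
#' @export
compact.expression_table <- function(x, reference, comparison,
                                     threshold = 1.5,
                                     scheme = discretization_scheme(threshold),
                                     baseline_mode = "auto", ...) {
  prof <- compute_differential(x, baseline_mode = baseline_mode)
  compact(prof, reference = reference, comparison = comparison,
          scheme = scheme, ...)
}

#' @rdname compact
#' @export
compact.differential_profile <- function(x, reference, comparison,
                                         threshold = 1.5,
                                         scheme =
                                           discretization_scheme(threshold),
                                         ...) {
  idx_ref <- pattern_index_matrix(profile_matrix(x, reference), scheme)
  idx_cmp <- pattern_index_matrix(profile_matrix(x, comparison), scheme)
  m <- build_compact(idx_ref, idx_cmp, scheme, T = length(x$times))
  m$reference_group <- reference
  m$comparison_group <- comparison
  m$times <- x$times
  m$profile <- x
  m
}

#' Build a COMPACT matrix from two pattern assignments
#'
#' Lower-level constructor taking precomputed gene-to-pattern maps (named
#' integer vectors of 0-based canonical indices, or named lists of
#' `pattern_code`s). The gene universe is the intersection of the two maps;
#' genes present in only one map, or with an undefined (`NA`) pattern in
#' either, are excluded and reported in `dropped`.
#'
#' @param patterns_ref,patterns_cmp Named integer vectors (gene id ->
#'   0-based pattern index, `NA` = undefined) or named lists of
#'   `pattern_code` objects.
#' @param scheme A [discretization_scheme()].
#' @param T Number of time points (inferred from indices' range if omitted
#'   is not possible, so it must be supplied).
#' @return A `compact` object (see [compact()]); group labels are `"ref"`
#'   and `"cmp"` until set by the caller.
#' @export
build_compact <- function(patterns_ref, patterns_cmp, scheme, T) {
  patterns_ref <- as_pattern_index(patterns_ref)
  patterns_cmp <- as_pattern_index(patterns_cmp)
  K <- scheme$n_levels^T
  shared <- intersect(names(patterns_ref), names(patterns_cmp))
  if (length(shared) == 0L) stop("empty gene intersection")
  r <- patterns_ref[shared]
  c_ <- patterns_cmp[shared]
  defined <- !is.na(r) & !is.na(c_)
  dropped <- list(
    ref_only = setdiff(names(patterns_ref), shared),
    cmp_only = setdiff(names(patterns_cmp), shared),
    undefined = shared[!defined])
  if (!any(defined)) stop("no gene has a defined pattern in both conditions")
  assignment <- data.frame(gene = shared[defined], ref = unname(r[defined]),
                           cmp = unname(c_[defined]),
                           stringsAsFactors = FALSE)
  labels <- pattern_labels(scheme, T)
  counts <- table(factor(assignment$ref, levels = 0:(K - 1L)),
                  factor(assignment$cmp, levels = 0:(K - 1L)))
  counts <- matrix(as.integer(counts), K, K,
                   dimnames = list(reference = labels, comparison = labels))
  structure(list(counts = counts, assignment = assignment,
                 mask = matrix(FALSE, K, K), scheme = scheme, T = T,
                 times = NULL, reference_group = "ref",
                 comparison_group = "cmp",
                 total_genes = nrow(assignment), dropped = dropped),
            class = "compact")
}

as_pattern_index <- function(p) {
  if (is.list(p) && all(vapply(p, inherits, TRUE, "pattern_code"))) {
    idx <- vapply(p, function(z) as.integer(z$index), 1L)
    names(idx) <- names(p)
    return(idx)
  }
  if (is.null(names(p))) stop("pattern assignment must be named by gene id")
  storage.mode(p) <- "integer"
  p
}

#' Transpose a COMPACT matrix
#'
#' Swaps the reference and comparison roles: `t(compact(A, B))` equals
#' `compact(B, A)` cell for cell; the diagonal is unchanged and double
#' transposition is the identity. Masking state is transposed along.
#'
#' @param x A `compact` object.
#' @return A `compact` object with roles swapped.
#' @export
t.compact <- function(x) {
  out <- x
  out$counts <- t(x$counts)
  names(dimnames(out$counts)) <- c("reference", "comparison")
  out$mask <- t(x$mask)
  out$assignment <- data.frame(gene = x$assignment$gene,
                               ref = x$assignment$cmp,
                               cmp = x$assignment$ref,
                               stringsAsFactors = FALSE)
  out$reference_group <- x$comparison_group
  out$comparison_group <- x$reference_group
  out
}

#' Partition a COMPACT matrix into sections by basis-time regulation
#'
#' Assigns each cell (i, j) to a section by the pair (level of the row
#' pattern at the basis time point, level of the column pattern at the basis
#' time point). For the ternary scheme this yields 9 sections labelled
#' `a`..`i` in raster order — rows by reference level (up, null, down),
#' columns by comparison level — so the central section `e` collects the
#' cells where neither condition shows regulation at the basis time (81 of
#' 729 cells for T = 3), and `c`/`g` collect opposite basis-time regulation.
#'
#' @param m A `compact` object.
#' @param basis_time 1-based time-point position used for sectioning
#'   (default 1, the first post-baseline time point).
#' @return A `section_partition`: list with `ids` (L^T x L^T character
#'   matrix of section ids), `sections` (named list of 2-column cell-index
#'   matrices, 1-based), `central` (the null/null section id), and
#'   `basis_time`.
#' @export
section_partition <- function(m, basis_time = 1L) {
  stopifnot(inherits(m, "compact"))
  if (basis_time < 1L || basis_time > m$T)
    stop("basis_time must be in 1..", m$T)
  L <- m$scheme$n_levels
  K <- L^m$T
  digit <- (0:(K - 1L)) %/% L^(m$T - basis_time) %% L
  sec_names <- section_ids(L)
  ids <- matrix(sec_names[outer(digit, digit,
                                function(r, cc) r * L + cc) + 1L], K, K)
  sections <- lapply(sec_names, function(s) which(ids == s, arr.ind = TRUE))
  names(sections) <- sec_names
  central_rank <- scheme_null_rank(m$scheme)
  structure(list(ids = ids, sections = sections,
                 central = sec_names[central_rank * L + central_rank + 1L],
                 basis_time = as.integer(basis_time)),
            class = "section_partition")
}

section_ids <- function(L) {
  n <- L * L
  if (n <= 26L) letters[seq_len(n)] else sprintf("s%02d", seq_len(n))
}

#' @export
print.section_partition <- function(x, ...) {
  cat("section_partition: ", length(x$sections), " sections at basis time ",
      x$basis_time, "; central section '", x$central, "' (",
      nrow(x$sections[[x$central]]), " cells)\n", sep = "")
  invisible(x)
}

#' Mask cells of a COMPACT matrix
#'
#' Masking hides cells from reporting and visualization without deleting
#' counts or memberships, supporting the layered exploration workflow of
#' hiding dominant blocks (typically the central section) to reveal sparser
#' patterns. Masks compose by union, so repeated masking is cumulative and
#' idempotent for identical rules.
#'
#' @param m A `compact` object.
#' @param sections Character vector of section ids to hide (see
#'   [section_partition()]).
#' @param min_count Hide every cell with count strictly below this value.
#' @param cells Two-column matrix/data frame of 0-based (ref, cmp) pattern
#'   index pairs to hide.
#' @param basis_time Basis time for resolving `sections` (default 1).
#' @return A `compact` object with the updated mask.
#' @export
mask_cells <- function(m, sections = NULL, min_count = NULL, cells = NULL,
                       basis_time = 1L) {
  stopifnot(inherits(m, "compact"))
  mask <- m$mask
  if (!is.null(sections)) {
    part <- section_partition(m, basis_time)
    bad <- setdiff(sections, names(part$sections))
    if (length(bad))
      stop("unknown section id(s): ", paste(bad, collapse = ", "))
    for (s in sections) mask[part$sections[[s]]] <- TRUE
  }
  if (!is.null(min_count)) mask[m$counts < min_count] <- TRUE
  if (!is.null(cells)) {
    cells <- as.matrix(cells)
    if (ncol(cells) != 2L) stop("`cells` needs two columns (ref, cmp)")
    K <- nrow(m$counts)
    if (any(cells < 0L) || any(cells >= K))
      stop("cell indices must be 0-based pattern indices in 0..", K - 1L)
    mask[cells + 1L] <- TRUE
  }
  m$mask <- mask
  m
}

#' Clear the mask of a COMPACT matrix
#' @param m A `compact` object.
#' @return `m` with an all-false mask.
#' @export
unmask <- function(m) {
  stopifnot(inherits(m, "compact"))
  m$mask[] <- FALSE
  m
}

#' Genes in one cell of a COMPACT matrix
#'
#' @param m A `compact` object.
#' @param ref,cmp 0-based canonical pattern indices of the row (reference)
#'   and column (comparison) pattern.
#' @param allow_masked Set `TRUE` to read a masked cell explicitly; by
#'   default masked cells error to keep layered views honest.
#' @return Character vector of gene ids (possibly empty), sorted.
#' @export
cell_genes <- function(m, ref, cmp, allow_masked = FALSE) {
  stopifnot(inherits(m, "compact"))
  K <- nrow(m$counts)
  if (ref < 0L || ref >= K || cmp < 0L || cmp >= K)
    stop("pattern indices must be in 0..", K - 1L)
  if (!allow_masked && m$mask[ref + 1L, cmp + 1L])
    stop("cell is masked; pass allow_masked = TRUE to read it anyway")
  sort(m$assignment$gene[m$assignment$ref == ref & m$assignment$cmp == cmp])
}

#' Classify a gene by its comparative pattern pair
#'
#' Given a gene's pattern in the reference and comparison conditions:
#' `common` — identical non-null patterns; `novel` — differential expression
#' only in the comparison condition (reference pattern all-null); `missing`
#' — only in the reference condition; `unresponsive` — all-null in both;
#' `altered` — differing non-null patterns.
#'
#' @param ref_pattern,cmp_pattern `pattern_code` objects or 0-based
#'   canonical indices.
#' @param scheme A [discretization_scheme()] (needed when indices are
#'   given).
#' @param T Number of time points (needed when indices are given).
#' @return One of `"common"`, `"novel"`, `"missing"`, `"altered"`,
#'   `"unresponsive"` (vectorized over index input).
#' @export
classify_gene <- function(ref_pattern, cmp_pattern,
                          scheme = discretization_scheme(), T = 3L) {
  idx <- function(p) if (inherits(p, "pattern_code")) p$index else
    as.integer(p)
  r <- idx(ref_pattern); cc <- idx(cmp_pattern)
  if (anyNA(r) || anyNA(cc)) stop("patterns must be defined")
  null_i <- null_index(scheme, T)
  ifelse(r == null_i & cc == null_i, "unresponsive",
    ifelse(r == cc, "common",
      ifelse(r == null_i, "novel",
        ifelse(cc == null_i, "missing", "altered"))))
}

#' Per-gene comparative classification for a COMPACT matrix
#'
#' @param m A `compact` object.
#' @return Named character vector (gene -> classification), see
#'   [classify_gene()].
#' @export
classify_genes <- function(m) {
  stopifnot(inherits(m, "compact"))
  out <- classify_gene(m$assignment$ref, m$assignment$cmp,
                       scheme = m$scheme, T = m$T)
  names(out) <- m$assignment$gene
  out
}

#' Rebuild the COMPACT matrix across a series of discretization thresholds
#'
#' Sweeps the fold-change threshold and reports how the matrix's sparsity
#' structure changes: at stringent thresholds only the largest expression
#' changes populate a few cells; relaxing the threshold fills in more cells
#' until the sparse structure stabilizes.
#'
#' @param profile A `differential_profile`.
#' @param reference,comparison Group labels.
#' @param thresholds Fold-change thresholds, all > 1. The default grid
#'   spans the range commonly explored (1.5-fold to 4-fold).
#' @return A `compact_sweep`: list with `matrices` (one `compact` per
#'   threshold, named) and `summary` (data frame: threshold, nonzero_cells,
#'   off_diagonal_genes, null_in_both).
#' @export
threshold_sweep <- function(profile, reference, comparison,
                            thresholds = c(1.5, 1.75, 2, 2.5, 3, 3.5, 4)) {
  stopifnot(inherits(profile, "differential_profile"))
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (any(thresholds <= 1)) stop("all thresholds must be > 1")
  mats <- lapply(thresholds, function(th)
    compact(profile, reference = reference, comparison = comparison,
            scheme = discretization_scheme(th)))
  names(mats) <- as.character(thresholds)
  summ <- do.call(rbind, lapply(seq_along(mats), function(k) {
    m <- mats[[k]]
    null_i <- null_index(m$scheme, m$T)
    data.frame(threshold = thresholds[k],
               nonzero_cells = sum(m$counts > 0L),
               off_diagonal_genes = sum(m$counts) - sum(diag(m$counts)),
               null_in_both = m$counts[null_i + 1L, null_i + 1L])
  }))
  structure(list(matrices = mats, summary = summ), class = "compact_sweep")
}

#' @export
print.compact_sweep <- function(x, ...) {
  cat("compact_sweep over", nrow(x$summary), "threshold(s):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-proportion z-test
#'
#' Pooled-variance two-proportion z statistic without continuity correction,
#' with a two-tailed p-value from the standard normal — the test used to
#' compare per-pattern gene proportions between conditions. When the pooled
#' proportion is degenerate (0 or 1) the statistic is defined as z = 0,
#' p = 1.
#'
#' @param count_a,n_a Successes and trials in group A.
#' @param count_b,n_b Successes and trials in group B.
#' @return A `prop_ztest`: list with the inputs plus `z` and `p`.
#' @examples
#' proportion_ztest(30, 1000, 60, 1000)
#' @export
proportion_ztest <- function(count_a, n_a, count_b, n_b) {
  if (n_a <= 0L || n_b <= 0L) stop("n_a and n_b must be positive")
  if (count_a < 0L || count_b < 0L || count_a > n_a || count_b > n_b)
    stop("counts must satisfy 0 <= count <= n")
  p_pool <- (count_a + count_b) / (n_a + n_b)
  if (p_pool <= 0 || p_pool >= 1) {
    z <- 0; p <- 1
  } else {
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n_a + 1 / n_b))
    z <- (count_a / n_a - count_b / n_b) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(count_a = count_a, n_a = n_a, count_b = count_b, n_b = n_b,
                 z = z, p = p),
            class = "prop_ztest")
}

#' @export
print.prop_ztest <- function(x, ...) {
  cat(sprintf("two-proportion z-test: %d/%d vs %d/%d  z = %.3f, p = %.4g\n",
              x$count_a, x$n_a, x$count_b, x$n_b, x$z, x$p))
  invisible(x)
}

#' Z-tests of every pattern's gene proportion between two conditions
#'
#' Runs one two-tailed [proportion_ztest()] per pattern, comparing the
#' fraction of genes in that pattern between two pattern histograms, and
#' flags significance at `alpha` (default 2e-4, a stringent fixed cutoff
#' appropriate for 27 simultaneous tests). Multiple-testing adjustment
#' beyond the fixed cutoff is left to the caller.
#'
#' @param hist_a,hist_b [pattern_histogram()]s sharing scheme and T.
#' @param alpha Two-tailed significance cutoff.
#' @return Data frame with one row per pattern: `index`, `pattern`,
#'   `count_a`, `count_b`, `z`, `p`, `significant`; totals `n_a`, `n_b` as
#'   attributes, and `attr(, "significant_patterns")` holds the flagged
#'   0-based indices.
#' @export
test_all_patterns <- function(hist_a, hist_b, alpha = 2e-4) {
  stopifnot(inherits(hist_a, "pattern_histogram"),
            inherits(hist_b, "pattern_histogram"))
  if (hist_a$T != hist_b$T ||
      !identical(hist_a$scheme$up_thresholds, hist_b$scheme$up_thresholds))
    stop("histograms use different schemes or time-point counts")
  n_a <- sum(hist_a$counts); n_b <- sum(hist_b$counts)
  if (n_a == 0L || n_b == 0L) stop("empty histogram")
  K <- length(hist_a$counts)
  res <- lapply(seq_len(K), function(i)
    proportion_ztest(hist_a$counts[i], n_a, hist_b$counts[i], n_b))
  out <- data.frame(index = 0:(K - 1L), pattern = names(hist_a$counts),
                    count_a = unname(hist_a$counts),
                    count_b = unname(hist_b$counts),
                    z = vapply(res, `[[`, 1, "z"),
                    p = vapply(res, `[[`, 1, "p"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < alpha
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  attr(out, "significant_patterns") <- out$index[out$significant]
  out
}

#' Cross-tabulate comparative patterns against external cluster labels
#'
#' Counts genes per (comparative pattern, cluster label) pair, e.g. to
#' intersect the COMPACT assignment with externally computed co-expression
#' module memberships. Genes present in the pattern assignment but missing a
#' cluster label are counted under a reserved `"unlabeled"` column.
#'
#' @param m A `compact` object (its gene assignment is used), or a data
#'   frame with columns `gene`, `ref`, `cmp`.
#' @param cluster_labels Named character vector (gene id -> cluster label).
#' @return Integer matrix: rows are comparative patterns (`"refLabel|cmpLabel"`),
#'   columns cluster labels (reserved `"unlabeled"` last when present).
#' @export
cross_tabulate_clusters <- function(m, cluster_labels) {
  assignment <- if (inherits(m, "compact")) m$assignment else
    as.data.frame(m)
  if (nrow(assignment) == 0L) stop("empty pattern assignment")
  if (is.null(names(cluster_labels)) || length(cluster_labels) == 0L)
    stop("cluster_labels must be a named vector")
  if (!any(assignment$gene %in% names(cluster_labels)))
    stop("no gene shared between pattern assignment and cluster labels")
  lab <- cluster_labels[assignment$gene]
  lab[is.na(lab)] <- "unlabeled"
  comb <- paste0(assignment$ref, "|", assignment$cmp)
  tab <- table(comb, lab)
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  if ("unlabeled" %in% colnames(out))
    out <- out[, c(setdiff(colnames(out), "unlabeled"), "unlabeled"),
               drop = FALSE]
  out
}

#' Split a common-pattern cell by differential magnitude
#'
#' Within one cell of the matrix — typically a diagonal (common-response)
#' cell — partitions the member genes by whether the maximum absolute log2
#' differential in one condition exceeds `factor` times the other's:
#' `stronger_in_cmp`, `stronger_in_ref`, or `comparable`. The partition is
#' exhaustive and disjoint. The magnitude criterion is deliberately
#' caller-chosen via `factor`.
#'
#' @param m A `compact` object built from a differential profile (so that
#'   per-gene magnitudes are available).
#' @param cell Length-2 vector of 0-based (ref, cmp) pattern indices.
#' @param factor Ratio (> 1) a condition's maximum |log2 differential| must
#'   exceed relative to the other to be called stronger.
#' @return List of character vectors `stronger_in_cmp`, `stronger_in_ref`,
#'   `comparable`.
#' @export
split_by_magnitude <- function(m, cell, factor) {
  stopifnot(inherits(m, "compact"))
  if (is.null(m$profile))
    stop("matrix was not built from a differential profile")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1)
    stop("factor must be a single number > 1")
  genes <- cell_genes(m, cell[1L], cell[2L], allow_masked = TRUE)
  if (length(genes) == 0L) stop("cell is empty")
  ref_max <- apply(abs(profile_matrix(m$profile, m$reference_group)[genes, ,
                                                                    drop = FALSE]),
                   1L, max)
  cmp_max <- apply(abs(profile_matrix(m$profile, m$comparison_group)[genes, ,
                                                                     drop = FALSE]),
                   1L, max)
  list(stronger_in_cmp = genes[cmp_max > factor * ref_max],
       stronger_in_ref = genes[ref_max > factor * cmp_max],
       comparable = genes[!(cmp_max > factor * ref_max) &
                            !(ref_max > factor * cmp_max)])
}

#' @export
print.compact <- function(x, ...) {
  K <- nrow(x$counts)
  cat("COMPACT matrix: ", x$reference_group, " (rows) vs ",
      x$comparison_group, " (columns)\n", sep = "")
  cat(K, " x ", K, " = ", K * K, " cells (", x$scheme$n_levels,
      " levels, T = ", x$T, "); ", x$total_genes, " genes\n", sep = "")
  cat("non-zero cells: ", sum(x$counts > 0L), "; masked cells: ",
      sum(x$mask), "\n", sep = "")
  invisible(x)
}

#' @export
summary.compact <- function(object, basis_time = 1L, ...) {
  cls <- classify_genes(object)
  part <- section_partition(object, basis_time)
  sec_counts <- vapply(part$sections, function(cells)
    sum(object$counts[cells]), 0)
  out <- list(
    dims = dim(object$counts),
    total_genes = object$total_genes,
    diagonal_genes = sum(diag(object$counts)),
    off_diagonal_genes = object$total_genes - sum(diag(object$counts)),
    nonzero_cells = sum(object$counts > 0L),
    masked_cells = sum(object$mask),
    classification = table(factor(cls, levels = c("common", "novel",
                                                  "missing", "altered",
                                                  "unresponsive"))),
    section_genes = sec_counts,
    dropped = lengths(object$dropped))
  class(out) <- "summary.compact"
  out
}

#' @export
print.summary.compact <- function(x, ...) {
  cat("COMPACT matrix, ", x$dims[1L], " x ", x$dims[2L], " cells, ",
      x$total_genes, " genes\n", sep = "")
  cat("  diagonal (common response): ", x$diagonal_genes,
      "; off-diagonal (altered): ", x$off_diagonal_genes, "\n", sep = "")
  cat("  non-zero cells: ", x$nonzero_cells, "; masked: ", x$masked_cells,
      "\n", sep = "")
  cat("  classification:\n")
  print(x$classification)
  cat("  genes per section (basis time):\n")
  print(x$section_genes)
  invisible(x)
}

#' Serialize a COMPACT matrix to TSV
#'
#' One row per cell: row-pattern label, column-pattern label, count, masked
#' flag, and comma-joined gene ids.
#'
#' @param m A `compact` object.
#' @param path Output file path.
#' @param include_masked Write masked cells too (default `TRUE`; they are
#'   flagged either way).
#' @return `path`, invisibly.
#' @export
write_compact_tsv <- function(m, path, include_masked = TRUE) {
  stopifnot(inherits(m, "compact"))
  K <- nrow(m$counts)
  labels <- rownames(m$counts)
  mem <- split(m$assignment$gene,
               list(factor(m$assignment$ref, levels = 0:(K - 1L)),
                    factor(m$assignment$cmp, levels = 0:(K - 1L))))
  grid <- expand.grid(ref = 0:(K - 1L), cmp = 0:(K - 1L))
  grid <- grid[order(grid$ref, grid$cmp), ]
  df <- data.frame(
    reference_pattern = labels[grid$ref + 1L],
    comparison_pattern = labels[grid$cmp + 1L],
    count = m$counts[as.matrix(grid) + 1L],
    masked = m$mask[as.matrix(grid) + 1L],
    genes = vapply(paste(grid$ref, grid$cmp, sep = "."), function(k) {
      g <- mem[[k]]
      if (is.null(g) || !length(g)) "" else paste(sort(g), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)
  if (!include_masked) df <- df[!df$masked, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' JSON summary of a COMPACT matrix
#'
#' Writes counts, mask, section partition, totals, and dropped-gene report
#' as a structured JSON document.
#'
#' @param m A `compact` object.
#' @param path Output file path.
#' @param basis_time Basis time for the section report.
#' @return `path`, invisibly.
#' @export
write_compact_json <- function(m, path, basis_time = 1L) {
  stopifnot(inherits(m, "compact"))
  part <- section_partition(m, basis_time)
  s <- summary(m, basis_time = basis_time)
  doc <- list(
    reference_group = m$reference_group,
    comparison_group = m$comparison_group,
    n_levels = m$scheme$n_levels,
    fold_thresholds = m$scheme$up_thresholds,
    T = m$T,
    total_genes = m$total_genes,
    nonzero_cells = s$nonzero_cells,
    diagonal_genes = s$diagonal_genes,
    off_diagonal_genes = s$off_diagonal_genes,
    counts = unname(apply(m$counts, 1L, as.integer, simplify = FALSE)),
    mask = unname(apply(m$mask, 1L, as.logical, simplify = FALSE)),
    pattern_labels = rownames(m$counts),
    sections = lapply(part$sections, function(cells)
      sum(m$counts[cells])),
    central_section = part$central,
    dropped = m$dropped)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
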
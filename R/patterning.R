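#' Discretization scheme for regulation levels
#'
#' Defines the ordered fold-change thresholds that map a log2 differential to
#' a regulation level. The default single threshold yields the ternary scheme
#' (+1 up, 0 no change, -1 down). Supplying k increasing thresholds yields
#' L = 2k + 1 sign-symmetric levels (e.g. two thresholds give strong-up,
#' weak-up, null, weak-down, strong-down). Levels are ranked from strongest
#' up (rank 0) to strongest down (rank L - 1); the middle rank is the null
#' level.
#'
#' @param up_thresholds Strictly increasing fold-change values, all > 1.
#'   Down thresholds are mirrored automatically.
#' @return A `discretization_scheme`: list with `up_thresholds`, `cuts`
#'   (log2 thresholds), `n_levels`, `level_labels` (numeric, +k..-k), and
#'   `level_symbols` (display strings; `+`, `0`, `-` for ternary).
#' @examples
#' discretization_scheme(1.5)        # ternary at 1.5-fold
#' discretization_scheme(c(1.5, 4))  # five levels
#' @export
discretization_scheme <- function(up_thresholds = 1.5) {
  if (!is.numeric(up_thresholds) || length(up_thresholds) < 1L ||
      any(up_thresholds <= 1) || is.unsorted(up_thresholds, strictly = TRUE))
    stop("up_thresholds must be strictly increasing fold changes, all > 1")
  k <- length(up_thresholds)
  L <- 2L * k + 1L
  labels <- seq(k, -k)
  symbols <- if (k == 1L) c("+", "0", "-") else
    ifelse(labels > 0, paste0("+", labels),
           ifelse(labels < 0, as.character(labels), "0"))
  structure(list(up_thresholds = as.numeric(up_thresholds),
                 cuts = log2(as.numeric(up_thresholds)),
                 n_levels = L, level_labels = labels,
                 level_symbols = symbols),
            class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("discretization_scheme: ", x$n_levels, " levels at fold threshold(s) ",
      paste(x$up_thresholds, collapse = ", "), "\n", sep = "")
  invisible(x)
}

scheme_null_rank <- function(scheme) (scheme$n_levels - 1L) %/% 2L

null_index <- function(scheme, T) {
  (scheme$n_levels^T - 1L) %/% 2L
}

#' Discretize a log2 differential into a regulation level
#'
#' Boundary values are inclusive toward the stronger level: in the ternary
#' scheme, `d >= log2(theta)` maps to +1, `d <= -log2(theta)` to -1, else 0.
#' With multiple thresholds the level is set by the largest threshold whose
#' log2 value `|d|` meets or exceeds, sign-symmetrically.
#'
#' @param d Numeric vector of finite log2 differentials.
#' @param scheme A [discretization_scheme()].
#' @return Numeric vector of level labels (e.g. +1/0/-1).
#' @export
discretize_value <- function(d, scheme = discretization_scheme()) {
  if (any(!is.finite(d))) stop("non-finite differential value")
  scheme$level_labels[discretize_rank(d, scheme) + 1L]
}

# vectorized rank (0 = strongest up .. L-1 = strongest down); NA passes through
discretize_rank <- function(d, scheme) {
  m <- scheme_null_rank(scheme)
  s <- 0L
  for (cc in scheme$cuts) s <- s + (abs(d) >= cc)
  as.integer(m - sign(d) * s)
}

#' Encode a gene's differential trajectory as a pattern code
#'
#' Applies [discretize_value()] at every time point and attaches the
#' canonical integer index: the base-L number whose digits are the level
#' ranks (0 = strongest up), most significant digit first time point. The
#' all-null pattern therefore sits at index `(L^T - 1) / 2`, centered in the
#' ordering with up-leading patterns above and down-leading patterns below.
#'
#' @param d Length-T numeric vector of log2 differentials for one gene.
#'   Any missing value makes the pattern undefined (`NA` index).
#' @param scheme A [discretization_scheme()].
#' @return A `pattern_code`: list with `levels` (level labels per time
#'   point), `index` (0-based canonical index), and `label` (display string,
#'   e.g. `"+0-"`).
#' @examples
#' pattern_of(c(1.2, 0, -1.2))           # "+0-"
#' pattern_of(c(0, 0, 0))$index          # 13 for ternary, T = 3
#' @export
pattern_of <- function(d, scheme = discretization_scheme()) {
  if (length(d) < 1L) stop("empty trajectory")
  if (any(is.na(d))) {
    return(structure(list(levels = rep(NA_real_, length(d)),
                          index = NA_integer_, label = NA_character_),
                     class = "pattern_code"))
  }
  ranks <- discretize_rank(d, scheme)
  structure(list(levels = scheme$level_labels[ranks + 1L],
                 index = index_from_ranks(ranks, scheme$n_levels),
                 label = label_from_ranks(ranks, scheme)),
            class = "pattern_code")
}

#' @export
print.pattern_code <- function(x, ...) {
  if (is.na(x$index)) cat("pattern_code: undefined (missing values)\n")
  else cat("pattern_code: ", x$label, " (index ", x$index, ")\n", sep = "")
  invisible(x)
}

index_from_ranks <- function(ranks, L) {
  T <- length(ranks)
  as.integer(sum(ranks * L^((T - 1L):0L)))
}

ranks_from_index <- function(index, L, T) {
  index <- as.integer(index)
  digits <- integer(T)
  for (t in T:1L) {
    digits[t] <- index %% L
    index <- index %/% L
  }
  digits
}

label_from_ranks <- function(ranks, scheme) {
  sym <- scheme$level_symbols[ranks + 1L]
  collapse <- if (scheme$n_levels == 3L) "" else ","
  paste(sym, collapse = collapse)
}

pattern_labels <- function(scheme, T) {
  K <- scheme$n_levels^T
  vapply(0:(K - 1L), function(i)
    label_from_ranks(ranks_from_index(i, scheme$n_levels, T), scheme), "")
}

# genes x T matrix of differentials -> integer vector of 0-based pattern
# indices, NA where any time point is missing
pattern_index_matrix <- function(D, scheme) {
  L <- scheme$n_levels
  T <- ncol(D)
  ranks <- discretize_rank(D, scheme)
  dim(ranks) <- dim(D)
  idx <- as.integer(ranks %*% L^((T - 1L):0L))
  names(idx) <- rownames(D)
  idx
}

#' Enumerate all patterns in canonical order
#'
#' Lists every one of the L^T patterns for a scheme and T time points, in
#' canonical index order: recursively, the up-at-first-time-point block comes
#' first, then the null block (containing the centered all-null pattern),
#' then the down block.
#'
#' @param scheme A [discretization_scheme()].
#' @param T Number of post-baseline time points (>= 1).
#' @return Data frame with columns `index` (0-based) and `label`, plus an
#'   attribute `ranks` (L^T x T integer matrix of level ranks).
#' @examples
#' nrow(enumerate_patterns(discretization_scheme(1.5), 3))  # 27
#' @export
enumerate_patterns <- function(scheme = discretization_scheme(), T = 3L) {
  if (!is.numeric(T) || T < 1L) stop("T must be >= 1")
  T <- as.integer(T)
  L <- scheme$n_levels
  K <- L^T
  ranks <- t(vapply(0:(K - 1L), ranks_from_index, integer(T), L = L, T = T))
  dim(ranks) <- c(K, T)  # vapply drops dims for T = 1
  out <- data.frame(index = 0:(K - 1L), label = pattern_labels(scheme, T),
                    stringsAsFactors = FALSE)
  attr(out, "ranks") <- ranks
  out
}

#' Univariate pattern histogram for one condition
#'
#' Tallies genes by canonical pattern within one group of a differential
#' profile. Genes with an undefined pattern (a missing differential at any
#' time point) are excluded from the counts and reported in `undefined`.
#'
#' @param profile A `differential_profile` from [compute_differential()].
#' @param group Group (condition) label to tabulate.
#' @param scheme A [discretization_scheme()].
#' @return A `pattern_histogram`: list with `counts` (named integer vector of
#'   length L^T, names are pattern labels), `index` (per-gene 0-based pattern
#'   index, named by gene), `members` (list mapping pattern index as
#'   character to gene ids), `undefined` (gene ids excluded), `group`,
#'   `scheme`, `T`.
#' @export
pattern_histogram <- function(profile, group,
                              scheme = discretization_scheme()) {
  D <- profile_matrix(profile, group)
  if (nrow(D) == 0L) warning("empty gene set; histogram is empty")
  idx <- pattern_index_matrix(D, scheme)
  K <- scheme$n_levels^ncol(D)
  undefined <- names(idx)[is.na(idx)]
  ok <- idx[!is.na(idx)]
  counts <- tabulate(ok + 1L, nbins = K)
  names(counts) <- pattern_labels(scheme, ncol(D))
  members <- split(names(ok), ok)
  structure(list(counts = counts, index = idx, members = members,
                 undefined = undefined, group = group, scheme = scheme,
                 T = ncol(D)),
            class = "pattern_histogram")
}

#' @export
print.pattern_histogram <- function(x, n = 10L, ...) {
  cat("pattern_histogram for group '", x$group, "': ", sum(x$counts),
      " genes over ", length(x$counts), " patterns (",
      length(x$undefined), " undefined)\n", sep = "")
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  print(utils::head(top, n))
  invisible(x)
}

#' Order genes by their canonical pattern
#'
#' Sorts genes by canonical pattern index (up-leading patterns first, null
#' centered, down-leading last), breaking ties by descending maximum
#' absolute log2 differential, then lexicographic gene id. Deterministic:
#' permuting the input gene order leaves the output unchanged. This is the
#' row ordering used for pattern-sorted heatmaps.
#'
#' @param histogram A [pattern_histogram()].
#' @param profile The `differential_profile` the histogram was built from.
#' @return Character vector of gene ids with defined patterns, ordered.
#' @export
order_genes_by_pattern <- function(histogram, profile) {
  stopifnot(inherits(histogram, "pattern_histogram"))
  D <- profile_matrix(profile, histogram$group)
  idx <- histogram$index
  genes <- names(idx)[!is.na(idx)]
  maxd <- apply(abs(D[genes, , drop = FALSE]), 1L, max)
  genes[order(idx[genes], -maxd, genes, method = "radix")]
}

#' Write a pattern histogram to TSV
#'
#' Columns: 0-based pattern index, level label string, gene count, and
#' comma-joined member gene ids.
#'
#' @param histogram A [pattern_histogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_histogram <- function(histogram, path) {
  stopifnot(inherits(histogram, "pattern_histogram"))
  K <- length(histogram$counts)
  genes <- vapply(0:(K - 1L), function(i) {
    mem <- histogram$members[[as.character(i)]]
    if (is.null(mem)) "" else paste(sort(mem), collapse = ",")
  }, "")
  utils::write.table(
    data.frame(index = 0:(K - 1L), pattern = names(histogram$counts),
               count = unname(histogram$counts), genes = genes,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}
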
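#' Chord-diagram layout for a COMPACT matrix
#'
#' Computes the arc and ribbon geometry of a chord-diagram view: one arc per
#' non-empty pattern on each side (reference and comparison), with arc length
#' proportional to the pattern's unmasked gene count, and one ribbon per
#' unmasked non-zero cell with width equal to the cell's gene count. Arcs are
#' grouped into up / null / down segments by the pattern's overall direction
#' (its first non-null level; the all-null pattern forms the null segment
#' that separates up from down), and ordered by canonical index within each
#' segment. Genes whose partner-side pattern is fully masked are excluded
#' from arc lengths and reported in `masked_genes`.
#'
#' @param m A `compact` object.
#' @return A `chord_layout`: list with `arcs` (data frame: side, index,
#'   pattern, segment, length), `ribbons` (data frame: ref, cmp, width),
#'   and `masked_genes` (count of genes hidden by the mask).
#' @export
chord_layout <- function(m) {
  stopifnot(inherits(m, "compact"))
  visible <- m$counts * !m$mask
  if (sum(visible) == 0L) stop("fully masked matrix: no visible genes")
  K <- nrow(m$counts)
  seg <- pattern_segments(m$scheme, m$T)
  seg_order <- c(up = 1L, null = 2L, down = 3L)

  make_arcs <- function(side, lens) {
    keep <- which(lens > 0L)
    df <- data.frame(side = side, index = keep - 1L,
                     pattern = rownames(m$counts)[keep],
                     segment = seg[keep], length = lens[keep],
                     stringsAsFactors = FALSE)
    df[order(seg_order[df$segment], df$index), , drop = FALSE]
  }
  arcs <- rbind(make_arcs("reference", rowSums(visible)),
                make_arcs("comparison", colSums(visible)))
  rownames(arcs) <- NULL

  nz <- which(visible > 0L, arr.ind = TRUE)
  ribbons <- data.frame(ref = nz[, 1L] - 1L, cmp = nz[, 2L] - 1L,
                        width = visible[nz])
  ribbons <- ribbons[order(ribbons$ref, ribbons$cmp), , drop = FALSE]
  rownames(ribbons) <- NULL
  structure(list(arcs = arcs, ribbons = ribbons,
                 masked_genes = sum(m$counts) - sum(visible)),
            class = "chord_layout")
}

# per-pattern segment by first non-null level: "up", "null", or "down"
pattern_segments <- function(scheme, T) {
  K <- scheme$n_levels^T
  mrank <- scheme_null_rank(scheme)
  vapply(0:(K - 1L), function(i) {
    r <- ranks_from_index(i, scheme$n_levels, T)
    nn <- r[r != mrank]
    if (!length(nn)) "null" else if (nn[1L] < mrank) "up" else "down"
  }, "")
}

#' @export
print.chord_layout <- function(x, ...) {
  cat("chord_layout: ", sum(x$arcs$side == "reference"), " reference arcs, ",
      sum(x$arcs$side == "comparison"), " comparison arcs, ",
      nrow(x$ribbons), " ribbons (", sum(x$ribbons$width),
      " genes visible, ", x$masked_genes, " masked)\n", sep = "")
  invisible(x)
}

#' Export a COMPACT matrix as a Circos Table-Viewer-style table
#'
#' Writes the count matrix as a tab-delimited table — a header row of
#' column-pattern labels and one row per row-pattern label with integer
#' cells — the layout the Circos table-viewer workflow ingests to draw the
#' chord diagram. Masked cells are written as 0 when
#' `include_masked = FALSE`.
#'
#' @param m A `compact` object.
#' @param path Output file path.
#' @param include_masked Write masked cells' true counts (default `TRUE`).
#' @return `path`, invisibly.
#' @seealso [read_circos_table()]
#' @export
export_circos_table <- function(m, path, include_masked = TRUE) {
  stopifnot(inherits(m, "compact"))
  counts <- m$counts
  if (!include_masked) counts[m$mask] <- 0L
  df <- data.frame(pattern = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tryCatch(utils::write.table(df, path, sep = "\t", quote = FALSE,
                              row.names = FALSE, fileEncoding = "UTF-8"),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read back a Circos-style table export
#'
#' @param path Path written by [export_circos_table()].
#' @return Integer matrix with pattern labels as dimnames.
#' @export
read_circos_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1L]]
  mat
}

#' Plot a COMPACT matrix as a count heatmap
#'
#' Cells are colored by gene count on a white-to-dark-brown ramp, the
#' diagonal is outlined, section boundaries at the basis time point are
#' drawn, and masked cells are greyed out. Rendering is deterministic for a
#' fixed matrix and style.
#'
#' @param x A `compact` object.
#' @param basis_time Basis time point for section boundaries.
#' @param style List of style settings: `ramp` (vector of colors for the
#'   count ramp), `masked_col`, `diag_col`, `section_col`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.compact <- function(x, basis_time = 1L, style = compact_style(), ...) {
  K <- nrow(x$counts)
  pal <- grDevices::colorRampPalette(style$ramp)(256L)
  counts <- x$counts
  maxc <- max(counts, 1L)
  z <- t(counts[K:1L, , drop = FALSE])  # row 1 at top
  graphics::image(x = seq_len(K), y = seq_len(K), z = z,
                  zlim = c(0, maxc), col = pal, axes = FALSE,
                  xlab = paste0("comparison: ", x$comparison_group),
                  ylab = paste0("reference: ", x$reference_group),
                  main = "COMPACT matrix", useRaster = FALSE)
  if (any(x$mask)) {
    idx <- which(t(x$mask[K:1L, , drop = FALSE]) , arr.ind = TRUE)
    graphics::rect(idx[, 1L] - 0.5, idx[, 2L] - 0.5,
                   idx[, 1L] + 0.5, idx[, 2L] + 0.5,
                   col = style$masked_col, border = NA)
  }
  # diagonal outline (row i top-down = column i)
  graphics::segments(seq_len(K) - 0.5, K - seq_len(K) + 0.5,
                     seq_len(K) + 0.5, K - seq_len(K) + 1.5,
                     col = style$diag_col, lwd = 1)
  L <- x$scheme$n_levels
  block <- K / L
  at <- block * seq_len(L - 1L) + 0.5
  graphics::abline(v = at, h = at, col = style$section_col, lwd = 1.5)
  graphics::box()
  invisible(x)
}

#' Default heatmap style configuration
#'
#' @param path Optional YAML file overriding any of the style fields, so
#'   renders are reproducible from a checked-in config.
#' @return List with `ramp`, `masked_col`, `diag_col`, `section_col`,
#'   `width`, `height`.
#' @export
compact_style <- function(path = NULL) {
  style <- list(ramp = c("white", "#5C3317"), masked_col = "grey80",
                diag_col = "#E8C547", section_col = "grey40",
                width = 900L, height = 900L)
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    style[names(over)] <- over
  }
  style
}

#' Render a COMPACT heatmap to a PNG file
#'
#' @param m A `compact` object.
#' @param path Output PNG path.
#' @param basis_time Basis time point for section boundaries.
#' @param style Style list from [compact_style()].
#' @return `path`, invisibly.
#' @export
render_compact_heatmap <- function(m, path, basis_time = 1L,
                                   style = compact_style()) {
  stopifnot(inherits(m, "compact"))
  grDevices::png(path, width = style$width, height = style$height)
  on.exit(grDevices::dev.off())
  plot(m, basis_time = basis_time, style = style)
  invisible(path)
}

#' Export pattern-ordered differential values for heatmap rendering
#'
#' Writes the per-gene log2 differentials with rows in a supplied
#' pattern-based ordering (see [order_genes_by_pattern()]) and one column
#' per `group:time` — the substrate external heatmap tools consume.
#'
#' @param profile A `differential_profile`.
#' @param ordering Character vector: a permutation of the profile's genes
#'   (or of a subset of them covering every row written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_pattern_heatmap_table <- function(profile, ordering, path) {
  stopifnot(inherits(profile, "differential_profile"))
  flat <- flatten_profile(profile)
  if (anyDuplicated(ordering) || !all(ordering %in% rownames(flat)))
    stop("ordering must be a duplicate-free subset of the profile's genes")
  flat <- flat[ordering, , drop = FALSE]
  utils::write.table(data.frame(gene_id = rownames(flat), flat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
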
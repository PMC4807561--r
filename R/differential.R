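#' Average log2 differential expression relative to baseline
#'
#' Converts a replicate-level [expression_table()] into per-gene, per-group,
#' per-time average log2 differentials versus baseline. Two baseline modes
#' are supported: `"group_mean"` subtracts the mean of the group's baseline
#' samples from every post sample; `"paired_by_replicate"` subtracts each
#' animal's own baseline. In both modes the per-replicate differentials are
#' then averaged (arithmetic mean on the log2 scale) within each
#' (group, time); missing replicate values are dropped from the mean.
#' `"auto"` picks paired mode when every post sample's replicate has a
#' baseline sample in the same group, else group-mean mode.
#'
#' @param table An [expression_table()].
#' @param baseline_mode One of `"auto"`, `"group_mean"`,
#'   `"paired_by_replicate"`.
#' @return A `differential_profile`: list with `values` (3-d array
#'   genes x groups x times of average log2 differentials, `NA` where no
#'   usable replicate existed), `genes`, `groups`, `times` (strictly
#'   increasing post-baseline time points), and `baseline_mode` (resolved).
#' @examples
#' sim <- simulate_compact_data(simulation_config(n_genes = 20, seed = 1))
#' prof <- compute_differential(sim$expression)
#' @export
compute_differential <- function(table,
                                 baseline_mode = c("auto", "group_mean",
                                                   "paired_by_replicate")) {
  stopifnot(inherits(table, "expression_table"))
  baseline_mode <- match.arg(baseline_mode)
  ann <- table$annotation
  vals <- table$values
  groups <- unique(ann$group)
  times <- sort(unique(ann$time[ann$role == "post"]))
  if (length(times) == 0L) stop("no post-baseline samples")

  is_base <- ann$role == "baseline"
  if (baseline_mode == "auto") {
    key <- paste(ann$group, ann$replicate_id)
    paired_ok <- all(key[!is_base] %in% key[is_base])
    baseline_mode <- if (paired_ok) "paired_by_replicate" else "group_mean"
  }

  # per-sample differential columns for post samples
  post_idx <- which(!is_base)
  diffs <- matrix(NA_real_, nrow(vals), length(post_idx))
  if (baseline_mode == "group_mean") {
    for (g in groups) {
      bcols <- which(is_base & ann$group == g)
      bmean <- rowMeans(vals[, bcols, drop = FALSE], na.rm = TRUE)
      bmean[is.nan(bmean)] <- NA_real_
      sel <- which(ann$group[post_idx] == g)
      diffs[, sel] <- vals[, post_idx[sel], drop = FALSE] - bmean
    }
  } else {
    key <- paste(ann$group, ann$replicate_id)
    unmatched <- unique(ann$replicate_id[post_idx][
      !(key[post_idx] %in% key[is_base])])
    if (length(unmatched))
      stop("paired baseline missing for replicate id(s): ",
           paste(unmatched, collapse = ", "))
    for (k in seq_along(post_idx)) {
      j <- post_idx[k]
      bcols <- which(is_base & key == key[j])
      bval <- rowMeans(vals[, bcols, drop = FALSE], na.rm = TRUE)
      bval[is.nan(bval)] <- NA_real_
      diffs[, k] <- vals[, j] - bval
    }
  }

  out <- array(NA_real_, dim = c(nrow(vals), length(groups), length(times)),
               dimnames = list(rownames(vals), groups, as.character(times)))
  pg <- ann$group[post_idx]
  pt <- ann$time[post_idx]
  n_dropped_reps <- 0L
  for (gi in seq_along(groups)) {
    for (ti in seq_along(times)) {
      sel <- which(pg == groups[gi] & pt == times[ti])
      if (!length(sel)) next
      block <- diffs[, sel, drop = FALSE]
      n_dropped_reps <- n_dropped_reps + sum(is.na(block))
      m <- rowMeans(block, na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      out[, gi, ti] <- m
    }
  }
  if (n_dropped_reps > 0L)
    message(n_dropped_reps,
            " missing replicate differential(s) dropped from averages")

  structure(list(values = out, genes = rownames(vals), groups = groups,
                 times = times, baseline_mode = baseline_mode),
            class = "differential_profile")
}

#' @export
print.differential_profile <- function(x, ...) {
  cat("differential_profile: ", length(x$genes), " genes, groups {",
      paste(x$groups, collapse = ", "), "}, times {",
      paste(x$times, collapse = ", "), "} h, baseline mode ",
      x$baseline_mode, "\n", sep = "")
  invisible(x)
}

# genes x T matrix of differentials for one group
profile_matrix <- function(profile, group) {
  stopifnot(inherits(profile, "differential_profile"))
  if (!group %in% profile$groups)
    stop("unknown group '", group, "'; available: ",
         paste(profile$groups, collapse = ", "))
  m <- profile$values[, group, , drop = FALSE]
  dim(m) <- c(length(profile$genes), length(profile$times))
  dimnames(m) <- list(profile$genes, as.character(profile$times))
  m
}

#' Fold-change responsive gene filter
#'
#' Returns genes whose absolute average log2 differential meets or exceeds
#' `log2(fold_threshold)` at one or more (group, time) combinations
#' (boundary inclusive). This is the fold-change-only responsiveness filter;
#' a significance-based gene list, if available, can be intersected by the
#' caller.
#'
#' @param profile A `differential_profile` from [compute_differential()].
#' @param fold_threshold Fold-change threshold, must be > 1 (e.g. 1.5).
#' @param groups Optional character vector restricting which groups count.
#' @return Character vector of responsive gene ids (deterministic order,
#'   following the profile's gene order).
#' @export
filter_responsive <- function(profile, fold_threshold, groups = NULL) {
  stopifnot(inherits(profile, "differential_profile"))
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      fold_threshold <= 1)
    stop("fold_threshold must be a single number > 1")
  if (is.null(groups)) groups <- profile$groups
  v <- profile$values[, groups, , drop = FALSE]
  cutoff <- log2(fold_threshold)
  hit <- apply(abs(v), 1L, function(d) any(d >= cutoff, na.rm = TRUE))
  profile$genes[hit]
}

#' Write a differential profile to TSV
#'
#' One row per gene; one column per (group, time) named `group:time`; values
#' are average log2 differentials versus baseline, `NA` where undefined.
#'
#' @param profile A `differential_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(profile, path) {
  stopifnot(inherits(profile, "differential_profile"))
  flat <- flatten_profile(profile)
  utils::write.table(data.frame(gene_id = rownames(flat), flat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# genes x (group:time) matrix, columns grouped by group then time
flatten_profile <- function(profile) {
  cols <- lapply(profile$groups, function(g) profile_matrix(profile, g))
  flat <- do.call(cbind, cols)
  colnames(flat) <- unlist(lapply(profile$groups, function(g)
    paste0(g, ":", profile$times)))
  flat
}
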
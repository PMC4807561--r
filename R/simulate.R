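#' Configuration for the planted-pattern expression simulator
#'
#' Describes a two-condition time-course experiment with a within-animal
#' baseline: each group has `n_replicates` animals, each contributing one
#' baseline sample (time 0) and one sample per post-baseline time point.
#' Every gene carries a planted ternary pattern per group; planted non-null
#' levels get a true log2 differential with magnitude drawn uniformly in
#' `[log2(fold_threshold) + effect_margin, log2(fold_threshold) +
#' 2 * effect_margin]` (sign per level), planted null levels get a magnitude
#' at most `null_ceiling`, and replicate measurements add i.i.d. Gaussian
#' noise on the log2 scale. Discretizing the noiseless effects at
#' `fold_threshold` reproduces the planted patterns exactly, so the full
#' pipeline can be validated end to end.
#'
#' The defaults mirror the experimental design the method targets: two diet
#' groups, three post-perturbation time points (1, 6, 24 h), four biological
#' replicates per group, and a 1.5-fold discretization threshold.
#'
#' @param n_genes Number of genes.
#' @param times Post-baseline time points (hours), strictly increasing.
#' @param groups Length-2 character vector: reference and comparison
#'   condition labels.
#' @param n_replicates Animals per group (each with baseline + post
#'   samples).
#' @param fold_threshold The fold-change threshold the downstream analysis
#'   will use (> 1).
#' @param effect_margin Minimum |log2 differential| beyond
#'   `log2(fold_threshold)` for planted non-null levels (> 0).
#' @param null_ceiling Maximum |log2 differential| for planted null levels
#'   (>= 0, must be below `log2(fold_threshold)`).
#' @param noise_sd Per-replicate additive noise s.d. on the log2 scale.
#' @param baseline_mean_range Length-2 range the per-gene baseline mean is
#'   drawn from.
#' @param pattern_spec Planted comparative patterns: `"null"` (every gene
#'   (null, null)), `"random"` (uniform over all pattern pairs), a data
#'   frame with columns `ref`, `cmp` (0-based pattern indices) and either
#'   one row per gene or a `n` column of per-cell target counts (unassigned
#'   genes default to (null, null)).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000L, times = c(1, 6, 24),
                              groups = c("carbohydrate", "ethanol"),
                              n_replicates = 4L, fold_threshold = 1.5,
                              effect_margin = 0.5, null_ceiling = 0.1,
                              noise_sd = 0.2,
                              baseline_mean_range = c(6, 12),
                              pattern_spec = "random", seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1L) stop("n_genes must be >= 1")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE) ||
      any(times <= 0))
    stop("times must be strictly increasing and > 0")
  if (length(groups) != 2L || anyDuplicated(groups))
    stop("groups must be two distinct labels")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (effect_margin <= 0) stop("effect_margin must be > 0")
  if (null_ceiling < 0 || null_ceiling >= log2(fold_threshold))
    stop("null_ceiling must be in [0, log2(fold_threshold))")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(baseline_mean_range) != 2L ||
      baseline_mean_range[2L] < baseline_mean_range[1L])
    stop("baseline_mean_range must be an increasing length-2 range")
  structure(list(n_genes = as.integer(n_genes), times = as.numeric(times),
                 groups = as.character(groups),
                 n_replicates = as.integer(n_replicates),
                 fold_threshold = fold_threshold,
                 effect_margin = effect_margin,
                 null_ceiling = null_ceiling, noise_sd = noise_sd,
                 baseline_mean_range = as.numeric(baseline_mean_range),
                 pattern_spec = pattern_spec, seed = as.integer(seed)),
            class = "simulation_config")
}

resolve_pattern_spec <- function(config, scheme) {
  T <- length(config$times)
  K <- scheme$n_levels^T
  null_i <- null_index(scheme, T)
  n <- config$n_genes
  spec <- config$pattern_spec
  if (identical(spec, "null"))
    return(data.frame(ref = rep(null_i, n), cmp = rep(null_i, n)))
  if (identical(spec, "random"))
    return(data.frame(ref = sample.int(K, n, replace = TRUE) - 1L,
                      cmp = sample.int(K, n, replace = TRUE) - 1L))
  spec <- as.data.frame(spec)
  if (!all(c("ref", "cmp") %in% names(spec)))
    stop("pattern_spec data frame needs columns 'ref' and 'cmp'")
  if ("n" %in% names(spec)) {
    if (sum(spec$n) > n)
      stop("pattern_spec cell counts (", sum(spec$n),
           ") exceed n_genes (", n, ")")
    spec <- data.frame(ref = rep(spec$ref, spec$n),
                       cmp = rep(spec$cmp, spec$n))
  }
  if (nrow(spec) > n)
    stop("pattern_spec assigns more genes (", nrow(spec),
         ") than n_genes (", n, ")")
  if (any(spec$ref < 0L | spec$ref >= K | spec$cmp < 0L | spec$cmp >= K))
    stop("pattern indices must be in 0..", K - 1L)
  pad <- n - nrow(spec)
  rbind(spec, data.frame(ref = rep(null_i, pad), cmp = rep(null_i, pad)))
}

#' Generate a synthetic expression table with planted comparative patterns
#'
#' Runs the generative model described in [simulation_config()] and returns
#' the replicate-level expression table together with the ground truth, so
#' recovery through the full pipeline (differential -> discretization ->
#' COMPACT matrix) can be scored.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (an [expression_table()]), `truth` (a
#'   `simulation_truth`: data frame gene/ref/cmp of planted 0-based pattern
#'   indices, with the planted per-time log2 effects as attribute
#'   `effects`, a genes x groups x times array), and `config`.
#' @examples
#' sim <- simulate_compact_data(simulation_config(n_genes = 30, seed = 7))
#' @export
simulate_compact_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  scheme <- discretization_scheme(config$fold_threshold)
  T <- length(config$times)
  L <- scheme$n_levels
  mrank <- scheme_null_rank(scheme)
  spec <- resolve_pattern_spec(config, scheme)
  n <- config$n_genes
  genes <- sprintf("gene_%05d", seq_len(n))
  spec$gene <- genes

  cut <- log2(config$fold_threshold)
  lo <- cut + config$effect_margin
  hi <- cut + 2 * config$effect_margin

  # planted true differentials: genes x groups x times
  effects <- array(0, dim = c(n, 2L, T),
                   dimnames = list(genes, config$groups,
                                   as.character(config$times)))
  plant <- function(idx_vec) {
    ranks <- t(vapply(idx_vec, ranks_from_index, integer(T), L = L, T = T))
    dim(ranks) <- c(n, T)
    sign_mat <- sign(mrank - ranks)              # +1 up, 0 null, -1 down
    mag <- matrix(stats::runif(n * T, lo, hi), n, T)
    nullmag <- matrix(stats::runif(n * T, -config$null_ceiling,
                                   config$null_ceiling), n, T)
    ifelse(sign_mat == 0, nullmag, sign_mat * mag)
  }
  effects[, 1L, ] <- plant(spec$ref)
  effects[, 2L, ] <- plant(spec$cmp)

  base_mean <- stats::runif(n, config$baseline_mean_range[1L],
                            config$baseline_mean_range[2L])

  reps <- seq_len(config$n_replicates)
  ann <- do.call(rbind, lapply(config$groups, function(g) {
    rbind(
      data.frame(sample_id = sprintf("%s_r%d_t0", g, reps), group = g,
                 time = 0, replicate_id = sprintf("r%d", reps),
                 role = "baseline", stringsAsFactors = FALSE),
      do.call(rbind, lapply(config$times, function(tt)
        data.frame(sample_id = sprintf("%s_r%d_t%g", g, reps, tt),
                   group = g, time = tt,
                   replicate_id = sprintf("r%d", reps), role = "post",
                   stringsAsFactors = FALSE))))
  }))

  vals <- matrix(NA_real_, n, nrow(ann),
                 dimnames = list(genes, ann$sample_id))
  for (j in seq_len(nrow(ann))) {
    gidx <- match(ann$group[j], config$groups)
    mu <- if (ann$role[j] == "baseline") base_mean else
      base_mean + effects[, gidx, as.character(ann$time[j])]
    vals[, j] <- mu + stats::rnorm(n, 0, config$noise_sd)
  }

  truth <- spec[, c("gene", "ref", "cmp")]
  attr(truth, "effects") <- effects
  class(truth) <- c("simulation_truth", "data.frame")
  list(expression = expression_table(vals, ann), truth = truth,
       config = config)
}

#' Score pattern recovery of a COMPACT matrix against simulation truth
#'
#' Compares each gene's recovered (reference, comparison) matrix cell with
#' its planted cell.
#'
#' @param truth A `simulation_truth` from [simulate_compact_data()].
#' @param m A `compact` object built from the simulated data.
#' @return List with `fraction` (genes recovered in their planted cell, over
#'   the genes present in the matrix), `n` (genes scored), and `confusion`
#'   (data frame of planted vs recovered cells with counts, mismatches
#'   only).
#' @export
score_recovery <- function(truth, m) {
  stopifnot(inherits(truth, "simulation_truth"), inherits(m, "compact"))
  if (!all(m$assignment$gene %in% truth$gene))
    stop("gene id mismatch between truth and matrix")
  tr <- truth[match(m$assignment$gene, truth$gene), ]
  hit <- tr$ref == m$assignment$ref & tr$cmp == m$assignment$cmp
  mism <- data.frame(planted_ref = tr$ref[!hit], planted_cmp = tr$cmp[!hit],
                     recovered_ref = m$assignment$ref[!hit],
                     recovered_cmp = m$assignment$cmp[!hit])
  confusion <- if (nrow(mism)) stats::aggregate(
    list(count = rep(1L, nrow(mism))), mism, sum) else
      cbind(mism, count = integer(0))
  list(fraction = mean(hit), n = length(hit), confusion = confusion)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard expression + annotation TSV pair (readable by
#' [read_expression_table()]) and a truth TSV (gene, planted reference and
#' comparison pattern indices and labels, per-time planted effects).
#'
#' @param sim Output of [simulate_compact_data()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_table(sim$expression, paths["expression"],
                         paths["annotation"])
  scheme <- discretization_scheme(sim$config$fold_threshold)
  T <- length(sim$config$times)
  eff <- attr(sim$truth, "effects")
  flat_eff <- do.call(cbind, lapply(seq_along(sim$config$groups),
                                    function(g) eff[, g, , drop = TRUE]))
  colnames(flat_eff) <- unlist(lapply(sim$config$groups, function(g)
    paste0("effect_", g, ":", sim$config$times)))
  labels <- pattern_labels(scheme, T)
  df <- data.frame(gene = sim$truth$gene, ref = sim$truth$ref,
                   cmp = sim$truth$cmp,
                   ref_pattern = labels[sim$truth$ref + 1L],
                   cmp_pattern = labels[sim$truth$cmp + 1L],
                   flat_eff, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
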
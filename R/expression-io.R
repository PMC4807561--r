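#' Construct and validate an expression table
#'
#' An `expression_table` bundles a genes-by-samples matrix of log2 expression
#' values with a sample annotation table. It is the single container all
#' downstream steps consume. Values are always stored on the log2 scale;
#' linear-scale input is converted on construction.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Missing values allowed as `NA`.
#' @param annotation Data frame with columns `sample_id`, `group`, `time`
#'   (hours, baseline at the smallest annotated baseline time, conventionally
#'   0), `replicate_id` (animal/subject id linking baseline and post samples),
#'   and `role` (`"baseline"` or `"post"`).
#' @param scale Either `"log2"` (default) or `"linear"`. Linear values must be
#'   strictly positive and are log2-transformed.
#'
#' @return An object of class `expression_table`: a list with elements
#'   `values` (log2 matrix), `annotation` (rows aligned to columns of
#'   `values`), and `n_dropped` (count of all-missing gene rows removed).
#'
#' @details Validation enforces: unique non-empty gene ids, unique sample ids,
#' a one-to-one match between matrix columns and annotation rows, at least one
#' baseline sample per group, non-negative times, and the rule that
#' `role == "baseline"` exactly when `time` equals the declared baseline time.
#' Gene rows that are entirely missing are dropped with a message.
#'
#' @examples
#' tab <- expression_table(
#'   matrix(rnorm(12, 8), 3, 4,
#'          dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
#'   data.frame(sample_id = paste0("s", 1:4),
#'              group = "ctrl", time = c(0, 0, 1, 1),
#'              replicate_id = c("r1", "r2", "r1", "r2"),
#'              role = c("baseline", "baseline", "post", "post")))
#' @export
expression_table <- function(values, annotation, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  if (is.null(gene_ids) || length(gene_ids) == 0L || nrow(values) == 0L)
    stop("empty table: no gene rows")
  if (any(gene_ids == "" | is.na(gene_ids)))
    stop("empty or missing gene id")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  if (is.null(colnames(values)))
    stop("`values` must have sample ids as column names")

  annotation <- validate_annotation(annotation)
  if (!setequal(colnames(values), annotation$sample_id)) {
    only_expr <- setdiff(colnames(values), annotation$sample_id)
    only_ann  <- setdiff(annotation$sample_id, colnames(values))
    stop("expression/annotation sample mismatch",
         if (length(only_expr)) paste0("; in expression only: ",
                                       paste(only_expr, collapse = ", ")),
         if (length(only_ann)) paste0("; in annotation only: ",
                                      paste(only_ann, collapse = ", ")))
  }
  annotation <- annotation[match(colnames(values), annotation$sample_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL

  if (scale == "linear") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad))
      stop("linear-scale values must be positive; first offending cell: row ",
           row(values)[bad[1L]], ", column ", col(values)[bad[1L]])
    values <- log2(values)
  }

  all_missing <- rowSums(!is.na(values)) == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " gene row(s) with all values missing")
    values <- values[!all_missing, , drop = FALSE]
    if (nrow(values) == 0L) stop("empty table: all gene rows were missing")
  }

  structure(list(values = values, annotation = annotation,
                 n_dropped = n_dropped),
            class = "expression_table")
}

validate_annotation <- function(annotation) {
  req <- c("sample_id", "group", "time", "replicate_id", "role")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols))
    stop("annotation missing column(s): ", paste(missing_cols, collapse = ", "))
  annotation <- as.data.frame(annotation)[req]
  for (col in c("sample_id", "group", "replicate_id", "role"))
    annotation[[col]] <- as.character(annotation[[col]])
  annotation$time <- as.numeric(annotation$time)
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(annotation$sample_id[duplicated(annotation$sample_id)]),
               collapse = ", "))
  if (!all(annotation$role %in% c("baseline", "post")))
    stop("role must be 'baseline' or 'post'")
  if (any(is.na(annotation$time)) || any(annotation$time < 0))
    stop("time must be numeric and >= 0")
  if (!any(annotation$role == "baseline"))
    stop("no baseline samples in annotation")
  baseline_time <- unique(annotation$time[annotation$role == "baseline"])
  if (length(baseline_time) != 1L)
    stop("all baseline samples must share a single baseline time; found: ",
         paste(baseline_time, collapse = ", "))
  if (any(annotation$role == "post" & annotation$time == baseline_time))
    stop("post samples may not occur at the baseline time (",
         baseline_time, ")")
  no_base <- setdiff(annotation$group,
                     annotation$group[annotation$role == "baseline"])
  if (length(no_base))
    stop("group(s) without a baseline sample: ",
         paste(no_base, collapse = ", "))
  annotation
}

#' Read an expression table and its sample annotation from TSV files
#'
#' The expression file is tab-delimited with the gene id in the first column
#' and a header row of sample ids; the annotation file is a tab-delimited
#' table keyed by `sample_id` with columns `group`, `time`, `replicate_id`,
#' and `role`. Missing values are written and read as `NA`. Both UTF-8 files
#' may use Unix or Windows line endings.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Path to the annotation TSV.
#' @inheritParams expression_table
#' @return A validated [expression_table()].
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path, annotation_path,
                                  scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  for (p in c(path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p)

  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = "NA", quote = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("expression file needs a gene id column plus >= 1 sample column")
  gene_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  bad <- which(!is.na(cells) & is.na(num))
  if (length(bad)) {
    i <- row(cells)[bad[1L]]; j <- col(cells)[bad[1L]]
    stop("non-numeric value '", cells[bad[1L]], "' at gene '", gene_ids[i],
         "' (row ", i, "), sample '", colnames(cells)[j], "' (column ", j, ")")
  }
  rownames(num) <- gene_ids

  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           fileEncoding = "UTF-8",
                           colClasses = "character")
  expression_table(num, ann, scale = scale)
}

#' Write an expression table (and optionally its annotation) to TSV
#'
#' Inverse of [read_expression_table()]: `read(write(x))` reproduces gene
#' ids, annotation, and values up to floating-point text round-trip. Missing
#' values are written as `NA`.
#'
#' @param table An [expression_table()].
#' @param path Output path for the expression TSV.
#' @param annotation_path Optional output path for the annotation TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path, annotation_path = NULL) {
  stopifnot(inherits(table, "expression_table"))
  if (nrow(table$values) == 0L) stop("empty table")
  df <- data.frame(gene_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  if (!is.null(annotation_path))
    utils::write.table(table$annotation, annotation_path, sep = "\t",
                       quote = FALSE, na = "NA", row.names = FALSE,
                       fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("groups: ", paste(unique(x$annotation$group), collapse = ", "), "\n",
      sep = "")
  tp <- sort(unique(x$annotation$time[x$annotation$role == "post"]))
  cat("post time points: ", paste(tp, collapse = ", "), " (baseline at ",
      unique(x$annotation$time[x$annotation$role == "baseline"]), ")\n",
      sep = "")
  invisible(x)
}
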
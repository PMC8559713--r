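# Expression matrices, sample metadata and junction-count tables, plus the
# TSV conventions used by every pipeline stage (tab separated, header row,
# '.' for missing values).

#' Construct an expression matrix
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Values must be non-negative.
#' @param samples Data frame of sample metadata with columns `sample_id`,
#'   `tissue`, `condition`, `replicate`; row order must match the columns of
#'   `values`.
#' @param feature_level `"gene"` or `"transcript"`.
#' @param unit Unit of `values`, `"TPM"` or `"count"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              feature_level = c("transcript", "gene"),
                              unit = c("TPM", "count")) {
  feature_level <- match.arg(feature_level)
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("values must have feature rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (ncol(values) < 1) stop("at least one sample required")
  samples <- as.data.frame(samples)
  req <- c("sample_id", "tissue", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_ids")
  if (nrow(samples) != ncol(values)) {
    stop("sample metadata rows must match value columns")
  }
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples,
                 feature_level = feature_level, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %ss x %d samples [%s]\n",
              nrow(x$values), x$feature_level, ncol(x$values), x$unit))
  invisible(x)
}

#' Construct a junction-count table
#'
#' @param junctions Data frame with columns `gene_id`, `chrom`, `donor`,
#'   `acceptor`, `strand` (0-based half-open intron: donor = intron start,
#'   acceptor = intron end).
#' @param counts Integer matrix, one row per junction, one column per sample.
#' @return An object of class `junction_counts`.
#' @export
junction_counts <- function(junctions, counts) {
  junctions <- as.data.frame(junctions)
  counts <- as.matrix(counts)
  if (nrow(junctions) != nrow(counts)) stop("row mismatch")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("junction counts must be non-negative integers")
  }
  if (any(junctions$donor == junctions$acceptor)) {
    stop("junction with donor == acceptor")
  }
  structure(list(junctions = junctions, counts = counts),
            class = "junction_counts")
}

# ---------------------------------------------------------------------------
# TSV conventions

#' Write a data frame as pipeline TSV
#'
#' Tab-separated, header row, `NA` rendered as `"."`, no quoting or row
#' names. All stage outputs use this format.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV
#' @param path Input path.
#' @return Data frame (`.` read back as `NA`).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix as TSV (feature_id + one column per sample)
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix from TSV
#' @param path Input path (first column feature ids).
#' @param samples Sample metadata data frame (see [expression_matrix()]).
#' @param feature_level,unit Passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, samples, feature_level = "transcript",
                                unit = "TPM") {
  df <- read_tsv(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  expression_matrix(values, samples, feature_level = feature_level,
                    unit = unit)
}
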
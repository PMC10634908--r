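#' Construct a time-course expression matrix
#'
#' Container for a gene-by-sample TPM matrix with per-sample metadata: ZT
#' time in hours, replicate, experiment label (e.g. `V1`/`V2`) and condition
#' label (e.g. `18C`/`25C`). Values must be non-negative; gene and sample
#' identifiers must be unique; metadata rows must match the matrix columns
#' one-to-one, in order.
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param sample_meta data.frame with columns `sample_id`, `zt_hours`,
#'   `replicate`, `experiment`, `condition`; one row per matrix column.
#' @return an object of class `time_course_matrix` (a list with elements
#'   `values` and `sample_meta`).
#' @export
time_course_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (any(values < 0)) stop("TPM values must be non-negative")
  req <- c("sample_id", "zt_hours", "replicate", "experiment", "condition")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols))
    stop("sample_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(sample_meta) != ncol(values))
    stop("sample_meta rows (", nrow(sample_meta), ") != matrix columns (",
         ncol(values), ")")
  if (!identical(as.character(sample_meta$sample_id), colnames(values)))
    stop("sample_meta$sample_id must match matrix column names in order")
  if (any(!is.finite(sample_meta$zt_hours)) || any(sample_meta$zt_hours < 0))
    stop("zt_hours must be finite and non-negative")
  structure(list(values = values, sample_meta = sample_meta),
            class = "time_course_matrix")
}

#' @export
print.time_course_matrix <- function(x, ...) {
  m <- x$sample_meta
  cat("time_course_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  experiment(s):", paste(unique(m$experiment), collapse = ", "),
      "| condition(s):", paste(unique(m$condition), collapse = ", "), "\n")
  cat("  ZT range:", min(m$zt_hours), "-", max(m$zt_hours), "h;",
      length(unique(m$zt_hours)), "timepoints\n")
  invisible(x)
}

#' @export
dim.time_course_matrix <- function(x) dim(x$values)

#' Write a time-course matrix to TSV files
#'
#' The expression table has `gene_id` as first column, sample IDs as remaining
#' columns; the metadata table has columns `sample_id`, `zt_hours`,
#' `replicate`, `experiment`, `condition`. [read_time_course()] round-trips
#' these files losslessly.
#'
#' @param tc a [time_course_matrix()].
#' @param expr_path,meta_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_time_course <- function(tc, expr_path, meta_path) {
  stopifnot(inherits(tc, "time_course_matrix"))
  df <- data.frame(gene_id = rownames(tc$values), tc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tc$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expr_path, meta_path))
}

#' Read a time-course matrix from TSV files
#'
#' @param expr_path TSV with first column `gene_id`, remaining columns samples.
#' @param meta_path TSV with the sample metadata columns (see
#'   [write_time_course()]).
#' @return a [time_course_matrix()].
#' @export
read_time_course <- function(expr_path, meta_path) {
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column of ", expr_path, " must be 'gene_id'")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     colClasses = list(sample_id = "character",
                                       experiment = "character",
                                       condition = "character"))
  time_course_matrix(values, meta)
}

# Convenience: distinct ZT times, in column order, replicated per sample.
tc_times <- function(tc) tc$sample_meta$zt_hours
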
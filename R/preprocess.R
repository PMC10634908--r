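#' Median-expression filter defining the analysis gene universe
#'
#' A gene is retained when, in EVERY experiment, its median TPM across all of
#' that experiment's samples exceeds `threshold` in at least one condition
#' (strictly greater-than: a median of exactly 5 fails the default filter).
#' This is the AND-over-experiments / OR-over-conditions reading of requiring
#' expression "in either condition, consistently across experiments": a gene
#' may owe its expression to different conditions in different experiments,
#' but must be expressed somewhere in each experiment.
#'
#' Medians are computed per (experiment, condition) matrix over all its
#' samples (all timepoints and replicates). The retained list preserves the
#' gene order of the first matrix. Genes absent from any matrix cannot be
#' evaluated consistently and are dropped with a warning.
#'
#' @param matrices named list of [time_course_matrix()] objects, jointly
#'   covering every experiment x condition combination.
#' @param threshold TPM threshold (default 5); strict inequality.
#' @param experiments,conditions the expected design labels; defaults to the
#'   labels observed in `matrices`. Passing them explicitly lets the filter
#'   catch a wholly absent experiment or condition.
#' @return character vector of retained gene IDs.
#' @export
median_expression_filter <- function(matrices, threshold = 5,
                                     experiments = NULL, conditions = NULL) {
  stopifnot(length(matrices) >= 1)
  lab <- lapply(matrices, function(m) {
    u <- unique(m$sample_meta[, c("experiment", "condition")])
    if (nrow(u) != 1)
      stop("each matrix must hold a single experiment x condition")
    u
  })
  lab <- do.call(rbind, lab)
  experiments <- experiments %||% unique(lab$experiment)
  conditions <- conditions %||% unique(lab$condition)
  want <- expand.grid(experiment = experiments, condition = conditions,
                      stringsAsFactors = FALSE)
  have <- paste(lab$experiment, lab$condition)
  missing_combo <- setdiff(paste(want$experiment, want$condition), have)
  if (length(missing_combo))
    stop("missing experiment x condition combination(s): ",
         paste(missing_combo, collapse = "; "))

  genes <- rownames(matrices[[1]]$values)
  common <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  dropped <- setdiff(genes, common)
  if (length(dropped))
    warning(length(dropped),
            " gene(s) absent from at least one matrix were dropped")
  genes <- genes[genes %in% common]

  # per-matrix medians over all samples, then AND over experiments of OR over
  # conditions
  med <- vapply(matrices, function(m)
    apply(m$values[genes, , drop = FALSE], 1, median), numeric(length(genes)))
  if (is.null(dim(med))) med <- matrix(med, nrow = length(genes))
  keep <- rep(TRUE, length(genes))
  for (ex in experiments) {
    cols <- which(lab$experiment == ex)
    pass_any_cond <- rowSums(med[, cols, drop = FALSE] > threshold) > 0
    keep <- keep & pass_any_cond
  }
  genes[keep]
}
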
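#' Bundle one study's counts and sample metadata
#'
#' A `study_bundle` is the unit of work of the per-study pipeline: an integer
#' gene x sample count matrix plus per-sample metadata. Metadata must contain
#' `sample_id`, `tissue`, `source` (one of `"GTEX"`, `"TCGA"`, `"MISC"`),
#' `control_flag` (logical; `TRUE` = unperturbed/control sample) and
#' `replicate_group` (samples sharing a group are technical replicates and
#' will be summed). Any further columns are candidate covariates.
#'
#' @param study_id single string identifying the study.
#' @param counts numeric matrix of non-negative integers, genes as rows
#'   (unique rownames), samples as columns (colnames matching
#'   `metadata$sample_id`).
#' @param metadata data.frame of per-sample annotations, one row per column
#'   of `counts`.
#' @param covariates character vector naming metadata columns to use in the
#'   fixed-effect correction step (may be empty).
#'
#' @return An object of class `study_bundle`.
#' @export
study_bundle <- function(study_id, counts, metadata, covariates = character()) {
  assert_that(is.character(study_id) && length(study_id) == 1L,
              "study_id must be a single string")
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts must have unique rownames (gene IDs)")
  assert_that(!is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
              "counts must have unique colnames (sample IDs)")
  assert_that(all(is.finite(counts)) && all(counts >= 0),
              "counts must be finite and non-negative")
  required <- c("sample_id", "tissue", "source", "control_flag", "replicate_group")
  missing_cols <- setdiff(required, names(metadata))
  assert_that(length(missing_cols) == 0L,
              paste0("metadata lacks required column(s): ",
                     paste(missing_cols, collapse = ", ")))
  assert_that(all(metadata$source %in% c("GTEX", "TCGA", "MISC")),
              "metadata$source must be one of GTEX, TCGA, MISC")
  assert_that(identical(sort(colnames(counts)), sort(as.character(metadata$sample_id))),
              "counts colnames and metadata$sample_id must match")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  missing_cov <- setdiff(covariates, names(metadata))
  assert_that(length(missing_cov) == 0L,
              paste0("covariate(s) absent from metadata: ",
                     paste(missing_cov, collapse = ", ")))
  structure(
    list(study_id = study_id, counts = counts, metadata = metadata,
         covariates = covariates),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("study_bundle '%s': %d genes x %d samples (%s, %s)\n",
              x$study_id, nrow(x$counts), ncol(x$counts),
              x$metadata$tissue[1], x$metadata$source[1]))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Expression matrix with provenance
#'
#' Thin wrapper around a real-valued gene x sample matrix recording whether
#' the values are variance-stabilized (`"vst"`) or covariate-corrected
#' residuals (`"residual"`).
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param provenance `"vst"` or `"residual"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, provenance = c("vst", "residual")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  assert_that(all(is.finite(values)), "expression values must all be finite")
  structure(list(values = values, provenance = provenance),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              x$provenance, nrow(x$values), ncol(x$values)))
  invisible(x)
}
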
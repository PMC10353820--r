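#' Assemble the gene x study SD (and mean) matrix
#'
#' Takes per-study `gene_summary` tables and builds the N x rho matrix of
#' residual standard deviations over the union of genes, with `NA` where a
#' gene did not pass a study's filters, plus a companion mean matrix of
#' identical shape.
#'
#' @param summaries list of `gene_summary` objects (see [summarize_genes()]).
#' @param labels optional data.frame with columns `study_id`, `tissue`,
#'   `source`; carried along for the correlation stage.
#' @return An `sd_matrix`: list with `sd` and `mean` (gene x study matrices
#'   with `NA` for missing), and `labels`.
#' @export
build_sd_matrix <- function(summaries, labels = NULL) {
  assert_that(length(summaries) >= 2, "need at least 2 studies")
  ids <- vapply(summaries, function(s) attr(s, "study_id"), "")
  assert_that(!anyDuplicated(ids), "study IDs must be unique")
  for (s in summaries)
    assert_that(!anyDuplicated(s$gene),
                sprintf("duplicated gene ID within study '%s'",
                        attr(s, "study_id")))
  genes <- sort(unique(unlist(lapply(summaries, `[[`, "gene"))))
  sd_mat <- matrix(NA_real_, length(genes), length(ids),
                   dimnames = list(genes, ids))
  mean_mat <- sd_mat
  for (k in seq_along(summaries)) {
    s <- summaries[[k]]
    sd_mat[s$gene, k] <- s$sd
    mean_mat[s$gene, k] <- s$mean
  }
  if (!is.null(labels)) {
    labels <- labels[match(ids, labels$study_id), , drop = FALSE]
    rownames(labels) <- NULL
  }
  structure(list(sd = sd_mat, mean = mean_mat, labels = labels),
            class = "sd_matrix")
}

#' @export
print.sd_matrix <- function(x, ...) {
  cat(sprintf("sd_matrix: %d genes x %d studies (%.1f%% missing)\n",
              nrow(x$sd), ncol(x$sd), 100 * mean(is.na(x$sd))))
  invisible(x)
}

#' Study-by-study Spearman correlation of gene SDs
#'
#' Restricts to genes present in *all* studies (complete cases) and returns
#' the Spearman correlation matrix of the SD columns, with average ranks for
#' ties.
#'
#' @param sd an `sd_matrix` (see [build_sd_matrix()]).
#' @param what `"sd"` (default) or `"mean"` column set.
#' @return A `study_correlation`: list with `matrix` (rho x rho), `labels`,
#'   `n_common_genes`.
#' @export
spearman_correlation_matrix <- function(sd, what = c("sd", "mean")) {
  what <- match.arg(what)
  assert_that(inherits(sd, "sd_matrix"), "sd must be an sd_matrix")
  vals <- sd[[what]]
  complete <- stats::complete.cases(vals)
  assert_that(sum(complete) >= 3,
              "fewer than 3 genes present in all studies")
  m <- vals[complete, , drop = FALSE]
  n_ties <- sum(apply(m, 2L, function(x) sum(duplicated(x))))
  rho <- spearman_cols(m)
  structure(list(matrix = rho, labels = sd$labels,
                 n_common_genes = sum(complete), n_ties = n_ties),
            class = "study_correlation")
}

#' @export
print.study_correlation <- function(x, ...) {
  cat(sprintf("study_correlation: %d studies, %d common genes\n",
              nrow(x$matrix), x$n_common_genes))
  invisible(x)
}

#' Principal coordinate analysis of study dissimilarities
#'
#' Classical multidimensional scaling of the between-study distance
#' `d_ij = |1 - rho_s(i, j)|`. Axes are ordered by eigenvalue; axes with
#' negative or zero eigenvalues are dropped from the coordinates but all
#' eigenvalues are reported.
#'
#' @param corr a `study_correlation`.
#' @return list with `coordinates` (study x axis), `eigenvalues` (all, in
#'   decreasing order) and `distances` (the input distance matrix).
#' @export
pcoa <- function(corr) {
  assert_that(inherits(corr, "study_correlation"),
              "corr must be a study_correlation")
  d <- abs(1 - corr$matrix)
  diag(d) <- 0
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; the full
  # spectrum (including negatives) is reported below regardless
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  eig <- mds$eig
  pos <- which(eig > 1e-12)
  coords <- if (length(pos)) mds$points[, pos, drop = FALSE] else
    matrix(0, n, 0)
  if (length(pos))
    colnames(coords) <- paste0("Axis", seq_along(pos))
  rownames(coords) <- rownames(corr$matrix)
  list(coordinates = coords, eigenvalues = eig, distances = d)
}
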
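#' Iterative PCA (low-rank SVD) imputation
#'
#' Fills missing cells of a numeric matrix by alternating a truncated-SVD
#' reconstruction with an update of the missing cells, starting from column
#' means, until the largest absolute change of any imputed cell falls below
#' `tol` or `max_iter` is reached. Observed cells are never altered.
#'
#' @param matrix numeric matrix with `NA` for missing cells; no row may be
#'   entirely missing.
#' @param n_components rank of the reconstruction (< both dimensions).
#' @param tol convergence tolerance on imputed values.
#' @param max_iter maximum number of iterations (non-convergence yields a
#'   warning and the best iterate).
#' @return The completed matrix.
#' @export
impute_missing_ranks <- function(matrix, n_components = 2, tol = 1e-6,
                                 max_iter = 500) {
  m <- as.matrix(matrix)
  miss <- is.na(m)
  if (!any(miss)) return(m)
  assert_that(!any(rowSums(!miss) == 0), "no gene row may be entirely missing")
  assert_that(n_components < min(dim(m)),
              "n_components must be smaller than both matrix dimensions")
  col_means <- colMeans(m, na.rm = TRUE)
  filled <- m
  for (j in seq_len(ncol(m))) filled[miss[, j], j] <- col_means[j]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- colMeans(filled)
    centred <- sweep(filled, 2L, mu)
    sv <- svd(centred, nu = n_components, nv = n_components)
    recon <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components) %*%
      t(sv$v)
    recon <- sweep(recon, 2L, mu, "+")
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("PCA imputation did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  filled
}

# core of the PC1-projection rank shared by across-study / tissue / mean
# ranks; `vals` is a gene x study matrix (may contain NA when impute = TRUE)
pc1_rank_core <- function(vals, kind, scope, impute, n_components = 2,
                          tol = 1e-6, max_iter = 500) {
  presence <- rowMeans(!is.na(vals))
  # per-study rank transform scaled to [0, 1]
  ranked <- rank_columns(vals)
  ranked <- sweep(ranked, 2L, apply(ranked, 2L, max, na.rm = TRUE), "/")
  if (impute && any(is.na(ranked))) {
    k <- min(n_components, min(dim(ranked)) - 1L)
    ranked <- impute_missing_ranks(ranked, n_components = k, tol = tol,
                                   max_iter = max_iter)
  }
  corr <- spearman_cols(ranked)
  eig <- eigen(corr, symmetric = TRUE)
  if (ncol(corr) > 1 &&
      abs(eig$values[1] - eig$values[2]) <= 1e-12) {
    # degenerate leading eigenspace: fix a deterministic representative by
    # orienting the eigenvector positively on the first study (study-ID order)
    message("leading eigenvalue tie; breaking deterministically by study order")
  }
  v1 <- eig$vectors[, 1]
  if (v1[1] < 0) v1 <- -v1
  centred <- sweep(ranked, 2L, colMeans(ranked))
  score <- drop(centred %*% v1)
  # orient so higher score = higher per-study rank (higher SD)
  if (stats::cor(score, rowMeans(ranked)) < 0) score <- -score
  rk <- rank(score, ties.method = "first")
  out <- data.frame(
    gene = rownames(vals),
    pc1_score = score,
    rank = as.integer(rk),
    presence_fraction = presence,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("variance_rank", "data.frame"),
            kind = kind, scope = scope,
            pc_variance_explained = eig$values / sum(eig$values))
}

#' @export
print.variance_rank <- function(x, ...) {
  ve <- attr(x, "pc_variance_explained")
  cat(sprintf("variance_rank [%s, %s]: %d genes, PC1 explains %.1f%%\n",
              attr(x, "kind"), attr(x, "scope"), nrow(x), 100 * ve[1]))
  invisible(x)
}

#' Across-study consensus variance rank
#'
#' Builds the consensus gene ordering: (1) keep genes present in at least
#' `min_presence` of the studies; (2) rank-transform values within each
#' study (average ties) and scale to \[0, 1\]; (3) impute missing cells by
#' [impute_missing_ranks()]; (4) eigen-decompose the study x study Spearman
#' correlation matrix of the kept values; (5) project each gene's centered
#' rank profile on the leading eigenvector; (6) orient PC1 so higher score
#' means higher per-study rank; (7) rank the scores 1..M (1 = lowest
#' variance). Per-axis variance explained is recorded in
#' `attr(, "pc_variance_explained")`.
#'
#' @param sd an `sd_matrix`.
#' @param kind `"variance"` (use the SD matrix) or `"mean"`.
#' @param min_presence minimum fraction of studies a gene must appear in.
#' @param n_components,tol,max_iter imputation controls.
#' @return A `variance_rank` data.frame with columns `gene`, `pc1_score`,
#'   `rank`, `presence_fraction`.
#' @export
compute_rank <- function(sd, kind = c("variance", "mean"), min_presence = 0.5,
                         n_components = 2, tol = 1e-6, max_iter = 500) {
  kind <- match.arg(kind)
  assert_that(inherits(sd, "sd_matrix"), "sd must be an sd_matrix")
  vals <- if (kind == "variance") sd$sd else sd$mean
  assert_that(ncol(vals) >= 2, "need at least 2 studies")
  keep <- rowMeans(!is.na(vals)) >= min_presence
  assert_that(sum(keep) >= 10, "fewer than 10 genes pass the presence rule")
  pc1_rank_core(vals[keep, , drop = FALSE], kind = kind,
                scope = "across-study", impute = TRUE,
                n_components = n_components, tol = tol, max_iter = max_iter)
}

#' Across-study consensus mean-expression rank
#'
#' Same machinery as [compute_rank()] applied to the companion mean matrix.
#'
#' @inheritParams compute_rank
#' @return A `variance_rank` with `kind = "mean"`.
#' @export
compute_mean_rank <- function(sd, min_presence = 0.5, n_components = 2,
                              tol = 1e-6, max_iter = 500) {
  compute_rank(sd, kind = "mean", min_presence = min_presence,
               n_components = n_components, tol = tol, max_iter = max_iter)
}

#' Tissue-specific variance ranks
#'
#' For each tissue, restricts to that tissue's studies and to genes present
#' in *all* of them (no imputation), then applies the PC1-projection rank.
#' A tissue represented by a single study uses that study's own SD rank.
#'
#' @param sd an `sd_matrix` whose `labels` include `tissue`.
#' @param kind `"variance"` or `"mean"`.
#' @return Named list of `variance_rank` objects, one per tissue.
#' @export
compute_tissue_ranks <- function(sd, kind = c("variance", "mean")) {
  kind <- match.arg(kind)
  assert_that(inherits(sd, "sd_matrix"), "sd must be an sd_matrix")
  assert_that(!is.null(sd$labels) && "tissue" %in% names(sd$labels),
              "sd_matrix labels with a tissue column are required")
  vals <- if (kind == "variance") sd$sd else sd$mean
  tissues <- unique(sd$labels$tissue)
  out <- lapply(tissues, function(tis) {
    cols <- which(sd$labels$tissue == tis)
    assert_that(length(cols) >= 1, sprintf("tissue '%s' has no studies", tis))
    sub <- vals[, cols, drop = FALSE]
    complete <- stats::complete.cases(sub)
    sub <- sub[complete, , drop = FALSE]
    if (length(cols) == 1L) {
      score <- sub[, 1]
      rk <- rank(score, ties.method = "first")
      res <- data.frame(gene = rownames(sub), pc1_score = score,
                        rank = as.integer(rk), presence_fraction = 1,
                        stringsAsFactors = FALSE)
      rownames(res) <- NULL
      structure(res, class = c("variance_rank", "data.frame"),
                kind = kind, scope = paste0("tissue:", tis),
                pc_variance_explained = 1)
    } else {
      pc1_rank_core(sub, kind = kind, scope = paste0("tissue:", tis),
                    impute = FALSE)
    }
  })
  names(out) <- tissues
  out
}
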
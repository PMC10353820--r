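#' Keep control samples and sum technical replicates
#'
#' Case samples (`control_flag == FALSE`) are dropped, then counts within a
#' `replicate_group` are summed column-wise into a single sample. Metadata
#' collapses with them; covariate values must agree within a group.
#'
#' @param bundle a [study_bundle()].
#' @return A [study_bundle()] with one column per replicate group of the
#'   control samples.
#' @export
select_controls_and_sum_replicates <- function(bundle) {
  assert_that(inherits(bundle, "study_bundle"), "bundle must be a study_bundle")
  md <- bundle$metadata
  assert_that(!any(is.na(md$replicate_group)),
              "replicate_group must be defined for all samples")
  keep <- which(as.logical(md$control_flag))
  assert_that(length(keep) > 0, "no control samples remain")
  md <- md[keep, , drop = FALSE]
  counts <- bundle$counts[, keep, drop = FALSE]

  groups <- split(seq_len(nrow(md)), md$replicate_group)
  # preserve first-appearance order of groups
  groups <- groups[order(vapply(groups, min, 1L))]
  collapse_cols <- c("tissue", "source", bundle$covariates)
  new_counts <- matrix(0, nrow(counts), length(groups),
                       dimnames = list(rownames(counts), names(groups)))
  new_md <- md[vapply(groups, `[`, 1L, 1L), , drop = FALSE]
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    for (col in collapse_cols) {
      vals <- unique(md[[col]][idx])
      assert_that(length(vals) == 1L,
                  sprintf("conflicting '%s' within replicate group '%s'",
                          col, names(groups)[k]))
    }
    new_counts[, k] <- rowSums(counts[, idx, drop = FALSE])
  }
  new_md$sample_id <- names(groups)
  new_md$replicate_group <- names(groups)
  rownames(new_md) <- NULL
  study_bundle(bundle$study_id, new_counts, new_md, bundle$covariates)
}

#' Filter genes on counts-per-million thresholds
#'
#' Keeps genes reaching `min_cpm_all` cpm in *every* sample and a mean of
#' `min_cpm_mean` cpm across samples. Library sizes are per-sample totals
#' over all pre-filter genes, so the filter is idempotent only because
#' library sizes are recorded before filtering (and reused on re-application
#' the totals barely change; in practice re-filtering removes nothing).
#'
#' @param bundle a [study_bundle()].
#' @param min_cpm_all minimum cpm required in all samples.
#' @param min_cpm_mean minimum mean cpm across samples.
#' @return The filtered [study_bundle()].
#' @export
filter_genes_by_cpm <- function(bundle, min_cpm_all = 1, min_cpm_mean = 5) {
  assert_that(inherits(bundle, "study_bundle"), "bundle must be a study_bundle")
  counts <- bundle$counts
  assert_that(ncol(counts) >= 1, "need at least one sample")
  lib <- colSums(counts)
  assert_that(all(lib > 0), "library sizes must be > 0")
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  keep <- matrixStats_rowMins(cpm) >= min_cpm_all &
    rowMeans(cpm) >= min_cpm_mean
  if (!any(keep))
    stop("cpm filter removed every gene; lower min_cpm_all/min_cpm_mean",
         call. = FALSE)
  out <- bundle
  out$counts <- counts[keep, , drop = FALSE]
  out
}

# rowMins without a matrixStats dependency
matrixStats_rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = FALSE)))
}

# DESeq-style median-of-ratios size factors
size_factors_mor <- function(counts) {
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  assert_that(any(usable),
              "no gene has all-positive counts; cannot compute size factors")
  sf <- apply(counts[usable, , drop = FALSE], 2L, function(x) {
    exp(stats::median(log(x) - log_geo[usable]))
  })
  sf
}

# least-squares fit of the dispersion-mean trend disp(mu) = a/mu + b on
# per-gene method-of-moments dispersions; a, b clamped to >= 0
fit_dispersion_trend <- function(mu, disp) {
  # method-of-moments dispersions may be negative (under-Poisson noise);
  # they stay in the fit and the trend coefficients are clamped at zero
  ok <- is.finite(mu) & is.finite(disp) & mu > 0
  assert_that(sum(ok) >= 10,
              "fewer than 10 genes available for dispersion trend fitting")
  x <- 1 / mu[ok]; y <- disp[ok]
  fit <- stats::lm.fit(cbind(x = x, b = 1), y)
  a <- fit$coefficients[["x"]]; b <- fit$coefficients[["b"]]
  if (a < 0) { a <- 0; b <- max(mean(y), 0) }
  if (b <= 0) b <- 1e-8
  c(a = a, b = b)
}

#' Variance-stabilizing transformation for NB counts
#'
#' Normalizes by median-of-ratios size factors, fits the parametric
#' dispersion-mean trend `disp(mu) = a/mu + b` to per-gene method-of-moments
#' dispersion estimates, and applies the closed-form NB variance-stabilizing
#' transform on the log2-like scale
#' `vst(q) = log2((1 + a + 2 b q + 2 sqrt(b q (1 + a + b q))) / (4 b))`.
#' The transform is monotone in counts within each sample and approximately
#' removes the variance-mean trend. Set `method = "logcpm"` for a
#' `log2(cpm + 0.5)` fallback used in robustness checks.
#'
#' @param bundle a [study_bundle()] (gene filter already applied).
#' @param method `"vst"` (default) or `"logcpm"`.
#' @return An [expression_matrix()] with provenance `"vst"`.
#' @export
variance_stabilize <- function(bundle, method = c("vst", "logcpm")) {
  method <- match.arg(method)
  assert_that(inherits(bundle, "study_bundle"), "bundle must be a study_bundle")
  counts <- bundle$counts
  if (method == "logcpm") {
    lib <- colSums(counts)
    vals <- log2(sweep(counts, 2L, lib, "/") * 1e6 + 0.5)
    return(expression_matrix(vals, "vst"))
  }
  sf <- size_factors_mor(counts)
  q <- sweep(counts, 2L, sf, "/")
  m <- rowMeans(q)
  v <- apply(q, 1L, stats::var)
  disp <- (v - m) / m^2
  ab <- fit_dispersion_trend(m, disp)
  a <- ab[["a"]]; b <- ab[["b"]]
  vals <- log2((1 + a + 2 * b * q + 2 * sqrt(b * q * (1 + a + b * q))) /
                 (4 * b))
  em <- expression_matrix(vals, "vst")
  attr(em, "dispersion_trend") <- ab
  attr(em, "size_factors") <- sf
  em
}

# intercept + dummy-coded categoricals + standardized continuous covariates;
# aliased columns dropped with a warning
build_design <- function(metadata, covariate_list) {
  missing_cov <- setdiff(covariate_list, names(metadata))
  assert_that(length(missing_cov) == 0L,
              paste0("covariate(s) absent from metadata: ",
                     paste(missing_cov, collapse = ", ")))
  n <- nrow(metadata)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cov in covariate_list) {
    v <- metadata[[cov]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      col <- if (is.na(s) || s == 0) rep(0, n) else (v - mean(v)) / s
      X <- cbind(X, stats::setNames(data.frame(col), cov))
    } else {
      f <- factor(v)
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cov, levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

#' Remove fixed covariate effects by per-gene OLS
#'
#' Fits, for every gene, an ordinary least squares model of the transformed
#' expression on an intercept, dummy-coded categorical covariates and
#' standardized continuous covariates, and returns the residuals. Aliased
#' design columns are dropped with a warning rather than an error.
#'
#' @param expr an [expression_matrix()].
#' @param metadata per-sample metadata aligned with `expr` columns.
#' @param covariate_list character vector of metadata columns.
#' @return An [expression_matrix()] with provenance `"residual"`.
#' @export
correct_covariates <- function(expr, metadata, covariate_list = character()) {
  assert_that(inherits(expr, "expression_matrix"),
              "expr must be an expression_matrix")
  vals <- expr$values
  assert_that(nrow(metadata) == ncol(vals),
              "metadata rows must match expression columns")
  X <- build_design(metadata, covariate_list)
  qrX <- qr(X)
  resid <- t(qr.resid(qrX, t(vals)))
  dimnames(resid) <- dimnames(vals)
  expression_matrix(resid, "residual")
}

#' Flag and drop outlier samples via robust PCA Mahalanobis distance
#'
#' Genes are centered and scaled by median and MAD (constant genes dropped),
#' samples are projected on the top principal components (default: as many
#' as explain 70\% of variance, capped at 10), and each sample's Mahalanobis
#' distance to the robust center (componentwise median, MAD-scaled diagonal
#' covariance in component space) is computed. Samples strictly above the
#' empirical `quantile` of the distance distribution are removed.
#'
#' @param expr an [expression_matrix()].
#' @param quantile empirical quantile (linear interpolation) above which a
#'   sample is an outlier.
#' @param n_components number of components; `NULL` for the 70\%-variance
#'   rule.
#' @return list with `expr` (filtered [expression_matrix()]), `outliers`
#'   (character vector of removed sample IDs) and `distances` (named).
#' @export
remove_outlier_samples <- function(expr, quantile = 0.99, n_components = NULL) {
  assert_that(inherits(expr, "expression_matrix"),
              "expr must be an expression_matrix")
  vals <- expr$values
  n_samples <- ncol(vals)
  assert_that(n_samples >= 10, "need at least 10 samples for outlier removal")
  if (!is.null(n_components))
    assert_that(n_components < n_samples,
                "n_components must be < number of samples")
  X <- t(vals)                                   # samples x genes
  med <- apply(X, 2L, stats::median)
  madv <- apply(X, 2L, stats::mad)
  ok <- madv > 0
  assert_that(any(ok), "all genes constant; cannot score outliers")
  Xs <- sweep(sweep(X[, ok, drop = FALSE], 2L, med[ok]), 2L, madv[ok], "/")
  sv <- svd(Xs, nu = min(dim(Xs)), nv = 0)
  var_expl <- sv$d^2 / sum(sv$d^2)
  k <- if (is.null(n_components)) {
    min(max(which(cumsum(var_expl) >= 0.7)[1], 1L), 10L)
  } else as.integer(n_components)
  k <- min(k, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  center <- apply(scores, 2L, stats::median)
  scl <- apply(scores, 2L, stats::mad)
  scl[scl == 0] <- 1
  z <- sweep(sweep(scores, 2L, center), 2L, scl, "/")
  d2 <- rowSums(z^2)
  names(d2) <- colnames(vals)
  cutoff <- stats::quantile(d2, probs = quantile, type = 7, names = FALSE)
  out <- names(d2)[d2 > cutoff]
  keep <- setdiff(colnames(vals), out)
  list(expr = expression_matrix(vals[, keep, drop = FALSE], expr$provenance),
       outliers = out, distances = d2)
}

#' Per-gene residual mean and SD
#'
#' Sample mean and sample SD (n-1 denominator) per gene. Because OLS
#' residual means are identically zero, the reported per-gene mean is taken
#' from `mean_from` (the pre-correction variance-stabilized matrix) when
#' supplied.
#'
#' @param expr an [expression_matrix()] of residuals.
#' @param mean_from optional [expression_matrix()] (same genes) whose
#'   per-gene means are reported instead of `expr`'s.
#' @param study_id study identifier recorded on the result.
#' @return A `gene_summary`: data.frame with columns `gene`, `mean`, `sd`,
#'   `n`; the study ID is kept in `attr(, "study_id")`.
#' @export
summarize_genes <- function(expr, mean_from = NULL, study_id = "study") {
  assert_that(inherits(expr, "expression_matrix"),
              "expr must be an expression_matrix")
  vals <- expr$values
  assert_that(ncol(vals) >= 4, "need >= 4 samples to summarize")
  mean_vals <- if (is.null(mean_from)) vals else {
    mf <- mean_from$values[rownames(vals), colnames(vals), drop = FALSE]
    mf
  }
  out <- data.frame(
    gene = rownames(vals),
    mean = rowMeans(mean_vals),
    sd = apply(vals, 1L, stats::sd),
    n = ncol(vals),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("gene_summary", "data.frame"), study_id = study_id)
}

#' Run the full per-study pipeline
#'
#' Composes, in order: control selection and replicate summing, cpm gene
#' filtering, variance stabilization, fixed-effect covariate correction and
#' robust-PCA outlier removal, then summarizes per-gene residual mean and
#' SD. Diagnostics capture the mean-SD relation before and after the
#' transform, PCA sample coordinates before/after correction and outlier
#' removal, and per-stage removal counts.
#'
#' @param bundle a [study_bundle()].
#' @param min_cpm_all,min_cpm_mean cpm filter thresholds.
#' @param transform `"vst"` or `"logcpm"`.
#' @param outlier_quantile Mahalanobis-distance quantile for outlier removal.
#' @param n_components robust-PCA components (`NULL` = 70\%-variance rule).
#' @return list with `summary` (a `gene_summary`) and `diagnostics`.
#' @export
run_study_pipeline <- function(bundle, min_cpm_all = 1, min_cpm_mean = 5,
                               transform = c("vst", "logcpm"),
                               outlier_quantile = 0.99, n_components = NULL) {
  transform <- match.arg(transform)
  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop(sprintf("[%s] stage '%s': %s", bundle$study_id, name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  n_genes_in <- nrow(bundle$counts)
  n_samples_in <- ncol(bundle$counts)

  b1 <- stage("controls_replicates",
              function() select_controls_and_sum_replicates(bundle))
  b2 <- stage("cpm_filter",
              function() filter_genes_by_cpm(b1, min_cpm_all, min_cpm_mean))
  vst <- stage("vst", function() variance_stabilize(b2, transform))

  raw_mean <- rowMeans(b2$counts)
  raw_sd <- apply(b2$counts, 1L, stats::sd)
  vst_mean <- rowMeans(vst$values)
  vst_sd <- apply(vst$values, 1L, stats::sd)

  resid <- stage("covariates",
                 function() correct_covariates(vst, b2$metadata, b2$covariates))
  pca_pre <- sample_pca_coords(vst$values)
  pca_post <- sample_pca_coords(resid$values)

  outl <- stage("outliers",
                function() remove_outlier_samples(resid, outlier_quantile,
                                                  n_components))
  pca_final <- sample_pca_coords(outl$expr$values)

  summ <- stage("summarize",
                function() summarize_genes(outl$expr, mean_from = vst,
                                           study_id = bundle$study_id))

  diagnostics <- list(
    mean_sd_raw = data.frame(gene = rownames(b2$counts), mean = raw_mean,
                             sd = raw_sd),
    mean_sd_vst = data.frame(gene = rownames(b2$counts), mean = vst_mean,
                             sd = vst_sd),
    pca_before_correction = pca_pre,
    pca_after_correction = pca_post,
    pca_after_outlier_removal = pca_final,
    removed = list(
      non_control_or_replicates = n_samples_in - ncol(b1$counts),
      genes_cpm_filter = nrow(b1$counts) - nrow(b2$counts),
      outlier_samples = outl$outliers
    ),
    genes_in = n_genes_in,
    genes_passing_filter = rownames(b2$counts)
  )
  list(summary = summ, diagnostics = diagnostics)
}

# top-2 PCA coordinates of samples, for diagnostics
sample_pca_coords <- function(vals, k = 2L) {
  X <- t(vals)
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X, nu = min(k, min(dim(X))), nv = 0)
  k <- min(k, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  data.frame(sample_id = rownames(X), PC1 = coords[, 1],
             PC2 = if (k >= 2) coords[, 2] else NA_real_)
}
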
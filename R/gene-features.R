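as_gene_vector <- function(x, what = "value") {
  if (inherits(x, "variance_rank")) return(stats::setNames(x$rank, x$gene))
  assert_that(is.numeric(x) && !is.null(names(x)),
              sprintf("%s must be a named numeric vector or a variance_rank",
                      what))
  x
}

# all-pairs Spearman on the rows of a gene x sample matrix, via Pearson on
# row ranks computed blockwise with crossprod (exactly equal to pairwise
# computation)
all_pairs_spearman <- function(vals) {
  ranked <- t(apply(vals, 1L, rank, ties.method = "average"))
  ranked <- ranked - rowMeans(ranked)
  norms <- sqrt(rowSums(ranked^2))
  norms[norms == 0] <- 1
  ranked <- ranked / norms
  tcrossprod(ranked)
}

#' Weighted co-expression connectivity
#'
#' Per study, computes all-pairs Spearman correlations between gene
#' expression profiles, keeps edges significant at a Benjamini-Hochberg FDR
#' of `fdr` (p-values from the t-approximation; for studies with <= 10
#' samples and untied data the exact permutation null is used instead), and
#' sums the surviving signed correlations per gene. The final connectivity
#' is the average over the studies in which the gene is expressed.
#'
#' @param expr_list list of residual [expression_matrix()] objects (or
#'   gene x sample matrices), one per study.
#' @param fdr edge-level BH false-discovery rate.
#' @param absolute sum `|rho|` instead of signed rho (sensitivity mode).
#' @return Named numeric vector: gene -> mean weighted connectivity.
#' @export
weighted_connectivity <- function(expr_list, fdr = 0.01, absolute = FALSE) {
  if (inherits(expr_list, "expression_matrix") || is.matrix(expr_list))
    expr_list <- list(expr_list)
  per_study <- lapply(expr_list, function(em) {
    vals <- if (inherits(em, "expression_matrix")) em$values else em
    n <- ncol(vals)
    assert_that(n >= 5, "need at least 5 samples per study")
    assert_that(nrow(vals) >= 2, "need at least 2 genes")
    rho <- all_pairs_spearman(vals)
    ut <- upper.tri(rho)
    r <- rho[ut]
    has_ties <- any(apply(vals, 1L, function(x) anyDuplicated(x) > 0))
    p <- if (n <= 10 && !has_ties) {
      pairs <- which(ut, arr.ind = TRUE)
      vapply(seq_len(nrow(pairs)), function(k) {
        suppressWarnings(stats::cor.test(
          vals[pairs[k, 1], ], vals[pairs[k, 2], ],
          method = "spearman", exact = TRUE)$p.value)
      }, 1)
    } else cor_pvalue_t(r, n)
    # fdr = 0 means an empty network by convention
    keep <- if (fdr > 0) bh_adjust(p) <= fdr else rep(FALSE, length(p))
    adj <- matrix(0, nrow(rho), ncol(rho),
                  dimnames = dimnames(rho))
    w <- if (absolute) abs(r) else r
    adj[ut] <- w * keep
    adj <- adj + t(adj)
    rowSums(adj)
  })
  genes <- unique(unlist(lapply(per_study, names)))
  conn <- matrix(NA_real_, length(genes), length(per_study),
                 dimnames = list(genes, NULL))
  for (k in seq_along(per_study))
    conn[names(per_study[[k]]), k] <- per_study[[k]]
  rowMeans(conn, na.rm = TRUE)
}

# data.frame in 0-based half-open coordinates -> GRanges (1-based closed)
df_to_granges <- function(df, extra = character()) {
  assert_that(all(c("chrom", "start", "end") %in% names(df)),
              "need chrom/start/end columns")
  assert_that(all(df$start < df$end), "malformed intervals: start must be < end")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- df[[col]]
  gr
}

#' Mean window metric per gene
#'
#' Assigns every window overlapping a gene region (any overlap, half-open
#' BED semantics, strand ignored) to that gene and reports the unweighted
#' mean of the window metric. Genes without any overlapping window are
#' `NA`.
#'
#' @param track data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `value`; windows must not overlap one another.
#' @param regions data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return Named numeric vector gene -> mean metric (`NA` if no window).
#' @export
windows_to_genes <- function(track, regions) {
  win <- df_to_granges(track)
  reg <- df_to_granges(regions)
  assert_that(all(GenomicRanges::countOverlaps(win, win) == 1L),
              "windows must be non-overlapping within the track")
  hits <- GenomicRanges::findOverlaps(reg, win)
  out <- stats::setNames(rep(NA_real_, nrow(regions)), regions$gene_id)
  if (length(hits)) {
    means <- tapply(track$value[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
    out[as.integer(names(means))] <- as.numeric(means)
  }
  out
}

#' Chromatin-state proportions of extended gene regions
#'
#' Extends each gene region by `flank` bases on both sides (clipped at
#' position 0 and at the chromosome length), intersects with a
#' non-overlapping labeled segmentation, and reports per gene the fraction
#' of the extended region covered by each state.
#'
#' @param segmentation data.frame with `chrom`, `start`, `end`, `state`
#'   (0-based half-open, non-overlapping).
#' @param regions data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param flank bases added on each side (gene +/- 10 kb by default).
#' @param chrom_lengths optional named vector; defaults to the largest
#'   segmentation end per chromosome.
#' @return Numeric matrix gene x state of proportions in \[0, 1\]; rows sum
#'   to 1 when the segmentation partitions the extended region.
#' @export
chromatin_state_proportions <- function(segmentation, regions, flank = 10000,
                                        chrom_lengths = NULL) {
  assert_that("state" %in% names(segmentation),
              "segmentation needs a 'state' column")
  seg <- df_to_granges(segmentation, extra = "state")
  assert_that(all(GenomicRanges::countOverlaps(seg, seg) == 1L),
              "segmentation intervals must be non-overlapping")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(segmentation$end, segmentation$chrom, max)
  ext_start <- pmax(regions$start - flank, 0)
  ext_end <- pmin(regions$end + flank,
                  as.numeric(chrom_lengths[regions$chrom]))
  ext <- data.frame(chrom = regions$chrom, start = ext_start, end = ext_end)
  reg <- df_to_granges(ext)
  states <- sort(unique(segmentation$state))
  props <- matrix(0, nrow(regions), length(states),
                  dimnames = list(regions$gene_id, states))
  hits <- GenomicRanges::findOverlaps(reg, seg)
  if (length(hits)) {
    ov <- IRanges::pintersect(reg[S4Vectors::queryHits(hits)],
                              seg[S4Vectors::subjectHits(hits)])
    widths <- GenomicRanges::width(ov)
    st <- segmentation$state[S4Vectors::subjectHits(hits)]
    for (k in seq_along(hits)) {
      props[S4Vectors::queryHits(hits)[k], st[k]] <-
        props[S4Vectors::queryHits(hits)[k], st[k]] + widths[k]
    }
  }
  sweep(props, 1L, ext_end - ext_start, "/")
}

#' Compare chromatin-state proportions between gene groups
#'
#' Per state, a two-sample Wilcoxon rank-sum (Mann-Whitney) test of the
#' high-variance versus low-variance genes' proportions, BH-adjusted across
#' states, with the display statistics of each group (median proportion and
#' standard error of the mean). A paired signed-rank mode is available for
#' matched designs.
#'
#' @param proportions gene x state matrix from
#'   [chromatin_state_proportions()].
#' @param high,low character vectors of gene IDs (disjoint, each >= 3).
#' @param paired use the paired signed-rank test (groups must align).
#' @return data.frame, one row per state, with medians, SEMs, `p` and
#'   `p_adjusted`; constant states are flagged with `p = 1`.
#' @export
compare_groups_states <- function(proportions, high, low, paired = FALSE) {
  assert_that(length(intersect(high, low)) == 0, "groups must be disjoint")
  high <- intersect(high, rownames(proportions))
  low <- intersect(low, rownames(proportions))
  assert_that(length(high) >= 3 && length(low) >= 3,
              "minimum group size is 3")
  if (paired)
    assert_that(length(high) == length(low),
                "paired mode needs equal-size, aligned groups")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(colnames(proportions), function(st) {
    a <- proportions[high, st]
    b <- proportions[low, st]
    constant <- stats::var(c(a, b)) == 0
    p <- if (constant) 1 else
      suppressWarnings(stats::wilcox.test(a, b, paired = paired)$p.value)
    data.frame(state = st,
               median_high = stats::median(a), sem_high = sem(a),
               median_low = stats::median(b), sem_low = sem(b),
               p = p, constant = constant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Partial Spearman correlation controlling for a covariate rank
#'
#' Rank-transforms the feature, the target rank and the control rank over
#' their common genes, regresses the first two on the control, and returns
#' the Pearson correlation of the residuals with a t-approximation p-value
#' on n - 3 degrees of freedom.
#'
#' @param feature named numeric vector (gene -> value) or `variance_rank`.
#' @param rank target `variance_rank` (or named vector).
#' @param control control `variance_rank` (or named vector), typically the
#'   mean-expression rank.
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(feature, rank, control) {
  f <- as_gene_vector(feature, "feature")
  r <- as_gene_vector(rank, "rank")
  c_ <- as_gene_vector(control, "control")
  genes <- Reduce(intersect, list(names(f), names(r), names(c_)))
  genes <- genes[!is.na(f[genes]) & !is.na(r[genes]) & !is.na(c_[genes])]
  n <- length(genes)
  assert_that(n >= 10, "need at least 10 genes with all three values")
  rf <- rank(f[genes]); rr <- rank(r[genes]); rc <- rank(c_[genes])
  assert_that(stats::var(rf) > 0 && stats::var(rr) > 0 && stats::var(rc) > 0,
              "constant vector: partial correlation undefined")
  res_f <- stats::lm.fit(cbind(1, rc), rf)$residuals
  res_r <- stats::lm.fit(cbind(1, rc), rr)$residuals
  # a vector perfectly explained by the control has no partial association;
  # guard against correlating pure rounding noise
  if (stats::var(res_f) < 1e-12 * stats::var(rf) ||
      stats::var(res_r) < 1e-12 * stats::var(rr))
    return(list(rho = 0, p = 1, n = n))
  rho <- stats::cor(res_f, res_r)
  list(rho = rho, p = cor_pvalue_t(rho, n, df = n - 3L), n = n)
}

#' Batch partial Spearman correlations with BH adjustment
#'
#' @param features named list of gene-level feature vectors.
#' @param rank,control as in [partial_spearman()].
#' @return data.frame with `feature`, `rho`, `p`, `n`, `p_adjusted`.
#' @export
partial_spearman_table <- function(features, rank, control) {
  rows <- Map(function(f, id) {
    res <- partial_spearman(f, rank, control)
    data.frame(feature = id, rho = res$rho, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  }, features, names(features))
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
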
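#' @keywords internal
"_PACKAGE"

# internal assertion helper: stop with the caller's message if cond is not TRUE
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Benjamini-Hochberg wrapper kept in one place so every module adjusts the
# same way
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# column-wise average ranks (ties.method = "average"), NA kept as NA
rank_columns <- function(mat) {
  apply(mat, 2L, function(x) {
    r <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    r[ok] <- rank(x[ok], ties.method = "average")
    r
  })
}

# Spearman rho for the columns of a complete matrix, via Pearson on ranks.
# Kept internal: callers decide on complete-case restriction.
spearman_cols <- function(mat) {
  stats::cor(apply(mat, 2L, rank, ties.method = "average"))
}

# t-approximation p-value for a (Spearman or Pearson) correlation at sample
# size n; two-sided
cor_pvalue_t <- function(r, n, df = n - 2L) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
}
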
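# shared fixtures, all built in code

# tiny handcrafted bundle: 3 genes, 4 samples, one batch covariate
toy_bundle <- function(counts = NULL, control = rep(TRUE, 4),
                       replicate_group = paste0("s", 1:4)) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 20, 30, 40,
                       5, 5, 5, 5,
                       100, 90, 110, 95),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  }
  md <- data.frame(sample_id = colnames(counts),
                   tissue = "blood", source = "GTEX",
                   control_flag = control,
                   replicate_group = replicate_group,
                   batch = factor(c("a", "a", "b", "b")[seq_len(ncol(counts))]),
                   stringsAsFactors = FALSE)
  study_bundle("toy", counts, md, covariates = "batch")
}

# gene_summary built directly from named sd/mean vectors
make_summary <- function(study_id, sds, means = sds) {
  structure(data.frame(gene = names(sds), mean = unname(means),
                       sd = unname(sds), n = 10L, stringsAsFactors = FALSE),
            class = c("gene_summary", "data.frame"), study_id = study_id)
}

# sd_matrix from a complete gene x study matrix (no missing values)
make_sd_matrix <- function(sd_mat, mean_mat = sd_mat, labels = NULL) {
  structure(list(sd = sd_mat, mean = mean_mat, labels = labels),
            class = "sd_matrix")
}

# study_correlation from a correlation matrix + labels
make_study_corr <- function(rho, labels = NULL) {
  structure(list(matrix = rho, labels = labels, n_common_genes = nrow(rho)),
            class = "study_correlation")
}

# independent enumeration oracle for the upper-tail hypergeometric p-value
hyper_oracle <- function(N, K, n, ov) {
  ks <- ov:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force per-base scan for interval operations on toy chromosomes
per_base_mean_oracle <- function(track, region) {
  vals <- rep(NA_real_, region$end - region$start)
  hit_windows <- c()
  for (w in seq_len(nrow(track))) {
    if (track$chrom[w] == region$chrom &&
        track$start[w] < region$end && track$end[w] > region$start)
      hit_windows <- c(hit_windows, w)
  }
  if (!length(hit_windows)) return(NA_real_)
  mean(track$value[hit_windows])
}

per_base_state_oracle <- function(segmentation, chrom, start, end) {
  bases <- start:(end - 1)
  states <- rep(NA_character_, length(bases))
  for (s in seq_len(nrow(segmentation))) {
    if (segmentation$chrom[s] != chrom) next
    sel <- bases >= segmentation$start[s] & bases < segmentation$end[s]
    states[sel] <- segmentation$state[s]
  }
  table(factor(states, levels = sort(unique(segmentation$state)))) /
    length(bases)
}

# default-scale simulation shared by several test files (built lazily once)
.sim_cache <- new.env(parent = emptyenv())
shared_small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(n_genes = 400, n_studies = 4, samples_per_study = 60,
                      seed = 42)
    .sim_cache$sim <- generate_multistudy_counts(cfg)
    .sim_cache$cfg <- cfg
  }
  list(sim = .sim_cache$sim, cfg = .sim_cache$cfg)
}

# independent brute-force connectivity oracle: double loop over gene pairs
connectivity_oracle <- function(vals, fdr = 0.01) {
  n_genes <- nrow(vals); n <- ncol(vals)
  rho <- matrix(0, n_genes, n_genes)
  for (i in seq_len(n_genes)) for (j in seq_len(n_genes)) {
    if (i < j) rho[i, j] <- cor(vals[i, ], vals[j, ], method = "spearman")
  }
  r <- rho[upper.tri(rho)]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  keep <- p.adjust(p, "BH") <= fdr
  adj <- matrix(0, n_genes, n_genes)
  adj[upper.tri(adj)] <- r * keep
  adj <- adj + t(adj)
  setNames(rowSums(adj), rownames(vals))
}
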
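#' Configuration for the multi-study simulator
#'
#' Describes the synthetic world the generators draw from: a panel of bulk
#' RNA-seq studies over a shared gene catalogue, where each gene carries a
#' latent *variance propensity* that is partially shared across studies. The
#' `consistency` parameter is the fraction of propensity signal shared across
#' studies: at 1 every study sees the same gene ordering of biological
#' variability, at 0 the orderings are independent.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_studies number of studies (>= 1).
#' @param samples_per_study single count or per-study vector (each >= 4;
#'   fewer samples leave the residual SD undefined after corrections).
#' @param tissue_labels character vector of per-study tissues (recycled
#'   default panel if `NULL`).
#' @param source_labels per-study source in `"GTEX"`, `"TCGA"`, `"MISC"`
#'   (balanced default if `NULL`).
#' @param consistency real in \[0, 1\]: fraction of the variance-propensity
#'   signal shared across studies.
#' @param dispersion_baseline negative-binomial dispersion common to all
#'   genes (counting noise floor, not the biological signal).
#' @param batch_levels number of technical batches per study (1 = no batch
#'   structure).
#' @param outlier_fraction fraction of samples per study given globally
#'   inflated noise (must be < 0.5).
#' @param seed integer seed; identical configs (including seed) give
#'   bit-identical outputs.
#'
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_genes = 2000, n_studies = 10, samples_per_study = 100,
                       tissue_labels = NULL, source_labels = NULL,
                       consistency = 0.9, dispersion_baseline = 0.05,
                       batch_levels = 2, outlier_fraction = 0.01, seed = 1) {
  assert_that(is_count(n_genes) && is_count(n_studies) && is_count(batch_levels),
              "n_genes, n_studies and batch_levels must be counts >= 1")
  samples_per_study <- as.integer(rep_len(samples_per_study, n_studies))
  assert_that(all(is.finite(samples_per_study)) && all(samples_per_study >= 4),
              "samples_per_study must be >= 4 (SD undefined after corrections)")
  assert_that(is.numeric(consistency) && is.finite(consistency) &&
                consistency >= 0 && consistency <= 1,
              "consistency must lie in [0, 1]")
  assert_that(is.numeric(dispersion_baseline) && is.finite(dispersion_baseline) &&
                dispersion_baseline > 0,
              "dispersion_baseline must be a positive real")
  assert_that(is.numeric(outlier_fraction) && is.finite(outlier_fraction) &&
                outlier_fraction >= 0 && outlier_fraction < 0.5,
              "outlier_fraction must lie in [0, 0.5)")
  assert_that(is_count(abs(seed) + 1), "seed must be an integer")
  if (is.null(tissue_labels)) {
    panel <- c("blood", "liver", "brain", "lung", "skin")
    tissue_labels <- rep_len(panel, n_studies)
  }
  if (is.null(source_labels)) {
    source_labels <- rep_len(c("GTEX", "TCGA", "MISC"), n_studies)
  }
  assert_that(length(tissue_labels) == n_studies &&
                length(source_labels) == n_studies,
              "tissue/source labels must have one entry per study")
  assert_that(all(source_labels %in% c("GTEX", "TCGA", "MISC")),
              "source_labels must be GTEX, TCGA or MISC")
  structure(
    list(n_genes = as.integer(n_genes), n_studies = as.integer(n_studies),
         samples_per_study = samples_per_study,
         tissue_labels = as.character(tissue_labels),
         source_labels = as.character(source_labels),
         consistency = consistency,
         dispersion_baseline = dispersion_baseline,
         batch_levels = as.integer(batch_levels),
         outlier_fraction = outlier_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# noise-scale map: realized propensity (roughly N(0,1)) -> per-sample
# log-normal SD of the biological signal, monotone increasing
propensity_to_sigma <- function(realized, sigma_min = 0.10, sigma_max = 0.90) {
  sigma_min + (sigma_max - sigma_min) * stats::pnorm(realized)
}

#' Simulate a panel of RNA-seq studies with known variance structure
#'
#' Draws negative-binomial counts for each study. Per gene and sample the
#' NB mean is `exp(log_mean + batch effect + covariate effect + eta)` scaled
#' by a log-normal library size (around 1e6 so cpm thresholds behave as they
#' would at realistic depth), where `eta` is zero-mean-on-the-natural-scale
#' log-normal noise whose standard deviation increases monotonically with
#' the gene's realized variance propensity
#' `consistency * shared + (1 - consistency) * study noise`. Outlier samples
#' get a globally inflated noise scale. Batch and a continuous `age`
#' covariate are recorded in the metadata.
#'
#' @param config a [sim_config()].
#' @return list with `studies` (list of [study_bundle()]) and `truth`, a
#'   `truth_record` holding `true_log_mean`, `shared_propensity`,
#'   `realized_propensity` (gene x study), and per-study outlier sample IDs.
#' @export
generate_multistudy_counts <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  # relative expression levels: wide log-normal so the cpm filter bites a
  # low tail differently in each study
  true_log_mean <- stats::rnorm(n, mean = log(100), sd = 1.5)
  names(true_log_mean) <- genes
  w <- exp(true_log_mean)
  rel <- w / sum(w)

  shared <- stats::rnorm(n)
  names(shared) <- genes
  realized <- matrix(NA_real_, n, config$n_studies,
                     dimnames = list(genes, NULL))

  studies <- vector("list", config$n_studies)
  outliers <- vector("list", config$n_studies)
  study_ids <- sprintf("study%02d", seq_len(config$n_studies))
  colnames(realized) <- study_ids

  for (s in seq_len(config$n_studies)) {
    m <- config$samples_per_study[s]
    own <- stats::rnorm(n)
    prop <- config$consistency * shared + (1 - config$consistency) * own
    realized[, s] <- prop
    sigma <- propensity_to_sigma(prop)

    sample_ids <- sprintf("%s_s%04d", study_ids[s], seq_len(m))
    batch <- factor(rep_len(seq_len(config$batch_levels), m),
                    labels = paste0("b", seq_len(config$batch_levels)))
    age <- stats::rnorm(m)
    lib <- stats::rlnorm(m, meanlog = log(1e6), sdlog = 0.2)

    n_out <- floor(config$outlier_fraction * m)
    out_idx <- if (n_out > 0) sample.int(m, n_out) else integer()
    noise_scale <- rep(1, m)
    noise_scale[out_idx] <- 4

    batch_fx <- matrix(stats::rnorm(n * config$batch_levels, sd = 0.3),
                       n, config$batch_levels)
    if (config$batch_levels == 1L) batch_fx[] <- 0
    age_slope <- stats::rnorm(n, sd = 0.1)

    # gene x sample log-scale mean, then log-normal biological noise
    logmu <- outer(log(rel), log(lib), "+") +
      batch_fx[, as.integer(batch), drop = FALSE] +
      outer(age_slope, age)
    sig <- sigma %o% noise_scale                  # gene x sample noise SD
    eta <- matrix(stats::rnorm(n * m), n, m) * sig - sig^2 / 2
    mu <- exp(logmu + eta)
    counts <- matrix(
      stats::rnbinom(n * m, mu = mu, size = 1 / config$dispersion_baseline),
      n, m, dimnames = list(genes, sample_ids)
    )

    metadata <- data.frame(
      sample_id = sample_ids,
      tissue = config$tissue_labels[s],
      source = config$source_labels[s],
      control_flag = TRUE,
      replicate_group = sample_ids,
      batch = batch,
      age = age,
      stringsAsFactors = FALSE
    )
    covs <- if (config$batch_levels > 1L) c("batch", "age") else "age"
    studies[[s]] <- study_bundle(study_ids[s], counts, metadata, covs)
    outliers[[s]] <- sample_ids[out_idx]
  }
  names(studies) <- study_ids
  names(outliers) <- study_ids

  truth <- structure(
    list(true_log_mean = true_log_mean,
         shared_propensity = shared,
         realized_propensity = realized,
         outlier_sample_ids = outliers,
         config = config),
    class = "truth_record"
  )
  list(studies = studies, truth = truth)
}

decile_of_rank <- function(rank, M) as.integer(ceiling(10 * rank / M))

# decile weights for biased gene-set sampling
skew_weights <- function(target_skew, lambda = 0.4) {
  d <- 1:10
  switch(target_skew,
         uniform = rep(1, 10),
         `low-biased` = exp(-lambda * (d - 1)),
         `high-biased` = exp(-lambda * (10 - d)),
         stop("target_skew must be 'uniform', 'low-biased' or 'high-biased'",
              call. = FALSE))
}

#' Generate gene-set annotations tied to the true variance propensity
#'
#' Builds GO-like gene sets whose members are sampled with decile-weighted
#' probabilities against the rank of the true (shared) variance propensity,
#' plus binary labels (housekeeping-like: biased toward low-variance deciles;
#' immediate-early-like: biased toward high-variance deciles) and a set of
#' binary per-environment responsiveness labels with configurable marginal
#' rate and breadth (overlap across environments), all with known skew
#' direction so the decile statistics have ground truth.
#'
#' @param config a [sim_config()].
#' @param truth the `truth_record` from [generate_multistudy_counts()].
#' @param term_spec data.frame with columns `term_id`, `n_genes`,
#'   `target_skew` (each in `"uniform"`, `"low-biased"`, `"high-biased"`).
#' @param n_env number of simulated environments.
#' @param env_rate marginal responsiveness rate per environment.
#' @param env_breadth in \[0, 1\]: probability an environment's responsive
#'   genes are drawn from a shared pool (controls how many environments a
#'   responsive gene responds to).
#' @param env_skew decile bias of the responsive sets: `"high-biased"`
#'   (default; responsiveness concentrates in high-variance deciles) or
#'   `"uniform"` (null world for calibration checks).
#' @param label_sizes named sizes for the binary labels.
#' @param lambda decile-weight decay for biased sampling.
#' @param seed integer seed (defaults to `config$seed + 1`).
#'
#' @return An `annotation_collection`: list with `terms` (named list of gene
#'   vectors), `term_spec`, `labels` (named list of gene vectors) and
#'   `env_response` (gene x environment logical matrix).
#' @export
generate_annotations <- function(config, truth, term_spec,
                                 n_env = 10, env_rate = 0.1, env_breadth = 0.5,
                                 env_skew = c("high-biased", "uniform"),
                                 label_sizes = c(housekeeping = 200, ieg = 150),
                                 lambda = 0.4, seed = config$seed + 1L) {
  env_skew <- match.arg(env_skew)
  assert_that(is.data.frame(term_spec) &&
                all(c("term_id", "n_genes", "target_skew") %in% names(term_spec)),
              "term_spec needs columns term_id, n_genes, target_skew")
  assert_that(all(term_spec$n_genes >= 1), "each term must have size >= 1")
  assert_that(all(term_spec$n_genes <= config$n_genes),
              "term size cannot exceed n_genes")
  set.seed(seed)
  genes <- names(truth$shared_propensity)
  M <- length(genes)
  dec <- decile_of_rank(rank(truth$shared_propensity, ties.method = "first"), M)

  draw_biased <- function(size, target_skew) {
    wts <- skew_weights(target_skew, lambda)[dec]
    if (size == M) return(genes)            # exhaustion forces uniformity
    sample(genes, size, prob = wts)
  }

  terms <- Map(function(id, size, skew) draw_biased(size, skew),
               term_spec$term_id, term_spec$n_genes, term_spec$target_skew)
  names(terms) <- term_spec$term_id

  labels <- list(
    housekeeping = draw_biased(min(label_sizes[["housekeeping"]], M), "low-biased"),
    ieg = draw_biased(min(label_sizes[["ieg"]], M), "high-biased")
  )

  pool_size <- min(M, max(2L * ceiling(env_rate * M), 1L))
  pool <- draw_biased(pool_size, env_skew)
  env <- matrix(FALSE, M, n_env,
                dimnames = list(genes, sprintf("env%02d", seq_len(n_env))))
  size_e <- max(1L, round(env_rate * M))
  for (e in seq_len(n_env)) {
    from_pool <- stats::runif(1) < env_breadth
    hit <- if (from_pool) sample(pool, min(size_e, length(pool)))
           else draw_biased(size_e, env_skew)
    env[hit, e] <- TRUE
  }

  structure(list(terms = terms, term_spec = term_spec, labels = labels,
                 env_response = env),
            class = "annotation_collection")
}

#' Simulate dyadic study-pair correlations from the random-effects model
#'
#' Draws Fisher-z study-pair correlations from the generative counterpart of
#' the dyadic model fitted by [fit_dyadic_model()]: per-study effects
#' `alpha_i ~ N(0, sigma_alpha)` and
#' `z_ij ~ N(mu0 + alpha_i + alpha_j + beta[t_ij] + gamma[so_ij], sigma)`
#' for all unordered pairs, with tissue-congruence index `t` and source-pair
#' index `so` coded exactly as [build_dyads()] codes them.
#'
#' @param design data.frame with columns `study_id`, `tissue`, `source`.
#' @param params list with `mu0` (scalar), `beta` (length 2), `gamma`
#'   (length 6), `sigma` (> 0), `sigma_alpha` (> 0).
#' @param seed integer seed.
#' @return A `dyad_table` (see [build_dyads()]) with the simulated truth
#'   (including the drawn `alpha`) in `attr(, "truth")`.
#' @export
generate_dyadic_correlations <- function(design, params, seed = 1) {
  assert_that(nrow(design) >= 3, "need at least 3 studies for dyads")
  assert_that(all(vapply(params[c("mu0", "sigma", "sigma_alpha")],
                         function(x) is.finite(x), TRUE)) &&
                all(is.finite(params$beta)) && all(is.finite(params$gamma)),
              "dyadic parameters must be finite")
  assert_that(params$sigma > 0 && params$sigma_alpha > 0,
              "sigma and sigma_alpha must be > 0")
  assert_that(length(params$beta) == 2 && length(params$gamma) == 6,
              "beta must have length 2 and gamma length 6")
  set.seed(seed)
  r <- nrow(design)
  alpha <- stats::rnorm(r, sd = params$sigma_alpha)
  pairs <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  t_index <- ifelse(design$tissue[i] == design$tissue[j], 1L, 2L)
  so_index <- source_pair_index(design$source[i], design$source[j])
  mu <- params$mu0 + alpha[i] + alpha[j] +
    params$beta[t_index] + params$gamma[so_index]
  z <- stats::rnorm(length(mu), mean = mu, sd = params$sigma)
  out <- data.frame(study_i = design$study_id[i], study_j = design$study_id[j],
                    z = z, t_index = t_index, so_index = so_index,
                    stringsAsFactors = FALSE)
  structure(out, class = c("dyad_table", "data.frame"),
            studies = design,
            truth = c(params, list(alpha = alpha)))
}

#' Simulate genomic windows, chromatin states and gene regions
#'
#' Lays `n_genes` non-overlapping gene regions on one synthetic chromosome
#' (gene length `2 * window_size`, intergenic gap `window_size`, so each
#' tiling window overlaps at most one gene), emits a window track whose
#' metric mixes a monotone transform of the true propensity rank (weight
#' `effect`) with uniform noise, and a chromatin-state segmentation that
#' partitions the chromosome, with active-state proportions decreasing in
#' propensity decile.
#'
#' @param config a [sim_config()].
#' @param truth the `truth_record`.
#' @param window_size window width in bases.
#' @param effect in \[0, 1\]: weight of the propensity signal in the window
#'   metric (0 = pure noise, 1 = noiseless monotone function of the rank).
#' @param seed integer seed (defaults to `config$seed + 2`).
#' @return list with `track`, `segmentation`, `regions` (data.frames in
#'   0-based half-open coordinates) and `chrom_length`.
#' @export
generate_genomic_tracks <- function(config, truth, window_size = 10000,
                                    effect = 0.5, seed = config$seed + 2L) {
  assert_that(is.numeric(window_size) && window_size > 0,
              "window_size must be > 0")
  assert_that(effect >= 0 && effect <= 1, "effect must lie in [0, 1]")
  set.seed(seed)
  w <- as.integer(window_size)
  genes <- names(truth$shared_propensity)
  n <- length(genes)
  slot <- 3L * w
  chrom_length <- n * slot
  assert_that(n * slot <= .Machine$integer.max,
              "genes exceed representable chromosome length")
  start <- (seq_len(n) - 1L) * slot
  end <- start + 2L * w
  regions <- data.frame(gene_id = genes, chrom = "chrS", start = start,
                        end = end, strand = "+", stringsAsFactors = FALSE)

  rk <- rank(truth$shared_propensity, ties.method = "first")
  target <- (rk - 0.5) / n                       # monotone in propensity
  n_win <- chrom_length %/% w
  win_start <- (seq_len(n_win) - 1L) * w
  # window k overlaps gene i iff k falls in the first two thirds of slot i
  slot_idx <- win_start %/% slot + 1L
  in_gene <- (win_start %% slot) < 2L * w
  value <- stats::runif(n_win)
  value[in_gene] <- effect * target[slot_idx[in_gene]] +
    (1 - effect) * stats::runif(sum(in_gene))
  track <- data.frame(chrom = "chrS", start = win_start, end = win_start + w,
                      value = value, stringsAsFactors = FALSE)

  # segmentation: each gene body split TssA | Tx | Het with active share
  # shrinking as the propensity decile rises; gaps are Quies
  dec <- decile_of_rank(rk, n)
  f <- (dec - 1) / 9
  p_tss <- 0.05 + 0.25 * (1 - f)
  p_tx <- 0.10 + 0.50 * (1 - f)
  seg_chrom <- character(0); seg_start <- integer(0)
  seg_end <- integer(0); seg_state <- character(0)
  gene_len <- 2L * w
  for (i in seq_len(n)) {
    l1 <- as.integer(round(p_tss[i] * gene_len))
    l2 <- as.integer(round(p_tx[i] * gene_len))
    b <- start[i]
    cuts <- c(b, b + l1, b + l1 + l2, b + gene_len, b + slot)
    seg_start <- c(seg_start, cuts[1:4])
    seg_end <- c(seg_end, cuts[2:5])
    seg_state <- c(seg_state, c("TssA", "Tx", "Het", "Quies"))
  }
  keep <- seg_end > seg_start
  segmentation <- data.frame(chrom = "chrS", start = seg_start[keep],
                             end = seg_end[keep], state = seg_state[keep],
                             stringsAsFactors = FALSE)
  list(track = track, segmentation = segmentation, regions = regions,
       chrom_length = chrom_length)
}
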
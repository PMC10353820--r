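test_that("control selection and replicate summing behave additively", {
  # two replicates with counts (3, 4) collapse to 7
  counts <- matrix(c(3, 4, 10, 20,
                     1, 1, 2, 2,
                     5, 5, 5, 5),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  b <- toy_bundle(counts, replicate_group = c("r1", "r1", "s3", "s4"))
  # replicate groups must agree on covariates: s1/s2 share batch "a"? no --
  # batch is c(a, a, b, b), so r1 = {s1, s2} agrees
  out <- select_controls_and_sum_replicates(b)
  expect_equal(ncol(out$counts), 3)
  expect_equal(unname(out$counts["g1", "r1"]), 7)

  # all controls, no replicate groups: identity
  b2 <- toy_bundle()
  out2 <- select_controls_and_sum_replicates(b2)
  expect_equal(out2$counts, b2$counts)

  # mixed case/control: 2 controls + 2 cases -> 2 samples
  b3 <- toy_bundle(control = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ncol(select_controls_and_sum_replicates(b3)$counts), 2)

  # conflicting covariate within a group errors naming the group
  b4 <- toy_bundle(replicate_group = c("rx", "rx", "rx", "s4"))
  expect_error(select_controls_and_sum_replicates(b4), "rx")
})

test_that("cpm filter applies the all-samples and mean rules", {
  # libraries of exactly 1e6 via a filler gene
  gA <- c(2, 3); gB <- c(10, 10); gZ <- c(4, 0)
  filler <- c(1e6 - 2 - 10 - 4, 1e6 - 3 - 10 - 0)
  counts <- rbind(gA = gA, gB = gB, gZ = gZ, filler = filler)
  colnames(counts) <- c("s1", "s2")
  md <- data.frame(sample_id = c("s1", "s2"), tissue = "t", source = "MISC",
                   control_flag = TRUE, replicate_group = c("s1", "s2"))
  b <- study_bundle("cpmtest", counts, md)

  f <- filter_genes_by_cpm(b)
  # gA: min cpm 2 >= 1 but mean 2.5 < 5 -> dropped; gB: 10 cpm -> kept
  # gZ: a zero count -> dropped regardless of mean
  expect_setequal(rownames(f$counts), c("gB", "filler"))

  # thresholds (0, 0) are vacuous
  f0 <- filter_genes_by_cpm(b, 0, 0)
  expect_equal(rownames(f0$counts), rownames(counts))

  # idempotence
  expect_equal(filter_genes_by_cpm(f)$counts, f$counts)

  expect_error(filter_genes_by_cpm(b, 1e9, 1e9), "thresholds|filter")
})

test_that("VST removes the variance-mean trend of NB counts", {
  set.seed(11)
  n_samp <- 500
  means <- c(rep(10, 50), rep(1000, 50))
  counts <- t(sapply(means, function(m)
    rnbinom(n_samp, mu = m, size = 1 / 0.05)))
  dimnames(counts) <- list(paste0("g", seq_along(means)),
                           paste0("s", seq_len(n_samp)))
  md <- data.frame(sample_id = colnames(counts), tissue = "t",
                   source = "MISC", control_flag = TRUE,
                   replicate_group = colnames(counts))
  b <- study_bundle("vst", counts, md)

  raw_sd <- apply(counts, 1, sd)
  ratio_raw <- mean(raw_sd[means == 1000]) / mean(raw_sd[means == 10])
  expect_gt(ratio_raw, 5)

  v <- variance_stabilize(b)
  vst_sd <- apply(v$values, 1, sd)
  ratio_vst <- mean(vst_sd[means == 1000]) / mean(vst_sd[means == 10])
  expect_gt(ratio_vst, 0.5)
  expect_lt(ratio_vst, 2)

  # monotone within sample
  ord_counts <- order(counts[, 1])
  expect_true(all(diff(v$values[ord_counts, 1]) >= 0))

  # zero counts map to finite values
  counts2 <- counts; counts2[1, 1] <- 0
  b2 <- study_bundle("vst2", counts2, md)
  expect_true(all(is.finite(variance_stabilize(b2)$values)))
})

test_that("VST of an all-constant matrix gives per-gene constant output", {
  counts <- matrix(rep(c(5, 50, 500, 17, 120, 3, 9, 1000, 42, 7, 88, 61),
                       each = 6),
                   nrow = 12, byrow = TRUE,
                   dimnames = list(paste0("g", 1:12), paste0("s", 1:6)))
  md <- data.frame(sample_id = colnames(counts), tissue = "t",
                   source = "MISC", control_flag = TRUE,
                   replicate_group = colnames(counts))
  b <- study_bundle("const", counts, md)
  v <- variance_stabilize(b)
  expect_true(all(apply(v$values, 1, sd) == 0))
})

test_that("covariate correction returns OLS residuals", {
  set.seed(4)
  n <- 40
  md <- data.frame(sample_id = paste0("s", 1:n),
                   batch = factor(rep(c("x", "y"), each = n / 2)),
                   age = rnorm(n))
  vals <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(paste0("g", 1:5), md$sample_id))
  em <- expression_matrix(vals, "vst")

  # intercept-only model: residuals = values minus per-gene mean
  r0 <- correct_covariates(em, md, character())
  expect_equal(r0$values, vals - rowMeans(vals), tolerance = 1e-12)

  # gene that is an exact linear function of a covariate -> zero residuals
  vals2 <- vals
  vals2[1, ] <- 2 + 3 * md$age
  r1 <- correct_covariates(expression_matrix(vals2, "vst"), md, "age")
  expect_lt(max(abs(r1$values[1, ])), 1e-8)

  # constructed batch effect is removed
  vals3 <- vals
  vals3[2, md$batch == "y"] <- vals3[2, md$batch == "y"] + 2
  r2 <- correct_covariates(expression_matrix(vals3, "vst"), md, "batch")
  gm <- tapply(r2$values[2, ], md$batch, mean)
  expect_lt(abs(gm[1] - gm[2]), 1e-8)

  # residuals orthogonal to every design column
  r3 <- correct_covariates(em, md, c("batch", "age"))
  expect_lt(max(abs(r3$values %*% md$age)), 1e-8)

  expect_error(correct_covariates(em, md, "nonexistent"), "absent")
})

test_that("covariate correction is invariant to constant shifts of covariates", {
  set.seed(5)
  n <- 30
  md <- data.frame(sample_id = paste0("s", 1:n), age = rnorm(n))
  md2 <- md; md2$age <- md2$age + 100
  vals <- matrix(rnorm(4 * n), 4, n,
                 dimnames = list(paste0("g", 1:4), md$sample_id))
  em <- expression_matrix(vals, "vst")
  r1 <- correct_covariates(em, md, "age")
  r2 <- correct_covariates(em, md2, "age")
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
})

test_that("outlier removal follows the strict-quantile convention", {
  set.seed(6)
  mk <- function(n) {
    vals <- matrix(rnorm(50 * n), 50, n,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:n)))
    expression_matrix(vals, "residual")
  }
  # 100 iid samples at quantile 0.99 -> exactly 1 removed
  expect_length(remove_outlier_samples(mk(100), 0.99, 3)$outliers, 1)
  # 50 samples at quantile 0.9 -> exactly 5 removed
  expect_length(remove_outlier_samples(mk(50), 0.9, 3)$outliers, 5)
  expect_error(remove_outlier_samples(mk(10), 0.99, 10), "n_components")
  expect_error(remove_outlier_samples(mk(9)), "10 samples")
})

test_that("a grossly displaced sample is always flagged", {
  hits <- sapply(1:20, function(k) {
    set.seed(200 + k)
    vals <- matrix(rnorm(40 * 60), 40, 60,
                   dimnames = list(paste0("g", 1:40), paste0("s", 1:60)))
    vals[, 13] <- vals[, 13] + 50
    out <- remove_outlier_samples(expression_matrix(vals, "residual"),
                                  0.99, 3)
    "s13" %in% out$outliers
  })
  expect_true(all(hits))
})

test_that("gene summaries use the n-1 denominator and are permutation invariant", {
  vals <- rbind(g1 = c(0, 0, 0, 0),
                g2 = c(-1, 1, -1, 1),
                g3 = c(2, 4, 6, 8))
  colnames(vals) <- paste0("s", 1:4)
  em <- expression_matrix(vals, "residual")
  s <- summarize_genes(em)
  expect_equal(s$sd[s$gene == "g1"], 0)
  # hand computation: sum of squares 4 over n-1 = 3
  expect_equal(s$sd[s$gene == "g2"], sqrt(4 / 3))

  perm <- expression_matrix(vals[, c(3, 1, 4, 2)], "residual")
  s2 <- summarize_genes(perm)
  expect_equal(s$sd, s2$sd)
  expect_equal(s$mean, s2$mean)

  # means can come from the pre-correction matrix
  pre <- expression_matrix(vals + 5, "vst")
  s3 <- summarize_genes(em, mean_from = pre)
  expect_equal(s3$mean, s$mean + 5)
})

test_that("the composed pipeline is deterministic and tracks stage counts", {
  ss <- shared_small_sim()
  b <- ss$sim$studies[[1]]
  r1 <- run_study_pipeline(b)
  r2 <- run_study_pipeline(b)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$summary),
               length(r1$diagnostics$genes_passing_filter))
  expect_equal(r1$diagnostics$genes_in, nrow(b$counts))
  expect_equal(r1$diagnostics$genes_in -
                 r1$diagnostics$removed$genes_cpm_filter,
               nrow(r1$summary))
  expect_true(all(r1$summary$sd >= 0))

  # a gene forced under the cpm threshold is counted as removed
  b2 <- b
  b2$counts["g00001", ] <- 0L
  r3 <- run_study_pipeline(b2)
  expect_false("g00001" %in% r3$summary$gene)
})
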
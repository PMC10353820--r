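make_rank <- function(M) {
  structure(data.frame(gene = paste0("g", 1:M), pc1_score = seq_len(M),
                       rank = seq_len(M), presence_fraction = 1,
                       stringsAsFactors = FALSE),
            class = c("variance_rank", "data.frame"),
            kind = "variance", scope = "across-study",
            pc_variance_explained = 1)
}

test_that("decile assignment is balanced and boundary-exact", {
  d100 <- assign_deciles(make_rank(100))
  expect_true(all(tabulate(d100, 10) == 10))
  expect_equal(unname(d100[["g1"]]), 1L)
  expect_equal(unname(d100[["g100"]]), 10L)

  d101 <- assign_deciles(make_rank(101))
  sizes <- tabulate(d101, 10)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 101)
})

test_that("decile profiles give the closed-form entropy and skewness", {
  M <- 1000
  deciles <- assign_deciles(make_rank(M))

  # uniform: maximum entropy ln 10, zero skew
  p_unif <- term_decile_profile(paste0("g", 1:M), deciles, "u",
                                min_genes = 100)
  expect_equal(p_unif$entropy, log(10), tolerance = 1e-12)
  expect_equal(p_unif$skewness, 0, tolerance = 1e-12)
  expect_true(p_unif$included)

  # all genes in one decile: entropy 0, skewness 0 by convention
  p_one <- term_decile_profile(paste0("g", 1:100), deciles, "d1",
                               min_genes = 50)
  expect_equal(p_one$counts, c(100, rep(0, 9)))
  expect_equal(p_one$entropy, 0)
  expect_equal(p_one$skewness, 0)

  # two equal cells: entropy ln 2; symmetric mass -> skewness exactly 0
  p_two <- term_decile_profile(paste0("g", 1:200), deciles, "d12",
                               min_genes = 100)
  expect_equal(p_two$counts[1:2], c(100, 100))
  expect_equal(p_two$entropy, log(2), tolerance = 1e-12)
  expect_equal(p_two$skewness, 0, tolerance = 1e-12)

  # genuinely low-biased profile: positive skew; its mirror: negative
  lo_genes <- paste0("g", 1:400)             # deciles 1..4 as 40/30/20/10%
  lo_genes <- c(paste0("g", 1:100), paste0("g", 101:175),
                paste0("g", 201:250), paste0("g", 301:325))
  p_lo <- term_decile_profile(lo_genes, deciles, "lo", min_genes = 100)
  expect_gt(p_lo$skewness, 0)
  hi_genes <- paste0("g", M + 1 - match(lo_genes, paste0("g", 1:M)))
  p_hi <- term_decile_profile(hi_genes, deciles, "hi", min_genes = 100)
  expect_equal(p_hi$skewness, -p_lo$skewness, tolerance = 1e-12)

  # min_genes exclusion is recorded, not fatal
  p_small <- term_decile_profile(paste0("g", 1:30), deciles, "small")
  expect_false(p_small$included)
  expect_match(p_small$exclusion_reason, "fewer than 100")
})

test_that("entropy and skewness invariants hold over random profiles", {
  set.seed(20)
  for (k in 1:25) {
    counts <- pmin(rmultinom(1, 500, prob = runif(10))[, 1], 100L)
    tot <- sum(counts)
    ent <- -sum((counts[counts > 0] / tot) * log(counts[counts > 0] / tot))
    deciles <- assign_deciles(make_rank(1000))
    genes <- unlist(lapply(1:10, function(d)
      paste0("g", (d - 1) * 100 + seq_len(counts[d]))))
    prof <- term_decile_profile(genes, deciles, "r", min_genes = 1)
    expect_equal(prof$counts, counts, ignore_attr = TRUE)
    expect_equal(prof$entropy, ent, tolerance = 1e-12)
    expect_lte(prof$entropy, log(10) + 1e-12)
    # label-permutation invariance of entropy; reversal antisymmetry of skew
    perm <- sample(10)
    genes_perm <- unlist(lapply(1:10, function(d)
      paste0("g", (perm[d] - 1) * 100 + seq_len(counts[d]))))
    prof_perm <- term_decile_profile(genes_perm, deciles, "p", min_genes = 1)
    expect_equal(prof_perm$entropy, prof$entropy, tolerance = 1e-12)
    genes_rev <- unlist(lapply(1:10, function(d)
      paste0("g", (10 - d) * 100 + seq_len(counts[d]))))
    prof_rev <- term_decile_profile(genes_rev, deciles, "v", min_genes = 1)
    expect_equal(prof_rev$skewness, -prof$skewness, tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches the enumeration oracle", {
  universe <- paste0("g", 1:20)
  annotation <- paste0("g", 1:5)
  target <- paste0("g", c(1:4, 10))          # overlap 4
  res <- hypergeometric_enrichment(target, annotation, universe)
  expect_equal(res$overlap, 4)
  expect_equal(res$fold, 3.2)
  expect_equal(res$p, hyper_oracle(20, 5, 5, 4), tolerance = 1e-12)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)

  # saturation: annotation = universe
  res_sat <- hypergeometric_enrichment(target, universe, universe)
  expect_equal(res_sat$fold, 1)
  expect_equal(res_sat$p, 1)

  # vacuous tail: zero overlap between nonempty sets -> fold 0, p = 1
  res_zero <- hypergeometric_enrichment(paste0("g", 6:9), annotation,
                                        universe)
  expect_equal(res_zero$overlap, 0)
  expect_equal(res_zero$fold, 0)
  expect_equal(res_zero$p, 1)

  expect_error(hypergeometric_enrichment(target, annotation, character()),
               "universe")
  expect_error(hypergeometric_enrichment("gX", annotation, universe),
               "subsets")
})

test_that("batch enrichment applies BH with its guarantees", {
  set.seed(21)
  universe <- paste0("g", 1:200)
  target <- paste0("g", 1:20)
  anns <- lapply(1:8, function(k) sample(universe, 30))
  names(anns) <- paste0("set", 1:8)
  anns$enriched <- c(paste0("g", 1:15), sample(universe[21:200], 10))
  tab <- enrichment_table(target, anns, universe)
  expect_true(all(tab$p_adjusted >= tab$p))
  ord <- order(tab$p)
  expect_true(all(diff(tab$p_adjusted[ord]) >= 0))
  expect_lt(tab$p_adjusted[tab$set_id == "enriched"], 0.01)
})

test_that("environment Fisher tests match enumeration and detect enrichment", {
  # balanced table: odds ratio 1, p = 1
  universe <- paste0("g", 1:40)
  high <- paste0("g", 1:20)
  resp <- paste0("g", c(1:10, 21:30))
  res <- env_responsiveness_tests(high, character(0), list(e1 = resp),
                                  universe)
  any_row <- res[res$direction == "high" & res$environment == "any", ]
  expect_equal(any_row$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(any_row$p_two_sided, 1)

  # [[9,1],[1,9]] against full enumeration with fixed margins
  u2 <- paste0("x", 1:20)
  h2 <- u2[1:10]
  r2 <- c(u2[1:9], u2[11])
  res2 <- env_responsiveness_tests(h2, character(0), list(e1 = r2), u2)
  # oracle: sum of hypergeometric probabilities of tables as or less likely
  probs <- dhyper(0:10, 10, 10, 10)
  p_oracle <- sum(probs[probs <= dhyper(9, 10, 10, 10) + 1e-12])
  expect_equal(res2$p_two_sided[res2$environment == "e1" &
                                  res2$direction == "high"], p_oracle,
               tolerance = 1e-10)

  # synthetic enrichment in the high tail is detected at FDR 10%
  set.seed(22)
  hits <- sapply(1:10, function(k) {
    uni <- paste0("g", 1:500)
    hi <- paste0("g", 451:500); lo <- paste0("g", 1:50)
    env <- lapply(1:5, function(e)
      unique(c(sample(hi, 25), sample(uni, 25))))
    names(env) <- paste0("e", 1:5)
    r <- env_responsiveness_tests(hi, lo, env, uni)
    any(r$p_adjusted[r$direction == "high"] <= 0.1, na.rm = TRUE)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Poisson GLM on environment counts recovers effects", {
  set.seed(23)
  # identical distributions: coefficients near zero, p > 0.1
  null_ps <- replicate(20, {
    counts <- rpois(300, 1.5)
    category <- rep(c("background", "high", "low"), each = 100)
    fit <- env_count_glm(counts, category)
    min(fit$coefficients$p[-1])
  })
  expect_gt(mean(null_ps > 0.1), 0.7)

  # multiplicative effect e on the high group: coefficient ~ 1
  counts <- c(rpois(2000, 1), rpois(2000, exp(1)))
  category <- rep(c("background", "high"), each = 2000)
  fit <- env_count_glm(counts, category)
  est <- fit$coefficients$estimate[fit$coefficients$term == "categoryhigh"]
  expect_equal(est, 1, tolerance = 0.15)
  expect_equal(fit$group_medians$category, c("background", "high"))

  expect_error(env_count_glm(rpois(10, 1), rep("high", 10)), "2 gene categories")
})

test_that("terms_at_level extracts depth-3 nodes of a DAG", {
  edges <- data.frame(
    parent = c("root", "root", "a", "a", "b", "c", "d", "e", "root"),
    child  = c("a",    "b",    "c", "d", "d", "e", "e", "f", "e"))
  # depths: a=1, b=1, c=2, d=2, e=1 (direct from root), f=2
  expect_setequal(terms_at_level(edges, 1), c("a", "b", "e"))
  expect_setequal(terms_at_level(edges, 2), c("c", "d", "f"))
  expect_setequal(terms_at_level(edges, 0), "root")
})
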
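#' Fisher z-transform of a correlation
#'
#' Maps a correlation in (-1, 1) to the real line via `atanh`.
#'
#' @param rho numeric vector with `|rho| < 1`.
#' @return `atanh(rho)`.
#' @export
fisher_z <- function(rho) {
  assert_that(all(is.finite(rho)) && all(abs(rho) < 1),
              "|rho| must be < 1 for the Fisher z-transform")
  atanh(rho)
}

# unordered source-pair -> index 1..6, lexicographic over {GTEX, MISC, TCGA}:
# GTEX-GTEX=1, GTEX-MISC=2, GTEX-TCGA=3, MISC-MISC=4, MISC-TCGA=5, TCGA-TCGA=6
source_pair_index <- function(s1, s2) {
  lv <- c("GTEX", "MISC", "TCGA")
  assert_that(all(c(s1, s2) %in% lv),
              "unknown source label; expected GTEX, TCGA or MISC")
  a <- pmin(match(s1, lv), match(s2, lv))
  b <- pmax(match(s1, lv), match(s2, lv))
  # pairs in lexicographic order: (1,1),(1,2),(1,3),(2,2),(2,3),(3,3)
  idx <- c(`11` = 1L, `12` = 2L, `13` = 3L, `22` = 4L, `23` = 5L, `33` = 6L)
  unname(idx[paste0(a, b)])
}

#' Build the dyad table from a study correlation matrix
#'
#' One row per unordered study pair (i > j) with the Fisher z-transformed
#' correlation, the tissue-congruence index `t_index` (1 = same tissue,
#' 2 = different) and the source-pair index `so_index` coding the six
#' unordered combinations of GTEX, MISC and TCGA (GTEX-GTEX = 1,
#' GTEX-MISC = 2, GTEX-TCGA = 3, MISC-MISC = 4, MISC-TCGA = 5,
#' TCGA-TCGA = 6).
#'
#' @param corr a `study_correlation` with `labels` giving per-study
#'   `tissue` and `source`.
#' @return A `dyad_table` data.frame with columns `study_i`, `study_j`, `z`,
#'   `t_index`, `so_index`; study labels kept in `attr(, "studies")`.
#' @export
build_dyads <- function(corr) {
  assert_that(inherits(corr, "study_correlation"),
              "corr must be a study_correlation")
  labels <- corr$labels
  assert_that(!is.null(labels) &&
                all(c("study_id", "tissue", "source") %in% names(labels)),
              "study labels (study_id, tissue, source) are required")
  rho <- corr$matrix
  r <- nrow(rho)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  out <- data.frame(
    study_i = labels$study_id[i],
    study_j = labels$study_id[j],
    z = fisher_z(rho[pairs]),
    t_index = ifelse(labels$tissue[i] == labels$tissue[j], 1L, 2L),
    so_index = source_pair_index(labels$source[i], labels$source[j]),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("dyad_table", "data.frame"), studies = labels)
}

# log full conditional for log(sigma): n normal observations with residual
# sum of squares ssr, Exp(1) prior on sigma, Jacobian included
log_cond_log_sigma <- function(phi, n, ssr) {
  s <- exp(phi)
  -n * phi - ssr / (2 * s^2) - s + phi
}

#' Fit the Bayesian dyadic random-effects model
#'
#' Models each Fisher-z study-pair correlation as
#' `z_ij ~ Normal(mu0 + alpha_i + alpha_j + beta[t_ij] + gamma[so_ij], sigma)`
#' with per-study random effects `alpha_i ~ Normal(0, sigma_alpha)` that
#' absorb the non-independence among the pairs sharing a study. Priors:
#' `mu0 ~ N(0, 1)`, `beta_l, gamma_k ~ N(0, 0.25)` (weakly informative,
#' SD one quarter), `sigma, sigma_alpha ~ Exponential(1)`.
#'
#' The sampler is a blocked Metropolis-within-Gibbs: the jointly Gaussian
#' location block `(mu0, beta, gamma, alpha)` is drawn exactly from its
#' conditional given `(sigma, sigma_alpha)`, while `log sigma` and
#' `log sigma_alpha` are updated by adaptive random-walk Metropolis with
#' dual-averaging step-size tuning during warmup. Because `mu0`, `beta` and
#' `gamma` enter as a sum, only contrasts among them are identified; see
#' [summarize_posterior()].
#'
#' @param dyads a `dyad_table`.
#' @param chains number of chains.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param sampling kept iterations per chain.
#' @param seed integer seed.
#' @return A `dyad_posterior`: list with `draws` (matrix, one column per
#'   parameter), `chain` (index per draw), `rhat`, `ess`, `converged`
#'   (all R-hat <= 1.05) and the design bookkeeping.
#' @export
fit_dyadic_model <- function(dyads, chains = 4, warmup = 1000, sampling = 1000,
                             seed = 1) {
  assert_that(inherits(dyads, "dyad_table"), "dyads must be a dyad_table")
  studies <- unique(c(dyads$study_i, dyads$study_j))
  r <- length(studies)
  assert_that(r >= 4, "need at least 4 studies to fit the dyadic model")
  assert_that(all(is.finite(dyads$z)), "z values must be finite")
  n <- nrow(dyads)

  # design: intercept | beta indicators | gamma indicators | alpha incidence
  Xb <- matrix(0, n, 2); Xb[cbind(seq_len(n), dyads$t_index)] <- 1
  Xg <- matrix(0, n, 6); Xg[cbind(seq_len(n), dyads$so_index)] <- 1
  A <- matrix(0, n, r)
  A[cbind(seq_len(n), match(dyads$study_i, studies))] <- 1
  A[cbind(seq_len(n), match(dyads$study_j, studies))] <- 1
  X <- cbind(1, Xb, Xg, A)
  p <- ncol(X)
  par_names <- c("mu0", paste0("beta[", 1:2, "]"), paste0("gamma[", 1:6, "]"),
                 paste0("alpha[", studies, "]"), "sigma", "sigma_alpha")
  XtX <- crossprod(X)
  Xtz <- crossprod(X, dyads$z)
  z <- dyads$z

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    # overdispersed-ish but stable inits (scales floored at 1e-4 throughout)
    sigma <- stats::rexp(1, 2) + 0.02
    sigma_alpha <- stats::rexp(1, 2) + 0.02
    theta <- stats::rnorm(p, 0, 0.1)
    draws <- matrix(NA_real_, sampling, p + 2)
    # dual-averaging state for the two scalar MH updates
    da <- lapply(1:2, function(i)
      list(log_eps = log(0.5), log_eps_bar = log(0.5), h_bar = 0,
           mu = log(2.5), counter = 0))
    target_acc <- 0.44
    mh_step <- function(which, phi, logpost, cur_lp) {
      st <- da[[which]]
      eps <- if (st$counter < warmup) exp(st$log_eps) else exp(st$log_eps_bar)
      prop <- phi + eps * stats::rnorm(1)
      # floor the scales at 1e-4 (z values are O(1)); keeps the Gaussian
      # block numerically positive definite on degenerate (noise-free) data
      lp_prop <- if (prop < log(1e-4)) -Inf else logpost(prop)
      acc_prob <- min(1, exp(lp_prop - cur_lp))
      accept <- stats::runif(1) < acc_prob
      if (st$counter < warmup) {               # dual averaging update
        st$counter <- st$counter + 1
        m <- st$counter
        st$h_bar <- (1 - 1 / (m + 10)) * st$h_bar +
          (target_acc - acc_prob) / (m + 10)
        st$log_eps <- st$mu - sqrt(m) / 0.05 * st$h_bar
        eta <- m^(-0.75)
        st$log_eps_bar <- eta * st$log_eps + (1 - eta) * st$log_eps_bar
      } else st$counter <- st$counter + 1
      da[[which]] <<- st
      if (accept) list(phi = prop, lp = lp_prop) else list(phi = phi, lp = cur_lp)
    }

    for (it in seq_len(warmup + sampling)) {
      # exact Gaussian draw for the location block
      prior_prec <- c(1, rep(1 / 0.25^2, 8), rep(1 / sigma_alpha^2, r))
      prec <- XtX / sigma^2
      diag(prec) <- diag(prec) + prior_prec
      R <- chol(prec)
      mean_theta <- backsolve(R, forwardsolve(t(R), Xtz / sigma^2))
      theta <- mean_theta + backsolve(R, stats::rnorm(p))

      resid <- z - X %*% theta
      ssr <- sum(resid^2)
      phi <- log(sigma)
      st1 <- mh_step(1, phi, function(ph) log_cond_log_sigma(ph, n, ssr),
                     log_cond_log_sigma(phi, n, ssr))
      sigma <- exp(st1$phi)

      alpha <- theta[(p - r + 1):p]
      ssa <- sum(alpha^2)
      psi <- log(sigma_alpha)
      st2 <- mh_step(2, psi, function(ph) log_cond_log_sigma(ph, r, ssa),
                     log_cond_log_sigma(psi, r, ssa))
      sigma_alpha <- exp(st2$phi)

      if (it > warmup) draws[it - warmup, ] <- c(theta, sigma, sigma_alpha)
    }
    draws
  }

  chain_seeds <- seed + seq_len(chains) * 1000L
  all_draws <- lapply(chain_seeds, run_chain)
  draws <- do.call(rbind, all_draws)
  colnames(draws) <- par_names
  chain <- rep(seq_len(chains), each = sampling)

  rhat <- apply_split_rhat(draws, chain)
  ess <- apply_ess(draws, chain)
  converged <- all(is.finite(rhat) & rhat <= 1.05)
  if (!converged)
    warning("dyadic model: R-hat > 1.05 for ",
            paste(par_names[which(rhat > 1.05)], collapse = ", "),
            call. = FALSE)

  structure(list(draws = draws, chain = chain, rhat = rhat, ess = ess,
                 converged = converged, studies = studies,
                 chains = chains, warmup = warmup, sampling = sampling),
            class = "dyad_posterior")
}

#' @export
print.dyad_posterior <- function(x, ...) {
  cat(sprintf(
    "dyad_posterior: %d parameters, %d chains x %d draws (max R-hat %.3f)\n",
    ncol(x$draws), x$chains, x$sampling, max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

# split-R-hat (rank-free classic version on split chains)
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(seq_along(x), chain), function(idx) {
    h <- length(idx) %/% 2L
    rep(1:2, c(h, length(idx) - h))
  }))
  groups <- interaction(chain, halves, drop = TRUE)
  m <- nlevels(groups)
  n_per <- tabulate(groups)
  if (m < 2 || any(n_per < 2)) return(NA_real_)
  means <- tapply(x, groups, mean)
  vars <- tapply(x, groups, stats::var)
  n <- min(n_per)
  W <- mean(vars)
  B <- n * stats::var(as.numeric(means))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

apply_split_rhat <- function(draws, chain) {
  apply(draws, 2L, split_rhat, chain = chain)
}

# effective sample size via Geyer initial positive sequence, per chain then
# combined
ess_one <- function(x, chain) {
  chains <- split(x, chain)
  n <- min(lengths(chains))
  acov <- sapply(chains, function(v) {
    v <- v[seq_len(n)] - mean(v[seq_len(n)])
    a <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    a * sum(v^2) / n
  })
  acov <- as.matrix(acov)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (ncol(acov) > 1) var_plus <- var_plus + stats::var(vapply(chains, function(v)
    mean(v[seq_len(n)]), 1))
  if (var_plus <= 0) return(length(x))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive pairs while positive
  t_max <- length(rho)
  ess_sum <- rho[1]
  t <- 2L
  while (t + 1L <= t_max) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    ess_sum <- ess_sum + pair
    t <- t + 2L
  }
  total <- length(x)
  max(min(total / (2 * ess_sum - 1), total), 1)
}

apply_ess <- function(draws, chain) {
  apply(draws, 2L, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    ess_one(x, chain)
  })
}

#' Summarize a dyadic-model posterior
#'
#' Per-parameter posterior mean, median, central 50\% and 95\% intervals,
#' R-hat and effective sample size, plus the identified contrasts: the
#' tissue-congruence effect `beta[1] - beta[2]` and the source-pair
#' contrasts `gamma[k] - gamma[6]`. Raw levels of `mu0`, `beta` and `gamma`
#' are reported but confounded by construction (they enter the mean as a
#' sum); only contrasts are interpretable.
#'
#' @param post a `dyad_posterior`.
#' @return data.frame with one row per parameter and contrast.
#' @export
summarize_posterior <- function(post) {
  assert_that(inherits(post, "dyad_posterior"),
              "post must be a dyad_posterior")
  draws <- post$draws
  contrasts <- cbind(
    `beta[1]-beta[2]` = draws[, "beta[1]"] - draws[, "beta[2]"]
  )
  for (k in 1:5)
    contrasts <- cbind(contrasts, draws[, paste0("gamma[", k, "]")] -
                         draws[, "gamma[6]"])
  colnames(contrasts)[2:6] <- paste0("gamma[", 1:5, "]-gamma[6]")
  all_draws <- cbind(draws, contrasts)
  qs <- t(apply(all_draws, 2L, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(
    parameter = colnames(all_draws),
    mean = colMeans(all_draws),
    median = qs[, 3],
    q2.5 = qs[, 1], q25 = qs[, 2], q75 = qs[, 4], q97.5 = qs[, 5],
    rhat = c(post$rhat, apply_split_rhat(contrasts, post$chain)),
    ess = c(post$ess, apply_ess(contrasts, post$chain)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
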
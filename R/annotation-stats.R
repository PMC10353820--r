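#' Assign variance-rank deciles
#'
#' Decile 1 holds the lowest-variance genes. Because the rank is a
#' permutation there are no ties: `decile = ceiling(10 * rank / M)`.
#'
#' @param rank a `variance_rank`.
#' @return Named integer vector (gene -> decile in 1..10).
#' @export
assign_deciles <- function(rank) {
  assert_that(inherits(rank, "variance_rank"), "rank must be a variance_rank")
  M <- nrow(rank)
  assert_that(M >= 10, "need at least 10 ranked genes for deciles")
  stats::setNames(decile_of_rank(rank$rank, M), rank$gene)
}

# Fisher-Pearson g1 (standardized third central moment) of the multiset of
# decile indices implied by the counts; 0 under the zero-variance convention
decile_skewness <- function(counts) {
  d <- 1:10
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts / n
  mu <- sum(p * d)
  m2 <- sum(p * (d - mu)^2)
  if (m2 == 0) return(0)
  m3 <- sum(p * (d - mu)^3)
  m3 / m2^1.5
}

decile_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Decile profile of a gene set
#'
#' Counts a term's genes per variance-rank decile and computes the Shannon
#' entropy (natural log; maximal at `ln 10` for a uniform profile) and the
#' Fisher-Pearson skewness g1 of the multiset of decile indices. Mass in the
#' low-variance deciles leaves a right tail (positive skew); mass in the
#' high-variance deciles gives negative skew; zero variance across deciles
#' is reported as skewness 0. Terms whose intersection with the ranked genes
#' falls below `min_genes` are flagged as excluded (with the entropy-ready
#' counts still reported).
#'
#' @param term_genes character vector of the term's genes.
#' @param deciles named decile vector from [assign_deciles()].
#' @param term_id identifier recorded on the profile.
#' @param min_genes minimum intersection size for inclusion.
#' @param entropy_base base for the *reported* entropy (internal bound
#'   checks always use natural log); default natural.
#' @return A `decile_profile`: list with `term_id`, `counts` (length 10),
#'   `n_genes`, `entropy`, `skewness`, `included`, `exclusion_reason`.
#' @export
term_decile_profile <- function(term_genes, deciles, term_id = "term",
                                min_genes = 100, entropy_base = exp(1)) {
  genes <- intersect(term_genes, names(deciles))
  assert_that(length(genes) > 0,
              sprintf("term '%s' has no genes in the ranked universe", term_id))
  counts <- tabulate(deciles[genes], nbins = 10L)
  ent <- decile_entropy(counts) / log(entropy_base)
  structure(
    list(term_id = term_id, counts = counts, n_genes = length(genes),
         entropy = ent, skewness = decile_skewness(counts),
         included = length(genes) >= min_genes,
         exclusion_reason = if (length(genes) >= min_genes) NA_character_
                            else sprintf("fewer than %d genes (%d)",
                                         min_genes, length(genes))),
    class = "decile_profile"
  )
}

#' Decile profiles for a collection of terms
#'
#' @param terms named list of gene vectors (e.g. from [read_gmt()] or
#'   [generate_annotations()]).
#' @inheritParams term_decile_profile
#' @return data.frame with one row per term (`included` marks terms passing
#'   `min_genes`), columns `term_id`, `n_genes`, `entropy`, `skewness`,
#'   `included`, and `d1`..`d10` counts.
#' @export
decile_profile_table <- function(terms, deciles, min_genes = 100,
                                 entropy_base = exp(1)) {
  profs <- Map(function(g, id)
    term_decile_profile(g, deciles, id, min_genes, entropy_base),
    terms, names(terms))
  counts <- do.call(rbind, lapply(profs, `[[`, "counts"))
  colnames(counts) <- paste0("d", 1:10)
  out <- data.frame(
    term_id = names(terms),
    n_genes = vapply(profs, `[[`, 0L, "n_genes"),
    entropy = vapply(profs, `[[`, 0, "entropy"),
    skewness = vapply(profs, `[[`, 0, "skewness"),
    included = vapply(profs, `[[`, TRUE, "included"),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, counts)
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment of an annotation in a target gene set
#'
#' Upper-tail hypergeometric test of overlap at least as large as observed
#' between `target` (e.g. the top-5\% variance genes) and `annotation`
#' within `universe`. Fold = (overlap / |target|) / (|annotation| /
#' |universe|).
#'
#' @param target,annotation,universe character gene vectors; target and
#'   annotation must be subsets of universe.
#' @param set_id identifier for reporting.
#' @return An `enrichment_result` data.frame row: `set_id`, `overlap`,
#'   `expected`, `fold`, `p`.
#' @export
hypergeometric_enrichment <- function(target, annotation, universe,
                                      set_id = "set") {
  assert_that(length(universe) > 0, "universe must be non-empty")
  assert_that(all(target %in% universe) && all(annotation %in% universe),
              "target and annotation must be subsets of the universe")
  N <- length(unique(universe))
  K <- length(unique(annotation))
  n <- length(unique(target))
  ov <- length(intersect(target, annotation))
  p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  fold <- if (n > 0 && K > 0) (ov / n) / (K / N) else NA_real_
  data.frame(set_id = set_id, overlap = ov, expected = expected,
             fold = fold, p = p, stringsAsFactors = FALSE)
}

#' Batch hypergeometric enrichment with BH correction
#'
#' @param target character gene vector.
#' @param annotations named list of gene sets.
#' @param universe background gene vector.
#' @return data.frame with one row per set and a `p_adjusted` column
#'   (Benjamini-Hochberg across the sets).
#' @export
enrichment_table <- function(target, annotations, universe) {
  rows <- Map(function(ann, id)
    hypergeometric_enrichment(target, intersect(ann, universe), universe, id),
    annotations, names(annotations))
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

fisher_2x2 <- function(tab) {
  ft <- stats::fisher.test(tab)
  gt <- stats::fisher.test(tab, alternative = "greater")
  lt <- stats::fisher.test(tab, alternative = "less")
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  data.frame(odds_ratio = if (degenerate) NA_real_ else unname(ft$estimate),
             p_two_sided = ft$p.value, p_greater = gt$p.value,
             p_less = lt$p.value, degenerate = degenerate)
}

#' Environmental-responsiveness Fisher tests
#'
#' For the high-variance gene set, tests whether membership is associated
#' with responsiveness to more than zero environments relative to all genes
#' *not* in the low-variance set (and vice versa for the low set). The
#' "any" row uses the union of the per-environment sets; per-environment
#' rows are BH-adjusted within each direction.
#'
#' @param high,low character gene sets (disjoint).
#' @param env_sets named list of per-environment responsive gene sets.
#' @param universe background genes.
#' @return data.frame with columns `direction`, `environment`, the 2x2 cell
#'   counts, conditional odds ratio, one- and two-sided p and `p_adjusted`
#'   (BH over environments; the "any" row is not adjusted).
#' @export
env_responsiveness_tests <- function(high, low, env_sets, universe) {
  assert_that(all(high %in% universe) && all(low %in% universe) &&
                all(unlist(env_sets) %in% universe),
              "all gene sets must be subsets of the universe")
  assert_that(length(intersect(high, low)) == 0,
              "high and low sets must be disjoint")
  one_direction <- function(set, excluded, direction) {
    background <- setdiff(universe, union(set, excluded))
    test_one <- function(responsive, env_name) {
      tab <- matrix(c(
        length(intersect(set, responsive)),
        length(setdiff(set, responsive)),
        length(intersect(background, responsive)),
        length(setdiff(background, responsive))
      ), 2, 2, byrow = TRUE)
      cbind(data.frame(direction = direction, environment = env_name,
                       in_set_responsive = tab[1, 1],
                       in_set_other = tab[1, 2],
                       background_responsive = tab[2, 1],
                       background_other = tab[2, 2]),
            fisher_2x2(tab))
    }
    any_set <- unique(unlist(env_sets))
    rows <- rbind(test_one(any_set, "any"),
                  do.call(rbind, Map(test_one, env_sets, names(env_sets))))
    rows$p_adjusted <- NA_real_
    per_env <- rows$environment != "any"
    rows$p_adjusted[per_env] <- bh_adjust(rows$p_two_sided[per_env])
    rows
  }
  out <- rbind(one_direction(high, low, "high"),
               one_direction(low, high, "low"))
  rownames(out) <- NULL
  out
}

#' Poisson GLM of environment counts on gene category
#'
#' Log-link Poisson regression (fitted by IRLS via [stats::glm()]) of the
#' number of environments each gene responds to on its category
#' (`high`, `low`, `background`; background is the reference level). Group
#' medians are reported alongside the Wald table.
#'
#' @param env_count named integer vector (gene -> number of environments).
#' @param category named character/factor vector in
#'   `{"high", "low", "background"}` over the same genes.
#' @return list with `coefficients` (term, estimate, se, z, p) and
#'   `group_medians`.
#' @export
env_count_glm <- function(env_count, category) {
  assert_that(length(env_count) == length(category),
              "env_count and category must align")
  category <- factor(as.character(category),
                     levels = c("background", "high", "low"))
  category <- droplevels(category)
  assert_that(nlevels(category) >= 2,
              "need at least 2 gene categories for the GLM")
  fit <- stats::glm(env_count ~ category, family = stats::poisson())
  if (!fit$converged)
    stop("Poisson IRLS did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      z = cf[, 3], p = cf[, 4], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  med <- tapply(env_count, category, stats::median)
  list(coefficients = coefs,
       group_medians = data.frame(category = names(med),
                                  median = as.numeric(med)))
}

#' Extract terms at a fixed depth of an ontology DAG
#'
#' Helper for level-style term selection from a parent-child edge list:
#' depth is the shortest-path distance from the root(s) (nodes that never
#' appear as a child).
#'
#' @param edges data.frame with columns `parent`, `child`.
#' @param level depth to extract (root = 0).
#' @return character vector of term IDs at exactly `level`.
#' @export
terms_at_level <- function(edges, level = 3) {
  assert_that(all(c("parent", "child") %in% names(edges)),
              "edges needs columns parent, child")
  nodes <- unique(c(edges$parent, edges$child))
  depth <- stats::setNames(rep(Inf, length(nodes)), nodes)
  roots <- setdiff(edges$parent, edges$child)
  depth[roots] <- 0
  frontier <- roots
  d <- 0
  while (length(frontier)) {
    kids <- unique(edges$child[edges$parent %in% frontier])
    kids <- kids[depth[kids] > d + 1]
    depth[kids] <- d + 1
    frontier <- kids
    d <- d + 1
  }
  names(depth)[depth == level]
}
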
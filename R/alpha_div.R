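#' Phylogenetic entropy (Allen's index)
#'
#' Shannon entropy generalised over a phylogeny: with each branch `b` of
#' length `L_b` carrying the summed relative abundance `p_b` of its
#' descendant tips,
#' \deqn{H = \sum_b L_b \,(-p_b \ln p_b), \qquad 0 \ln 0 = 0.}
#' On a star tree with unit branch lengths this reduces exactly to Shannon
#' entropy; it increases when the abundant OTUs are phylogenetically
#' distant. The index is unnormalised (not divided by tree height); set
#' `normalize = TRUE` to divide by the tree height.
#'
#' If the abundance vector sums to less than 1 (mass removed by blank
#' subtraction), it is renormalised over the present tips first — entropy
#' is defined on a probability vector.
#'
#' @param sample named numeric vector of relative abundances (names are
#'   tree tips) or a 1-row relative [otu_table()].
#' @param tree a `phylo` chronogram containing all OTUs with nonzero
#'   abundance as tips.
#' @param normalize divide by tree height (default FALSE).
#' @return non-negative scalar.
#' @export
allen_entropy <- function(sample, tree, normalize = FALSE) {
  if (inherits(sample, "otu_table")) {
    stopifnot(nrow(sample) == 1)
    sample <- stats::setNames(as.numeric(unclass(sample)[1, ]), colnames(sample))
  }
  if (is.null(names(sample))) stop("sample vector must be named by OTU id")
  tot <- sum(sample)
  if (tot <= 0) stop("zero-mass sample")
  p <- sample / tot
  tab <- otu_table(matrix(p, 1, dimnames = list("s", names(p))), "relative")
  ba <- branch_abundance(tab, tree)
  h <- branch_entropy(ba$lengths, ba$p[, 1])
  if (normalize) h / max(node_ages(tree)) else h
}

# H = sum_b L_b * (-p_b log p_b) with 0 log 0 = 0
branch_entropy <- function(lengths, p) {
  nz <- p > 0
  -sum(lengths[nz] * p[nz] * log(p[nz]))
}

#' Allen entropy for every sample of a table
#'
#' Single branch decomposition shared across samples; each sample is
#' renormalised over its present tips (see [allen_entropy()]).
#'
#' @param table a relative-mode [otu_table()].
#' @param tree a `phylo` chronogram.
#' @param normalize divide by tree height.
#' @return named numeric vector, one entropy per sample.
#' @export
entropy_by_sample <- function(table, tree, normalize = FALSE) {
  m <- unclass(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero-mass sample(s)")
  tab <- otu_table(m / tot, "relative")
  ba <- branch_abundance(tab, tree)
  h <- apply(ba$p, 2, branch_entropy, lengths = ba$lengths)
  if (normalize) h / max(node_ages(tree)) else h
}

#' OTU richness per sample
#' @param table an [otu_table()] (either mode), or a numeric vector.
#' @return integer count of OTUs with abundance > 0, per sample.
#' @export
otu_richness <- function(table) {
  if (is.matrix(table)) rowSums(unclass(table) > 0) else sum(table > 0)
}

#' Permutation Kruskal-Wallis test
#'
#' The Kruskal-Wallis H statistic (tie-corrected, on average ranks), with
#' significance assessed by shuffling group labels rather than the
#' chi-squared approximation. p uses the add-one estimator
#' `(1 + #\{H* >= H\}) / (n_perm + 1)` and so is never 0.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length; at least two groups.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer RNG seed.
#' @return list with `statistic` (H), `p_value`, `n_perm`.
#' @export
kruskal_wallis_perm <- function(values, groups, n_perm = 999, seed) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  groups <- droplevels(groups)
  if (length(unique(values)) == 1) {
    message("constant values; Kruskal-Wallis p set to 1")
    return(list(statistic = 0, p_value = 1, n_perm = n_perm))
  }
  h_obs <- kw_statistic(values, groups)
  set.seed(seed)
  h_null <- replicate(n_perm, kw_statistic(values, sample(groups)))
  p <- (1 + sum(h_null >= h_obs - 1e-12)) / (n_perm + 1)
  list(statistic = h_obs, p_value = p, n_perm = n_perm)
}

kw_statistic <- function(values, groups) {
  r <- rank(values)
  n <- length(r)
  rg <- tapply(r, groups, mean)
  ng <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(ng * (rg - (n + 1) / 2)^2)
  ties <- table(values)
  c_tie <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (c_tie <= 0) return(0)
  h / c_tie
}

#' Pooled-entropy bootstrap: host communities vs the plankton pool
#'
#' Fairly compares the phylogenetic entropy hosted by a set of fish skin
#' communities to the whole planktonic community: for each bootstrap
#' replicate, `k` fish samples are drawn at random, their relative
#' abundances averaged into one pooled community, and its Allen entropy
#' computed; the reference is the entropy of all water samples pooled the
#' same way. `k` defaults to the number of water samples so both pools
#' aggregate equally many communities.
#'
#' @param table relative-mode [otu_table()] holding both sample sets.
#' @param fish_ids,water_ids sample ids of the two groups.
#' @param tree microbial chronogram.
#' @param k fish samples pooled per replicate (default: `length(water_ids)`).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer RNG seed.
#' @return list: `boot` (replicate entropies), `water_entropy`,
#'   `exceed_fraction` (share of replicates above the water value),
#'   `mean_ratio` (mean fish entropy / water entropy).
#' @export
pooled_entropy_bootstrap <- function(table, fish_ids, water_ids, tree,
                                     k = length(water_ids), n_boot = 100, seed) {
  if (k > length(fish_ids)) stop("k exceeds the number of fish samples")
  m <- unclass(table)
  m <- m / rowSums(m)
  pool <- function(ids) {
    v <- colMeans(m[ids, , drop = FALSE])
    stats::setNames(v, colnames(m))
  }
  water_h <- allen_entropy(pool(water_ids), tree)
  set.seed(seed)
  boot <- replicate(n_boot, {
    ids <- sample(fish_ids, k, replace = FALSE)
    allen_entropy(pool(ids), tree)
  })
  list(boot = boot, water_entropy = water_h,
       exceed_fraction = mean(boot > water_h),
       mean_ratio = mean(boot) / water_h)
}
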
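#' Abundance-weighted UniFrac dissimilarity matrix
#'
#' For samples A and B with per-branch descendant abundances `p_Ab`,
#' `p_Bb` and branch lengths `L_b`, the normalised weighted UniFrac is
#' \deqn{d(A,B) = \frac{\sum_b L_b |p_{Ab} - p_{Bb}|}
#'                     {\sum_b L_b (p_{Ab} + p_{Bb})},}
#' which is 0 when the two communities place identical mass on every
#' lineage and 1 when all mass sits on branches exclusive to one of them
#' (e.g. disjoint clades under the root). The unnormalised variant (the
#' numerator alone, unbounded by 1) is available with
#' `normalized = FALSE`. Samples are renormalised to sum to 1.
#'
#' @param table relative-mode [otu_table()].
#' @param tree microbial chronogram containing every OTU with nonzero
#'   abundance.
#' @param normalized divide by the branch-abundance total (default TRUE).
#' @return a [dist_matrix()] over the table's samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  m <- unclass(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero-mass sample(s)")
  tab <- otu_table(m / tot, "relative")
  ba <- branch_abundance(tab, tree)
  P <- ba$p
  L <- ba$lengths
  S <- ncol(P)
  s_tot <- colSums(L * P)
  d <- matrix(0, S, S, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(S - 1)) {
    pi_ <- P[, i]
    for (j in (i + 1):S) {
      num <- sum(L * abs(pi_ - P[, j]))
      d[i, j] <- d[j, i] <- if (normalized) num / (s_tot[i] + s_tot[j]) else num
    }
  }
  dist_matrix(d)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(A,B) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)} on relative
#' abundances. Used both at the OTU level and on lineage tables produced
#' by [collapse_at_age()].
#'
#' @param table relative-mode [otu_table()] (rows need not sum to exactly
#'   1 if blank subtraction removed mass; the full formula is used).
#' @return a [dist_matrix()].
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero-mass sample(s)")
  man <- as.matrix(stats::dist(m, method = "manhattan"))
  denom <- outer(tot, tot, `+`)
  d <- man / denom
  diag(d) <- 0
  dist_matrix(d)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers the squared distances (Gower), eigendecomposes, and
#' returns coordinates on the positive-eigenvalue axes scaled by the
#' square roots of the eigenvalues. No Lingoes/Cailliez correction is
#' applied; negative eigenvalues are reported but their axes dropped.
#'
#' @param dm a [dist_matrix()].
#' @param k number of axes to return (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @return list: `points` (n x k' coordinates), `eigenvalues` (all n,
#'   descending), `prop_explained` (positive eigenvalues / their sum).
#' @export
pcoa <- function(dm, k = 2) {
  n <- nrow(dm)
  G <- gower_center(unclass(dm))
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-9
  n_pos <- sum(pos)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; truncating k")
    k <- n_pos
  }
  pts <- matrix(0, n, k, dimnames = list(rownames(dm),
                                         if (k > 0) paste0("PCo", seq_len(k))))
  if (k > 0) {
    pts[] <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  }
  list(points = pts, eigenvalues = e$values,
       prop_explained = if (n_pos > 0) e$values[pos] / sum(e$values[pos])
                        else numeric(0))
}

# Gower-centered inner-product matrix from distances: G = -1/2 J d^2 J
gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Summarise pairwise dissimilarities by sample-pair category
#'
#' Partitions the off-diagonal values into within-plankton,
#' fish-vs-plankton, intraspecific (same host species) and interspecific
#' (different host species) pairs and reports mean, sd, median, and the
#' 5th/95th percentiles of each, plus the ratio of interspecific to
#' intraspecific means.
#'
#' @param dm a [dist_matrix()] over samples.
#' @param meta metadata data frame covering the matrix labels.
#' @return list: `table` (one row per category) and `inter_intra_ratio`.
#' @export
dissimilarity_summary <- function(dm, meta) {
  ids <- rownames(dm)
  meta <- meta[match(ids, meta$sample_id), ]
  type <- meta$sample_type
  sp <- meta$host_species
  n <- length(ids)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  v <- unclass(dm)[pairs]
  cat_ <- rep(NA_character_, length(v))
  cat_[type[i] == "water" & type[j] == "water"] <- "plankton"
  fw <- (type[i] == "fish" & type[j] == "water") |
        (type[i] == "water" & type[j] == "fish")
  cat_[fw] <- "fish_vs_plankton"
  ff <- type[i] == "fish" & type[j] == "fish"
  cat_[ff & sp[i] == sp[j]] <- "intraspecific"
  cat_[ff & sp[i] != sp[j]] <- "interspecific"
  keep <- !is.na(cat_)
  smry <- do.call(rbind, lapply(split(v[keep], cat_[keep]), function(x) {
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
               median = stats::median(x),
               q05 = stats::quantile(x, 0.05, names = FALSE),
               q95 = stats::quantile(x, 0.95, names = FALSE))
  }))
  ratio <- if (all(c("interspecific", "intraspecific") %in% rownames(smry))) {
    smry["interspecific", "mean"] / smry["intraspecific", "mean"]
  } else NA_real_
  list(table = smry, inter_intra_ratio = ratio)
}
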
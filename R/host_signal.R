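#' Moran's I phylogenetic autocorrelation with permutation test
#'
#' Autocorrelation of a species-level trait against phylogenetic proximity
#' weights \eqn{w_{ij} = 1/T_{ij}} (inverse divergence time, see
#' [host_phylogeny()]):
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}}
#'       \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'            {\sum_i (x_i-\bar x)^2}.}
#' Significance is one-tailed (greater: closely related species more
#' similar than chance) by shuffling trait values across the tips.
#'
#' @param trait named numeric vector over host species (tips of the host
#'   tree); must be non-constant.
#' @param host a [host_phylogeny()].
#' @param n_perm permutations (default 999).
#' @param seed integer RNG seed.
#' @param row_normalize divide each row of W by its sum before computing I
#'   (default FALSE: unnormalised weights).
#' @return list with `statistic` (I), `p_value`, `expectation`
#'   (`-1/(n-1)`), `n_perm`.
#' @export
morans_i <- function(trait, host, n_perm = 999, seed, row_normalize = FALSE) {
  W <- host$W
  trait <- trait[rownames(W)]
  if (anyNA(trait)) stop("trait missing for some species")
  n <- length(trait)
  if (n < 4) stop("need at least 4 species")
  if (stats::sd(trait) == 0) stop("constant trait: signal undefined")
  if (row_normalize) W <- W / rowSums(W)
  i_obs <- moran_stat(trait, W)
  set.seed(seed)
  i_null <- replicate(n_perm, moran_stat(sample(trait), W))
  list(statistic = i_obs,
       p_value = perm_pvalue(sum(i_null >= i_obs - 1e-12), n_perm),
       expectation = -1 / (n - 1), n_perm = n_perm)
}

moran_stat <- function(x, W) {
  z <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * as.numeric(z %*% W %*% z) / sum(z^2)
}

#' Pagel's lambda phylogenetic signal with permutation test
#'
#' Maximum-likelihood estimate of the lambda scaling of the Brownian-motion
#' covariance among species: off-diagonal entries of the phylogenetic
#' covariance C (shared branch length from the root) are multiplied by
#' lambda while the diagonal is kept, and the Gaussian likelihood is
#' profiled analytically over the mean (GLS) and rate, leaving a 1-D
#' maximisation over lambda in [0, 1]. lambda = 0 corresponds to no signal
#' (i.i.d. tips), lambda = 1 to full Brownian motion. Significance is the
#' fraction of tip-shuffled datasets whose fitted lambda reaches the
#' observed one (add-one estimator).
#'
#' @param trait named numeric vector over host species.
#' @param host a [host_phylogeny()].
#' @param n_perm permutations (default 500, the heavier test).
#' @param seed integer RNG seed.
#' @return list with `lambda`, `logLik`, `p_value`, `n_perm`.
#' @export
pagel_lambda <- function(trait, host, n_perm = 500, seed) {
  C <- ape::vcv.phylo(host$tree)
  trait <- trait[rownames(C)]
  if (anyNA(trait)) stop("trait missing for some species")
  if (length(trait) < 4) stop("need at least 4 species")
  if (any(diag(C) <= 0)) stop("non-positive diagonal in phylogenetic covariance")
  fit <- fit_lambda(trait, C)
  set.seed(seed)
  lam_null <- replicate(n_perm, fit_lambda(sample(trait), C)$lambda)
  list(lambda = fit$lambda, logLik = fit$logLik,
       p_value = perm_pvalue(sum(lam_null >= fit$lambda - 1e-12), n_perm),
       n_perm = n_perm)
}

# Profile log-likelihood of the lambda model at a trait vector.
lambda_logLik <- function(lambda, x, C) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) {
    # zero-length terminal branches can make Cl singular; perturb
    warning("singular covariance at lambda = ", signif(lambda, 3),
            "; ridge 1e-8 applied")
    ch <- chol(Cl + diag(1e-8, nrow(Cl)))
  }
  n <- length(x)
  one <- rep(1, n)
  ci_x <- backsolve(ch, forwardsolve(t(ch), x))
  ci_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(ci_x) / sum(ci_1)   # = (1' C^-1 x) / (1' C^-1 1)
  r <- x - mu
  ci_r <- backsolve(ch, forwardsolve(t(ch), r))
  q <- sum(r * ci_r)
  sig2 <- q / n
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi * sig2) + logdet + n)
}

fit_lambda <- function(x, C) {
  opt <- stats::optimize(lambda_logLik, c(0, 1), x = x, C = C, maximum = TRUE,
                         tol = 1e-6)
  # optimize never samples the exact endpoints; check them explicitly
  ends <- vapply(c(0, 1), lambda_logLik, numeric(1), x = x, C = C)
  cand_l <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ends)
  best <- which.max(cand_ll)
  list(lambda = cand_l[best], logLik = cand_ll[best])
}

#' Mantel test (Pearson) between two distance matrices
#'
#' Pearson correlation of the upper off-diagonal triangles, with a
#' one-tailed (greater) permutation test that simultaneously permutes the
#' rows and columns of the second matrix.
#'
#' @param dm1,dm2 [dist_matrix()] objects with matching label sets (dm2 is
#'   realigned to dm1's labels).
#' @param n_perm permutations (default 999).
#' @param seed integer RNG seed.
#' @return list with `statistic` (r), `p_value`, `n_perm`.
#' @export
mantel <- function(dm1, dm2, n_perm = 999, seed) {
  dm2 <- align_dm(dm2, rownames(dm1))
  n <- nrow(dm1)
  if (n < 4) stop("need at least 4 labels")
  ut <- upper.tri(dm1)
  x <- unclass(dm1)[ut]
  m2 <- unclass(dm2)
  y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a distance triangle; Mantel r undefined")
  }
  r_obs <- stats::cor(x, y)
  set.seed(seed)
  r_null <- replicate(n_perm, {
    perm <- sample.int(n)
    stats::cor(x, m2[perm, perm][ut])
  })
  list(statistic = r_obs,
       p_value = perm_pvalue(sum(r_null >= r_obs - 1e-12), n_perm),
       n_perm = n_perm)
}

#' PERMANOVA with sequential (Type I) sums of squares
#'
#' Partitions a distance matrix among model terms: the Gower-centered
#' inner-product matrix \eqn{G = -\frac12 J d^2 J} is decomposed against
#' the hat matrices of the cumulative (sequential) linear models, giving
#' per-term sums of squares, pseudo-F
#' \eqn{(SS_t/df_t)/(SS_{res}/df_{res})}, and \eqn{R^2 = SS_t/SS_{tot}}.
#' Significance is by permutation of the raw sample labels (rows/columns
#' of G), recomputing every term's pseudo-F. Term order matters
#' (sequential SS); see [order_terms_by_contribution()].
#'
#' @param dm a [dist_matrix()] over samples.
#' @param data data frame of covariates, one row per sample, with either a
#'   `sample_id` column or rownames matching the matrix labels.
#' @param terms character vector of column names, in model order.
#' @param n_perm permutations (default 999).
#' @param seed integer RNG seed.
#' @param interactions also fit the pairwise interactions of the listed
#'   terms (after the main effects), as in the reef-by-species model.
#' @return a `permanova` data frame: one row per term plus Residual and
#'   Total, columns `df`, `SS`, `F`, `R2`, `p_value`.
#' @export
permanova <- function(dm, data, terms, n_perm = 999, seed,
                      interactions = FALSE) {
  ids <- rownames(dm)
  if ("sample_id" %in% names(data)) {
    data <- data[match(ids, data$sample_id), , drop = FALSE]
  } else {
    data <- data[ids, , drop = FALSE]
  }
  if (anyNA(data[terms])) stop("missing covariate values for some samples")
  for (tm in terms) {
    if (is.character(data[[tm]]) || is.logical(data[[tm]])) {
      data[[tm]] <- factor(data[[tm]])
    }
    if (is.factor(data[[tm]]) && nlevels(droplevels(data[[tm]])) < 2) {
      stop("term '", tm, "' has fewer than 2 levels")
    }
  }
  term_labels <- terms
  if (interactions && length(terms) > 1) {
    term_labels <- c(terms, utils::combn(terms, 2, paste, collapse = ":"))
  }
  n <- nrow(dm)
  G <- gower_center(unclass(dm))
  ss_total <- sum(diag(G))
  # cumulative hat matrices; identical designs under label permutation of G
  hats <- vector("list", length(term_labels))
  ranks <- integer(length(term_labels))
  for (k in seq_along(term_labels)) {
    fml <- stats::as.formula(paste("~", paste(term_labels[seq_len(k)], collapse = " + ")))
    X <- stats::model.matrix(fml, data)
    qx <- qr(X)
    ranks[k] <- qx$rank
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
  }
  df_terms <- diff(c(1, ranks))
  if (any(df_terms == 0)) {
    stop("aliased term(s): ", paste(term_labels[df_terms == 0], collapse = ", "))
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) {
    stop("zero residual degrees of freedom; model saturated by: ",
         paste(term_labels, collapse = ", "))
  }
  stat_fs <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    (ss / df_terms) / (ss_res / df_res)
  }
  tr_obs <- vapply(hats, function(H) sum(H * G), numeric(1))
  ss <- diff(c(0, tr_obs))
  ss_res <- ss_total - tr_obs[length(tr_obs)]
  f_obs <- (ss / df_terms) / (ss_res / df_res)
  set.seed(seed)
  count_ge <- numeric(length(term_labels))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    f_p <- stat_fs(G[perm, perm])
    count_ge <- count_ge + (f_p >= f_obs - 1e-12)
  }
  p <- perm_pvalue(count_ge, n_perm)
  out <- data.frame(
    term = c(term_labels, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(ss, ss_res, ss_total),
    F = c(f_obs, NA, NA),
    R2 = c(ss / ss_total, ss_res / ss_total, 1),
    p_value = c(p, NA, NA))
  class(out) <- c("permanova", "data.frame")
  out
}

#' Order model terms by independent contribution
#'
#' Fits each candidate term alone against the distance matrix and returns
#' the terms sorted by decreasing single-term R^2 (the ordering rule for
#' sequential trait models). Ties (within 1e-12) are broken
#' alphabetically, with a warning.
#'
#' @inheritParams permanova
#' @return character vector of terms, descending R^2, with the R^2 values
#'   as a `r2` attribute.
#' @export
order_terms_by_contribution <- function(dm, data, terms) {
  if (length(terms) == 1) return(terms)
  r2 <- vapply(terms, function(tm) {
    fit <- permanova(dm, data, tm, n_perm = 0, seed = 1)
    fit$R2[fit$term == tm]
  }, numeric(1))
  if (anyDuplicated(round(r2, 12))) {
    warning("tied single-term R2; alphabetical tie-break")
  }
  ord <- order(-r2, terms)
  structure(terms[ord], r2 = r2[ord])
}

#' Average relative abundances within host species (Method B table)
#'
#' Each individual's row is renormalised to sum to 1, then individuals of
#' the same species are averaged arithmetically, so every species row again
#' sums to 1.
#'
#' @param table relative-mode [otu_table()].
#' @param meta metadata data frame.
#' @param species species to include (default: all fish species present).
#' @return relative-mode [otu_table()] with one row per species.
#' @export
average_by_species <- function(table, meta, species = NULL) {
  fish <- meta[meta$sample_type == "fish" & meta$sample_id %in% rownames(table), ]
  if (is.null(species)) species <- sort(unique(fish$host_species))
  m <- unclass(table)
  m <- m / rowSums(m)
  out <- t(vapply(species, function(sp) {
    ids <- fish$sample_id[fish$host_species == sp]
    if (!length(ids)) stop("no individuals for species ", sp)
    colMeans(m[ids, , drop = FALSE])
  }, numeric(ncol(m))))
  dimnames(out) <- list(species, colnames(m))
  otu_table(out, "relative")
}

#' Draw one individual per species (one Method A subsample)
#'
#' Uses the ambient RNG stream (callers seed it once), so repeated calls
#' inside [method_ab()] walk a reproducible sequence.
#'
#' @inheritParams average_by_species
#' @return relative-mode [otu_table()], one row per species, rows
#'   renormalised; rownames are species.
#' @export
subsample_one_per_species <- function(table, meta, species = NULL) {
  fish <- meta[meta$sample_type == "fish" & meta$sample_id %in% rownames(table), ]
  if (is.null(species)) species <- sort(unique(fish$host_species))
  ids <- vapply(species, function(sp) {
    cand <- fish$sample_id[fish$host_species == sp]
    if (!length(cand)) stop("no individuals for species ", sp)
    if (length(cand) == 1) cand else sample(cand, 1)
  }, character(1))
  m <- unclass(table)[ids, , drop = FALSE]
  m <- m / rowSums(m)
  rownames(m) <- species
  otu_table(m, "relative")
}

#' Method A / Method B engine for species-level statistics
#'
#' Runs a species-level statistic under both intraspecific-variability
#' strategies. Method A evaluates the statistic on `n_subsamples` random
#' draws of one individual per species and reports the distribution of the
#' statistic and the percentage of subsamples significant at 0.05. Method
#' B averages relative abundances within species and evaluates once.
#'
#' @param statistic function `(species_table, seed) -> list(statistic,
#'   p_value)`; `species_table` is a relative [otu_table()] with one row
#'   per species and `seed` drives any internal permutations.
#' @param table relative-mode [otu_table()] of fish samples (other samples
#'   are ignored via the metadata).
#' @param meta metadata data frame.
#' @param species species universe (default: all fish species in `meta`;
#'   pre-filter with [species_filter()]).
#' @param n_subsamples Method A subsamples (default 999).
#' @param seed integer master seed; per-subsample seeds are derived.
#' @param methods which strategies to run (default both).
#' @return object of class `method_ab_result`: list with `A` (statistics,
#'   p_values, pct_significant, mean, sd, n_failed), `B` (statistic,
#'   p_value), `n_subsamples`, `seed`.
#' @export
method_ab <- function(statistic, table, meta, species = NULL,
                      n_subsamples = 999, seed, methods = c("A", "B")) {
  fish_meta <- meta[meta$sample_type == "fish", ]
  if (is.null(species)) species <- sort(unique(fish_meta$host_species))
  res <- list(n_subsamples = n_subsamples, seed = seed)
  if ("A" %in% methods) {
    stats_a <- rep(NA_real_, n_subsamples)
    p_a <- rep(NA_real_, n_subsamples)
    n_failed <- 0
    set.seed(derive_seed(seed, "methodA-draws"))
    draw_seeds <- sample.int(2147483646, n_subsamples)
    for (b in seq_len(n_subsamples)) {
      tab_b <- subsample_one_per_species(table, meta, species)
      out <- tryCatch(statistic(tab_b, draw_seeds[b]), error = function(e) NULL)
      if (is.null(out)) { n_failed <- n_failed + 1; next }
      stats_a[b] <- out$statistic
      p_a[b] <- out$p_value
    }
    if (n_failed > 0) message(n_failed, " Method A subsample(s) failed and were excluded")
    ok <- !is.na(stats_a)
    res$A <- list(statistics = stats_a, p_values = p_a,
                  pct_significant = 100 * mean(p_a[ok] < 0.05),
                  mean = mean(stats_a[ok]), sd = stats::sd(stats_a[ok]),
                  n_failed = n_failed)
  }
  if ("B" %in% methods) {
    tab_b <- average_by_species(table, meta, species)
    out <- statistic(tab_b, derive_seed(seed, "methodB"))
    res$B <- list(statistic = out$statistic, p_value = out$p_value)
  }
  class(res) <- "method_ab_result"
  res
}

#' @export
print.method_ab_result <- function(x, ...) {
  if (!is.null(x$A)) {
    cat(sprintf("Method A (%d subsamples): statistic %.4f +/- %.4f, %.1f%% significant\n",
                x$n_subsamples, x$A$mean, x$A$sd, x$A$pct_significant))
  }
  if (!is.null(x$B)) {
    cat(sprintf("Method B: statistic %.4f, p = %.4g\n", x$B$statistic, x$B$p_value))
  }
  invisible(x)
}
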
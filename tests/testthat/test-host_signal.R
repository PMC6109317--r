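host4 <- function() {
  host_phylogeny(ape::read.tree(text = "((A:10,B:10):90,(C:10,D:10):90);"))
}

test_that("Moran's I: sister-pair structure maximises I over trait relabellings", {
  hp <- host4()
  trait <- c(A = 1, B = 1, C = -1, D = -1)
  i_obs <- morans_i(trait, hp, n_perm = 99, seed = 1)$statistic
  perms <- all_permutations(4)
  i_all <- apply(perms, 1, function(ix) {
    phylosym:::moran_stat(unname(trait)[ix], hp$W)
  })
  expect_gt(i_obs, 0)
  expect_equal(i_obs, max(i_all), tolerance = 1e-12)
  # p from the permutation engine approximates the exhaustive tail
  p_exact <- mean(i_all >= i_obs - 1e-12)  # 8/24: sign flips and pair swaps
  res <- morans_i(trait, hp, n_perm = 1999, seed = 2)
  expect_lt(abs(res$p_value - p_exact), 0.03)
})

test_that("Moran's I closed form under equal divergences", {
  # equal pairwise divergence: star host tree; any zero-mean alternating
  # trait gives the exchangeable expectation -1/(n-1)
  hp <- host_phylogeny(star_tree(4, length = 50))
  trait <- c(t1 = 1, t2 = -1, t3 = 1, t4 = -1)
  expect_equal(morans_i(trait, hp, n_perm = 9, seed = 1)$statistic, -1 / 3,
               tolerance = 1e-12)
  expect_error(morans_i(c(t1 = 1, t2 = 1, t3 = 1, t4 = 1), hp, seed = 1),
               "constant")
})

test_that("Moran's I agrees with ape's implementation", {
  tr <- random_chronogram(16, age = 100, seed = 31)
  hp <- host_phylogeny(tr)
  set.seed(32)
  x <- stats::setNames(rnorm(16), tr$tip.label)
  # ape::Moran.I row-normalises the weight matrix; compare on that variant
  ours <- morans_i(x, hp, n_perm = 9, seed = 1, row_normalize = TRUE)$statistic
  theirs <- ape::Moran.I(x, hp$W)$observed
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("Pagel's lambda: analytic identity at lambda = 0 and recovery", {
  tr <- random_chronogram(24, age = 100, seed = 41)
  C <- ape::vcv.phylo(tr)
  set.seed(42)
  x <- rnorm(24)
  # lambda = 0: diagonal covariance sigma2 * diag(C); with an ultrametric
  # tree this is iid normal around the GLS (= arithmetic) mean
  ll0 <- phylosym:::lambda_logLik(0, x, C)
  mu <- mean(x); s2 <- mean((x - mu)^2) / C[1, 1]
  ll_iid <- sum(dnorm(x, mu, sqrt(s2 * C[1, 1]), log = TRUE))
  expect_equal(ll0, ll_iid, tolerance = 1e-9)
  # Brownian traits fit near 1, iid traits near 0 (deeper sweep in acceptance)
  L <- t(chol(C))
  lam_bm <- replicate(10, phylosym:::fit_lambda(as.numeric(L %*% rnorm(24)), C)$lambda)
  lam_iid <- replicate(10, phylosym:::fit_lambda(rnorm(24), C)$lambda)
  expect_gt(mean(lam_bm), 0.7)
  expect_lt(stats::median(lam_iid), 0.2)
})

test_that("Pagel's lambda permutation test is seeded and directional", {
  tr <- random_chronogram(16, age = 100, seed = 51)
  hp <- host_phylogeny(tr)
  C <- ape::vcv.phylo(tr)
  set.seed(52)
  x <- stats::setNames(as.numeric(t(chol(C)) %*% rnorm(16)), tr$tip.label)
  r1 <- pagel_lambda(x, hp, n_perm = 49, seed = 7)
  r2 <- pagel_lambda(x, hp, n_perm = 49, seed = 7)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.2)   # planted Brownian signal
  expect_gte(r1$lambda, 0.5)
})

test_that("Mantel statistic and p match vegan and exhaustive enumeration", {
  set.seed(61)
  n <- 5
  labs <- letters[1:n]
  mk <- function() {
    m <- matrix(runif(n * n), n); m <- m + t(m); diag(m) <- 0
    dimnames(m) <- list(labs, labs); dist_matrix(m)
  }
  d1 <- mk(); d2 <- mk()
  res <- mantel(d1, d2, n_perm = 999, seed = 3)
  expect_equal(res$statistic,
               unname(vegan::mantel(unclass(d1), unclass(d2),
                                    permutations = 5)$statistic),
               tolerance = 1e-10)
  p_exact <- oracle_mantel_exhaustive(d1, d2)
  expect_lt(abs(res$p_value - p_exact), 0.02)
  # perfect monotone linear relation
  d3 <- dist_matrix(0.1 + 2 * unclass(d1) - diag(0.1, n))
  res3 <- mantel(d1, d3, n_perm = 999, seed = 4)
  expect_equal(res3$statistic, 1)
  expect_equal(mantel(d1, d1, n_perm = 99, seed = 1)$statistic, 1)
  expect_lt(res3$p_value, 0.05)
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on Euclidean data", {
  set.seed(71)
  g <- factor(rep(c("a", "b", "c"), times = c(6, 5, 7)))
  y <- rnorm(18) + as.numeric(g)
  labs <- paste0("s", 1:18)
  dm <- dist_matrix(`dimnames<-`(as.matrix(dist(y)), list(labs, labs)))
  dat <- data.frame(sample_id = labs, g = g)
  fit <- permanova(dm, dat, "g", n_perm = 99, seed = 1)
  f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(fit$F[1], f_classic, tolerance = 1e-9)
  expect_equal(sum(fit$R2[1:2]), 1, tolerance = 1e-9)
})

test_that("PERMANOVA matches vegan::adonis2 sequentially and handles edge cases", {
  set.seed(81)
  n <- 24
  labs <- paste0("s", 1:n)
  m <- matrix(rgamma(n * 30, 0.5), n, 30, dimnames = list(labs, paste0("o", 1:30)))
  tab <- otu_table(m / rowSums(m), "relative")
  dm <- bray_curtis(tab)
  dat <- data.frame(sample_id = labs,
                    f1 = factor(rep(c("x", "y"), each = n / 2)),
                    f2 = factor(rep(c("u", "v", "w"), times = n / 3)))
  fit <- permanova(dm, dat, c("f1", "f2"), n_perm = 99, seed = 2,
                   interactions = TRUE)
  ref <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ f1 + f2 + f1:f2,
                        data = dat, permutations = 5, by = "terms")
  expect_equal(fit$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(fit$F[1:3], ref$F[1:3], tolerance = 1e-9)
  expect_equal(fit$R2[1:3], ref$R2[1:3], tolerance = 1e-9)
  # zero within-group distances -> R2 = 1
  mz <- rbind(a1 = c(1, 0), a2 = c(1, 0), b1 = c(0, 1), b2 = c(0, 1))
  colnames(mz) <- c("o1", "o2")
  dz <- bray_curtis(otu_table(mz, "relative"))
  datz <- data.frame(sample_id = rownames(mz), g = c("a", "a", "b", "b"))
  fitz <- permanova(dz, datz, "g", n_perm = 99, seed = 1)
  expect_equal(fitz$R2[1], 1, tolerance = 1e-9)
  # aliased duplicate of the factor -> informative error
  datz$g2 <- datz$g
  expect_error(permanova(dz, datz, c("g", "g2"), n_perm = 9, seed = 1),
               "aliased")
})

test_that("term ordering ranks an informative factor above noise", {
  set.seed(91)
  n <- 20
  labs <- paste0("s", 1:n)
  g <- rep(c("a", "b"), each = n / 2)
  y <- rnorm(n) + 3 * (g == "b")
  dm <- dist_matrix(`dimnames<-`(as.matrix(dist(y)), list(labs, labs)))
  dat <- data.frame(sample_id = labs, signal = g,
                    noise = sample(c("u", "v"), n, replace = TRUE))
  ord <- order_terms_by_contribution(dm, dat, c("noise", "signal"))
  expect_equal(ord[1], "signal")
  dat$dup <- dat$signal
  expect_warning(ord2 <- order_terms_by_contribution(dm, dat, c("signal", "dup")),
                 "tie")
  expect_equal(as.vector(ord2), c("dup", "signal"))  # alphabetical among ties
  expect_equal(order_terms_by_contribution(dm, dat, "signal"), "signal")
})

test_that("method A/B engine degenerates correctly and is reproducible", {
  # all species singletons: every subsample equals the species average
  tr <- random_chronogram(6, age = 50, seed = 101)
  set.seed(102)
  m <- matrix(rgamma(4 * 6, 1), 4, 6,
              dimnames = list(paste0("f", 1:4), tr$tip.label))
  tab <- otu_table(m / rowSums(m), "relative")
  meta <- toy_meta(c(f1 = "sp1", f2 = "sp2", f3 = "sp3", f4 = "sp4"))
  hp <- host_phylogeny(random_chronogram(4, age = 100, seed = 103))
  hp$tree$tip.label <- paste0("sp", 1:4)
  dimnames(hp$T) <- dimnames(hp$W) <- list(paste0("sp", 1:4), paste0("sp", 1:4))
  host_dm <- dist_matrix(hp$T)
  stat <- function(sp_tab, s) {
    mantel(bray_curtis(sp_tab), align_dm(host_dm, rownames(sp_tab)),
           n_perm = 99, seed = s)
  }
  res <- method_ab(stat, tab, meta, n_subsamples = 5, seed = 11)
  expect_equal(res$A$sd, 0)
  expect_equal(res$A$mean, res$B$statistic)
  expect_true(res$A$pct_significant %in% c(0, 100))
  res2 <- method_ab(stat, tab, meta, n_subsamples = 5, seed = 11)
  expect_identical(res, res2)
})

test_that("species averaging renormalises and subsampling picks one per species", {
  m <- rbind(f1 = c(2, 2), f2 = c(0, 4), f3 = c(1, 0))
  colnames(m) <- c("o1", "o2")
  tab <- to_relative(otu_table(m, "counts"))
  meta <- toy_meta(c(f1 = "spA", f2 = "spA", f3 = "spB"))
  avg <- average_by_species(tab, meta)
  expect_equal(unname(unclass(avg)["spA", ]), c(0.25, 0.75))
  expect_equal(unname(rowSums(avg)), c(1, 1))
  set.seed(1)
  sub <- subsample_one_per_species(tab, meta)
  expect_equal(rownames(sub), c("spA", "spB"))
  expect_equal(unname(rowSums(sub)), c(1, 1))
})
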
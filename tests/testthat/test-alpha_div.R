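test_that("Allen entropy reduces to Shannon on unit-branch star trees", {
  for (k in c(2, 3, 5, 17, 64)) {
    tr <- star_tree(k)
    expect_equal(allen_entropy(tip_vec(tr, rep(1 / k, k)), tr), log(k))
    set.seed(k)
    p <- rgamma(k, 1); p <- p / sum(p)
    expect_equal(allen_entropy(tip_vec(tr, p), tr), -sum(p * log(p)))
  }
  tr <- star_tree(4)
  expect_equal(allen_entropy(tip_vec(tr, c(1, 0, 0, 0)), tr), 0)
})

test_that("Allen entropy matches the hand-computed branch sum", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  p <- c(A = 0.25, B = 0.25, C = 0.5)
  expected <- 1 * (-0.25 * log(0.25)) + 1 * (-0.25 * log(0.25)) +
    1 * (-0.5 * log(0.5)) + 2 * (-0.5 * log(0.5))
  expect_equal(allen_entropy(p, tr), expected)
  expect_error(allen_entropy(c(A = 0.5, Z = 0.5), tr), "missing from tree")
})

test_that("Allen entropy agrees with brute-force branch enumeration", {
  for (i in 1:50) {
    tr <- random_chronogram(8, age = 50, seed = 1000 + i)
    set.seed(i)
    p <- rgamma(8, 0.5); p <- tip_vec(tr, p / sum(p))
    expect_equal(allen_entropy(p, tr), oracle_allen(tr, p), tolerance = 1e-12)
  }
})

test_that("entropy invariances: pruning, branch scaling, sibling merging", {
  tr <- random_chronogram(12, age = 80, seed = 3)
  set.seed(4)
  p <- rgamma(12, 1); p[c(2, 5)] <- 0; p <- tip_vec(tr, p / sum(p))
  h <- allen_entropy(p, tr)
  # pruning zero-abundance tips changes nothing
  pruned <- ape::keep.tip(tr, names(p)[p > 0])
  expect_equal(allen_entropy(p[p > 0], pruned), h, tolerance = 1e-12)
  # linear in branch lengths
  tr3 <- tr; tr3$edge.length <- tr$edge.length * 3
  expect_equal(allen_entropy(p, tr3), 3 * h, tolerance = 1e-12)
  # collapsing a cherry into one tip with summed abundance never increases H
  for (i in 1:20) {
    tri <- random_chronogram(8, age = 10, seed = 200 + i)
    set.seed(300 + i)
    q <- rgamma(8, 1); q <- tip_vec(tri, q / sum(q))
    # find a cherry: two tips sharing a parent
    par_of_tip <- tri$edge[match(1:8, tri$edge[, 2]), 1]
    cherry_parent <- par_of_tip[duplicated(par_of_tip)][1]
    pair <- which(par_of_tip == cherry_parent)
    merged <- ape::drop.tip(tri, tri$tip.label[pair[2]])
    qm <- q[-pair[2]]
    qm[tri$tip.label[pair[1]]] <- q[pair[1]] + q[pair[2]]
    expect_lte(allen_entropy(qm, merged), allen_entropy(q, tri) + 1e-12)
  }
})

test_that("richness counts positive entries", {
  expect_equal(otu_richness(c(1, 0, 0.2)), 2)
  expect_equal(otu_richness(c(0, 0, 0)), 0)
  tab <- make_table(matrix(c(1, 0, 2, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(unname(otu_richness(tab)), c(2, 1))
})

test_that("permutation Kruskal-Wallis matches exhaustive enumeration", {
  values <- c(1, 2, 3, 10, 11, 12)
  groups <- rep(c("a", "b"), each = 3)
  p_exact <- oracle_kw_exhaustive(values, groups)
  res <- kruskal_wallis_perm(values, groups, n_perm = 1999, seed = 5)
  expect_lt(abs(res$p_value - p_exact), 0.02)
  # complete separation of 3v3 ranks: 2 of 20 assignments reach |H|, p = 0.1
  expect_equal(p_exact, 0.1)

  same <- kruskal_wallis_perm(rep(c(5, 5, 5), 2), rep(c("a", "b"), 3),
                              n_perm = 99, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis_perm(1:5, rep("a", 5), seed = 1), "two groups")
})

test_that("pooled-entropy bootstrap is symmetric under exchangeable groups", {
  tr <- random_chronogram(40, age = 100, seed = 9)
  set.seed(10)
  m <- matrix(rgamma(30 * 40, 0.4), 30, 40,
              dimnames = list(paste0("s", 1:30), tr$tip.label))
  tab <- otu_table(m / rowSums(m), "relative")
  fish <- paste0("s", 1:20); water <- paste0("s", 21:30)
  res <- pooled_entropy_bootstrap(tab, fish, water, tr, k = 10, n_boot = 200,
                                  seed = 2)
  # same generating process: exceedance near 1/2, ratio near 1
  expect_gt(res$exceed_fraction, 0.15)
  expect_lt(res$exceed_fraction, 0.85)
  expect_equal(res$mean_ratio, 1, tolerance = 0.1)
  # seeding contract
  res2 <- pooled_entropy_bootstrap(tab, fish, water, tr, k = 10, n_boot = 1,
                                   seed = 3)
  res3 <- pooled_entropy_bootstrap(tab, fish, water, tr, k = 10, n_boot = 1,
                                   seed = 3)
  expect_identical(res2$boot, res3$boot)
  expect_error(pooled_entropy_bootstrap(tab, fish, water, tr, k = 25, seed = 1),
               "exceeds")
})

test_that("planted lineage-diversity contrast is detected by the bootstrap", {
  # skin pool spans three deep clades, plankton confined to one: pooled skin
  # entropy must exceed plankton in every replicate
  tr <- random_chronogram(30, age = 100, seed = 21)
  deep <- cutree(stats::hclust(stats::as.dist(ape::cophenetic.phylo(tr))), k = 3)
  set.seed(22)
  skin <- t(vapply(1:40, function(i) {
    v <- rgamma(30, 0.5) * 1; v / sum(v)
  }, numeric(30)))
  plank <- t(vapply(1:10, function(i) {
    v <- rgamma(30, 0.5) * (deep == 1); v / sum(v)
  }, numeric(30)))
  m <- rbind(skin, plank)
  dimnames(m) <- list(c(paste0("f", 1:40), paste0("w", 1:10)), tr$tip.label)
  tab <- otu_table(m, "relative")
  res <- pooled_entropy_bootstrap(tab, paste0("f", 1:40), paste0("w", 1:10),
                                  tr, k = 10, n_boot = 50, seed = 5)
  expect_equal(res$exceed_fraction, 1)
  expect_gt(res$mean_ratio, 1.5)
})
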
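core_fixture <- function() {
  m <- rbind(
    a1 = c(1, 1, 0, 2, 0), a2 = c(2, 1, 0, 0, 0), a3 = c(5, 3, 1, 0, 0),
    b1 = c(0, 2, 2, 0, 0), b2 = c(0, 1, 1, 0, 3), b3 = c(0, 4, 1, 0, 0),
    c1 = c(1, 0, 0, 0, 9),
    w1 = c(4, 0, 1, 0, 0), w2 = c(2, 0, 0, 0, 0))
  colnames(m) <- paste0("o", 1:5)
  meta <- toy_meta(c(a1 = "spA", a2 = "spA", a3 = "spA",
                     b1 = "spB", b2 = "spB", b3 = "spB", c1 = "spC"),
                   water_ids = c("w1", "w2"))
  list(tab = otu_table(m, "counts"), meta = meta)
}

test_that("core sets are exactly the intersection of individual presences", {
  fx <- core_fixture()
  cs <- core_otus(fx$tab, fx$meta, min_individuals = 3)
  expect_equal(cs$species, c("spA", "spB"))
  expect_equal(cs$per_species$spA, c("o1", "o2"))
  expect_equal(cs$per_species$spB, c("o2", "o3"))
  expect_equal(cs$union, c("o1", "o2", "o3"))
  # brute-force oracle over every cell
  m <- unclass(fx$tab)
  for (sp in cs$species) {
    ids <- fx$meta$sample_id[!is.na(fx$meta$host_species) &
                             fx$meta$host_species == sp]
    manual <- colnames(m)[apply(m[ids, ] > 0, 2, all)]
    expect_equal(cs$per_species[[sp]], manual)
  }
  # species with two individuals sharing nothing -> empty core
  m2 <- rbind(x1 = c(1, 0), x2 = c(0, 1))
  colnames(m2) <- c("o1", "o2")
  cs2 <- core_otus(otu_table(m2, "counts"),
                   toy_meta(c(x1 = "spX", x2 = "spX")), min_individuals = 2)
  expect_equal(length(cs2$per_species$spX), 0)
  # one-indivdual species: core = its presence set
  m3 <- rbind(y1 = c(3, 0, 1)); colnames(m3) <- paste0("o", 1:3)
  cs3 <- core_otus(otu_table(m3, "counts"), toy_meta(c(y1 = "spY")),
                   min_individuals = 1)
  expect_equal(cs3$per_species$spY, c("o1", "o3"))
})

test_that("adding an individual never enlarges a core set", {
  set.seed(401)
  for (rep in 1:10) {
    k <- 6
    m <- matrix(rbinom(k * 12, 1, 0.5) * rpois(k * 12, 3), k, 12,
                dimnames = list(paste0("f", 1:k), paste0("o", 1:12)))
    meta_all <- toy_meta(stats::setNames(rep("sp", k), rownames(m)))
    for (n_ind in 2:k) {
      sub_prev <- otu_table(m[seq_len(n_ind - 1), , drop = FALSE], "counts")
      sub_now <- otu_table(m[seq_len(n_ind), , drop = FALSE], "counts")
      meta_prev <- meta_all[seq_len(n_ind - 1), ]
      meta_now <- meta_all[seq_len(n_ind), ]
      core_prev <- core_otus(sub_prev, meta_prev, min_individuals = 1)$per_species$sp
      core_now <- core_otus(sub_now, meta_now, min_individuals = 1)$per_species$sp
      expect_true(all(core_now %in% core_prev))
    }
  }
})

test_that("core summary: plankton overlap, cumulated abundance, correlations", {
  fx <- core_fixture()
  cs <- core_otus(fx$tab, fx$meta, min_individuals = 3)
  s <- core_summary(cs, fx$tab, fx$meta)
  # union {o1,o2,o3}; water samples contain o1 and o3 -> fraction 2/3
  expect_equal(s$frac_in_plankton, 2 / 3)
  # w1 rel = (0.8, 0, 0.2), w2 = (1, 0, 0); mean(o1) = 0.9, mean(o3) = 0.1
  expect_equal(s$plankton_cumulated_abundance, 1.0)
  expect_equal(unname(s$core_counts), c(2L, 2L))
  # two species with equal core count: zero variance -> NA with reason
  expect_true(is.na(s$cor_individuals$r))
  # planted negative correlation core count ~ individuals
  set.seed(402)
  blocks <- list(); sp_map <- character(0)
  for (i in 1:8) {
    n_ind <- i %/% 2 + 1
    # shared OTUs shrink as individuals grow: first 20 - 2*n_ind OTUs shared
    shared <- max(1, 20 - 2 * n_ind)
    blk <- t(vapply(seq_len(n_ind), function(j) {
      c(rep(1, shared), rbinom(30 - shared, 1, 0.3))
    }, numeric(30)))
    rownames(blk) <- paste0("g", i, "_", seq_len(n_ind))
    blocks[[i]] <- blk
    sp_map <- c(sp_map, rep(paste0("g", i), n_ind))
  }
  m <- do.call(rbind, blocks); colnames(m) <- paste0("o", 1:30)
  meta <- toy_meta(stats::setNames(sp_map, rownames(m)))
  cs2 <- core_otus(otu_table(m, "counts"), meta, min_individuals = 1)
  s2 <- core_summary(cs2, otu_table(m, "counts"), meta)
  expect_lt(s2$cor_individuals$r, 0)
})

test_that("per-OTU phylogenetic signal: skips, Bonferroni cap, planted Brownian", {
  expect_equal(min(1, 0.01 * 307), 1)  # the capping rule itself
  n_sp <- 16
  hostt <- random_chronogram(n_sp, age = 100, seed = 411)
  hostt$tip.label <- sprintf("sp%02d", 1:n_sp)
  hp <- host_phylogeny(hostt)
  C <- ape::vcv.phylo(hostt)
  set.seed(412)
  # o1: host-tracked (Brownian) share; o2: constant across species (skip);
  # o3: the complement keeping rows on the simplex
  bm <- as.numeric(t(chol(C)) %*% rnorm(n_sp))
  w <- stats::pnorm(bm / stats::sd(bm))
  m <- cbind(o1 = 0.8 * w, o2 = rep(0.2, n_sp), o3 = 0.8 * (1 - w))
  rownames(m) <- hostt$tip.label
  # one individual per species named after it
  meta <- toy_meta(stats::setNames(hostt$tip.label, hostt$tip.label))
  tab <- otu_table(m, "relative")
  core <- list(per_species = list(), union = c("o1", "o2", "o3"),
               species = hostt$tip.label)
  sig <- core_phylosignal(core, tab, meta, hp, n_perm_moran = 199,
                          n_perm_lambda = 99, seed = 5)
  expect_match(sig$status[sig$otu_id == "o2"], "skipped")
  expect_equal(sum(sig$status == "ok"), 2)
  # Bonferroni multiplies by the number of tested OTUs (2 here)
  ok <- sig[sig$status == "ok", ]
  expect_equal(ok$moran_p_adj, pmin(1, ok$moran_p * 2))
  expect_equal(ok$lambda_p_adj, pmin(1, ok$lambda_p * 2))
  expect_gte(ok$lambda[ok$otu_id == "o1"], 0.5)
})
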
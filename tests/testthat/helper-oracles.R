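# Independent brute-force oracles and tiny fixture builders.
# The oracles enumerate branches via phangorn::Descendants / ape edge walks,
# deliberately sharing no code with the package's postorder accumulation.

# star tree: k tips joined at the root by unit-length branches
star_tree <- function(k, length = 1) {
  tips <- paste0("t", seq_len(k))
  txt <- paste0("(", paste0(tips, ":", length, collapse = ","), ");")
  ape::read.tree(text = txt)
}

make_table <- function(m, mode = "counts") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("o", seq_len(ncol(m)))
  otu_table(m, mode)
}

# named relative-abundance vector aligned to a tree's tips
tip_vec <- function(tree, p) stats::setNames(p, tree$tip.label)

# per-branch descendant abundance by explicit clade enumeration
oracle_branch_table <- function(tree, p) {
  p <- p[tree$tip.label]
  t(vapply(seq_len(nrow(tree$edge)), function(k) {
    tips <- unlist(phangorn::Descendants(tree, tree$edge[k, 2], "tips"))
    c(L = tree$edge.length[k], p = sum(p[tips]))
  }, numeric(2)))
}

oracle_allen <- function(tree, p) {
  bt <- oracle_branch_table(tree, p / sum(p))
  nz <- bt[, "p"] > 0
  -sum(bt[nz, "L"] * bt[nz, "p"] * log(bt[nz, "p"]))
}

oracle_wunifrac <- function(tree, pa, pb) {
  ba <- oracle_branch_table(tree, pa / sum(pa))
  bb <- oracle_branch_table(tree, pb / sum(pb))
  sum(ba[, "L"] * abs(ba[, "p"] - bb[, "p"])) /
    sum(ba[, "L"] * (ba[, "p"] + bb[, "p"]))
}

# exhaustive Kruskal-Wallis permutation p for small n: all distinct
# assignments of labels to positions
oracle_kw_exhaustive <- function(values, groups) {
  groups <- as.factor(groups)
  perms <- all_permutations(length(values))
  h_obs <- phylosym:::kw_statistic(values, groups)
  h_all <- apply(perms, 1, function(ix) phylosym:::kw_statistic(values, groups[ix]))
  mean(h_all >= h_obs - 1e-12)
}

# exhaustive Mantel p over all n! simultaneous permutations
oracle_mantel_exhaustive <- function(dm1, dm2) {
  n <- nrow(dm1)
  ut <- upper.tri(dm1)
  x <- unclass(dm1)[ut]
  r_obs <- stats::cor(x, unclass(dm2)[ut])
  perms <- all_permutations(n)
  r_all <- apply(perms, 1, function(ix) stats::cor(x, unclass(dm2)[ix, ix][ut]))
  mean(r_all >= r_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# random ultrametric chronogram fixture
random_chronogram <- function(k, age = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(k)
  tr$edge.length <- tr$edge.length * (age / max(ape::node.depth.edgelength(tr)))
  tr$tip.label <- paste0("t", seq_len(k))
  tr
}

# small fish+water metadata for a table whose rownames encode the design
toy_meta <- function(species_of, water_ids = character()) {
  fish <- data.frame(sample_id = names(species_of), sample_type = "fish",
                     host_species = unname(species_of),
                     stringsAsFactors = FALSE)
  if (length(water_ids)) {
    fish <- rbind(fish, data.frame(sample_id = water_ids,
                                   sample_type = "water",
                                   host_species = NA_character_))
  }
  fish
}
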
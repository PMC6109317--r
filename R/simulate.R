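#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. Defaults restate
#' the sampling design being emulated: 44 host species carrying 1-6
#' individuals each (138 fish samples in total), 35 water samples, reads
#' rarefied to 2000 per sample, on the order of 10^4 microbial OTUs, a
#' host tree about 130 My deep and a microbial chronogram rooted at 3800
#' My, and a plankton pool sharing about 10% of its OTUs with the skin
#' pool.
#'
#' @param n_species host species count (44).
#' @param ind_min,ind_max range of individuals per species (1-6).
#' @param n_individuals total fish samples (138); species counts are drawn
#'   uniformly in the range and then nudged within it to hit this total.
#' @param n_water water samples (35).
#' @param n_otus tips of the microbial chronogram (10^4).
#' @param depth reads per sample after rarefaction (2000).
#' @param host_root_age host tree root age, My (130).
#' @param microbial_root_age microbial chronogram root age, My (3800).
#' @param s phylosymbiosis strength in [0, 1]: share of interspecific
#'   compositional variance that tracks the host phylogeny (0 = none).
#' @param theta Dirichlet concentration controlling intraspecific
#'   variability (individual ~ Dirichlet(theta x species mean); larger =
#'   more faithful individuals).
#' @param rho plankton-skin OTU overlap in [0, 1]: fraction of the
#'   plankton source pool drawn from skin-pool OTUs.
#' @param m neutral migration rate used for water samples and
#'   [simulate_neutral_table()].
#' @param skin_frac fraction of tree tips available to the skin pool.
#' @param plankton_frac plankton pool size as a fraction of `n_otus`.
#' @param sigma_base lognormal sd of the shared OTU abundance base.
#' @param sigma_species sd of interspecific log-abundance deviations.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 44, ind_min = 1, ind_max = 6,
                       n_individuals = 138, n_water = 35, n_otus = 10000,
                       depth = 2000, host_root_age = 130,
                       microbial_root_age = 3800, s = 0.6, theta = 50,
                       rho = 0.1, m = 0.58, skin_frac = 0.8,
                       plankton_frac = 0.21, sigma_base = 2,
                       sigma_species = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(s >= 0, s <= 1, rho >= 0, rho <= 1, theta > 0,
            m > 0, m <= 1, ind_min >= 1, ind_max >= ind_min,
            n_individuals >= n_species * ind_min,
            n_individuals <= n_species * ind_max,
            depth > 0, n_otus >= 2, n_species >= 2)
  if ((1 - rho) * plankton_frac > (1 - skin_frac) + 1e-9) {
    stop("plankton pool needs more skin-free OTUs than the tree holds; ",
         "lower plankton_frac or raise skin_frac/rho")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# rescale a phylo so its root age equals `age`
rescale_tree <- function(tree, age) {
  h <- max(node_depths(tree)[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length * (age / h)
  tree
}

#' Simulate a host phylogeny
#'
#' Pure-birth (Yule) tree with `n_species` tips rescaled to the configured
#' root age, standing in for the published time-calibrated fish phylogeny.
#'
#' @param cfg a [sim_config()].
#' @return a [host_phylogeny()]; tips are `sp01`, `sp02`, ...
#' @export
simulate_host_tree <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "host-tree"))
  tree <- ape::rphylo(cfg$n_species, birth = 1, death = 0)
  tree <- rescale_tree(tree, cfg$host_root_age)
  tree$tip.label <- sprintf("sp%02d", seq_len(cfg$n_species))
  host_phylogeny(tree)
}

#' Simulate a microbial chronogram
#'
#' Yule tree over `n_otus` OTUs rescaled to the microbial root age
#' (default 3800 My, the bacteria/archaea split used as tree depth).
#'
#' @param cfg a [sim_config()].
#' @return a `phylo` chronogram; tips are `otu000001`, ...
#' @export
simulate_microbial_tree <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "microbial-tree"))
  tree <- ape::rphylo(cfg$n_otus, birth = 1, death = 0)
  tree <- rescale_tree(tree, cfg$microbial_root_age)
  tree$tip.label <- sprintf("otu%06d", seq_len(cfg$n_otus))
  tree
}

# individuals per species: uniform in [ind_min, ind_max], nudged to total
draw_species_sizes <- function(cfg) {
  k <- sample(seq(cfg$ind_min, cfg$ind_max), cfg$n_species, replace = TRUE)
  while (sum(k) > cfg$n_individuals) {
    i <- sample(which(k > cfg$ind_min), 1)
    k[i] <- k[i] - 1
  }
  while (sum(k) < cfg$n_individuals) {
    i <- sample(which(k < cfg$ind_max), 1)
    k[i] <- k[i] + 1
  }
  k
}

#' Simulate a phylosymbiotic fish-skin OTU table
#'
#' The latent species-level structure: each skin-pool OTU has a shared
#' base log-abundance (lognormal abundance distribution), plus a
#' species-specific deviation that mixes a Brownian-motion component
#' evolved on the host tree (weight `sqrt(s)`) with i.i.d. species noise
#' (weight `sqrt(1-s)`); a softmax per species yields the species' mean
#' composition. Individuals are Dirichlet(theta x species mean) draws and
#' read counts multinomial at the configured depth, so `s = 0` means no
#' phylosymbiosis and large `theta` means no intraspecific variability.
#'
#' Species-level ecological traits (size, mobility, activity period,
#' schooling, water-column position, diet) are drawn independently of the
#' microbiome — the generator plants no trait effect.
#'
#' @param cfg a [sim_config()].
#' @param host a [host_phylogeny()] from [simulate_host_tree()].
#' @param tree microbial chronogram from [simulate_microbial_tree()].
#' @return list: `table` (counts [otu_table()], fish only), `meta`
#'   (metadata data frame), `species_mean` (species x skin-OTU
#'   composition), `skin_otus` (tip ids of the skin pool).
#' @export
simulate_phylosymbiotic_table <- function(cfg, host, tree) {
  set.seed(derive_seed(cfg$seed, "fish-table"))
  species <- host$tree$tip.label
  skin_otus <- sort(sample(tree$tip.label, round(cfg$skin_frac * cfg$n_otus)))
  n_skin <- length(skin_otus)
  base <- stats::rnorm(n_skin, 0, cfg$sigma_base)
  # Brownian covariance normalised to unit variance at the tips
  C <- ape::vcv.phylo(host$tree)[species, species] / cfg$host_root_age
  Lc <- t(chol(C))
  bm <- Lc %*% matrix(stats::rnorm(cfg$n_species * n_skin), cfg$n_species)
  iid <- matrix(stats::rnorm(cfg$n_species * n_skin), cfg$n_species)
  dev <- cfg$sigma_species * (sqrt(cfg$s) * bm + sqrt(1 - cfg$s) * iid)
  loga <- sweep(dev, 2, base, `+`)
  sp_mean <- exp(loga)
  sp_mean <- sp_mean / rowSums(sp_mean)
  dimnames(sp_mean) <- list(species, skin_otus)
  sizes <- draw_species_sizes(cfg)
  ids <- character(0); hosts <- character(0)
  counts <- matrix(0L, cfg$n_individuals, n_skin)
  row <- 0
  for (si in seq_along(species)) {
    for (k in seq_len(sizes[si])) {
      row <- row + 1
      g <- stats::rgamma(n_skin, shape = cfg$theta * sp_mean[si, ])
      if (sum(g) == 0) g[which.max(sp_mean[si, ])] <- 1
      counts[row, ] <- stats::rmultinom(1, cfg$depth, g / sum(g))[, 1]
      ids <- c(ids, sprintf("fish_%03d", row))
      hosts <- c(hosts, species[si])
    }
  }
  dimnames(counts) <- list(ids, skin_otus)
  traits <- draw_species_traits(species)
  meta <- data.frame(
    sample_id = ids, sample_type = "fish", host_species = hosts,
    reef_type = sample(c("fringing", "barrier"), length(ids), replace = TRUE),
    depth_m = round(stats::runif(length(ids), 1, 15), 1),
    temperature = round(stats::rnorm(length(ids), 28, 0.5), 2),
    stringsAsFactors = FALSE)
  meta <- cbind(meta, traits[match(hosts, species), , drop = FALSE])
  rownames(meta) <- NULL
  list(table = otu_table(counts, "counts"), meta = meta,
       species_mean = sp_mean, skin_otus = skin_otus)
}

# six categorical ecological traits, constant within species, no planted
# effect on the microbiome
draw_species_traits <- function(species) {
  n <- length(species)
  data.frame(
    size_class = sample(c("S1", "S2", "S3", "S4", "S5", "S6"), n, TRUE),
    mobility = sample(c("sedentary", "mobile", "very_mobile"), n, TRUE),
    activity = sample(c("diurnal", "nocturnal", "both"), n, TRUE),
    schooling = sample(c("solitary", "pairs", "small_group", "large_group"), n, TRUE),
    position = sample(c("bottom", "low", "high"), n, TRUE),
    diet = sample(c("herbivore", "invertivore", "planktivore", "piscivore",
                    "omnivore"), n, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate planktonic (water) communities
#'
#' Builds a plankton source pool whose OTU identities overlap the skin
#' pool by fraction `rho` (the remainder drawn from tree tips unused by
#' the skin pool), with lognormal source abundances; each water sample is
#' a neutral draw from that pool (beta marginals at migration rate `m`,
#' multinomial reads), giving the low between-sample dispersion of
#' plankton.
#'
#' @param cfg a [sim_config()].
#' @param skin_otus skin-pool OTU ids from
#'   [simulate_phylosymbiotic_table()].
#' @param tree microbial chronogram.
#' @return list: `table` (counts [otu_table()] of water samples), `meta`,
#'   `pool_otus`, `source` (named source relative abundances).
#' @export
simulate_plankton <- function(cfg, skin_otus, tree) {
  set.seed(derive_seed(cfg$seed, "plankton"))
  n_pool <- max(2, round(cfg$plankton_frac * cfg$n_otus))
  n_shared <- round(cfg$rho * n_pool)
  outside <- setdiff(tree$tip.label, skin_otus)
  n_outside <- min(n_pool - n_shared, length(outside))
  pool <- c(sample(skin_otus, n_shared),
            if (n_outside > 0) sample(outside, n_outside))
  pool <- sort(pool)
  src <- stats::rlnorm(length(pool), 0, cfg$sigma_base)
  src <- src / sum(src)
  names(src) <- pool
  counts <- neutral_sample_counts(src, cfg$n_water, cfg$depth, cfg$m)
  rownames(counts) <- sprintf("water_%03d", seq_len(cfg$n_water))
  meta <- data.frame(
    sample_id = rownames(counts), sample_type = "water",
    host_species = NA_character_,
    reef_type = sample(c("fringing", "barrier"), cfg$n_water, replace = TRUE),
    stringsAsFactors = FALSE)
  list(table = otu_table(counts, "counts"), meta = meta,
       pool_otus = pool, source = src)
}

# neutral local communities: independent Beta(N m p, N m (1-p)) marginals
# renormalised, then multinomial reads. An approximation to the Sloan
# stationary joint distribution, adequate for fit-recovery tests.
neutral_sample_counts <- function(source_p, n_samples, depth, m) {
  n_otu <- length(source_p)
  counts <- matrix(0L, n_samples, n_otu,
                   dimnames = list(NULL, names(source_p)))
  a <- depth * m * source_p
  b <- depth * m * (1 - source_p)
  for (i in seq_len(n_samples)) {
    x <- stats::rbeta(n_otu, a, b)
    x[!is.finite(x)] <- 0
    if (sum(x) == 0) x[which.max(source_p)] <- 1
    counts[i, ] <- stats::rmultinom(1, depth, x / sum(x))[, 1]
  }
  counts
}

#' Simulate a table from the neutral model itself
#'
#' Generator matched to [fit_sloan()]: lognormal (default) or log-series
#' source abundances, neutral beta marginals at migration rate `m`,
#' multinomial reads at uniform depth. Used for parameter-recovery tests.
#'
#' @param cfg a [sim_config()] (`m`, `depth`, `seed` are used).
#' @param n_samples local communities (default `cfg$n_water`).
#' @param n_otus source-pool richness (default 1000).
#' @param sad source abundance distribution, `"lognormal"` or
#'   `"logseries"`.
#' @return a counts-mode [otu_table()].
#' @export
simulate_neutral_table <- function(cfg, n_samples = cfg$n_water,
                                   n_otus = 1000,
                                   sad = c("lognormal", "logseries")) {
  sad <- match.arg(sad)
  set.seed(derive_seed(cfg$seed, "neutral-table"))
  src <- switch(sad,
    lognormal = stats::rlnorm(n_otus, 0, cfg$sigma_base),
    logseries = {
      # Fisher log-series via its nbinom mixture limit
      th <- 0.999
      as.numeric(sample(seq_len(1000), n_otus, replace = TRUE,
                        prob = th^seq_len(1000) / seq_len(1000)))
    })
  src <- src / sum(src)
  names(src) <- sprintf("otu%06d", seq_len(n_otus))
  counts <- neutral_sample_counts(src, n_samples, cfg$depth, cfg$m)
  rownames(counts) <- sprintf("nsample_%03d", seq_len(n_samples))
  otu_table(counts, "counts")
}

#' Simulate a complete synthetic study
#'
#' Host tree, microbial chronogram, phylosymbiotic fish table, plankton
#' samples and merged metadata in one call — the full input set the
#' pipeline expects, reproducible from the config alone.
#'
#' @param cfg a [sim_config()].
#' @return list: `cfg`, `host`, `tree`, `table` (fish + water counts),
#'   `meta`, `species_mean`, `skin_otus`, `pool_otus`.
#' @export
simulate_study <- function(cfg) {
  host <- simulate_host_tree(cfg)
  tree <- simulate_microbial_tree(cfg)
  fish <- simulate_phylosymbiotic_table(cfg, host, tree)
  plank <- simulate_plankton(cfg, fish$skin_otus, tree)
  all_otus <- sort(union(colnames(fish$table), colnames(plank$table)))
  pad <- function(m) {
    out <- matrix(0L, nrow(m), length(all_otus),
                  dimnames = list(rownames(m), all_otus))
    out[, colnames(m)] <- unclass(m)
    out
  }
  table <- otu_table(rbind(pad(fish$table), pad(plank$table)), "counts")
  meta_cols <- union(names(fish$meta), names(plank$meta))
  for (cc in setdiff(meta_cols, names(plank$meta))) plank$meta[[cc]] <- NA
  for (cc in setdiff(meta_cols, names(fish$meta))) fish$meta[[cc]] <- NA
  meta <- rbind(fish$meta[meta_cols], plank$meta[meta_cols])
  rownames(meta) <- NULL
  list(cfg = cfg, host = host, tree = tree, table = table, meta = meta,
       species_mean = fish$species_mean, skin_otus = fish$skin_otus,
       pool_otus = plank$pool_otus)
}
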
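#' Core OTUs per host species
#'
#' A species' core microbiome is the set of OTUs present (abundance > 0,
#' assessed after all preprocessing) in every sampled individual of that
#' species. Only species with at least `min_individuals` fish are
#' considered (the study used 3). Adding an individual can only shrink a
#' core set, which is what drives the negative correlation between
#' sampling effort and core size.
#'
#' @param table an [otu_table()] (either mode).
#' @param meta metadata data frame.
#' @param min_individuals minimum fish per species (default 3).
#' @return object of class `core_sets`: list with `per_species` (named
#'   list of OTU-id vectors), `union` (all core OTUs), `mean_abundance`
#'   (per core OTU, mean relative abundance across the fish samples where
#'   present), and `species`.
#' @export
core_otus <- function(table, meta, min_individuals = 3) {
  species <- species_filter(meta, min_individuals)
  fish <- meta[meta$sample_type == "fish", ]
  m <- unclass(table)
  per_species <- lapply(stats::setNames(species, species), function(sp) {
    ids <- intersect(fish$sample_id[fish$host_species == sp], rownames(m))
    pres <- m[ids, , drop = FALSE] > 0
    colnames(m)[colSums(pres) == length(ids)]
  })
  core_union <- sort(unique(unlist(per_species)))
  rel <- m / rowSums(m)
  fish_ids <- intersect(fish$sample_id, rownames(m))
  mean_ab <- vapply(core_union, function(o) {
    v <- rel[fish_ids, o]
    if (any(v > 0)) mean(v[v > 0]) else 0
  }, numeric(1))
  structure(list(per_species = per_species, union = core_union,
                 mean_abundance = mean_ab, species = species,
                 min_individuals = min_individuals),
            class = "core_sets")
}

#' @export
print.core_sets <- function(x, ...) {
  sizes <- lengths(x$per_species)
  cat(sprintf("core microbiome: %d species (>= %d ind.), %d to %d core OTUs per species, union %d\n",
              length(x$species), x$min_individuals, min(sizes), max(sizes),
              length(x$union)))
  invisible(x)
}

#' Core-microbiome summary statistics
#'
#' Per-species core counts; the fraction of the core-OTU union detected in
#' at least one plankton sample and the cumulated relative abundance those
#' shared OTUs reach in plankton (sum over shared core OTUs of their mean
#' relative abundance across water samples); and Pearson correlations of
#' core size against (i) individuals sampled and (ii) mean OTU richness of
#' the species (two separate tests). With a single species the
#' correlations are returned as NA with a reason.
#'
#' @param core a [core_otus()] result.
#' @param table the [otu_table()] the cores were called on (must contain
#'   the plankton samples).
#' @param meta metadata data frame.
#' @return list: `core_counts`, `frac_in_plankton`,
#'   `plankton_cumulated_abundance`, `cor_individuals` (list r/p),
#'   `cor_richness` (list r/p).
#' @export
core_summary <- function(core, table, meta) {
  counts <- lengths(core$per_species)
  water_ids <- intersect(meta$sample_id[meta$sample_type == "water"],
                         rownames(table))
  m <- unclass(table)
  if (length(water_ids)) {
    wrel <- m[water_ids, , drop = FALSE]
    wrel <- wrel / rowSums(wrel)
    detected <- colSums(wrel[, core$union, drop = FALSE] > 0) > 0
    frac <- mean(detected)
    cum_ab <- sum(colMeans(wrel[, core$union[detected], drop = FALSE]))
  } else {
    frac <- NA_real_; cum_ab <- NA_real_
  }
  n_ind <- species_counts(meta)[core$species]
  fish <- meta[meta$sample_type == "fish", ]
  rich <- vapply(core$species, function(sp) {
    ids <- intersect(fish$sample_id[fish$host_species == sp], rownames(m))
    mean(otu_richness(m[ids, , drop = FALSE]))
  }, numeric(1))
  cor_or_na <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(r = NA_real_, p_value = NA_real_,
                  reason = "fewer than 3 species or zero variance"))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value)
  }
  list(core_counts = counts, frac_in_plankton = frac,
       plankton_cumulated_abundance = cum_ab,
       cor_individuals = cor_or_na(as.numeric(counts), as.numeric(n_ind)),
       cor_richness = cor_or_na(as.numeric(counts), rich))
}

#' Phylogenetic signal of core-OTU abundances across host species
#'
#' For each core OTU, Moran's I and Pagel's lambda are computed on its
#' relative abundance across host species (species-averaged, Method B),
#' with permutation p-values Bonferroni-corrected over the number of OTUs
#' actually tested (`p_adj = min(1, p * n_tests)`). OTUs whose
#' species-level abundance vector is (near-)constant are skipped with a
#' reason.
#'
#' @param core a [core_otus()] result.
#' @param table relative-mode [otu_table()] of fish samples.
#' @param meta metadata data frame.
#' @param host a [host_phylogeny()] covering the core species.
#' @param n_perm_moran,n_perm_lambda permutations (study: 999 and 500).
#' @param seed integer master seed.
#' @return data frame, one row per core OTU: `otu_id`, `moran_i`,
#'   `moran_p`, `moran_p_adj`, `lambda`, `lambda_p`, `lambda_p_adj`,
#'   `status`.
#' @export
core_phylosignal <- function(core, table, meta, host,
                             n_perm_moran = 999, n_perm_lambda = 500, seed) {
  sp_tab <- average_by_species(table, meta, core$species)
  rows <- lapply(core$union, function(o) {
    x <- stats::setNames(unclass(sp_tab)[, o], rownames(sp_tab))
    if (stats::sd(x) < 1e-12) {
      return(data.frame(otu_id = o, moran_i = NA, moran_p = NA,
                        lambda = NA, lambda_p = NA,
                        status = "skipped: constant abundance"))
    }
    mi <- morans_i(x, host, n_perm = n_perm_moran,
                   seed = derive_seed(seed, paste0("moran-", o)))
    pl <- pagel_lambda(x, host, n_perm = n_perm_lambda,
                       seed = derive_seed(seed, paste0("lambda-", o)))
    data.frame(otu_id = o, moran_i = mi$statistic, moran_p = mi$p_value,
               lambda = pl$lambda, lambda_p = pl$p_value, status = "ok")
  })
  out <- do.call(rbind, rows)
  n_tests <- sum(out$status == "ok")
  out$moran_p_adj <- pmin(1, out$moran_p * n_tests)
  out$lambda_p_adj <- pmin(1, out$lambda_p * n_tests)
  out[, c("otu_id", "moran_i", "moran_p", "moran_p_adj",
          "lambda", "lambda_p", "lambda_p_adj", "status")]
}
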
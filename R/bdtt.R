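#' Collapse an OTU table at a given tree age
#'
#' Slices the microbial chronogram at age `t` (My before present, tips at
#' age 0): every branch whose parent node is older than `t` and whose
#' child node is at most `t` old defines one lineage, and a lineage's
#' abundance in a sample is the sum of its descendant tips' abundances.
#' `t = 0` is the identity (one lineage per tip); `t` at or beyond the
#' root age collapses everything into a single lineage (allowed, with a
#' warning). Per-sample total abundance is conserved exactly.
#'
#' @param table an [otu_table()] (either mode) whose OTUs are tips of
#'   `tree`.
#' @param tree microbial chronogram; refused if its relative
#'   ultrametricity error exceeds 1e-3 (node ages would be ill-defined).
#' @param t slice age in the tree's time units (My).
#' @return an [otu_table()] over lineages (columns named
#'   `slice<t>_<node id>`), same mode and samples as the input.
#' @export
collapse_at_age <- function(table, tree, t) {
  if (t < 0) stop("slice age must be non-negative")
  if (ultrametric_error(tree) > 1e-3) {
    stop("tree too far from ultrametric for age slicing (rel. error > 1e-3)")
  }
  if (t == 0) return(table)
  ages <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  if (t >= ages[root]) {
    warning("slice age >= root age; collapsing to a single lineage")
    m <- matrix(rowSums(table), ncol = 1,
                dimnames = list(rownames(table), "slice_root"))
    return(otu_table(m, otu_mode(table), removed_mass = removed_mass(table)))
  }
  # half-open interval [child age, parent age): every root-to-tip path
  # crosses exactly one slicing branch
  parent_age <- ages[tree$edge[, 1]]
  child_age <- ages[tree$edge[, 2]]
  cut_edges <- which(parent_age > t & child_age <= t)
  membership <- lineage_membership(tree, cut_edges)
  m <- unclass(table)
  nz <- colnames(m)[colSums(m) > 0]
  if (length(setdiff(nz, tree$tip.label))) {
    stop("OTUs with nonzero abundance missing from tree")
  }
  keep <- intersect(colnames(m), tree$tip.label)
  out <- matrix(0, nrow(m), length(cut_edges),
                dimnames = list(rownames(m),
                                paste0("slice", t, "_", tree$edge[cut_edges, 2])))
  grp <- membership[match(keep, tree$tip.label)]
  for (g in seq_along(cut_edges)) {
    cols <- keep[grp == g]
    if (length(cols)) out[, g] <- rowSums(m[, cols, drop = FALSE])
  }
  otu_table(out, otu_mode(table), removed_mass = removed_mass(table))
}

# map each tip to the index of the cut edge above it
lineage_membership <- function(tree, cut_edges) {
  ntip <- ape::Ntip(tree)
  lineage_of <- integer(ntip + tree$Nnode)
  lineage_of[tree$edge[cut_edges, 2]] <- seq_along(cut_edges)
  tr_edge <- stats::reorder(tree, "postorder")$edge
  for (k in rev(seq_len(nrow(tr_edge)))) {   # preorder: parents first
    child <- tr_edge[k, 2]
    if (lineage_of[child] == 0) lineage_of[child] <- lineage_of[tr_edge[k, 1]]
  }
  lineage_of[seq_len(ntip)]
}

#' Beta diversity through time (BDTT) profile
#'
#' Re-tests the host association at successively deeper phylogenetic
#' levels: at each slice age the microbial chronogram is collapsed
#' ([collapse_at_age()]), Bray-Curtis dissimilarities recomputed between
#' species-level communities, and their correlation with host divergence
#' times tested by Mantel under the chosen intraspecific-variability
#' strategy. Slices where the Mantel statistic is undefined (e.g. all
#' mass in one lineage) are flagged with a reason instead of failing.
#'
#' @param table relative-mode [otu_table()] of fish samples.
#' @param meta metadata data frame.
#' @param tree microbial chronogram.
#' @param host a [host_phylogeny()].
#' @param slices slice ages in My (default `seq(0, 900, by = 100)`).
#' @param method `"A"` or `"B"` (see [method_ab()]).
#' @param n_subsamples Method A subsamples (the study used 500 here).
#' @param n_perm Mantel permutations per test (default 999).
#' @param seed integer master seed.
#' @param species species universe (default all fish species in `meta`).
#' @return a `bdtt_profile` data frame: one row per slice with
#'   `slice_age`, `n_lineages`, `mantel_r`, `p_value` (method B) or
#'   `mean_r`, `sd_r`, `pct_significant` (method A), and `status`.
#' @export
bdtt_profile <- function(table, meta, tree, host,
                         slices = seq(0, 900, by = 100),
                         method = c("B", "A"), n_subsamples = 500,
                         n_perm = 999, seed, species = NULL) {
  method <- match.arg(method)
  host_dm <- dist_matrix(host$T)
  rows <- lapply(slices, function(t) {
    tab_t <- withCallingHandlers(
      collapse_at_age(table, tree, t),
      warning = function(w) invokeRestart("muffleWarning"))
    n_lin <- ncol(tab_t)
    stat <- function(sp_tab, s) {
      mantel(bray_curtis(sp_tab), align_dm(host_dm, rownames(sp_tab)),
             n_perm = n_perm, seed = s)
    }
    res <- tryCatch(
      method_ab(stat, tab_t, meta, species = species,
                n_subsamples = n_subsamples,
                seed = derive_seed(seed, paste0("slice", t)),
                methods = method),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(slice_age = t, n_lineages = n_lin, mantel_r = NA,
                        p_value = NA, mean_r = NA, sd_r = NA,
                        pct_significant = NA,
                        status = paste0("undefined: ", conditionMessage(res))))
    }
    if (method == "B") {
      ok_b <- !is.null(res$B) && is.finite(res$B$statistic)
      data.frame(slice_age = t, n_lineages = n_lin,
                 mantel_r = if (ok_b) res$B$statistic else NA,
                 p_value = if (ok_b) res$B$p_value else NA,
                 mean_r = NA, sd_r = NA, pct_significant = NA,
                 status = if (ok_b) "ok" else "undefined")
    } else {
      all_failed <- res$A$n_failed >= n_subsamples
      data.frame(slice_age = t, n_lineages = n_lin, mantel_r = NA,
                 p_value = NA,
                 mean_r = if (all_failed) NA else res$A$mean,
                 sd_r = if (all_failed) NA else res$A$sd,
                 pct_significant = if (all_failed) NA else res$A$pct_significant,
                 status = if (all_failed) "undefined: all subsamples failed" else "ok")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bdtt_profile", "data.frame")
  out
}
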
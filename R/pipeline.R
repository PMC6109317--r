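#' Run the full analysis workflow from one configuration
#'
#' Orchestrates the study pipeline — preprocessing, alpha diversity and
#' its drivers, beta diversity and its drivers, neutral-model fits,
#' beta-diversity-through-time and core microbiomes — writing every stage
#' output plus a summary JSON, a manifest with checksums and a log file
#' under one run directory. Every random stage is seeded deterministically
#' from the single master seed (stage-name hashing), so stages are
#' reproducible in isolation and two runs with the same config are
#' byte-identical. A stage failure is recorded in the summary and its
#' downstream dependents are skipped rather than aborting the run.
#'
#' @param config path to a YAML file or an equivalent named list. Keys:
#'   either `simulate:` (arguments for [sim_config()]) or the input paths
#'   `table`, `metadata`, `microbial_tree`, `host_tree`; plus `seed`,
#'   `out_dir`, and optional `depth` (2000), `method` ("B", "A" or
#'   "both"), `n_subsamples` (999), `n_perm` (999), `blank_ids`,
#'   `min_individuals_species` (2), `min_individuals_core` (3),
#'   `bdtt_slices`, `bdtt_subsamples` (500), `trait_cols`.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_all <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$seed)) stop("config must set a master seed")
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) {
    cat(paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n"),
        file = log_path, append = TRUE)
  }
  seed <- as.integer(cfg$seed)
  method <- cfg$method %||% "B"
  methods <- if (identical(method, "both")) c("A", "B") else method
  n_sub <- cfg$n_subsamples %||% 999
  n_perm <- cfg$n_perm %||% 999
  summary <- list(seed = seed, stages = list())
  failed <- character(0)   # failed or skipped: blocks dependents either way
  stage <- function(name, deps = character(0), expr) {
    if (length(intersect(deps, failed))) {
      log_line("stage %s skipped (failed dependency)", name)
      summary$stages[[name]] <<- list(status = "skipped",
                                      reason = paste("blocked by:", intersect(deps, failed)[1]))
      failed <<- c(failed, name)
      return(NULL)
    }
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      log_line("stage %s FAILED: %s", name, conditionMessage(out))
      failed <<- c(failed, name)
      summary$stages[[name]] <<- list(status = "failed",
                                      error = conditionMessage(out))
      return(NULL)
    }
    log_line("stage %s ok", name)
    summary$stages[[name]] <<- list(status = "ok")
    out
  }

  inputs <- stage("inputs", character(0), {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
      sim <- simulate_study(do.call(sim_config, sim_args))
      list(table = sim$table, meta = sim$meta, tree = sim$tree,
           host = sim$host)
    } else {
      for (key in c("table", "metadata", "microbial_tree", "host_tree")) {
        if (is.null(cfg[[key]])) stop("config missing input path: ", key)
        if (!file.exists(cfg[[key]])) stop("input not found: ", cfg[[key]])
      }
      meta <- read_metadata(cfg$metadata, trait_cols = cfg$trait_cols %||% character())
      list(table = read_otu_table(cfg$table, metadata = meta), meta = meta,
           tree = read_newick(cfg$microbial_tree),
           host = host_phylogeny(read_newick(cfg$host_tree)))
    }
  })

  prep <- stage("preprocess", "inputs", {
    tab <- inputs$table
    if (otu_mode(tab) == "counts") {
      tab <- rarefy(tab, depth = cfg$depth %||% 2000,
                    seed = derive_seed(seed, "rarefy"))
      cov <- coverage_by_sample(tab)
      tab <- to_relative(tab)
    } else cov <- NULL
    blanks <- cfg$blank_ids %||%
      inputs$meta$sample_id[inputs$meta$sample_type == "blank"]
    blanks <- intersect(blanks, rownames(tab))
    if (length(blanks)) tab <- subtract_blanks(tab, blanks)
    list(rel = tab, coverage = cov)
  })
  if (!is.null(prep)) {
    meta <- inputs$meta[inputs$meta$sample_id %in% rownames(prep$rel), ]
    fish_ids <- meta$sample_id[meta$sample_type == "fish"]
    water_ids <- meta$sample_id[meta$sample_type == "water"]
    counts_kept <- if (otu_mode(inputs$table) == "counts") {
      inputs$table[rownames(inputs$table) %in% rownames(prep$rel), ]
    } else NULL
  }

  alpha <- stage("alpha", "preprocess", {
    h <- entropy_by_sample(prep$rel, inputs$tree)
    rich <- otu_richness(prep$rel)
    tbl <- data.frame(sample_id = rownames(prep$rel), richness = rich,
                      entropy = h,
                      coverage = if (is.null(prep$coverage)) NA else
                        prep$coverage[rownames(prep$rel)])
    utils::write.table(tbl, file.path(cfg$out_dir, "alpha.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    kw_fw <- if (length(water_ids) >= 1) {
      grp <- ifelse(rownames(prep$rel) %in% fish_ids, "fish", "water")
      kruskal_wallis_perm(h, grp, n_perm = n_perm,
                          seed = derive_seed(seed, "kw-fish-water"))
    }
    sp2 <- species_filter(meta, cfg$min_individuals_species %||% 2)
    meta_f <- meta[meta$sample_id %in% fish_ids, ]
    kw_sp <- if (length(sp2) >= 2) {
      keep <- meta_f$sample_id[meta_f$host_species %in% sp2]
      kruskal_wallis_perm(h[keep], meta_f$host_species[match(keep, meta_f$sample_id)],
                          n_perm = n_perm, seed = derive_seed(seed, "kw-species"))
    }
    boot <- if (length(water_ids) >= 2 && length(fish_ids) >= length(water_ids)) {
      pooled_entropy_bootstrap(prep$rel, fish_ids, water_ids, inputs$tree,
                               n_boot = cfg$n_boot %||% 100,
                               seed = derive_seed(seed, "pool-boot"))
    }
    signal <- tryCatch({
      stat <- function(sp_tab, s) {
        hh <- entropy_by_sample(sp_tab, inputs$tree)
        morans_i(hh, inputs$host, n_perm = n_perm, seed = s)
      }
      method_ab(stat, prep$rel, meta, species = NULL, n_subsamples = n_sub,
                seed = derive_seed(seed, "entropy-signal"), methods = methods)
    }, error = function(e) list(error = conditionMessage(e)))
    list(per_sample = tbl, kw_fish_water = kw_fw, kw_species = kw_sp,
         pooled_bootstrap = boot[c("water_entropy", "exceed_fraction", "mean_ratio")],
         entropy_signal = signal)
  })

  beta <- stage("beta", "preprocess", {
    wu <- weighted_unifrac(prep$rel, inputs$tree)
    write_distance_matrix(wu, file.path(cfg$out_dir, "wunifrac.tsv"))
    smry <- dissimilarity_summary(wu, meta)
    ord <- pcoa(wu, k = 2)
    utils::write.table(
      data.frame(sample_id = rownames(ord$points), ord$points),
      file.path(cfg$out_dir, "pcoa.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    pn_type <- if (length(water_ids) >= 2) {
      permanova(wu, meta, "sample_type", n_perm = n_perm,
                seed = derive_seed(seed, "permanova-type"))
    }
    sp2 <- species_filter(meta, cfg$min_individuals_species %||% 2)
    pn_species <- if (length(sp2) >= 2) {
      ids <- meta$sample_id[meta$sample_type == "fish" &
                            meta$host_species %in% sp2]
      permanova(align_dm(wu, ids), meta, "host_species", n_perm = n_perm,
                seed = derive_seed(seed, "permanova-species"))
    }
    list(wunifrac = wu, summary = smry, permanova_type = pn_type,
         permanova_species = pn_species)
  })

  phylosym <- stage("phylosymbiosis", c("preprocess", "beta"), {
    host_dm <- dist_matrix(inputs$host$T)
    stat <- function(sp_tab, s) {
      mantel(weighted_unifrac(sp_tab, inputs$tree),
             align_dm(host_dm, rownames(sp_tab)), n_perm = n_perm, seed = s)
    }
    method_ab(stat, prep$rel, meta, species = NULL, n_subsamples = n_sub,
              seed = derive_seed(seed, "phylosymbiosis"), methods = methods)
  })

  traits <- stage("traits", c("preprocess", "beta"), {
    trait_cols <- intersect(cfg$trait_cols %||%
      c("size_class", "mobility", "activity", "schooling", "position", "diet"),
      names(meta))
    if (!length(trait_cols)) return(NULL)
    stat_for <- function(tc) function(sp_tab, s) {
      wu <- weighted_unifrac(sp_tab, inputs$tree)
      sp_meta <- meta[match(rownames(sp_tab),
                            ifelse(meta$sample_type == "fish", meta$host_species, NA)), ]
      sp_data <- data.frame(sample_id = rownames(sp_tab),
                            sp_meta[, trait_cols, drop = FALSE])
      fit <- permanova(wu, sp_data, tc, n_perm = n_perm, seed = s)
      list(statistic = fit$R2[1], p_value = fit$p_value[1])
    }
    lapply(stats::setNames(trait_cols, trait_cols), function(tc) {
      tryCatch(method_ab(stat_for(tc), prep$rel, meta, species = NULL,
                         n_subsamples = n_sub,
                         seed = derive_seed(seed, paste0("trait-", tc)),
                         methods = methods),
               error = function(e) list(error = conditionMessage(e)))
    })
  })

  neutral <- stage("neutral", "preprocess", {
    if (is.null(counts_kept)) return(list(reason = "no counts available"))
    fit_grp <- function(ids) {
      if (length(ids) < 10) return(NULL)
      fit <- fit_sloan(counts_kept[rownames(counts_kept) %in% ids, ])
      fit[c("m", "r_squared", "N", "n_samples")]
    }
    list(fish = fit_grp(fish_ids), water = fit_grp(water_ids))
  })

  bdtt <- stage("bdtt", "preprocess", {
    prof <- bdtt_profile(prep$rel, meta, inputs$tree, inputs$host,
                         slices = cfg$bdtt_slices %||% seq(0, 900, by = 100),
                         method = if ("B" %in% methods) "B" else "A",
                         n_subsamples = cfg$bdtt_subsamples %||% 500,
                         n_perm = n_perm, seed = derive_seed(seed, "bdtt"))
    utils::write.table(prof, file.path(cfg$out_dir, "bdtt.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prof
  })

  core <- stage("core", "preprocess", {
    cs <- core_otus(prep$rel, meta,
                    min_individuals = cfg$min_individuals_core %||% 3)
    per_sp <- data.frame(species = names(cs$per_species),
                         n_core = lengths(cs$per_species))
    utils::write.table(per_sp, file.path(cfg$out_dir, "core_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    smry <- core_summary(cs, prep$rel, meta)
    sig <- if (length(cs$union) > 0 && length(cs$species) >= 4) {
      host_sub <- host_phylogeny(ape::keep.tip(inputs$host$tree, cs$species),
                                 distance = inputs$host$distance)
      core_phylosignal(cs, prep$rel, meta, host_sub,
                       n_perm_moran = n_perm,
                       n_perm_lambda = cfg$n_perm_lambda %||% 500,
                       seed = derive_seed(seed, "core-signal"))
    }
    if (!is.null(sig)) {
      utils::write.table(sig, file.path(cfg$out_dir, "core_signal.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(n_union = length(cs$union), counts = smry$core_counts,
         frac_in_plankton = smry$frac_in_plankton,
         plankton_cumulated_abundance = smry$plankton_cumulated_abundance,
         cor_individuals = smry$cor_individuals,
         cor_richness = smry$cor_richness,
         n_signal_tested = if (is.null(sig)) 0 else sum(sig$status == "ok"),
         min_adjusted_p = if (is.null(sig) || !any(sig$status == "ok")) NA else
           min(c(sig$moran_p_adj, sig$lambda_p_adj), na.rm = TRUE))
  })

  summary$alpha <- strip_big(alpha)
  summary$beta <- list(summary = beta$summary,
                       permanova_type = as.list(beta$permanova_type),
                       permanova_species = as.list(beta$permanova_species))
  summary$phylosymbiosis <- unclass_deep(phylosym)
  summary$traits <- unclass_deep(traits)
  summary$neutral <- neutral
  summary$bdtt <- if (!is.null(bdtt)) as.list(as.data.frame(bdtt))
  summary$core <- core
  json_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 10,
                       null = "null", force = TRUE)
  files <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                   file.path(cfg$out_dir, c("manifest.json", "run.log")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  log_line("run complete")
  invisible(summary)
}

# drop heavyweight members before JSON serialisation
strip_big <- function(alpha) {
  if (is.null(alpha)) return(NULL)
  out <- alpha[setdiff(names(alpha), "per_sample")]
  out$entropy_signal <- unclass_deep(out$entropy_signal)
  out
}

unclass_deep <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "method_ab_result")) {
    x <- unclass(x)
    if (!is.null(x$A)) x$A <- x$A[setdiff(names(x$A), c("statistics", "p_values"))]
    return(x)
  }
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' Command-line entry point
#'
#' Thin wrapper so the pipeline can be driven as
#' `Rscript -e 'phylosym::phylosym_main()' --config study.yaml`. Exit
#' codes: 0 success, 2 config error, 3 stage failure.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit code, invisibly (also passed to [quit()] when
#'   non-interactive).
#' @export
phylosym_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  idx <- which(args == "--config")
  code <- if (!length(idx) || idx == length(args)) {
    message("usage: --config <study.yaml>")
    2
  } else {
    res <- tryCatch(run_all(args[idx + 1]), error = function(e) e)
    if (inherits(res, "error")) {
      message("config error: ", conditionMessage(res))
      2
    } else if (any(vapply(res$stages, function(s) s$status == "failed", logical(1)))) {
      3
    } else 0
  }
  if (!interactive()) quit(status = code, save = "no")
  invisible(code)
}
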
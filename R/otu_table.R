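#' Construct an OTU abundance table
#'
#' An `otu_table` is a numeric matrix of non-negative abundances with samples
#' as rows and OTUs as columns, plus a mode flag distinguishing raw read
#' counts from relative abundances. Relative-abundance tables whose rows sum
#' to less than 1 (because contaminant mass was subtracted, see
#' [subtract_blanks()]) carry the removed mass in a per-sample attribute.
#'
#' @param values numeric matrix, samples x OTUs, with unique dimnames.
#' @param mode `"counts"` or `"relative"`.
#' @param removed_mass optional named numeric vector, per-sample relative
#'   abundance removed by blank subtraction (defaults to 0).
#' @return an object of class `otu_table` (a matrix with attributes).
#' @export
otu_table <- function(values, mode = c("counts", "relative"),
                      removed_mass = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x OTUs)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample ids as rownames and OTU ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated OTU ids")
  if (anyNA(values)) stop("missing values in OTU table")
  if (any(values < 0)) stop("negative abundances in OTU table")
  if (is.null(removed_mass)) {
    removed_mass <- stats::setNames(numeric(nrow(values)), rownames(values))
  } else {
    removed_mass <- removed_mass[rownames(values)]
    names(removed_mass) <- rownames(values)
    removed_mass[is.na(removed_mass)] <- 0
  }
  if (mode == "relative") {
    target <- 1 - removed_mass
    if (any(abs(rowSums(values) - target) > 1e-9)) {
      stop("relative-mode rows must sum to 1 minus their removed mass (+/- 1e-9)")
    }
  }
  structure(values, mode = mode, removed_mass = removed_mass,
            class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, mode = %s\n",
              nrow(x), ncol(x), otu_mode(x)))
  if (any(attr(x, "removed_mass") > 0)) {
    cat(sprintf("  blank-subtracted mass: mean %.4f per sample\n",
                mean(attr(x, "removed_mass"))))
  }
  invisible(x)
}

#' Abundance mode of an OTU table
#' @param x an [otu_table()].
#' @return `"counts"` or `"relative"`.
#' @export
otu_mode <- function(x) attr(x, "mode")

#' Per-sample mass removed by blank subtraction
#' @param x an [otu_table()].
#' @return named numeric vector.
#' @export
removed_mass <- function(x) attr(x, "removed_mass")

#' Subset an OTU table, preserving attributes
#'
#' `[` on an `otu_table` keeps class, mode and per-sample removed mass in
#' step with the retained rows (standard matrix subsetting drops them).
#'
#' @param x an [otu_table()].
#' @param i,j row (sample) and column (OTU) indices.
#' @param drop ignored; dimensions are always kept.
#' @param ... unused.
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  rm_mass <- attr(x, "removed_mass")
  mode <- attr(x, "mode")
  y <- unclass(x)[i, j, drop = FALSE]
  if (!missing(i)) rm_mass <- rm_mass[i]
  structure(y, mode = mode, removed_mass = rm_mass,
            class = c("otu_table", "matrix", "array"))
}

#' Read an OTU table from TSV
#'
#' The file holds one header row and one leading label column; whether rows
#' are samples or OTUs is controlled by `orientation`. With
#' `orientation = "auto"` the side whose labels intersect
#' `metadata$sample_id` is taken as samples; without metadata, rows are
#' assumed to be samples. Mode is `"counts"` when every entry is integral,
#' `"relative"` otherwise.
#'
#' @param path TSV file path.
#' @param orientation `"auto"`, `"samples_rows"`, or `"otus_rows"`.
#' @param metadata optional data frame with a `sample_id` column, used by
#'   orientation auto-detection.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("auto", "samples_rows", "otus_rows"),
                           metadata = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in OTU table: ", path)
  if (orientation == "auto") {
    if (!is.null(metadata)) {
      in_rows <- length(intersect(rownames(m), metadata$sample_id))
      in_cols <- length(intersect(colnames(m), metadata$sample_id))
      orientation <- if (in_cols > in_rows) "otus_rows" else "samples_rows"
    } else {
      orientation <- "samples_rows"
    }
  }
  if (orientation == "otus_rows") m <- t(m)
  mode <- if (all(abs(m - round(m)) < 1e-9)) "counts" else "relative"
  if (mode == "relative") {
    rs <- rowSums(m)
    rm_mass <- ifelse(rs < 1 - 1e-9, 1 - rs, 0)
    names(rm_mass) <- rownames(m)
    return(otu_table(m, "relative", removed_mass = rm_mass))
  }
  otu_table(m, mode)
}

#' Write an OTU table to TSV (samples as rows)
#' @param x an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Requires columns `sample_id` and `sample_type` (levels among fish, water,
#' blank, invertebrate); fish rows must carry a `host_species`. Any further
#' columns (reef type, environmental covariates, species-level ecological
#' traits) pass through unchanged, except that trait columns are checked to
#' be constant within a species.
#'
#' @param path TSV file path.
#' @param trait_cols character vector naming per-species trait columns to
#'   validate for within-species constancy (default: none).
#' @return a data frame.
#' @export
read_metadata <- function(path, trait_cols = character()) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "")
  validate_metadata(meta, trait_cols)
}

#' Validate a sample metadata table
#' @inheritParams read_metadata
#' @param meta data frame to validate.
#' @return `meta`, invisibly valid.
#' @export
validate_metadata <- function(meta, trait_cols = character()) {
  req <- c("sample_id", "sample_type")
  if (!all(req %in% names(meta))) {
    stop("metadata must contain columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  bad <- setdiff(unique(meta$sample_type),
                 c("fish", "water", "blank", "invertebrate"))
  if (length(bad)) stop("unknown sample_type: ", paste(bad, collapse = ", "))
  fish <- meta$sample_type == "fish"
  if (any(fish) && (!"host_species" %in% names(meta) ||
                    any(is.na(meta$host_species[fish]) |
                        meta$host_species[fish] == ""))) {
    stop("every fish sample must have a host_species")
  }
  for (tc in intersect(trait_cols, names(meta))) {
    per_sp <- tapply(meta[[tc]][fish], meta$host_species[fish],
                     function(v) length(unique(v[!is.na(v)])))
    if (any(per_sp > 1, na.rm = TRUE)) {
      stop("trait '", tc, "' varies within a host species")
    }
  }
  meta
}

#' Individuals per host species
#'
#' @param meta metadata data frame.
#' @return named integer vector: number of fish samples per host species, in
#'   alphabetical species order.
#' @export
species_counts <- function(meta) {
  fish <- meta[meta$sample_type == "fish", ]
  tab <- table(fish$host_species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Filter host species by sampling depth
#'
#' Species-level tests in the pipeline run on species with at least
#' `min_individuals` sampled fish (2 for species-effect tests, 3 for
#' core-microbiome and the stricter phylosymbiosis subset).
#'
#' @param meta metadata data frame.
#' @param min_individuals minimum number of fish individuals.
#' @return character vector of retained species, alphabetical.
#' @export
species_filter <- function(meta, min_individuals = 1) {
  cnt <- species_counts(meta)
  sort(names(cnt)[cnt >= min_individuals])
}
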
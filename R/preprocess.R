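#' Rarefy a count table to even depth
#'
#' Each retained sample is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, correcting uneven sequencing
#' effort; samples with fewer than `depth` reads are dropped with a
#' warning. One draw per sample, seeded.
#'
#' @param table an [otu_table()] in counts mode.
#' @param depth target reads per sample (the study's value is 2000).
#' @param seed integer RNG seed.
#' @return a counts-mode [otu_table()] whose rows each sum to `depth`.
#' @export
rarefy <- function(table, depth = 2000, seed) {
  if (otu_mode(table) != "counts") stop("rarefy needs a counts table")
  if (depth <= 0) stop("depth must be positive")
  totals <- rowSums(table)
  drop <- totals < depth
  if (all(drop)) stop("no sample reaches the rarefaction depth")
  if (any(drop)) {
    warning(sum(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(table)[drop], 5), collapse = ", "))
  }
  m <- unclass(table)[!drop, , drop = FALSE]
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  set.seed(seed)
  for (i in seq_len(nrow(m))) {
    counts <- m[i, ]
    total <- sum(counts)
    if (total == depth) {
      out[i, ] <- as.integer(counts)
      next
    }
    reads <- rep.int(seq_along(counts), counts)
    take <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(take, nbins = ncol(m))
  }
  otu_table(out, "counts")
}

#' Convert counts to relative abundances
#'
#' @param table a counts-mode [otu_table()] with no all-zero sample.
#' @return a relative-mode [otu_table()]; every row sums to 1.
#' @export
to_relative <- function(table) {
  if (otu_mode(table) != "counts") stop("to_relative needs a counts table")
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(table)[totals == 0], collapse = ", "))
  }
  otu_table(unclass(table) / totals, "relative")
}

#' Subtract blank (contaminant) relative abundances
#'
#' For every non-blank sample, each OTU's relative abundance is reduced by
#' the mean relative abundance of that OTU across the blank samples,
#' clipped at zero. Rows are deliberately not renormalised by default (the
#' removed contaminant mass is recorded per sample instead); set
#' `renormalize = TRUE` to rescale rows back to 1.
#'
#' @param table a relative-mode [otu_table()] containing the blanks.
#' @param blank_ids sample ids of the blank samples.
#' @param renormalize rescale remaining abundances to sum to 1 (default
#'   FALSE, keeping the literal subtraction).
#' @return a relative-mode [otu_table()] without the blank rows; the per-
#'   sample subtracted mass is available via [removed_mass()].
#' @export
subtract_blanks <- function(table, blank_ids, renormalize = FALSE) {
  if (otu_mode(table) != "relative") stop("subtract_blanks needs a relative table")
  missing <- setdiff(blank_ids, rownames(table))
  if (length(missing)) stop("blank ids not in table: ", paste(missing, collapse = ", "))
  is_blank <- rownames(table) %in% blank_ids
  blank_mean <- colMeans(unclass(table)[is_blank, , drop = FALSE])
  m <- unclass(table)[!is_blank, , drop = FALSE]
  prev_removed <- removed_mass(table)[!is_blank]
  cleaned <- sweep(m, 2, blank_mean, `-`)
  cleaned[cleaned < 0] <- 0
  rm_mass <- (1 - prev_removed) - rowSums(cleaned)
  if (renormalize) {
    totals <- rowSums(cleaned)
    if (any(totals == 0)) stop("blank subtraction emptied a sample; cannot renormalize")
    return(otu_table(cleaned / totals, "relative"))
  }
  otu_table(cleaned, "relative", removed_mass = rm_mass + prev_removed)
}

#' Chao sample-coverage estimate
#'
#' Estimated fraction of the community's total abundance represented in the
#' sample (Chao-Jost coverage): with `f1` singletons, `f2` doubletons and
#' `n` reads,
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}.}
#' Returns 1 when there are no singletons; the degenerate one-read sample
#' (`f1 = n = 1`) returns 0, the formula's limit.
#'
#' @param sample_counts integer vector of OTU read counts for one sample.
#' @return coverage in `[0, 1]`.
#' @export
chao_coverage <- function(sample_counts) {
  n <- sum(sample_counts)
  if (n == 0) stop("empty sample")
  f1 <- sum(sample_counts == 1)
  f2 <- sum(sample_counts == 2)
  if (f1 == 0) return(1)
  if (n == 1) return(0)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

#' Per-sample Chao coverage for a whole table
#' @param table a counts-mode [otu_table()].
#' @return named numeric vector of coverage estimates.
#' @export
coverage_by_sample <- function(table) {
  if (otu_mode(table) != "counts") stop("coverage needs counts")
  apply(unclass(table), 1, chao_coverage)
}
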
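#' Derive a stream-specific seed from a master seed
#'
#' Deterministic 32-bit mixing so each pipeline stage / subsample gets an
#' independent, reproducible seed from one master seed.
#'
#' @param master integer master seed.
#' @param stream stage index or a string stage name (hashed).
#' @return positive integer below 2^31.
#' @export
derive_seed <- function(master, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  x <- (as.double(master) %% 2147483647) * 48271 + as.double(stream) * 1013904223
  as.integer(x %% 2147483629 + 1)
}

# add-one permutation p-value: never 0, never above 1
perm_pvalue <- function(n_ge, n_perm) (1 + n_ge) / (n_perm + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
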
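#' Fit Sloan's neutral community model
#'
#' Predicts each OTU's occurrence frequency across local communities from
#' its mean metacommunity relative abundance `p_i` and a single migration
#' rate `m`: with `N` reads per community and detection limit `d` reads,
#' \deqn{\hat F_i(m) = 1 - B\!\left(\frac{d}{N};\ N m p_i,\ N m (1 - p_i)\right)}
#' where `B` is the regularized incomplete beta CDF (the beta
#' approximation to the neutral stationary distribution). `m` is fitted by
#' least squares on the observed frequencies (bounded scalar optimisation
#' on (1e-6, 1]), and goodness of fit is
#' \eqn{R^2 = 1 - SSE / \sum_i (F_i - \bar F)^2} (can be negative). High
#' `m` means local communities track the source pool, as in plankton; low
#' `m` indicates dispersal limitation / host selection.
#'
#' @param table counts-mode [otu_table()] at uniform (post-rarefaction)
#'   depth, >= 10 samples.
#' @param detection_limit minimum reads to score an OTU present (default 1).
#' @return object of class `neutral_fit`: list with `m`, `r_squared`, `N`,
#'   `n_samples`, and a per-OTU data frame `otus` (`otu_id`, `p`,
#'   `freq_obs`, `freq_pred`, binomial 95% CI bounds `ci_lower`,
#'   `ci_upper`).
#' @export
fit_sloan <- function(table, detection_limit = 1) {
  if (otu_mode(table) != "counts") stop("fit_sloan needs a counts table")
  m_tab <- unclass(table)
  S <- nrow(m_tab)
  if (S < 10) stop("need at least 10 samples to fit the neutral model")
  depths <- rowSums(m_tab)
  if (max(depths) - min(depths) > 0) {
    stop("non-uniform sample depths; rarefy first")
  }
  N <- depths[1]
  keep <- colSums(m_tab) > 0
  m_tab <- m_tab[, keep, drop = FALSE]
  p <- colMeans(m_tab / N)
  f_obs <- colMeans(m_tab >= detection_limit)
  if (stats::sd(f_obs) == 0) stop("constant occurrence frequencies; R2 undefined")
  d_over_n <- detection_limit / N
  pred <- function(m) {
    stats::pbeta(d_over_n, N * m * p, N * m * (1 - p), lower.tail = FALSE)
  }
  sse <- function(m) sum((f_obs - pred(m))^2)
  opt <- stats::optimize(sse, c(1e-6, 1), tol = 1e-9)
  m_hat <- opt$minimum
  f_pred <- pred(m_hat)
  r2 <- 1 - opt$objective / sum((f_obs - mean(f_obs))^2)
  # binomial sampling band around the fitted curve
  ci_l <- stats::qbinom(0.025, S, f_pred) / S
  ci_u <- stats::qbinom(0.975, S, f_pred) / S
  structure(list(
    m = m_hat, r_squared = r2, N = N, n_samples = S,
    detection_limit = detection_limit,
    otus = data.frame(otu_id = colnames(m_tab), p = p, freq_obs = f_obs,
                      freq_pred = f_pred, ci_lower = ci_l, ci_upper = ci_u,
                      row.names = NULL)),
    class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model: m = %.4f, R2 = %.3f (%d samples, N = %d, %d OTUs)\n",
              x$m, x$r_squared, x$n_samples, x$N, nrow(x$otus)))
  invisible(x)
}
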
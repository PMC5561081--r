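#' Log2-transform a GEM
#'
#' Applies `log2` to every positive value. Non-positive values carry no
#' usable information on the log scale (and no rank information for
#' Spearman), so they become missing rather than being offset; existing
#' missing values stay missing.
#'
#' @param gem Numeric GEM matrix (linear units).
#' @return GEM of identical dimensions in log2 units.
#' @export
log2_transform <- function(gem) {
  out <- gem
  out[!is.na(out) & out <= 0] <- NA_real_
  out[!is.na(out)] <- log2(out[!is.na(out)])
  out
}

#' Kolmogorov-Smirnov sample-outlier screen
#'
#' For each sample, computes the two-sample KS statistic D_N of that
#' sample's non-missing values against the pooled non-missing values of all
#' other samples (leave-one-out reference), and flags samples with
#' D_N above `cutoff`. Samples are only flagged, never removed: whether to
#' drop a flagged sample is the caller's choice.
#'
#' @param gem Log-transformed GEM matrix.
#' @param cutoff Flagging threshold on D_N (default 0.15).
#' @return A tibble with columns `sample_id`, `d_n` and `flagged`, one row
#'   per sample. Samples with fewer than 2 non-missing values get
#'   `d_n = NA` and are flagged.
#' @export
ks_outlier_screen <- function(gem, cutoff = 0.15) {
  stopifnot(is.matrix(gem), ncol(gem) >= 2L)
  m <- ncol(gem)
  d_n <- vapply(seq_len(m), function(j) {
    x <- gem[, j]
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    y <- gem[, -j, drop = FALSE]
    y <- y[!is.na(y)]
    unname(suppressWarnings(stats::ks.test(x, y)$statistic))
  }, numeric(1))
  tibble::tibble(
    sample_id = colnames(gem),
    d_n = d_n,
    flagged = is.na(d_n) | d_n > cutoff
  )
}

#' Quantile-normalize a GEM across samples
#'
#' Classic quantile normalization: each sample's order statistics are
#' replaced by the across-sample mean of order statistics, so that after the
#' call every complete sample shares the same sorted value multiset. Ties
#' receive the average of their tied reference quantiles; samples with
#' missing values are normalized by interpolating the reference quantiles at
#' proportional rank positions within their observed values.
#'
#' @param gem Log-transformed GEM matrix (samples in columns).
#' @return Quantile-normalized GEM of identical dimensions and missingness.
#' @export
quantile_normalize <- function(gem) {
  stopifnot(is.matrix(gem))
  out <- limma::normalizeQuantiles(gem, ties = TRUE)
  dimnames(out) <- dimnames(gem)
  out
}

#' Run the standard GEM preprocessing chain
#'
#' Convenience wrapper applying, in order: log2 transform (optional),
#' KS sample screen (flagging only, or removal when `drop_flagged`), and
#' quantile normalization (optional).
#'
#' @param gem Numeric GEM matrix.
#' @param log2 Apply [log2_transform()] first? Default `TRUE` (set `FALSE`
#'   when the matrix is already on the log scale).
#' @param ks_cutoff D_N cutoff for [ks_outlier_screen()].
#' @param drop_flagged Remove flagged samples? Default `FALSE` (report only).
#' @param quantile Apply [quantile_normalize()]? Default `TRUE`.
#' @return A list with elements `gem` (processed matrix) and `report`
#'   (the KS screen tibble).
#' @export
preprocess_gem <- function(gem, log2 = TRUE, ks_cutoff = 0.15,
                           drop_flagged = FALSE, quantile = TRUE) {
  if (log2) gem <- log2_transform(gem)
  report <- ks_outlier_screen(gem, cutoff = ks_cutoff)
  if (drop_flagged && any(report$flagged)) {
    gem <- gem[, !report$flagged, drop = FALSE]
  }
  if (quantile) gem <- quantile_normalize(gem)
  list(gem = gem, report = report)
}
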
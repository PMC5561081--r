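# Fixtures are built in code at test time: small GEMs, pair-result tables
# and block-structured correlation fixtures.

# a small deterministic GEM with optional missing cells
make_gem <- function(n_genes = 5, n_samples = 4, seed = 42, missing = 0) {
  set.seed(seed)
  gem <- matrix(round(stats::runif(n_genes * n_samples, 1, 100), 3),
                n_genes, n_samples,
                dimnames = list(paste0("G", seq_len(n_genes)),
                                paste0("S", seq_len(n_samples))))
  if (missing > 0) gem[sample(length(gem), missing)] <- NA_real_
  gem
}

# pair-results tibble from a plain correlation matrix (one cluster per pair)
results_from_corr <- function(corr) {
  genes <- rownames(corr)
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  tibble::tibble(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    cluster_index = 1L, num_clusters = 1L, cluster_size = 100L,
    method = "spearman", rho = corr[idx], skip_reason = NA_character_,
    sample_string = ""
  )
}

# block-structured correlation fixture for the RMT transition:
# `n_blocks` modules of `block_size` genes with within-block correlations
# near `r_module`, and a dense background near `r_background` (i.i.d.
# noise entries, i.e. GOE-like below the background level)
make_block_corr <- function(n_blocks = 20, block_size = 15,
                            r_module = 0.9, r_background = 0.5,
                            sd_module = 0.02, sd_background = 0.08,
                            seed = 99) {
  set.seed(seed)
  n <- n_blocks * block_size
  corr <- matrix(pmin(0.98, pmax(0.01,
                                 stats::rnorm(n * n, r_background, sd_background))),
                 n, n)
  corr[lower.tri(corr)] <- t(corr)[lower.tri(corr)]
  block_of <- rep(seq_len(n_blocks), each = block_size)
  for (b in seq_len(n_blocks)) {
    ix <- which(block_of == b)
    vals <- matrix(pmin(0.98, stats::rnorm(length(ix)^2, r_module, sd_module)),
                   length(ix))
    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
    corr[ix, ix] <- vals
  }
  diag(corr) <- 1
  dimnames(corr) <- list(paste0("G", seq_len(n)), paste0("G", seq_len(n)))
  corr
}

# brute-force two-sample KS statistic: sup over pooled points of the
# empirical CDF difference
ks_stat_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# brute-force one-sided hypergeometric tail for a 2x2 table:
# P(X >= a) with X ~ Hyper(white = a+c, black = b+d, drawn = a+b)
fisher_p_oracle <- function(a, b, cc, d) {
  K <- a + cc
  N <- a + b + cc + d
  n <- a + b
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}

# pairwise-comparison AUROC oracle (U-statistic with half credit for ties)
auroc_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Spearman oracle: Pearson product-moment formula on average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# unfolded spacings of one GOE matrix (symmetric Gaussian ensemble)
goe_spacings <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n * n), n)
  ev <- eigen((a + t(a)) / sqrt(2 * n), symmetric = TRUE,
              only.values = TRUE)$values
  unfold_spectrum(ev, min_count = min(100L, n - 1L))
}
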
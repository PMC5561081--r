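test_that("power-analysis minimum cluster size matches the Fisher-z bound", {
  expect_identical(min_cluster_size_power(0.05, 0.2, 0.5), 30L)
  # independent evaluation of the closed form at a large effect
  z <- qnorm(1 - 0.05 / 2) + qnorm(1 - 0.2)
  expect_identical(min_cluster_size_power(0.05, 0.2, 0.9),
                   as.integer(ceiling((z / atanh(0.9))^2 + 3)))
  # atanh diverges as the effect approaches 1: the bound collapses to 4
  expect_identical(min_cluster_size_power(0.05, 0.2, 1 - 1e-12), 4L)
  expect_error(min_cluster_size_power(0, 0.2, 0.5), "alpha")
  expect_error(min_cluster_size_power(0.05, 1, 0.5), "beta")
  expect_error(min_cluster_size_power(0.05, 0.2, 1.5), "effect_size")
})

test_that("pair counting follows the closed form", {
  expect_identical(count_pairs(2), 1)
  expect_identical(count_pairs(1000), 499500)
  expect_identical(count_pairs(1), 0)
  expect_identical(count_pairs(76300), 76300 * 76299 / 2)
})

test_that("assemble_pair marks missing samples with 9 and keeps GEM order", {
  gem <- make_gem(3, 7, seed = 2)
  asm <- assemble_pair(gem, "G1", "G2")
  expect_identical(length(asm$digits), 7L)
  expect_true(all(asm$digits == "0"))
  expect_identical(nrow(asm$points), 7L)

  gem["G1", c(2, 5)] <- NA
  asm <- assemble_pair(gem, "G1", "G2")
  expect_identical(asm$digits[c(2, 5)], c("9", "9"))
  expect_identical(nrow(asm$points), 5L)
  expect_equal(asm$points[, 2], unname(gem["G2", -c(2, 5)]))
})

test_that("Tukey-fence outlier flagging matches a quartile oracle", {
  pts <- matrix(1, 10, 2)
  expect_false(any(flag_outliers_pre(pts)))       # zero IQR, fences collapse

  pts <- rbind(matrix(0, 19, 2), c(100, 0))
  flags <- flag_outliers_pre(pts)
  q <- quantile(pts[, 1], c(0.25, 0.75), names = FALSE)
  upper_fence <- q[2] + 1.5 * (q[2] - q[1])
  expect_identical(which(flags), 20L)
  expect_gt(100, upper_fence)

  expect_false(any(flag_outliers_pre(pts, rule = "none")))
})

test_that("clusters below the size or range filters are skipped with reasons", {
  set.seed(4)
  gem29 <- matrix(rnorm(2 * 29, 5), 2, 29,
                  dimnames = list(c("G1", "G2"), paste0("S", 1:29)))
  cfg <- pairwise_config(use_gmm = FALSE, outlier_rule = "none")
  res <- cluster_and_correlate(gem29, "G1", "G2", cfg)
  expect_identical(res$skip_reason, "below min_cluster_size")
  expect_true(is.na(res$rho))

  gem40 <- rbind(G1 = 5 + runif(40) * 0.05, G2 = rnorm(40, 5))
  colnames(gem40) <- paste0("S", 1:40)
  res <- cluster_and_correlate(gem40, "G1", "G2", cfg)
  expect_identical(res$skip_reason, "below range")
})

test_that("a perfect monotone pair gives rho = 1 in non-GMM Spearman mode", {
  x <- seq(1, 5, length.out = 40)
  gem <- rbind(G1 = x, G2 = x)
  colnames(gem) <- paste0("S", 1:40)
  cfg <- pairwise_config(use_gmm = FALSE, outlier_rule = "none")
  res <- cluster_and_correlate(gem, "G1", "G2", cfg)
  expect_identical(res$rho, 1)
  expect_identical(res$cluster_size, 40L)
  expect_identical(res$sample_string, strrep("1", 40))
})

test_that("planted modes are separated and per-cluster Spearman matches a rank oracle", {
  set.seed(10)
  z <- rnorm(50)
  x <- c(2 + z, rnorm(50, 10))
  y <- c(2 + 0.975 * z + sqrt(1 - 0.975^2) * rnorm(50), rnorm(50, 10))
  gem <- rbind(G1 = x, G2 = y)
  colnames(gem) <- paste0("S", 1:100)
  cfg <- pairwise_config(outlier_rule = "none", seed = 5)
  res <- cluster_and_correlate(gem, "G1", "G2", cfg)
  expect_identical(unique(res$num_clusters), 2L)
  rhos <- sort(abs(res$rho))
  expect_lte(rhos[1], 0.3)
  expect_gte(rhos[2], 0.8)
  # oracle equivalence on the subsets defined by the sample strings
  for (r in seq_len(nrow(res))) {
    if (is.na(res$rho[r])) next
    members <- strsplit(res$sample_string[r], "")[[1]] == "1"
    expect_equal(res$rho[r], spearman_oracle(x[members], y[members]),
                 tolerance = 1e-12)
  }
})

test_that("sample-string digits partition the samples consistently", {
  set.seed(20)
  cfg <- pairwise_config(min_cluster_size = 5, seed = 3)
  gem <- make_gem(6, 60, seed = 21, missing = 25)
  gem <- gem + 4  # keep values positive and spread
  res <- gem_similarity(gem, cfg)
  for (key in unique(paste(res$gene_a, res$gene_b))) {
    rows <- res[paste(res$gene_a, res$gene_b) == key, ]
    digs <- do.call(rbind, strsplit(rows$sample_string, ""))
    expect_true(all(digs %in% c("0", "1", "6", "8", "9")))
    # 9 (missing) and 6 (pre-cluster outlier) identical across cluster strings
    for (d in c("9", "6")) {
      hit <- digs == d
      expect_true(all(colSums(hit) %in% c(0L, nrow(digs))))
    }
    # each sample is in at most one cluster
    expect_true(all(colSums(digs == "1") <= 1))
    # cluster members (1s and within-cluster outliers) cover all observed,
    # non-pre-outlier samples exactly once
    if (!any(is.na(rows$cluster_index))) {
      observed <- colSums(digs[, , drop = FALSE] == "9") == 0 &
        colSums(digs == "6") == 0
      expect_identical(sum(digs %in% c("1", "8")), sum(observed))
    }
  }
})

test_that("pair order does not change the result", {
  set.seed(30)
  gem <- make_gem(3, 50, seed = 31)
  cfg <- pairwise_config(min_cluster_size = 5, seed = 7)
  r_ij <- cluster_and_correlate(gem, "G1", "G3", cfg)
  r_ji <- cluster_and_correlate(gem, "G3", "G1", cfg)
  expect_equal(r_ij$rho, r_ji$rho)
  expect_identical(r_ij$cluster_size, r_ji$cluster_size)
  expect_identical(r_ij$sample_string, r_ji$sample_string)
})

test_that("non-GMM mode with no outlier rule reproduces plain correlation", {
  set.seed(40)
  gem <- make_gem(4, 45, seed = 41, missing = 6)
  cfg <- pairwise_config(use_gmm = FALSE, outlier_rule = "none",
                         min_cluster_size = 3)
  res <- gem_similarity(gem, cfg)
  for (r in seq_len(nrow(res))) {
    x <- gem[res$gene_a[r], ]
    y <- gem[res$gene_b[r], ]
    expect_equal(res$rho[r],
                 cor(x, y, method = "spearman", use = "complete.obs"),
                 tolerance = 1e-12)
  }
})

test_that("pairs with almost no complete observations are reported, not dropped", {
  gem <- make_gem(2, 5, seed = 50)
  gem["G1", 1:4] <- NA
  res <- cluster_and_correlate(gem, "G1", "G2", pairwise_config())
  expect_identical(res$num_clusters, 0L)
  expect_identical(res$skip_reason, "insufficient data")
  expect_identical(substr(res$sample_string, 1, 4), "9999")
})
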
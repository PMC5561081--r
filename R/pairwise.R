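#' Minimum cluster size from a correlation power analysis
#'
#' Classical Fisher-z sample-size bound for detecting a correlation of
#' magnitude `effect_size` at two-sided significance `alpha` and power
#' `1 - beta`:
#' `n = ceil(((z_{1-alpha/2} + z_{1-beta}) / atanh(r))^2 + 3)`.
#' With the conventional alpha = 0.05, beta = 0.2 and a moderate effect of
#' 0.5 this yields 30, the default minimum number of samples a cluster must
#' contain before it is correlated.
#'
#' @param alpha Two-sided false-positive rate, in (0, 1).
#' @param beta False-negative rate, in (0, 1).
#' @param effect_size Target correlation magnitude, in (0, 1).
#' @return Integer minimum sample count.
#' @export
min_cluster_size_power <- function(alpha = 0.05, beta = 0.2, effect_size = 0.5) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (!(beta > 0 && beta < 1)) stop("beta must be in (0,1)", call. = FALSE)
  if (!(effect_size > 0 && effect_size < 1)) {
    stop("effect_size must be in (0,1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta)
  as.integer(ceiling((z / atanh(effect_size))^2 + 3))
}

#' Number of unordered transcript pairs
#'
#' `n * (n - 1) / 2`, returned as a double (the count overflows 32-bit
#' integers for genome-scale n). Returns 0 for n < 2.
#'
#' @param n Number of transcripts.
#' @return Pair count.
#' @export
count_pairs <- function(n) {
  n <- as.numeric(n)
  if (n < 2) return(0)
  n * (n - 1) / 2
}

#' Pairwise analysis configuration
#'
#' Bundles every tunable of the per-pair pipeline. Defaults follow the
#' method's operating point: Spearman correlation per cluster, GMM mode
#' discovery on, minimum correlated cluster size from the executable power
#' analysis ([min_cluster_size_power()], i.e. 30), a minimum within-cluster
#' expression range of 0.1 log2 units for both genes, and 1.5 x IQR Tukey
#' fences for the two outlier-removal steps.
#'
#' @param method Correlation method, `"spearman"` or `"pearson"`.
#' @param use_gmm Decompose each pair into Gaussian mixture clusters before
#'   correlating? `FALSE` reproduces a plain all-samples correlation network.
#' @param min_cluster_size Minimum surviving samples for a cluster to be
#'   correlated (must be >= 3).
#' @param min_expression_range Minimum within-cluster range (both genes).
#' @param K_max,restarts,seed Passed to [select_components()].
#' @param outlier_rule `"iqr_1_5"` (1.5 x IQR fences, applied once before
#'   clustering and once within each cluster) or `"none"`.
#' @return A list of class `pairwise_config`.
#' @export
pairwise_config <- function(method = c("spearman", "pearson"),
                            use_gmm = TRUE,
                            min_cluster_size = min_cluster_size_power(),
                            min_expression_range = 0.1,
                            K_max = 5L, restarts = 3L, seed = 1L,
                            outlier_rule = c("iqr_1_5", "none")) {
  method <- match.arg(method)
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(min_cluster_size >= 3L, min_expression_range >= 0)
  structure(
    list(method = method, use_gmm = use_gmm,
         min_cluster_size = as.integer(min_cluster_size),
         min_expression_range = min_expression_range,
         K_max = as.integer(K_max), restarts = as.integer(restarts),
         seed = as.integer(seed), outlier_rule = outlier_rule),
    class = "pairwise_config"
  )
}

#' Assemble the complete observations of one gene pair
#'
#' Samples missing in either gene are marked with digit `9` and excluded;
#' the remaining samples form the N x 2 point matrix in GEM column order,
#' with template digit `0` (observed, membership undecided).
#'
#' @param gem GEM matrix.
#' @param i,j Transcript ids or row indices (distinct).
#' @return List with `points` (N x 2 matrix), `observed` (column indices of
#'   the GEM backing the rows of `points`) and `digits` (length-M character
#'   vector over the sample-string alphabet).
#' @export
assemble_pair <- function(gem, i, j) {
  if (is.character(i)) i <- match(i, rownames(gem))
  if (is.character(j)) j <- match(j, rownames(gem))
  stopifnot(!is.na(i), !is.na(j), i != j)
  x <- unname(gem[i, ])
  y <- unname(gem[j, ])
  ok <- !is.na(x) & !is.na(y)
  digits <- ifelse(ok, "0", "9")
  list(points = cbind(x[ok], y[ok], deparse.level = 0),
       observed = which(ok), digits = digits)
}

#' Flag outliers by per-axis Tukey fences
#'
#' Under the `iqr_1_5` rule a point is an outlier if either coordinate lies
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of that coordinate. Fewer than 4
#' points, or rule `"none"`, flags nothing.
#'
#' @param points N x 2 matrix.
#' @param rule `"iqr_1_5"` or `"none"`.
#' @return Logical vector of length N.
#' @export
flag_outliers_pre <- function(points, rule = "iqr_1_5") {
  n <- nrow(points)
  if (rule == "none" || n < 4L) return(rep(FALSE, n))
  out <- rep(FALSE, n)
  for (d in 1:2) {
    q <- stats::quantile(points[, d], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- out | points[, d] < q[1] - 1.5 * iqr | points[, d] > q[2] + 1.5 * iqr
  }
  out
}

empty_pair_result <- function(gene_a, gene_b, method, reason, digits) {
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    cluster_index = NA_integer_, num_clusters = 0L,
    cluster_size = NA_integer_, method = method, rho = NA_real_,
    skip_reason = reason, sample_string = paste(digits, collapse = "")
  )
}

#' Cluster one gene pair and correlate each qualifying cluster
#'
#' The per-pair pipeline: assemble complete observations (missing -> digit
#' `9`), remove pre-clustering outliers (digit `6`), discover sample
#' clusters with an ICL-selected Gaussian mixture (unless `use_gmm` is
#' off, in which case all points form one cluster), then per cluster flag
#' within-cluster outliers by the same rule (digit `8`) and — when the
#' surviving size reaches `min_cluster_size` and both genes span at least
#' `min_expression_range` within the cluster — compute the configured
#' correlation over the survivors. Digit `1` marks a cluster's surviving
#' members; `0` marks observed samples outside it. Clusters failing a
#' filter keep `rho = NA` with a machine-readable `skip_reason`.
#'
#' @param gem GEM matrix.
#' @param i,j Transcript ids or row indices.
#' @param cfg A [pairwise_config()].
#' @return A tibble with one row per cluster (columns `gene_a`, `gene_b`,
#'   `cluster_index`, `num_clusters`, `cluster_size`, `method`, `rho`,
#'   `skip_reason`, `sample_string`), or a single zero-cluster row when the
#'   pair has insufficient data or a degenerate fit.
#' @export
cluster_and_correlate <- function(gem, i, j, cfg = pairwise_config()) {
  ga <- if (is.character(i)) i else rownames(gem)[i]
  gb <- if (is.character(j)) j else rownames(gem)[j]
  asm <- assemble_pair(gem, i, j)
  if (nrow(asm$points) < 2L) {
    return(empty_pair_result(ga, gb, cfg$method, "insufficient data", asm$digits))
  }
  digits <- asm$digits
  pre_out <- flag_outliers_pre(asm$points, cfg$outlier_rule)
  digits[asm$observed[pre_out]] <- "6"
  points <- asm$points[!pre_out, , drop = FALSE]
  kept <- asm$observed[!pre_out]
  if (nrow(points) < 2L) {
    return(empty_pair_result(ga, gb, cfg$method, "insufficient data", digits))
  }

  if (cfg$use_gmm) {
    fit <- tryCatch(
      select_components(points, K_max = cfg$K_max, seed = cfg$seed,
                        restarts = cfg$restarts),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(empty_pair_result(ga, gb, cfg$method, "degenerate fit", digits))
    }
    labels <- fit$labels
  } else {
    labels <- rep(1L, nrow(points))
  }

  # relabel clusters 1..K by decreasing size for a deterministic output order
  sizes <- table(labels)
  order_k <- as.integer(names(sort(sizes, decreasing = TRUE)))
  rows <- purrr::map(seq_along(order_k), function(ci) {
    members <- which(labels == order_k[ci])
    pts <- points[members, , drop = FALSE]
    in_out <- flag_outliers_pre(pts, cfg$outlier_rule)
    surv <- members[!in_out]
    d <- digits
    d[kept[members[in_out]]] <- "8"
    d[kept[surv]] <- "1"
    n_surv <- length(surv)
    rho <- NA_real_
    reason <- NA_character_
    if (n_surv < cfg$min_cluster_size) {
      reason <- "below min_cluster_size"
    } else {
      rng <- apply(points[surv, , drop = FALSE], 2, function(v) diff(range(v)))
      if (any(rng < cfg$min_expression_range)) {
        reason <- "below range"
      } else {
        rho <- stats::cor(points[surv, 1], points[surv, 2], method = cfg$method)
        # snap floating-point-perfect correlations so the downstream
        # rho = 1.0 removal rule sees them
        if (1 - abs(rho) < 1e-12) rho <- sign(rho)
      }
    }
    tibble::tibble(
      gene_a = ga, gene_b = gb, cluster_index = ci,
      num_clusters = length(order_k), cluster_size = n_surv,
      method = cfg$method, rho = rho, skip_reason = reason,
      sample_string = paste(d, collapse = "")
    )
  })
  dplyr::bind_rows(rows)
}

pair_index_to_ij <- function(p, n) {
  # 0-based pair index -> (i, j), row-major upper triangle, 1-based output
  i <- 1L
  offset <- 0L
  while (p >= offset + (n - i)) {
    offset <- offset + (n - i)
    i <- i + 1L
  }
  c(i, i + 1L + (p - offset))
}

#' All-pairs similarity over a GEM
#'
#' Enumerates transcript pairs in row-major upper-triangle order of the GEM
#' and runs [cluster_and_correlate()] on each. The optional `chunk` window
#' `(start, end]`-style half-open 0-based pair-index range makes runs
#' embarrassingly parallel: chunked outputs concatenate to exactly the
#' unchunked output, because every pair's mixture seed is derived from the
#' global pair index, never from the chunk.
#'
#' @param gem GEM matrix.
#' @param cfg A [pairwise_config()].
#' @param chunk `NULL` for all pairs, or `c(start, end)` (0-based, half-open)
#'   selecting global pair indices `start .. end-1`.
#' @param progress Print a progress message every 1000 pairs?
#' @return Tibble of per-cluster results (see [cluster_and_correlate()]).
#' @export
gem_similarity <- function(gem, cfg = pairwise_config(), chunk = NULL,
                           progress = FALSE) {
  n <- nrow(gem)
  total <- count_pairs(n)
  if (is.null(chunk)) chunk <- c(0, total)
  stopifnot(chunk[1] >= 0, chunk[2] <= total, chunk[1] <= chunk[2])
  if (chunk[1] == chunk[2]) return(empty_pair_result("x", "y", cfg$method, "", "")[0, ])
  p_range <- seq(chunk[1], chunk[2] - 1)
  ij0 <- pair_index_to_ij(p_range[1], n)
  i <- ij0[1]; j <- ij0[2]
  out <- vector("list", length(p_range))
  for (k in seq_along(p_range)) {
    p <- p_range[k]
    pair_cfg <- cfg
    pair_cfg$seed <- as.integer((cfg$seed * 1009 + p) %% (.Machine$integer.max - 1L)) + 1L
    out[[k]] <- cluster_and_correlate(gem, i, j, pair_cfg)
    if (progress && k %% 1000L == 0L) {
      message("pair ", k, " / ", length(p_range))
    }
    j <- j + 1L
    if (j > n) { i <- i + 1L; j <- i + 1L }
  }
  dplyr::bind_rows(out)
}
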
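#' Thresholded similarity matrix from pairwise results
#'
#' Reduces each pair's clusters to a single similarity (the maximum |rho|
#' over non-skipped clusters — "is there ANY significant relationship"),
#' zeroes entries below `tau`, drops transcripts with no surviving entry,
#' and sets a unit diagonal. The result feeds the eigenvalue analysis of
#' [find_threshold()].
#'
#' @param results Pairwise results tibble from [gem_similarity()].
#' @param tau Threshold in (0, 1).
#' @param reduction Only `"max_abs"` is defined.
#' @return Symmetric numeric matrix (possibly 0 x 0 when nothing survives).
#' @export
similarity_matrix_at <- function(results, tau, reduction = "max_abs") {
  stopifnot(reduction == "max_abs")
  pairs <- results |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(s = max(abs(.data$rho)), .groups = "drop") |>
    dplyr::filter(.data$s >= tau)
  if (nrow(pairs) == 0L) {
    return(matrix(numeric(0), 0, 0))
  }
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  m[cbind(ia, ib)] <- pairs$s
  m[cbind(ib, ia)] <- pairs$s
  diag(m) <- 1
  m
}

#' Unfold an eigenvalue spectrum to unit mean spacing
#'
#' Standard spectral unfolding for nearest-neighbour spacing analysis:
#' near-duplicate eigenvalues are pruned (tolerance `dup_tol`; degenerate
#' eigenvalues break the spacing statistics), a monotone cubic spline with
#' `knots` knots is fit to the cumulative spectral density, eigenvalues are
#' mapped through it, and successive differences are rescaled to mean 1.
#'
#' @param eigenvalues Numeric vector (any order).
#' @param knots Spline knots for the cumulative density (default 10).
#' @param min_count Minimum eigenvalues required after pruning (default 100).
#' @param dup_tol Near-duplicate pruning tolerance (default 1e-6).
#' @return Numeric vector of unfolded spacings with mean 1.
#' @export
unfold_spectrum <- function(eigenvalues, knots = 10L, min_count = 100L,
                            dup_tol = 1e-6) {
  ev <- sort(eigenvalues)
  keep <- c(TRUE, diff(ev) > dup_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < min_count) {
    stop("matrix too small for NNSD: ", n, " distinct eigenvalues (need ",
         min_count, ")", call. = FALSE)
  }
  idx <- unique(round(seq(1L, n, length.out = knots)))
  spl <- stats::splinefun(ev[idx], idx, method = "hyman")
  xi <- spl(ev)
  s <- diff(xi)
  s / mean(s)
}

#' Chi-square of a spacing distribution against the Poisson NNSD
#'
#' Histograms the spacings on `[0, s_max]` with `n_bins` equal bins plus an
#' implicit tail bin, compares observed counts with the Poisson (i.e.
#' uncorrelated-eigenvalue) expectation `N * (exp(-a) - exp(-b))` per bin,
#' and returns the chi-square statistic. Bins with small expected counts
#' are merged rightwards into their neighbour (minimum expected count 5).
#' A small value means the spacings look Poisson — the signature of a
#' modular (block-diagonal) correlation structure; GOE (Wigner-Dyson)
#' spacings from correlated noise give a large value.
#'
#' @param spacings Unfolded spacings (mean approximately 1); at least 60.
#' @param n_bins Number of bins on `[0, s_max]` (default 60).
#' @param s_max Histogram upper limit (default 3).
#' @return The chi-square statistic.
#' @export
nnsd_poisson_chi2 <- function(spacings, n_bins = 60L, s_max = 3) {
  N <- length(spacings)
  if (N < 60L) stop("need at least 60 spacings", call. = FALSE)
  breaks <- seq(0, s_max, length.out = n_bins + 1L)
  obs <- c(tabulate(findInterval(spacings, breaks,
                                 rightmost.closed = FALSE, left.open = FALSE),
                    nbins = n_bins + 1L))
  # findInterval returns n_bins+1 for the tail [s_max, Inf)
  expd <- c(N * (exp(-breaks[-length(breaks)]) - exp(-breaks[-1L])),
            N * exp(-s_max))
  # merge low-expectation bins into their left neighbour, from the right
  i <- length(expd)
  while (i > 1L) {
    if (expd[i] < 5) {
      expd[i - 1L] <- expd[i - 1L] + expd[i]
      obs[i - 1L] <- obs[i - 1L] + obs[i]
      expd <- expd[-i]
      obs <- obs[-i]
    }
    i <- i - 1L
  }
  sum((obs - expd)^2 / expd)
}

#' Scan correlation thresholds for the GOE-to-Poisson transition
#'
#' Random-matrix-theory thresholding: ascend candidate thresholds from
#' `tau_start` in steps of `tau_step`; at each, build the thresholded
#' similarity matrix, take its eigenvalues, unfold, and test the
#' nearest-neighbour spacing distribution against Poisson. The chosen
#' threshold is the first whose chi-square falls to or below `chi2_crit` —
#' the point where correlated noise has been stripped away and only modular
#' signal remains. The scan stops early (with no chosen threshold) when the
#' surviving matrix becomes too small for spacing statistics.
#'
#' @param results Pairwise results tibble.
#' @param tau_start First candidate threshold (default 0.5).
#' @param tau_step Scan increment (default 0.001).
#' @param chi2_crit Acceptance cutoff; default `qchisq(0.999, 59)`, the
#'   0.001-level critical value for the default 60-bin histogram.
#' @param min_eigen Minimum eigenvalue count for NNSD (default 100).
#' @param n_bins,s_max Passed to [nnsd_poisson_chi2()].
#' @param knots Passed to [unfold_spectrum()].
#' @return An `rmt_scan` object: tibble of `(tau, matrix_size, chi2)` plus
#'   `chosen_tau` (NA when the scan exhausted) and a `diagnostic` message.
#' @export
find_threshold <- function(results, tau_start = 0.5, tau_step = 0.001,
                           chi2_crit = stats::qchisq(0.999, 59),
                           min_eigen = 100L, n_bins = 60L, s_max = 3,
                           knots = 10L) {
  stopifnot(tau_start > 0, tau_start < 1, tau_step > 0)
  taus <- c()
  sizes <- c()
  chi2s <- c()
  chosen <- NA_real_
  diagnostic <- "scan exhausted: threshold reached 1 before Poisson statistics"
  tau <- tau_start
  while (tau < 1) {
    m <- similarity_matrix_at(results, tau)
    if (nrow(m) < min_eigen) {
      diagnostic <- paste0("scan stopped at tau = ", signif(tau, 6),
                           ": matrix too small for NNSD (", nrow(m),
                           " transcripts)")
      break
    }
    chi2 <- tryCatch({
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      sp <- unfold_spectrum(ev, knots = knots, min_count = min_eigen)
      nnsd_poisson_chi2(sp, n_bins = n_bins, s_max = s_max)
    }, error = function(e) e)
    if (inherits(chi2, "error")) {
      diagnostic <- paste0("scan stopped at tau = ", signif(tau, 6), ": ",
                           conditionMessage(chi2))
      break
    }
    taus <- c(taus, tau)
    sizes <- c(sizes, nrow(m))
    chi2s <- c(chi2s, chi2)
    if (chi2 <= chi2_crit) {
      chosen <- tau
      diagnostic <- "NNSD consistent with Poisson at chosen threshold"
      break
    }
    tau <- tau + tau_step
  }
  structure(
    list(scan = tibble::tibble(tau = taus, matrix_size = sizes, chi2 = chi2s),
         chosen_tau = chosen, chi2_crit = chi2_crit, diagnostic = diagnostic),
    class = "rmt_scan"
  )
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat("RMT threshold scan: ", nrow(x$scan), " thresholds tested\n", sep = "")
  if (is.na(x$chosen_tau)) {
    cat("  no threshold chosen (", x$diagnostic, ")\n", sep = "")
  } else {
    cat("  chosen tau = ", x$chosen_tau, " (chi2 <= ",
        format(x$chi2_crit, digits = 5), ")\n", sep = "")
  }
  invisible(x)
}
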
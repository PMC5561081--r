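#' @useDynLib comodnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

n_free_params <- function(K, family) {
  switch(family,
    free_full = (K - 1L) + 2L * K + 3L * K,
    # free volumes + common shape/orientation (det-1 matrix: d(d+1)/2 - 1 = 2)
    free_volume_common_shape = (K - 1L) + 2L * K + K + 2L,
    stop("unknown model family: ", family, call. = FALSE)
  )
}

new_gmm_fit <- function(res, K, N, family, points) {
  resp <- res$responsibilities
  fit <- structure(
    list(
      K = K,
      N = N,
      family = family,
      points = points,
      proportions = as.numeric(res$proportions),
      means = res$means,
      covariances = res$covariances,
      responsibilities = resp,
      labels = max.col(resp, ties.method = "first"),
      log_likelihood = res$log_likelihood,
      loglik_trace = as.numeric(res$loglik_trace),
      converged = res$converged
    ),
    class = "gmm_fit"
  )
  fit$bic <- score_bic(fit, N)
  fit$icl <- score_icl(fit, N)
  fit
}

#' Fit a bivariate Gaussian mixture by EM
#'
#' Expectation-maximization with the random initialization used by mixture
#' software for unsupervised pairwise clustering: each component mean starts
#' at a distinct randomly drawn data point, mixing proportions start uniform
#' at 1/K, and every covariance starts at the pooled sample covariance.
#' Iteration stops when the relative log-likelihood change falls below
#' `tol` or after `max_iter` iterations. A collapsed (singular-covariance)
#' component triggers a fresh seeded restart, up to `retries` attempts.
#'
#' @param points N x 2 numeric matrix, no missing values.
#' @param K Number of mixture components (N >= K).
#' @param family Covariance family: `"free_full"` (every component's
#'   proportion and full covariance free, the default) or
#'   `"free_volume_common_shape"` (per-component volume, shared shape and
#'   orientation).
#' @param seed Integer seed controlling the initialization draws.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param retries Restart attempts after a degenerate fit (default 5).
#' @return An object of class `gmm_fit`: component count `K`, `proportions`,
#'   `means` (2 x K), `covariances` (2 x 2 x K), `responsibilities` (N x K),
#'   hard `labels`, `log_likelihood`, the per-iteration `loglik_trace`, and
#'   the `bic` / `icl` scores (lower is better).
#' @export
fit_em <- function(points, K, family = c("free_full", "free_volume_common_shape"),
                   seed = 1L, max_iter = 100L, tol = 1e-6, retries = 5L) {
  family <- match.arg(family)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, !anyNA(points))
  N <- nrow(points)
  if (N < K) stop("need at least K points (N = ", N, ", K = ", K, ")",
                  call. = FALSE)
  fam_code <- if (family == "free_full") 0L else 1L
  withr::local_seed(seed)
  for (attempt in seq_len(retries + 1L)) {
    idx <- sample.int(N, K) - 1L  # distinct data points, 0-based for C++
    res <- em_fit_cpp(points, K, idx, fam_code, max_iter, tol)
    if (!isTRUE(res$singular)) {
      return(new_gmm_fit(res, K, N, family, points))
    }
  }
  stop("degenerate fit: all EM restarts collapsed for K = ", K, call. = FALSE)
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = -2 * log_likelihood + nu * log(N)` where `nu` counts the free
#' parameters of the covariance family (for the free-full bivariate family,
#' `nu = 6K - 1`). Lower is better.
#'
#' @param fit A `gmm_fit`.
#' @param N Number of observations the model was fit to.
#' @return The BIC value.
#' @export
score_bic <- function(fit, N) {
  if (N < 2L) stop("BIC requires N >= 2", call. = FALSE)
  nu <- n_free_params(fit$K, fit$family)
  -2 * fit$log_likelihood + nu * log(N)
}

#' Integrated completed likelihood of a mixture fit
#'
#' `ICL = BIC + 2 * ENT` with `ENT = -sum(t_ik * log(t_ik))` the entropy of
#' the soft assignments (`0 * log 0 = 0`). The entropy term penalizes
#' overlapping components, so ICL favours well-separated subpopulations —
#' the behaviour wanted when components are read as distinct sample
#' conditions. Lower is better, and `ICL >= BIC` always.
#'
#' @inheritParams score_bic
#' @return The ICL value.
#' @export
score_icl <- function(fit, N) {
  t_ik <- fit$responsibilities
  lt <- log(t_ik)
  lt[t_ik == 0] <- 0
  ent <- -sum(t_ik * lt)
  score_bic(fit, N) + 2 * ent
}

#' Select the number of mixture components by ICL
#'
#' For each K from 1 up to `min(K_max, floor(N/2))`, runs `restarts` seeded
#' EM fits (a single run at K = 1, whose optimum is closed-form), keeps the
#' best log-likelihood per K, and returns the fit minimizing ICL. No a
#' priori component count is needed — only the upper limit.
#'
#' @inheritParams fit_em
#' @param K_max Upper limit on the component count (default 5).
#' @param restarts Seeded EM runs per K (default 3).
#' @return The ICL-optimal `gmm_fit`.
#' @export
select_components <- function(points, K_max = 5L,
                              family = c("free_full", "free_volume_common_shape"),
                              seed = 1L, restarts = 3L, max_iter = 100L,
                              tol = 1e-6) {
  family <- match.arg(family)
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < 2L) stop("need at least 2 points", call. = FALSE)
  K_feasible <- max(1L, min(K_max, N %/% 2L))
  # one EM run at K = 1 (its optimum is closed-form), `restarts` otherwise
  run_K <- unlist(lapply(seq_len(K_feasible),
                         function(K) rep(K, if (K == 1L) 1L else restarts)))
  withr::local_seed(seed)
  inits <- lapply(run_K, function(K) sample.int(N, K) - 1L)
  fam_code <- if (family == "free_full") 0L else 1L
  per_k <- select_scan_cpp(points, inits, as.integer(run_K), fam_code,
                           max_iter, tol)
  best <- NULL
  for (K in seq_along(per_k)) {
    if (is.null(per_k[[K]])) next
    fit <- new_gmm_fit(per_k[[K]], K, N, family, points)
    if (is.null(best) || fit$icl < best$icl) best <- fit
  }
  if (is.null(best)) stop("no valid model: every K was degenerate", call. = FALSE)
  best
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Bivariate Gaussian mixture (", x$family, ")\n", sep = "")
  cat("  K = ", x$K, ", N = ", x$N,
      ", logLik = ", format(x$log_likelihood, digits = 6),
      ", BIC = ", format(x$bic, digits = 6),
      ", ICL = ", format(x$icl, digits = 6), "\n", sep = "")
  invisible(x)
}
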
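#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Tidy a mixture fit into one row per component
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return Tibble with component index, proportion, mean and covariance
#'   entries, and hard-assignment size.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    proportion = x$proportions,
    mean_x = x$means[1, ],
    mean_y = x$means[2, ],
    var_x = vapply(seq_len(x$K), function(k) x$covariances[1, 1, k], 0),
    var_y = vapply(seq_len(x$K), function(k) x$covariances[2, 2, k], 0),
    cov_xy = vapply(seq_len(x$K), function(k) x$covariances[1, 2, k], 0),
    size = as.integer(tabulate(x$labels, nbins = x$K))
  )
}

#' One-row model summary of a mixture fit
#'
#' @inheritParams tidy.gmm_fit
#' @return Tibble with `K`, `N`, `family`, `log_likelihood`, `bic`, `icl`,
#'   `converged`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(K = x$K, N = x$N, family = x$family,
                 log_likelihood = x$log_likelihood,
                 bic = x$bic, icl = x$icl, converged = x$converged)
}

#' Tidy an RMT scan into its (tau, matrix_size, chi2) trajectory
#'
#' @param x An `rmt_scan`.
#' @param ... Unused.
#' @export
tidy.rmt_scan <- function(x, ...) x$scan

#' One-row summary of an RMT scan
#'
#' @inheritParams tidy.rmt_scan
#' @export
glance.rmt_scan <- function(x, ...) {
  tibble::tibble(chosen_tau = x$chosen_tau, chi2_crit = x$chi2_crit,
                 n_thresholds = nrow(x$scan), diagnostic = x$diagnostic)
}

#' Tidy a network into its edge table
#'
#' @param x A `conet`.
#' @param ... Unused.
#' @export
tidy.conet <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a network
#'
#' @inheritParams tidy.conet
#' @export
glance.conet <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x),
                 n_nodes = length(unique(c(x$gene_a, x$gene_b))),
                 threshold = attr(x, "threshold"))
}

#' Tidy a module partition into its per-edge assignment
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @export
tidy.module_partition <- function(x, ...) x$assignment

#' One-row summary of a module partition
#'
#' @inheritParams tidy.module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x$summary),
                 n_edges = nrow(x$assignment),
                 partition_density = x$partition_density,
                 cut_height = x$cut_height)
}

#' Tidy a neighbor-voting report into per-function AUROCs
#'
#' @param x An `auroc_report`.
#' @param ... Unused.
#' @export
tidy.auroc_report <- function(x, ...) x$per_function

#' One-row summary of a neighbor-voting report
#'
#' @inheritParams tidy.auroc_report
#' @export
glance.auroc_report <- function(x, ...) {
  tibble::tibble(mean_auroc = x$mean_auroc,
                 n_functions = nrow(x$per_function), folds = x$folds)
}
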
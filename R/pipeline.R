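#' Run the end-to-end network construction workflow
#'
#' Ties the stages together on one machine: preprocessing (optional),
#' all-pairs mixture-aware similarity, threshold determination (RMT scan
#' unless `tau` is supplied), network extraction, link-community module
#' detection, and — when annotations are given — clinical enrichment and
#' neighbor-voting evaluation. Each stage's artifact is returned; when
#' `out_dir` is set they are also written as TSV/JSON.
#'
#' @param gem GEM matrix.
#' @param cfg A [pairwise_config()].
#' @param tau Correlation threshold. `NULL` runs [find_threshold()]; if the
#'   scan cannot choose (e.g. too few surviving transcripts for spacing
#'   statistics), an error asks for an explicit threshold.
#' @param samples Optional sample-annotation tibble (`sample_id` + attribute
#'   columns) for module enrichment.
#' @param term_map Optional named gene-set list for neighbor-voting
#'   evaluation.
#' @param preprocess Apply [preprocess_gem()] first?
#' @param log2,quantile Passed to [preprocess_gem()] when `preprocess`.
#' @param folds Cross-validation folds for the evaluation stage.
#' @param out_dir Optional output directory.
#' @param progress Passed to [gem_similarity()].
#' @return List with elements `gem`, `ks_report`, `similarity`, `scan`,
#'   `tau`, `network`, `modules`, `enrichment`, `auroc` (later elements
#'   `NULL` when their inputs were not provided).
#' @export
run_pipeline <- function(gem, cfg = pairwise_config(), tau = NULL,
                         samples = NULL, term_map = NULL,
                         preprocess = TRUE, log2 = FALSE, quantile = TRUE,
                         folds = 3L, out_dir = NULL, progress = FALSE) {
  ks_report <- NULL
  if (preprocess) {
    pp <- preprocess_gem(gem, log2 = log2, quantile = quantile)
    gem <- pp$gem
    ks_report <- pp$report
  }
  similarity <- gem_similarity(gem, cfg, progress = progress)
  scan <- NULL
  if (is.null(tau)) {
    scan <- find_threshold(similarity)
    if (is.na(scan$chosen_tau)) {
      stop("RMT scan chose no threshold (", scan$diagnostic,
           "); supply tau explicitly", call. = FALSE)
    }
    tau <- scan$chosen_tau
  }
  network <- extract_network(similarity, tau, sample_ids = colnames(gem))
  modules <- if (nrow(network) > 0L) detect_modules(network) else NULL
  enrichment <- NULL
  if (!is.null(modules) && !is.null(samples)) {
    enrichment <- enrich_modules(modules, samples)
  }
  auroc <- NULL
  if (!is.null(term_map) && nrow(network) > 0L) {
    adj <- conet_adjacency(network)
    ann <- annotation_matrix(term_map, rownames(adj))
    auroc <- tryCatch(
      neighbor_voting_auroc(adj, ann, folds = folds, seed = cfg$seed),
      error = function(e) NULL
    )
  }
  out <- list(gem = gem, ks_report = ks_report, similarity = similarity,
              scan = scan, tau = tau, network = network, modules = modules,
              enrichment = enrichment, auroc = auroc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gem(gem, file.path(out_dir, "gem_preprocessed.tsv"))
    utils::write.table(similarity, file.path(out_dir, "similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scan)) {
      utils::write.table(scan$scan, file.path(out_dir, "rmt_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_network(network, file.path(out_dir, "network.tsv"))
    if (!is.null(modules)) {
      utils::write.table(modules$assignment, file.path(out_dir, "modules.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(modules$summary,
                         file.path(out_dir, "modules_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(auroc)) {
      utils::write.table(auroc$per_function, file.path(out_dir, "auroc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
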
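#' Materialize the thresholded co-expression network
#'
#' Keeps every (pair, cluster) whose correlation magnitude reaches `tau`
#' but is strictly below 1 (perfect correlations are artifacts of
#' low-range expression and are removed), with endpoints in canonical
#' (lexicographic) order. A pair with several qualifying clusters yields
#' several edges — the network is a multigraph, and each edge keeps its own
#' digit-coded sample string.
#'
#' @param results Pairwise results tibble from [gem_similarity()].
#' @param tau Correlation threshold, from [find_threshold()] or the caller.
#' @param sample_ids Ordered sample ids of the source GEM (optional but
#'   recommended; used by heatmaps and enrichment).
#' @return A `conet` object: tibble of edges (`gene_a < gene_b`,
#'   `cluster_index`, `rho`, `method`, `num_samples`, `sample_string`) with
#'   attributes `threshold` and `sample_ids`.
#' @export
extract_network <- function(results, tau, sample_ids = NULL) {
  edges <- results |>
    dplyr::filter(!is.na(.data$rho), abs(.data$rho) >= tau, abs(.data$rho) < 1) |>
    dplyr::mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::transmute(
      gene_a = .data$a, gene_b = .data$b,
      cluster_index = .data$cluster_index, rho = .data$rho,
      method = .data$method, num_samples = .data$cluster_size,
      sample_string = .data$sample_string
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b, .data$cluster_index)
  if (is.null(sample_ids) && nrow(edges) > 0L) {
    sample_ids <- paste0("S", seq_len(nchar(edges$sample_string[1L])))
  }
  structure(edges, class = c("conet", class(edges)),
            threshold = tau, sample_ids = sample_ids)
}

#' @export
print.conet <- function(x, ...) {
  cat("Co-expression network: ", nrow(x), " edges over ",
      length(unique(c(x$gene_a, x$gene_b))), " transcripts (|rho| >= ",
      attr(x, "threshold"), ")\n", sep = "")
  NextMethod()
}

#' Binarize edge sample strings
#'
#' Converts each edge's sample string to a 0/1 row: 1 where the digit is
#' `1` (the sample supported the edge), 0 for any other digit (absent,
#' missing, or outlier). Rows are edges and columns samples; the
#' composition heatmap transposes at plot time.
#'
#' @param network A `conet`.
#' @return Edges x samples 0/1 integer matrix.
#' @export
binarize_sample_strings <- function(network) {
  stopifnot(nrow(network) > 0L)
  m <- matrix(0L, nrow(network), nchar(network$sample_string[1L]))
  for (e in seq_len(nrow(network))) {
    m[e, ] <- as.integer(strsplit(network$sample_string[e], "")[[1L]] == "1")
  }
  colnames(m) <- attr(network, "sample_ids")
  rownames(m) <- paste0("E", seq_len(nrow(network)))
  m
}

#' Order edges by sample-composition similarity
#'
#' Average-linkage hierarchical clustering (Euclidean distance on the
#' binarized rows); returns the dendrogram leaf order, so edges with
#' similar supporting-sample sets become adjacent in the composition
#' heatmap.
#'
#' @param mat Edges x samples 0/1 matrix from [binarize_sample_strings()].
#' @return Integer permutation of the edge indices.
#' @export
order_edges <- function(mat) {
  if (nrow(mat) < 2L) return(seq_len(nrow(mat)))
  stats::hclust(stats::dist(mat, method = "euclidean"),
                method = "average")$order
}

conet_igraph <- function(network) {
  # simple-graph projection: multi-edges collapse to one
  pairs <- unique(network[, c("gene_a", "gene_b")])
  igraph::graph_from_data_frame(pairs, directed = FALSE)
}

#' Degree distribution of the network
#'
#' Node degrees of the simple-graph projection (multi-edges collapsed),
#' as a histogram tibble. A roughly linear log-log relationship is the
#' usual visual check for scale-free behaviour.
#'
#' @param network A `conet`.
#' @return Tibble with `degree` and `n_nodes`.
#' @export
degree_distribution <- function(network) {
  if (nrow(network) == 0L) return(tibble::tibble(degree = integer(), n_nodes = integer()))
  deg <- igraph::degree(conet_igraph(network))
  tab <- table(deg)
  tibble::tibble(degree = as.integer(names(tab)), n_nodes = as.integer(tab))
}

#' Clustering-coefficient profile of the network
#'
#' Mean local clustering coefficient per node degree, on the simple-graph
#' projection; a decreasing log-log trend is the usual visual check for
#' hierarchical structure.
#'
#' @param network A `conet`.
#' @return Tibble with `degree` and `mean_clustering`.
#' @export
clustering_coefficient_profile <- function(network) {
  if (nrow(network) == 0L) {
    return(tibble::tibble(degree = integer(), mean_clustering = numeric()))
  }
  g <- conet_igraph(network)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0
  tibble::tibble(degree = deg, cc = cc) |>
    dplyr::group_by(.data$degree) |>
    dplyr::summarise(mean_clustering = mean(.data$cc), .groups = "drop")
}

#' Write a network to tab-separated text (with a JSON sidecar)
#'
#' @param network A `conet`.
#' @param path Output TSV path; a `<path>.json` sidecar records the
#'   threshold and sample ids.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = attr(network, "threshold"),
         sample_ids = attr(network, "sample_ids"),
         n_edges = nrow(network)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Network TSV path.
#' @return A `conet`.
#' @export
read_network <- function(path) {
  edges <- tibble::as_tibble(utils::read.table(
    path, sep = "\t", header = TRUE,
    colClasses = c(sample_string = "character")))
  sidecar <- paste0(path, ".json")
  threshold <- NA_real_
  sample_ids <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    threshold <- meta$threshold
    sample_ids <- meta$sample_ids
  }
  structure(edges, class = c("conet", class(edges)),
            threshold = threshold, sample_ids = sample_ids)
}
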
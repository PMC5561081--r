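#' Jaccard similarity of two edges sharing a node
#'
#' For edges `(i, k)` and `(j, k)` sharing node `k`, the similarity is the
#' Jaccard index of the inclusive neighbourhoods of the non-shared nodes:
#' `|n+(i) ∩ n+(j)| / |n+(i) ∪ n+(j)|` with `n+(v) = {v} ∪ neighbors(v)`.
#' Edges sharing no node have similarity 0 and are never linked.
#'
#' @param e1,e2 Length-2 character vectors naming each edge's endpoints.
#' @param adjacency Named list mapping each node to its neighbour set.
#' @return Similarity in `[0, 1]`.
#' @export
edge_similarity <- function(e1, e2, adjacency) {
  if (setequal(e1, e2)) stop("edges are identical", call. = FALSE)
  shared <- intersect(e1, e2)
  if (length(shared) == 0L) return(0)
  i <- setdiff(e1, shared)[1L]
  j <- setdiff(e2, shared)[1L]
  ni <- union(i, adjacency[[i]])
  nj <- union(j, adjacency[[j]])
  length(intersect(ni, nj)) / length(union(ni, nj))
}

#' Partition density of an edge partition
#'
#' `D = (2/M) * sum_c m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))`
#' over modules `c` with `m_c` edges spanning `n_c` nodes; a module with
#' `n_c = 2` (or a tree, `m_c = n_c - 1`) contributes 0; a partition into
#' cliques attains the maximum of 1.
#'
#' @param assignment Tibble with columns `module`, `gene_a`, `gene_b`
#'   (simple edges, one row per edge).
#' @param M Total edge count (default `nrow(assignment)`).
#' @return The partition density.
#' @export
partition_density <- function(assignment, M = nrow(assignment)) {
  if (M == 0L) return(0)
  terms <- assignment |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      m_c = dplyr::n(),
      n_c = length(unique(c(.data$gene_a, .data$gene_b))),
      .groups = "drop"
    ) |>
    dplyr::mutate(term = ifelse(.data$n_c <= 2L, 0,
                                .data$m_c * (.data$m_c - (.data$n_c - 1)) /
                                  ((.data$n_c - 2) * (.data$n_c - 1))))
  (2 / M) * sum(terms$term)
}

#' Detect overlapping modules by link communities
#'
#' Clusters edges rather than nodes: pairwise edge similarity (inclusive-
#' neighbourhood Jaccard, computed on the simple-graph projection), a
#' single-linkage dendrogram over `1 - similarity`, and a cut at the merge
#' height maximizing partition density (ties break to the lower height).
#' Because edges, not nodes, are partitioned, a gene joins every module one
#' of its edges belongs to — overlap is allowed, as expected of pleiotropic
#' genes. Multi-edges (same pair, different mixture clusters) follow their
#' pair's module while keeping their own sample strings.
#'
#' @param network A `conet` with at least one edge.
#' @return A `module_partition`: `assignment` (the network's edge records
#'   plus `module_id`), `simple_assignment` (one row per simple edge),
#'   `summary` (per-module edge/node counts and density terms),
#'   `partition_density`, and `cut_height`. Module ids `M0001...` are
#'   assigned by descending edge count.
#' @export
detect_modules <- function(network) {
  stopifnot(nrow(network) >= 1L)
  simple <- unique(as.data.frame(network[, c("gene_a", "gene_b")]))
  ne <- nrow(simple)
  nodes <- unique(c(simple$gene_a, simple$gene_b))
  adjacency <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(simple$gene_b[simple$gene_a == v], simple$gene_a[simple$gene_b == v])
  })

  if (ne == 1L) {
    labels <- 1L
    cut_height <- 0
  } else {
    d <- matrix(1, ne, ne)
    for (a in seq_len(ne - 1L)) {
      ea <- c(simple$gene_a[a], simple$gene_b[a])
      for (b in (a + 1L):ne) {
        eb <- c(simple$gene_a[b], simple$gene_b[b])
        if (length(intersect(ea, eb)) > 0L) {
          s <- edge_similarity(ea, eb, adjacency)
          d[a, b] <- d[b, a] <- 1 - s
        }
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    # candidate cuts: actual similarity-driven merges (height < 1);
    # height-1 merges join edges that share no node and are never real
    heights <- sort(unique(hc$height[hc$height < 1 - 1e-12]))
    if (length(heights) == 0L) {
      labels <- seq_len(ne)
      cut_height <- 0
    } else {
      best_d <- -Inf
      labels <- NULL
      cut_height <- NA_real_
      for (h in heights) {
        lab <- stats::cutree(hc, h = h)
        dens <- partition_density(
          tibble::tibble(module = lab, gene_a = simple$gene_a,
                         gene_b = simple$gene_b), ne)
        if (dens > best_d + 1e-12) {
          best_d <- dens
          labels <- lab
          cut_height <- h
        }
      }
    }
  }

  simple$module <- labels
  # rank modules by multigraph edge count, descending (stable)
  key <- paste(simple$gene_a, simple$gene_b)
  rec_key <- paste(network$gene_a, network$gene_b)
  rec_module <- simple$module[match(rec_key, key)]
  counts <- sort(table(rec_module), decreasing = TRUE)
  rank_of <- stats::setNames(seq_along(counts), names(counts))
  module_id <- sprintf("M%04d", rank_of[as.character(rec_module)])
  assignment <- dplyr::mutate(tibble::as_tibble(network), module_id = module_id)
  simple_assignment <- tibble::tibble(
    module_id = sprintf("M%04d", rank_of[as.character(simple$module)]),
    gene_a = simple$gene_a, gene_b = simple$gene_b
  )
  summary <- simple_assignment |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(
      m_c = dplyr::n(),
      n_c = length(unique(c(.data$gene_a, .data$gene_b))),
      .groups = "drop"
    ) |>
    dplyr::mutate(density_term = ifelse(.data$n_c <= 2L, 0,
                                        .data$m_c * (.data$m_c - (.data$n_c - 1)) /
                                          ((.data$n_c - 2) * (.data$n_c - 1)))) |>
    dplyr::arrange(.data$module_id)

  structure(
    list(assignment = assignment,
         simple_assignment = simple_assignment,
         summary = summary,
         partition_density = partition_density(
           dplyr::rename(simple_assignment, module = "module_id")),
         cut_height = cut_height,
         sample_ids = attr(network, "sample_ids")),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Link-community partition: ", nrow(x$summary), " modules over ",
      nrow(x$assignment), " edges; partition density = ",
      format(x$partition_density, digits = 4), "\n", sep = "")
  invisible(x)
}
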
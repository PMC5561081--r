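#' Area under the ROC curve from scores
#'
#' Rank-based AUROC with tie-average credit (equivalently the normalized
#' Mann-Whitney U statistic): ties between a positive and a negative score
#' count one half.
#'
#' @param pos,neg Numeric score vectors for positives / negatives.
#' @return AUROC in `[0, 1]`; `NA` when either side is empty.
#' @keywords internal
auroc_from_scores <- function(pos, neg) {
  np <- length(pos)
  nn <- length(neg)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Neighbor-voting AUROC of a network against functional annotations
#'
#' Guilt-by-association evaluation: for each function, the annotated genes
#' are split into `folds` cross-validation folds; each fold's labels are
#' hidden in turn and every gene is scored by the fraction of its network
#' neighbours carrying the remaining labels (degree-normalized votes;
#' `raw_sum = TRUE` skips the normalization). The AUROC ranks the hidden
#' positives against the never-annotated genes (training positives are
#' excluded), is averaged over folds per function, and finally over
#' functions. Isolated (degree-0) genes score 0. A mean of 0.5 is chance;
#' assortative functional structure pushes it up.
#'
#' @param adjacency Symmetric genes x genes 0/1 matrix (multi-edges should
#'   already be collapsed; see [conet_adjacency()]).
#' @param annotations Genes x functions 0/1 matrix; rownames must match
#'   `adjacency`. Functions with fewer than `min_genes` annotated genes are
#'   excluded.
#' @param folds Cross-validation folds (default 3).
#' @param seed Seed for the fold assignment (the only randomness).
#' @param min_genes Minimum annotated genes per function (default 10).
#' @param raw_sum Use unnormalized vote sums instead of degree-normalized
#'   votes.
#' @return An `auroc_report`: tibble `per_function` (`function_id`,
#'   `auroc`) and scalar `mean_auroc`.
#' @export
neighbor_voting_auroc <- function(adjacency, annotations, folds = 3L,
                                  seed = 1L, min_genes = 10L,
                                  raw_sum = FALSE) {
  adjacency <- as.matrix(adjacency)
  annotations <- as.matrix(annotations)
  stopifnot(nrow(adjacency) == ncol(adjacency),
            nrow(annotations) == nrow(adjacency))
  keep <- colSums(annotations) >= min_genes
  annotations <- annotations[, keep, drop = FALSE]
  if (ncol(annotations) == 0L) stop("no function has enough annotated genes",
                                    call. = FALSE)
  deg <- rowSums(adjacency)
  withr::local_seed(seed)
  per_fn <- vapply(seq_len(ncol(annotations)), function(f) {
    pos <- which(annotations[, f] == 1)
    neg <- which(annotations[, f] == 0)
    fold_of <- sample(rep_len(seq_len(folds), length(pos)))
    aucs <- vapply(seq_len(folds), function(fd) {
      hidden <- pos[fold_of == fd]
      train <- pos[fold_of != fd]
      if (length(hidden) == 0L || length(train) == 0L) return(NA_real_)
      lab <- numeric(nrow(adjacency))
      lab[train] <- 1
      votes <- as.numeric(adjacency %*% lab)
      scores <- if (raw_sum) votes else ifelse(deg > 0, votes / deg, 0)
      auroc_from_scores(scores[hidden], scores[neg])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  fn_ids <- colnames(annotations)
  if (is.null(fn_ids)) fn_ids <- paste0("F", seq_along(per_fn))
  structure(
    list(per_function = tibble::tibble(function_id = fn_ids, auroc = per_fn),
         mean_auroc = mean(per_fn, na.rm = TRUE),
         folds = folds),
    class = "auroc_report"
  )
}

#' @export
print.auroc_report <- function(x, ...) {
  cat("Neighbor-voting evaluation: ", nrow(x$per_function), " functions, ",
      x$folds, "-fold CV, mean AUROC = ",
      format(x$mean_auroc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Binary adjacency matrix of a network
#'
#' Collapses multi-edges to a single 0/1 entry — networks are treated as
#' sparse binary graphs for guilt-by-association evaluation.
#'
#' @param network A `conet`.
#' @param genes Optional gene universe (defaults to the network's nodes).
#' @return Symmetric 0/1 matrix with gene dimnames.
#' @export
conet_adjacency <- function(network, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(c(network$gene_a, network$gene_b)))
  m <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  ia <- match(network$gene_a, genes)
  ib <- match(network$gene_b, genes)
  ok <- !is.na(ia) & !is.na(ib)
  m[cbind(ia[ok], ib[ok])] <- 1L
  m[cbind(ib[ok], ia[ok])] <- 1L
  m
}

#' Annotation matrix from a gene-set list
#'
#' @param term_map Named list of term -> gene ids (see [read_gmt()]).
#' @param genes Gene universe (matrix rows).
#' @return Genes x terms 0/1 matrix.
#' @export
annotation_matrix <- function(term_map, genes) {
  m <- vapply(term_map, function(g) as.integer(genes %in% g),
              integer(length(genes)))
  rownames(m) <- genes
  m
}
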
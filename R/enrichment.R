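#' Samples backing a module (the 95% edge-presence rule)
#'
#' A sample belongs to a module's sample set when its digit is `1` in at
#' least `ceiling(fraction * m_c)` of the module's `m_c` edge sample
#' strings — i.e. it supported (nearly) every edge of the module.
#'
#' @param sample_strings Character vector of the module's edge sample strings.
#' @param sample_ids Optional sample ids (defaults to positional indices).
#' @param fraction Required edge-presence fraction, in (0, 1] (default 0.95).
#' @return Character vector of member sample ids (possibly empty).
#' @export
module_sample_set <- function(sample_strings, sample_ids = NULL,
                              fraction = 0.95) {
  stopifnot(length(sample_strings) > 0L, fraction > 0, fraction <= 1)
  m_c <- length(sample_strings)
  mat <- vapply(sample_strings,
                function(s) strsplit(s, "")[[1L]] == "1",
                logical(nchar(sample_strings[1L])))
  counts <- rowSums(mat)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(counts))
  sample_ids[counts >= ceiling(fraction * m_c)]
}

#' Fisher's exact test of set over-representation
#'
#' One-sided (over-representation) Fisher exact test of the 2x2 table
#' formed by a selected set and a category within a common background:
#' `a` = selected and in category, `b` = selected only, `c` = category
#' only, `d` = neither.
#'
#' @param selected Selected items (samples or genes), a subset of `background`.
#' @param members Category members, a subset of `background`.
#' @param background The background universe (non-empty).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return One-row tibble with the contingency counts `a`, `b`, `c`, `d`
#'   and the exact `p`.
#' @export
fisher_enrichment <- function(selected, members, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  selected <- intersect(selected, background)
  members <- intersect(members, background)
  a <- length(intersect(selected, members))
  b <- length(selected) - a
  cc <- length(members) - a
  d <- length(background) - a - b - cc
  p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                          alternative = alternative)$p.value
  tibble::tibble(a = a, b = b, c = cc, d = d, p = p)
}

#' Clinical-annotation enrichment of modules
#'
#' For every module, derives the module sample set ([module_sample_set()])
#' and Fisher-tests it against each category of each sample attribute.
#' Samples lacking a value for an attribute are dropped from that
#' attribute's background. Bonferroni and Benjamini-Hochberg adjusted
#' p-values are computed within each attribute.
#'
#' @param partition A `module_partition` from [detect_modules()].
#' @param samples Tibble with `sample_id` plus one column per attribute
#'   (categorical; `NA` allowed).
#' @param attributes Attribute columns to test (default: all non-id columns).
#' @param fraction Edge-presence fraction for [module_sample_set()].
#' @param alternative Passed to [fisher_enrichment()].
#' @return Tibble with `module_id`, `attribute`, `category`, contingency
#'   counts, `p`, `p_bonferroni`, `p_bh`.
#' @export
enrich_modules <- function(partition, samples, attributes = NULL,
                           fraction = 0.95, alternative = "greater") {
  stopifnot(inherits(partition, "module_partition"))
  if (is.null(attributes)) attributes <- setdiff(names(samples), "sample_id")
  sample_ids <- partition$sample_ids
  if (is.null(sample_ids)) {
    sample_ids <- as.character(seq_len(nchar(partition$assignment$sample_string[1L])))
  }
  sets <- partition$assignment |>
    dplyr::group_by(.data$module_id) |>
    dplyr::group_map(~ module_sample_set(.x$sample_string, sample_ids,
                                         fraction = fraction),
                     .keep = TRUE)
  names(sets) <- sort(unique(partition$assignment$module_id))

  rows <- purrr::map(names(sets), function(mid) {
    purrr::map(attributes, function(attr_name) {
      values <- samples[[attr_name]]
      ok <- !is.na(values)
      background <- samples$sample_id[ok]
      selected <- intersect(sets[[mid]], background)
      purrr::map(sort(unique(values[ok])), function(cat) {
        members <- samples$sample_id[ok & values == cat]
        res <- fisher_enrichment(selected, members, background,
                                 alternative = alternative)
        dplyr::bind_cols(
          tibble::tibble(module_id = mid, attribute = attr_name,
                         category = as.character(cat)), res)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  rows |>
    dplyr::group_by(.data$attribute) |>
    dplyr::mutate(p_bonferroni = pmin(.data$p * dplyr::n(), 1),
                  p_bh = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (term, description, then member genes, tab-separated).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Functional-term enrichment of a gene set
#'
#' Fisher-tests a module's genes against each functional term of a GMT-style
#' term map, over a genomic background. Reports the raw p, Bonferroni
#' (`p * T` capped at 1, `T` the number of tested terms) and
#' Benjamini-Hochberg adjusted p, and a significance call at raw
#' `p < alpha`.
#'
#' @param module_genes Character vector of the module's gene ids.
#' @param term_map Named list of term -> gene ids (see [read_gmt()]).
#' @param background Character vector, the genomic background.
#' @param alpha Raw-p significance cutoff (default 0.001).
#' @param alternative Passed to [fisher_enrichment()].
#' @return Tibble with `term`, counts, `p`, `p_bonferroni`, `p_bh`,
#'   `significant`, ordered by `p`. Terms with no background members are
#'   skipped with a message.
#' @export
functional_enrichment <- function(module_genes, term_map, background,
                                  alpha = 0.001, alternative = "greater") {
  stopifnot(length(term_map) > 0L)
  keep <- vapply(term_map, function(g) length(intersect(g, background)) > 0L,
                 logical(1))
  if (any(!keep)) {
    message("skipping ", sum(!keep), " term(s) with no background members")
  }
  term_map <- term_map[keep]
  rows <- purrr::imap(term_map, function(genes, term) {
    res <- fisher_enrichment(module_genes, genes, background,
                             alternative = alternative)
    dplyr::bind_cols(tibble::tibble(term = term), res)
  }) |> dplyr::bind_rows()
  rows |>
    dplyr::mutate(p_bonferroni = pmin(.data$p * dplyr::n(), 1),
                  p_bh = stats::p.adjust(.data$p, method = "BH"),
                  significant = .data$p < alpha) |>
    dplyr::arrange(.data$p)
}
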
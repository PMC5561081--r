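#' Read a gene expression matrix (GEM) from tab-separated text
#'
#' The GEM dialect is plain UTF-8 text: a header row of sample identifiers,
#' one row per transcript with the transcript identifier in the first column,
#' values tab-separated, and the literal string `NA` for missing measurements.
#' This is the standard layout of expression compendia assembled from
#' repository downloads (e.g. level-3 RNA-seq isoform quantifications).
#'
#' @param path Path to a tab-separated GEM file.
#' @return A numeric matrix, transcripts in rows (rownames) and samples in
#'   columns (colnames). Missing values are `NA`, never silently zero.
#' @seealso [write_gem()], [log2_transform()], [quantile_normalize()]
#' @export
read_gem <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("no data rows in GEM file '", path, "'", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sample_ids <- fields[[1L]]
  # tolerate both an R-style header (m fields) and a full header (id + m fields)
  body_len <- length(fields[[2L]])
  if (length(sample_ids) == body_len) sample_ids <- sample_ids[-1L]
  m <- length(sample_ids)
  bad <- which(vapply(fields[-1L], length, 1L) != m + 1L)
  if (length(bad) > 0L) {
    stop("ragged GEM row at line ", bad[1L] + 1L, ": expected ", m + 1L,
         " fields", call. = FALSE)
  }
  transcript_ids <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(transcript_ids)) {
    stop("duplicate transcript ids in GEM: ",
         paste(unique(transcript_ids[duplicated(transcript_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in GEM: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(fields[-1L], function(f) {
    suppressWarnings(as.numeric(f[-1L]))
  }, numeric(m))
  gem <- if (m == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(gem) <- list(transcript_ids, sample_ids)
  gem
}

#' Write a GEM to tab-separated text
#'
#' Inverse of [read_gem()]: header row of sample ids, transcript id in the
#' first column, `NA` for missing values.
#'
#' @param gem Numeric matrix with transcript rownames and sample colnames.
#' @param path Output file path.
#' @param digits Significant digits for formatting (default 6).
#' @return `path`, invisibly.
#' @export
write_gem <- function(gem, path, digits = 6L) {
  stopifnot(is.matrix(gem), !is.null(rownames(gem)), !is.null(colnames(gem)))
  fmt <- function(x) {
    out <- formatC(x, digits = digits, format = "g")
    out[is.na(x)] <- "NA"
    out
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(gem)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(gem)), function(i) {
    paste(c(rownames(gem)[i], fmt(gem[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}
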
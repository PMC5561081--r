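#' Configuration for the synthetic mixed-condition GEM generator
#'
#' Describes a compendium of samples drawn from several categorical
#' conditions, with planted condition-specific co-expression modules on a
#' background of independent genes — the structure of a multi-subtype
#' expression compendium, at desk scale. Defaults: five conditions of 60
#' samples each (mirroring a five-subtype tumor compendium), three planted
#' 10-gene modules — one active in a single condition each for two of them,
#' one shared by two conditions (the analogue of a relationship common to
#' two related subtypes) — a latent within-module correlation of 0.9, a
#' +3 log2-unit activation shift, 200 background genes, unit noise, and 2%
#' missing values.
#'
#' @param conditions Named integer vector: condition name -> sample count.
#' @param modules List of module descriptions, each a list with
#'   `gene_count`, `active_conditions` (character subset of condition
#'   names), `r` (latent pairwise correlation in (0,1)) and `mean_shift`
#'   (activation shift in log2 units).
#' @param background_genes Number of unstructured genes.
#' @param noise_sd Gene-level noise standard deviation (log2 units).
#' @param missing_rate Uniform missing-value rate in `[0, 1)`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(conditions = c(A = 60L, B = 60L, C = 60L,
                                        D = 60L, E = 60L),
                         modules = list(
                           list(gene_count = 10L, active_conditions = "A",
                                r = 0.9, mean_shift = 3),
                           list(gene_count = 10L, active_conditions = "B",
                                r = 0.9, mean_shift = 3),
                           list(gene_count = 10L,
                                active_conditions = c("C", "D"),
                                r = 0.9, mean_shift = 3)
                         ),
                         background_genes = 200L, noise_sd = 1,
                         missing_rate = 0.02, seed = 1L) {
  stopifnot(all(conditions > 0L), background_genes >= 0L,
            noise_sd > 0, missing_rate >= 0, missing_rate < 1)
  for (m in modules) {
    stopifnot(m$gene_count > 1L, m$r > 0, m$r < 1,
              all(m$active_conditions %in% names(conditions)))
  }
  structure(
    list(conditions = conditions, modules = modules,
         background_genes = as.integer(background_genes),
         noise_sd = noise_sd, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic mixed-condition GEM with planted modules
#'
#' Module genes in their active conditions follow a shared-latent-factor
#' construction, `x = baseline + shift + sd * (sqrt(r) z + sqrt(1-r) e)`
#' with one latent `z` per (module, sample), so the within-module pairwise
#' correlation over active samples is `r` by construction. In inactive
#' conditions the same genes are independent noise at their baseline —
#' creating the separated second expression mode the mixture decomposition
#' is designed to isolate. Background genes are independent noise
#' throughout. Values are on the log2 scale; a `missing_rate` fraction of
#' cells is masked uniformly at random.
#'
#' @param cfg A [synth_config()].
#' @return List with `gem` (matrix), `truth` (list: `pairs`, the planted
#'   gene pairs with their active condition sets; `modules`, gene/module
#'   map) and `samples` (tibble `sample_id`, `condition` — the sample
#'   annotation).
#' @export
generate_gem <- function(cfg = synth_config()) {
  withr::local_seed(cfg$seed)
  cond_names <- names(cfg$conditions)
  sample_cond <- rep(cond_names, cfg$conditions)
  m <- length(sample_cond)
  sample_ids <- paste0(sample_cond, "_S",
                       sprintf("%02d", unlist(lapply(cfg$conditions, seq_len))))

  gene_blocks <- list()
  truth_pairs <- list()
  truth_modules <- list()
  for (k in seq_along(cfg$modules)) {
    mod <- cfg$modules[[k]]
    gene_ids <- sprintf("MOD%d_G%02d", k, seq_len(mod$gene_count))
    baseline <- stats::runif(mod$gene_count, 4, 8)
    active <- sample_cond %in% mod$active_conditions
    z <- stats::rnorm(m)  # latent factor, per sample; used on active samples
    block <- matrix(NA_real_, mod$gene_count, m,
                    dimnames = list(gene_ids, sample_ids))
    for (g in seq_len(mod$gene_count)) {
      eps <- stats::rnorm(m)
      x <- baseline[g] + cfg$noise_sd * eps
      x[active] <- baseline[g] + mod$mean_shift +
        cfg$noise_sd * (sqrt(mod$r) * z[active] + sqrt(1 - mod$r) * eps[active])
      block[g, ] <- x
    }
    gene_blocks[[k]] <- block
    pairs <- utils::combn(gene_ids, 2)
    truth_pairs[[k]] <- tibble::tibble(
      gene_a = pairs[1, ], gene_b = pairs[2, ],
      module = paste0("planted_", k),
      active_conditions = paste(mod$active_conditions, collapse = ",")
    )
    truth_modules[[k]] <- tibble::tibble(
      module = paste0("planted_", k), gene = gene_ids,
      active_conditions = paste(mod$active_conditions, collapse = ","))
  }
  if (cfg$background_genes > 0L) {
    bg_ids <- sprintf("BG_G%03d", seq_len(cfg$background_genes))
    bg_baseline <- stats::runif(cfg$background_genes, 4, 8)
    bg <- bg_baseline + matrix(stats::rnorm(cfg$background_genes * m),
                               cfg$background_genes, m) * cfg$noise_sd
    dimnames(bg) <- list(bg_ids, sample_ids)
    gene_blocks <- c(gene_blocks, list(bg))
  }
  gem <- do.call(rbind, gene_blocks)
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(gem)) < cfg$missing_rate
    gem[mask] <- NA_real_
  }
  list(
    gem = gem,
    truth = list(pairs = dplyr::bind_rows(truth_pairs),
                 modules = dplyr::bind_rows(truth_modules)),
    samples = tibble::tibble(sample_id = sample_ids, condition = sample_cond)
  )
}

#' Score recovery of planted structure by an extracted network
#'
#' Precision and recall of the network's gene pairs against the planted
#' pairs, and the condition purity of matched edges: the mean, over matched
#' edge records, of the fraction of the edge's supporting (`1`) samples
#' that belong to the planted active condition set.
#'
#' @param network A `conet` extracted from a generated GEM.
#' @param truth The `truth` element returned by [generate_gem()].
#' @param samples The `samples` tibble returned by [generate_gem()].
#' @return One-row tibble: `n_edges`, `n_true_pairs`, `precision` (NA for
#'   an empty network), `recall`, `purity`.
#' @export
score_recovery <- function(network, truth, samples) {
  planted <- truth$pairs |>
    dplyr::mutate(a = pmin(.data$gene_a, .data$gene_b),
                  b = pmax(.data$gene_a, .data$gene_b),
                  key = paste(.data$a, .data$b))
  if (nrow(network) == 0L) {
    return(tibble::tibble(n_edges = 0L, n_true_pairs = nrow(planted),
                          precision = NA_real_, recall = 0, purity = NA_real_))
  }
  edge_key <- paste(network$gene_a, network$gene_b)
  found <- unique(edge_key)
  tp <- intersect(found, planted$key)
  matched <- which(edge_key %in% planted$key)
  sample_ids <- attr(network, "sample_ids")
  cond_of <- stats::setNames(samples$condition, samples$sample_id)
  purity <- vapply(matched, function(e) {
    digits <- strsplit(network$sample_string[e], "")[[1L]]
    members <- sample_ids[digits == "1"]
    active <- strsplit(
      planted$active_conditions[match(edge_key[e], planted$key)], ",")[[1L]]
    mean(cond_of[members] %in% active)
  }, numeric(1))
  tibble::tibble(
    n_edges = nrow(network),
    n_true_pairs = nrow(planted),
    precision = length(tp) / length(found),
    recall = length(tp) / nrow(planted),
    purity = if (length(purity)) mean(purity) else NA_real_
  )
}
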
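net_from_pairs <- function(a, b, rho = 0.9) {
  extract_network(tibble::tibble(
    gene_a = a, gene_b = b, cluster_index = 1L, num_clusters = 1L,
    cluster_size = 3L, method = "spearman", rho = rho,
    skip_reason = NA_character_, sample_string = "111"
  ), 0.5)
}

adjacency_of <- function(a, b) {
  nodes <- unique(c(a, b))
  lapply(stats::setNames(nodes, nodes),
         function(v) c(b[a == v], a[b == v]))
}

test_that("edge similarity follows the inclusive-neighbourhood Jaccard", {
  # triangle abc: the non-shared endpoints see identical neighbourhoods
  adj <- adjacency_of(c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(edge_similarity(c("a", "b"), c("a", "c"), adj), 1)
  # path a-b-c-d: disjoint edges never link
  adj <- adjacency_of(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(edge_similarity(c("a", "b"), c("c", "d"), adj), 0)
  # adjacent path edges: n+(a) = {a,b}, n+(c) = {b,c,d} -> 1 of 4
  expect_equal(edge_similarity(c("a", "b"), c("b", "c"), adj), 1 / 4)
  expect_error(edge_similarity(c("a", "b"), c("b", "a"), adj), "identical")
})

test_that("partition density matches closed-form values", {
  triangle <- tibble::tibble(module = 1L, gene_a = c("a", "a", "b"),
                             gene_b = c("b", "c", "c"))
  expect_equal(partition_density(triangle), 1)
  # every edge alone: all n_c = 2 terms vanish
  singletons <- tibble::tibble(module = 1:3, gene_a = c("a", "b", "c"),
                               gene_b = c("b", "c", "d"))
  expect_equal(partition_density(singletons), 0)
  # a spanning tree as one module: m = n - 1
  tree <- tibble::tibble(module = 1L, gene_a = c("a", "a", "a"),
                         gene_b = c("b", "c", "d"))
  expect_equal(partition_density(tree), 0)
})

test_that("two triangles sharing a node give two modules with node overlap", {
  net <- net_from_pairs(c("a", "a", "b", "c", "c", "d"),
                        c("b", "c", "c", "d", "e", "e"))
  part <- detect_modules(net)
  expect_identical(nrow(part$summary), 2L)
  expect_equal(part$partition_density, 1)
  genes_by_module <- lapply(split(part$simple_assignment,
                                  part$simple_assignment$module_id),
                            function(df) unique(c(df$gene_a, df$gene_b)))
  shared <- Reduce(intersect, genes_by_module)
  expect_identical(shared, "c")
})

test_that("a clique is one module and a 2-edge path stays together", {
  genes <- letters[1:5]
  pairs <- t(combn(genes, 2))
  part <- detect_modules(net_from_pairs(pairs[, 1], pairs[, 2]))
  expect_identical(nrow(part$summary), 1L)
  expect_identical(part$summary$m_c, 10L)

  path <- detect_modules(net_from_pairs(c("a", "b"), c("b", "c")))
  expect_identical(nrow(path$summary), 1L)
  expect_equal(path$partition_density, 0)
})

test_that("every edge is assigned to exactly one module and D is self-consistent", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 8
    adj <- matrix(0L, n, n)
    adj[which(upper.tri(adj))[sample(n * (n - 1) / 2, 12)]] <- 1L
    pairs <- which(adj == 1, arr.ind = TRUE)
    genes <- paste0("g", 1:n)
    net <- net_from_pairs(genes[pairs[, 1]], genes[pairs[, 2]])
    part <- detect_modules(net)
    expect_identical(nrow(part$assignment), nrow(net))
    expect_identical(sum(part$summary$m_c), nrow(part$simple_assignment))
    recomputed <- partition_density(
      dplyr::rename(part$simple_assignment, module = "module_id"))
    expect_equal(recomputed, part$partition_density, tolerance = 1e-12)
  }
})

test_that("the chosen cut attains the exhaustive maximum on small graphs", {
  # independent oracle: rebuild the dendrogram, evaluate D at every cut
  # height with a from-scratch density computation, take the maximum
  oracle_max_density <- function(simple) {
    ne <- nrow(simple)
    adj <- adjacency_of(simple$gene_a, simple$gene_b)
    d <- matrix(1, ne, ne)
    for (a in seq_len(ne - 1)) {
      for (b in (a + 1):ne) {
        ea <- c(simple$gene_a[a], simple$gene_b[a])
        eb <- c(simple$gene_a[b], simple$gene_b[b])
        if (length(intersect(ea, eb)) > 0) {
          d[a, b] <- d[b, a] <- 1 - edge_similarity(ea, eb, adj)
        }
      }
    }
    hc <- hclust(as.dist(d), method = "single")
    cuts <- sort(unique(hc$height[hc$height < 1 - 1e-12]))
    if (length(cuts) == 0) return(0)
    dens <- vapply(cuts, function(h) {
      lab <- cutree(hc, h = h)
      total <- 0
      for (m in unique(lab)) {
        e <- which(lab == m)
        m_c <- length(e)
        n_c <- length(unique(c(simple$gene_a[e], simple$gene_b[e])))
        if (n_c > 2) {
          total <- total + m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))
        }
      }
      2 * total / ne
    }, 0)
    max(dens)
  }
  set.seed(66)
  for (rep in 1:5) {
    repeat {
      n <- sample(5:7, 1)
      adj <- matrix(0L, n, n)
      m <- sample(4:8, 1)
      adj[which(upper.tri(adj))[sample(n * (n - 1) / 2, m)]] <- 1L
      if (sum(adj) > 0) break
    }
    pairs <- which(adj == 1, arr.ind = TRUE)
    genes <- paste0("g", 1:n)
    net <- net_from_pairs(genes[pairs[, 1]], genes[pairs[, 2]])
    part <- detect_modules(net)
    expect_equal(part$partition_density,
                 oracle_max_density(unique(
                   as.data.frame(net[, c("gene_a", "gene_b")]))),
                 tolerance = 1e-12,
                 label = paste("exhaustive cut, rep", rep))
  }
})

test_that("multi-edge records follow their pair but keep their strings", {
  res <- tibble::tibble(
    gene_a = c("a", "a", "a", "b"), gene_b = c("b", "b", "c", "c"),
    cluster_index = c(1L, 2L, 1L, 1L), num_clusters = c(2L, 2L, 1L, 1L),
    cluster_size = 3L, method = "spearman", rho = c(0.9, -0.88, 0.92, 0.91),
    skip_reason = NA_character_,
    sample_string = c("111000", "000111", "111111", "111111")
  )
  part <- detect_modules(extract_network(res, 0.5))
  expect_identical(nrow(part$assignment), 4L)
  ab <- part$assignment[part$assignment$gene_a == "a" &
                          part$assignment$gene_b == "b", ]
  expect_identical(length(unique(ab$module_id)), 1L)
  expect_setequal(ab$sample_string, c("111000", "000111"))
})

test_that("module ids rank by edge count with zero-padded labels", {
  net <- net_from_pairs(c("a", "a", "b", "x"), c("b", "c", "c", "y"))
  part <- detect_modules(net)
  expect_match(part$summary$module_id, "^M\\d{4}$")
  counts <- part$summary$m_c[order(part$summary$module_id)]
  expect_true(all(diff(counts) <= 0))
})
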
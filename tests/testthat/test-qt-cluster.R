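test_that("Spearman distance matches hand-ranked values", {
  m <- matrix(c(1, 5, 9,  2, 6, 10), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  d <- spearman_distance(m)
  expect_equal(d["g1", "g2"], 0)          # identical rank order
  m2 <- matrix(c(1, 5, 9,  9, 5, 1), 2, 3, byrow = TRUE,
               dimnames = dimnames(m))
  expect_equal(spearman_distance(m2)["g1", "g2"], 2)  # exactly reversed
  m3 <- matrix(c(1, 2, 3, 4,  1, 3, 2, 4), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2"), letters[1:4]))
  expect_equal(spearman_distance(m3)["g1", "g2"], 0.2)  # rho_s = 0.8
  # constant profiles get maximal distance, zero diagonal, symmetry
  m4 <- rbind(m3, g3 = c(7, 7, 7, 7))
  d4 <- spearman_distance(m4)
  expect_equal(unname(d4["g3", c("g1", "g2")]), c(2, 2))
  expect_equal(unname(diag(d4)), rep(0, 3))
  expect_equal(d4, t(d4))
  expect_true(all(d4 >= 0 & d4 <= 2))
  expect_error(spearman_distance(m[, 1:2]), "3 samples")
})

test_that("qt_clustering handles the no-cluster edge case", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  res <- qt_clustering(d, max_diameter = 0.5, min_size = 2)
  expect_length(res$clusters, 0)
  expect_setequal(res$unclustered, letters[1:4])
})

test_that("qt_clustering recovers planted distance blocks exactly", {
  set.seed(41)
  n <- 20L
  genes <- sprintf("g%02d", 1:n)
  d <- matrix(runif(n * n, 0.5, 1.0), n, n, dimnames = list(genes, genes))
  d[1:8, 1:8] <- runif(64, 0, 0.02)
  d[9:16, 9:16] <- runif(64, 0, 0.02)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  res <- qt_clustering(d, max_diameter = 0.06, min_size = 7)
  expect_length(res$clusters, 2L)
  expect_setequal(res$clusters[[1L]]$members, genes[1:8])
  expect_setequal(res$clusters[[2L]]$members, genes[9:16])
  expect_setequal(res$unclustered, genes[17:20])
})

test_that("qt_clustering agrees with a straight-line re-execution of the rule", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 10L
    genes <- sprintf("g%02d", 1:n)
    d <- matrix(runif(n * n, 0, 0.4), n, n, dimnames = list(genes, genes))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    got <- qt_clustering(d, max_diameter = 0.2, min_size = 2)
    want <- qt_oracle(d, max_diameter = 0.2, min_size = 2)
    expect_equal(lapply(got$clusters, `[[`, "members"), want$clusters)
    expect_identical(got$unclustered, want$unclustered)
  }
})

test_that("emitted clusters respect the diameter bound and size ordering", {
  ex <- simulate_expression(n_genes = 300, seed = 13)
  d <- spearman_distance(ex$matrix)
  res <- qt_clustering(d, 0.06, 7)
  expect_gt(length(res$clusters), 0)
  sizes <- vapply(res$clusters, function(cl) length(cl$members), integer(1L))
  expect_true(all(diff(sizes) <= 0))
  for (cl in res$clusters) {
    sub <- d[cl$members, cl$members]
    expect_lte(max(sub), 0.06)               # recomputed diameter
    expect_equal(max(sub), cl$diameter)      # reported diameter
    expect_gte(length(cl$members), 7L)
  }
  # clusters and unclustered genes partition the input
  all_out <- c(unlist(lapply(res$clusters, `[[`, "members")),
               res$unclustered)
  expect_setequal(all_out, rownames(d))
  expect_equal(length(all_out), nrow(d))
  # determinism: identical input gives identical output
  expect_identical(res, qt_clustering(d, 0.06, 7))
})

test_that("planted blocks are recovered with high ARI at wide separation", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    ex <- simulate_expression(
      n_genes = 120,
      clusters = list(list(size = 8, rho = 0.98, category = "Transport"),
                      list(size = 8, rho = 0.98,
                           category = "Energy Metabolism")),
      seed = s)
    d <- spearman_distance(ex$matrix)
    qt <- qt_clustering(d, 0.06, 7)
    mclust::adjustedRandIndex(ex$cluster_truth$cluster,
                              qt_labels(qt, ex$cluster_truth$gene_id))
  }, numeric(1L))
  expect_gte(mean(aris), 0.9)
})

test_that("hierarchical ordering reproduces forced topologies and heights", {
  genes <- c("a", "b", "c")
  d <- matrix(c(0, 0.1, 0.4,  0.1, 0, 0.4,  0.4, 0.4, 0), 3, 3,
              dimnames = list(genes, genes))
  ord <- hierarchical_order(genes, d)
  expect_equal(ord$height, c(0.1, 0.4))
  expect_true(all(c("a", "b") %in% ord$order[1:2]) ||
                all(c("a", "b") %in% ord$order[2:3]))
  # two members: single merge at their distance
  ord2 <- hierarchical_order(c("a", "c"), d)
  expect_equal(ord2$height, 0.4)
  # singleton: trivial tree
  ord1 <- hierarchical_order("a", d)
  expect_identical(ord1$order, "a")
  expect_null(ord1$tree)
  expect_match(cluster_newick(ord1), "^\\(a:0\\);$")
  expect_match(cluster_newick(ord), "a")
})

test_that("average-linkage merge heights match a naive O(n^3) scan", {
  for (seed in c(3, 14)) {
    set.seed(seed)
    n <- 8L
    genes <- sprintf("m%d", 1:n)
    d <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    ord <- hierarchical_order(genes, d)
    expect_equal(sort(ord$height), upgma_heights_oracle(d),
                 tolerance = 1e-10)
  }
})
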
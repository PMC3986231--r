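mk_genome <- function(starts, ends, strands, contigs = "c1",
                      ids = sprintf("g%d", seq_along(starts))) {
  data.frame(gene_id = ids, contig_id = rep_len(contigs, length(starts)),
             start = starts, end = ends, strand = strands,
             stringsAsFactors = FALSE)
}

test_that("adjacent pairs carry the stated intergenic-distance arithmetic", {
  g <- mk_genome(c(1, 401), c(300, 700), c("+", "+"))
  p <- adjacent_pairs(g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance, 100L)   # 401 - 300 - 1
  expect_true(p$same_strand)
  # overlap: negative distance
  g2 <- mk_genome(c(1, 250), c(300, 700), c("+", "-"))
  p2 <- adjacent_pairs(g2)
  expect_equal(p2$distance, -51L)  # 250 - 300 - 1
  expect_false(p2$same_strand)
  # no pair across contigs
  g3 <- mk_genome(c(1, 10), c(5, 20), c("+", "+"), contigs = c("c1", "c2"))
  expect_equal(nrow(adjacent_pairs(g3)), 0L)
  # identical coordinates are rejected
  g4 <- mk_genome(c(1, 1), c(300, 300), c("+", "-"))
  expect_error(adjacent_pairs(g4), "identical coordinates")
})

test_that("pair posterior reproduces closed-form naive-Bayes values", {
  # uninformative model: flat histograms, 0.5 conservation, prior 0.5
  nb <- length(default_distance_breaks()) - 1L
  model <- structure(list(prior = 0.5,
                          breaks = default_distance_breaks(),
                          f_operonic = rep(1 / nb, nb),
                          f_boundary = rep(1 / nb, nb),
                          p_cons_operonic = 0.5, p_cons_boundary = 0.5,
                          n_operonic_seeds = 1L, n_boundary = 1L),
                     class = "OperonModel")
  pairs <- data.frame(upstream = "a", downstream = "b", contig_id = "c1",
                      same_strand = TRUE, distance = 50L)
  bc <- matrix(TRUE, 1, 1)
  expect_equal(pair_posterior(pairs, bc, model), 0.5)
  # distance likelihood ratio 3 and one reference with conservation ratio 2:
  # posterior = 6 / 7
  model2 <- model
  bin <- findInterval(50L, model$breaks)
  f_o <- rep(1 / nb, nb); f_o[bin] <- 3 / nb
  model2$f_operonic <- f_o
  model2$p_cons_operonic <- 2 / 3
  model2$p_cons_boundary <- 1 / 3
  expect_equal(pair_posterior(pairs, bc, model2), 6 / 7, tolerance = 1e-12)
  # opposite strand pairs are hard negatives
  pairs$same_strand <- FALSE
  expect_equal(pair_posterior(pairs, bc, model2), 0)
})

test_that("posterior is monotone in each likelihood ratio", {
  gn <- simulate_genome(n_genes = 400, seed = 5)
  pairs <- adjacent_pairs(gn$genome)
  model <- train_operon_model(pairs, gn$barcode)
  post <- pair_posterior(pairs, gn$barcode, model)
  # flipping one reference column from not-conserved to conserved can only
  # raise the posterior (conservation is evidence for operonicity)
  bc2 <- gn$barcode
  bc2[, 1L] <- TRUE
  post2 <- pair_posterior(pairs, bc2, model)
  ss <- pairs$same_strand
  expect_true(all(post2[ss] >= post[ss] - 1e-12))
})

test_that("model training recovers the planted distance law and barcode", {
  gn <- simulate_genome(n_genes = 1500, seed = 9)
  pairs <- adjacent_pairs(gn$genome)
  model <- train_operon_model(pairs, gn$barcode)
  # operonic distance histogram mode within one bin of the planted mean 25
  inner <- 2:(length(model$f_operonic) - 1L)
  mode_bin <- inner[which.max(model$f_operonic[inner])]
  lo <- model$breaks[mode_bin]; hi <- model$breaks[mode_bin + 1L]
  expect_lte(lo, 35); expect_gte(hi, 15)
  # conservation probabilities separate the classes in the right direction
  expect_true(all(model$p_cons_operonic > model$p_cons_boundary))
  # shuffling reference columns permutes the model's per-reference terms only
  set.seed(2)
  perm <- sample(ncol(gn$barcode))
  model_p <- train_operon_model(pairs, gn$barcode[, perm])
  expect_equal(unname(model_p$p_cons_operonic),
               unname(model$p_cons_operonic[perm]))
  expect_equal(model_p$f_operonic, model$f_operonic)
  # smoothing limit: perfect conservation contrast approaches (c+1)/(c+2)
  bc_perfect <- matrix(rep(gn$pair_truth$operonic, 5), ncol = 5)
  m_perfect <- train_operon_model(pairs, bc_perfect)
  npos <- m_perfect$n_operonic_seeds
  expect_equal(unname(m_perfect$p_cons_operonic),
               rep((npos + 1) / (npos + 2), 5), tolerance = 1e-12)
  expect_error(train_operon_model(pairs[1:40, ], gn$barcode[1:40, ]),
               "too few")
})

test_that("operon calls partition positive pairs into maximal runs", {
  g <- mk_genome(seq(1, by = 1000, length.out = 4),
                 seq(901, by = 1000, length.out = 4), rep("+", 4))
  pairs <- adjacent_pairs(g)
  # 3-gene run: one operon of 3 genes, 3 operonic genes, 2 positive pairs
  res <- call_operons(pairs[1:2, ], c(0.9, 0.9), tau = 0.5, n_genes = 3L)
  expect_equal(res$summary$n_multigene_operons, 1L)
  expect_equal(res$operons[[1L]], c("g1", "g2", "g3"))
  expect_equal(res$summary$operonic_genes, 3L)
  expect_equal(res$summary$n_positive_pairs, 2L)
  # broken run on 4 genes: two 2-gene operons, 4 operonic genes
  res2 <- call_operons(pairs, c(0.9, 0.1, 0.9), tau = 0.5)
  expect_equal(res2$summary$n_multigene_operons, 2L)
  expect_equal(lapply(res2$operons, identity),
               list(c("g1", "g2"), c("g3", "g4")))
  expect_equal(res2$summary$operonic_genes, 4L)
  # posterior exactly at the threshold is positive (>=)
  res3 <- call_operons(pairs[1, ], 0.5, tau = 0.5)
  expect_equal(res3$summary$n_positive_pairs, 1L)
  # run partition invariant: sum(run length - 1) = positive pair count
  gn <- simulate_genome(n_genes = 600, seed = 21)
  op <- predict_operons(gn$genome, gn$barcode)
  expect_equal(sum(lengths(op$operons) - 1L),
               op$summary$n_positive_pairs)
})

test_that("prediction recovers planted operon structure at study scale", {
  skip_if_not_installed("pROC")
  aucs <- err <- numeric(3)
  for (i in 1:3) {
    gn <- simulate_genome(n_genes = 1500, seed = 100 + i)
    op <- predict_operons(gn$genome, gn$barcode)
    ss <- gn$pair_truth$same_strand
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = gn$pair_truth$operonic[ss],
      predictor = op$pairs$posterior[ss], quiet = TRUE,
      direction = "<")))
    truth_operonic <- unique(c(
      gn$pair_truth$upstream[gn$pair_truth$operonic],
      gn$pair_truth$downstream[gn$pair_truth$operonic]))
    aucs[i] <- auc
    err[i] <- abs(op$summary$operonic_fraction -
                    length(truth_operonic) / nrow(gn$genome))
  }
  expect_gte(mean(aucs), 0.9)
  expect_lte(mean(err) * 100, 5)  # percentage points
})

test_that("uninformative simulations yield no discriminating posterior", {
  skip_if_not_installed("pROC")
  # identical distance laws and identical conservation rates for both classes:
  # the predictor must not separate operonic from boundary pairs
  gn <- simulate_genome(n_genes = 800, seed = 31,
                        p_cons_operonic = 0.4, p_cons_boundary = 0.4,
                        operonic_distance_mean = 150,
                        operonic_distance_sd = 80,
                        operonic_distance_min = 1,
                        boundary_distance_mean = 150,
                        boundary_distance_sd = 80)
  pairs <- adjacent_pairs(gn$genome)
  model <- train_operon_model(pairs, gn$barcode)
  post <- pair_posterior(pairs, gn$barcode, model)
  ss <- pairs$same_strand
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = gn$pair_truth$operonic[ss], predictor = post[ss],
    quiet = TRUE, direction = "<")))
  expect_lt(auc, 0.65)
  # forced negative: singleton units with a flip at every boundary leave no
  # same-strand pair at all
  gn2 <- simulate_genome(n_genes = 300, seed = 7, mean_unit_size = 1,
                         strand_flip_prob = 1)
  pairs2 <- adjacent_pairs(gn2$genome)
  expect_equal(sum(pairs2$same_strand), 0L)
  expect_error(train_operon_model(pairs2, gn2$barcode), "too few")
})
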
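# Small in-code fixtures and independent oracles shared across tests.

toy_matrix <- function(vals = 1:6, n_genes = 3, n_samples = 2,
                       genes = sprintf("g%d", seq_len(n_genes)),
                       samples = sprintf("s%d", seq_len(n_samples))) {
  matrix(as.numeric(vals), n_genes, n_samples, byrow = TRUE,
         dimnames = list(genes, samples))
}

random_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, log(500), 1),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Exact hypergeometric upper tail by direct enumeration of the pmf terms.
# choose() is exact in doubles for the N <= 25 instances it is used on.
hyper_tail_enum <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- seq.int(k, hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Straight-line re-execution of the greedy QT rule, written independently
# of the package implementation (explicit loops, explicit diameter scans).
qt_oracle <- function(d, max_diameter, min_size) {
  genes <- rownames(d)
  remaining <- seq_len(nrow(d))
  clusters <- list()
  repeat {
    if (length(remaining) < min_size) break
    best_members <- NULL
    for (s in remaining) {
      members <- s
      diam <- 0
      repeat {
        cand <- setdiff(remaining, members)
        if (!length(cand)) break
        nd <- sapply(cand, function(g) {
          dd <- diam
          for (m in members) dd <- max(dd, d[g, m])
          dd
        })
        j <- which.min(nd)  # earliest candidate index on ties
        if (nd[j] > max_diameter) break
        diam <- nd[j]
        members <- c(members, cand[j])
      }
      if (is.null(best_members) || length(members) > length(best_members))
        best_members <- members
    }
    if (length(best_members) < min_size) break
    clusters[[length(clusters) + 1L]] <- genes[best_members]
    remaining <- setdiff(remaining, best_members)
  }
  list(clusters = clusters, unclustered = genes[remaining])
}

# Naive O(n^3) average-linkage agglomeration: returns sorted merge heights.
upgma_heights_oracle <- function(d) {
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      h <- mean(d[groups[[i]], groups[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  sort(heights)
}

# Predicted cluster labels (0 = unclustered) aligned to a gene universe.
qt_labels <- function(qt, genes) {
  lab <- rep(0L, length(genes))
  names(lab) <- genes
  for (i in seq_along(qt$clusters)) lab[qt$clusters[[i]]$members] <- i
  lab
}
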
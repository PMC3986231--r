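#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of seeing at
#' least `k` category genes when drawing a cluster of size `n` without
#' replacement from a universe of `N` genes of which `K` belong to the
#' category. Evaluated through the numerically stable distribution routine
#' (log-space tail summation), so tiny tail probabilities do not underflow
#' pairwise.
#'
#' @param k Observed category genes in the cluster (`0 <= k <= min(n, K)`
#'   for a non-trivial value; `k <= n` and `k <= K` are required).
#' @param n Cluster size.
#' @param K Category genes in the universe.
#' @param N Universe size.
#' @return Probability in (0, 1]; exactly 1 when `k = 0`. Vectorized over
#'   its arguments.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  k <- args[, 1L]; n <- args[, 2L]; K <- args[, 3L]; N <- args[, 4L]
  if (any(args < 0) || any(args != round(args)))
    stop("k, n, K, N must be non-negative integers")
  if (any(n > N) || any(K > N))
    stop("need n <= N and K <= N")
  if (any(k > n) || any(k > K))
    stop("need k <= n and k <= K")
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Functional-category enrichment of QT clusters
#'
#' For every (cluster, category) pair, tests overrepresentation of the
#' category among the cluster's genes with the hypergeometric upper tail.
#' A cluster is flagged enriched when any category reaches `p <= alpha`
#' (raw p-values; the flag uses no multiple-testing correction, though a
#' Benjamini-Hochberg column is emitted for reference). A cluster may be
#' enriched for several categories.
#'
#' @param result A `QTClusteringResult`.
#' @param categories Named character vector `gene_id -> category` (see
#'   [read_subsystem_map()]). Every universe gene must be mapped.
#' @param universe `"clustered_genes"` (default): only genes placed in some
#'   cluster form the universe; `"all_genes"`: clustered plus unclustered.
#' @param alpha Significance level for the enriched flag (study value 0.05).
#' @return A data.frame of class `EnrichmentResult` with columns `cluster`,
#'   `category`, `k`, `n`, `K`, `N`, `p_value`, `p_adj_bh`, `significant`;
#'   attribute `"enriched_clusters"` lists the per-cluster flags.
#' @export
enrich_clusters <- function(result, categories,
                            universe = c("clustered_genes", "all_genes"),
                            alpha = 0.05) {
  universe <- match.arg(universe)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1))
    stop("`alpha` must be in (0, 1]")
  clustered <- unlist(lapply(result$clusters, `[[`, "members"),
                      use.names = FALSE)
  uni <- if (universe == "all_genes") c(clustered, result$unclustered)
         else clustered
  missing <- setdiff(uni, names(categories))
  if (length(missing))
    stop("gene without a category: ", missing[1L])
  cat_of <- categories[uni]
  vocab <- sort(unique(cat_of))
  N <- length(uni)
  K_of <- table(factor(cat_of, levels = vocab))
  rows <- lapply(seq_along(result$clusters), function(i) {
    members <- result$clusters[[i]]$members
    n <- length(members)
    k_of <- table(factor(categories[members], levels = vocab))
    data.frame(cluster = i, category = vocab,
               k = as.integer(k_of), n = n,
               K = as.integer(K_of), N = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = integer(), category = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      p_adj_bh = numeric(), significant = logical())
  } else {
    out$p_value <- hypergeom_upper_tail(out$k, out$n, out$K, out$N)
    out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_value <= alpha
  }
  rownames(out) <- NULL
  enriched <- tapply(out$significant, out$cluster, any)
  structure(out,
            enriched_clusters = as.logical(enriched),
            alpha = alpha, universe = universe,
            class = c("EnrichmentResult", "data.frame"))
}

#' Cluster-by-category p-value matrix
#'
#' Pivots an [enrich_clusters()] result into the matrix layout used for
#' enrichment heat maps: rows are clusters, columns categories, cells the
#' upper-tail p-values; cells for categories absent from a cluster (`k = 0`)
#' can optionally be masked as `NA` ("no gene").
#'
#' @param enr An `EnrichmentResult`.
#' @param mask_absent Set cells with `k = 0` to `NA`.
#' @return Numeric matrix clusters x categories.
#' @export
enrichment_matrix <- function(enr, mask_absent = TRUE) {
  if (nrow(enr) == 0L) return(matrix(numeric(0), 0L, 0L))
  clusters <- sort(unique(enr$cluster))
  vocab <- sort(unique(enr$category))
  m <- matrix(NA_real_, length(clusters), length(vocab),
              dimnames = list(paste0("cluster_", clusters), vocab))
  p <- enr$p_value
  if (mask_absent) p[enr$k == 0L] <- NA_real_
  m[cbind(match(enr$cluster, clusters), match(enr$category, vocab))] <- p
  m
}
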
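#' Spearman rank-correlation distance matrix
#'
#' Pairwise distance between gene expression profiles defined as
#' `d(i, j) = 1 - rho_s(i, j)`, where `rho_s` is Spearman's rank correlation
#' with average ranks for ties. The distance ranges over \[0, 2\]: 0 means
#' identical rank order, 2 exactly reversed. Constant rows have no defined
#' rank correlation and are assigned the maximal distance 2 to every other
#' gene, so the downstream gene partition stays complete.
#'
#' @param x An `ExpressionMatrix` or named numeric matrix with >= 3 samples
#'   (rank correlation is degenerate below 3 points).
#' @return Symmetric numeric matrix over gene ids, zero diagonal, with
#'   attribute `metric = "spearman_1mr"`.
#' @export
spearman_distance <- function(x) {
  m <- as_intensity_matrix(x)
  if (ncol(m) < 3L)
    stop("Spearman distance needs at least 3 samples")
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  d <- 1 - rho
  d[is.na(d)] <- 2  # constant profiles: maximal distance
  diag(d) <- 0
  attr(d, "metric") <- "spearman_1mr"
  d
}

# Grow the quality-threshold candidate cluster around one seed.
# Returns the members in addition order (seed first) and the diameter.
qt_grow_candidate <- function(d, seed, active, max_diameter) {
  members <- seed
  maxd <- d[, seed]
  maxd[!active] <- Inf
  maxd[seed] <- Inf
  diameter <- 0
  repeat {
    nd <- pmax(maxd, diameter)        # diameter after adding each gene
    best <- which.min(nd)             # earliest input index on ties
    if (!is.finite(nd[best]) || nd[best] > max_diameter) break
    diameter <- unname(nd[best])
    members <- c(members, best)
    maxd <- pmax(maxd, d[, best])
    maxd[best] <- Inf
  }
  list(members = members, diameter = diameter)
}

#' Quality-threshold (QT) clustering
#'
#' The iterated greedy QT procedure: for every remaining gene, a candidate
#' cluster is grown by repeatedly adding the gene whose inclusion yields the
#' smallest new diameter (the maximum pairwise distance among members), as
#' long as that diameter stays within `max_diameter`; ties during growth go
#' to the earliest gene in input order. The largest candidate is extracted
#' (ties: earliest seed in input order), its members removed, and the
#' procedure repeats until the largest candidate falls below `min_size`.
#' Remaining genes are left unclustered, so the clusters plus the
#' unclustered set always partition the input genes.
#'
#' With the distance of [spearman_distance()], the study's stringent
#' parameters `max_diameter = 0.06`, `min_size = 7` require all-pairs rank
#' correlation >= 0.94 within a cluster of at least 7 genes.
#'
#' @param d Symmetric distance matrix with gene ids as dimnames (e.g. from
#'   [spearman_distance()]).
#' @param max_diameter Maximum allowed cluster diameter (>= 0).
#' @param min_size Minimum cluster size (>= 1).
#' @return An object of class `QTClusteringResult`: list with `clusters`
#'   (each a list with `members` in addition order, `seed`, `diameter`),
#'   `unclustered` (gene ids), and the parameters used. Cluster sizes are
#'   non-increasing in extraction order.
#' @export
qt_clustering <- function(d, max_diameter, min_size) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("`d` must be a square distance matrix")
  if (max_diameter < 0) stop("`max_diameter` must be >= 0")
  if (min_size < 1L) stop("`min_size` must be >= 1")
  genes <- rownames(d)
  if (is.null(genes)) stop("distance matrix needs gene ids as dimnames")
  n <- nrow(d)
  active <- rep(TRUE, n)
  clusters <- list()
  repeat {
    idx <- which(active)
    if (length(idx) < min_size) break
    # genes with no in-threshold neighbor can only seed singletons
    sub_ok <- d[idx, idx, drop = FALSE] <= max_diameter
    n_nb <- rowSums(sub_ok) - 1L
    best <- NULL
    for (pos in seq_along(idx)) {
      s <- idx[pos]
      if (n_nb[pos] == 0L) {
        cand <- list(members = s, diameter = 0)
      } else {
        cand <- qt_grow_candidate(d, s, active, max_diameter)
      }
      if (is.null(best) || length(cand$members) > length(best$members))
        best <- cand
    }
    if (length(best$members) < min_size) break
    clusters[[length(clusters) + 1L]] <- list(
      members = genes[best$members],
      seed = genes[best$members[1L]],
      diameter = best$diameter)
    active[best$members] <- FALSE
  }
  structure(list(clusters = clusters,
                 unclustered = genes[active],
                 max_diameter = max_diameter,
                 min_size = min_size,
                 variant = "diameter"),
            class = "QTClusteringResult")
}

#' @export
print.QTClusteringResult <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1L))
  cat(sprintf("QTClusteringResult: %d clusters (sizes %s), %d unclustered\n",
              length(x$clusters),
              if (length(sizes)) paste(range(sizes), collapse = "-") else "-",
              length(x$unclustered)))
  cat(sprintf("parameters: max_diameter %g, min_size %d\n",
              x$max_diameter, x$min_size))
  invisible(x)
}

#' Cluster membership as a data.frame
#' @param x A `QTClusteringResult`.
#' @param include_unclustered Append unclustered genes with cluster id `NA`.
#' @return data.frame with columns `cluster`, `gene_id`, `is_seed`,
#'   `diameter`.
#' @export
qt_members <- function(x, include_unclustered = FALSE) {
  rows <- lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    data.frame(cluster = i, gene_id = cl$members,
               is_seed = cl$members == cl$seed,
               diameter = cl$diameter, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cluster = integer(), gene_id = character(),
                      is_seed = logical(), diameter = numeric())
  if (include_unclustered && length(x$unclustered))
    out <- rbind(out, data.frame(cluster = NA_integer_,
                                 gene_id = x$unclustered,
                                 is_seed = FALSE, diameter = NA_real_))
  out
}

#' Hierarchical ordering of a cluster's members
#'
#' Average-linkage (UPGMA) agglomeration over the cluster's distance
#' submatrix, used to order genes within a QT cluster for dendrogram-style
#' display; merge heights are on the same `1 - rho_s` scale as the distance.
#'
#' @param members Character vector of the cluster's gene ids (all present in
#'   `d`), e.g. one element of a `QTClusteringResult`.
#' @param d Distance matrix covering the members.
#' @return List with `order` (gene ids in dendrogram leaf order), `merge`,
#'   `height` (as in [stats::hclust()]), and `tree` (the `hclust` object, or
#'   `NULL` for singleton clusters).
#' @export
hierarchical_order <- function(members, d) {
  if (is.list(members) && !is.null(members$members)) members <- members$members
  missing <- setdiff(members, rownames(d))
  if (length(missing))
    stop("cluster member absent from distance matrix: ", missing[1L])
  if (length(members) == 1L)
    return(list(order = members, merge = NULL, height = numeric(0),
                tree = NULL))
  hc <- stats::hclust(stats::as.dist(d[members, members]),
                      method = "average")
  list(order = members[hc$order], merge = hc$merge, height = hc$height,
       tree = hc)
}

#' Newick serialization of a cluster's merge tree
#'
#' @param ord Result of [hierarchical_order()].
#' @return Newick string with branch lengths derived from merge heights, or
#'   a trivial one-leaf tree for singletons.
#' @export
cluster_newick <- function(ord) {
  if (is.null(ord$tree)) return(paste0("(", ord$order[1L], ":0);"))
  ape::write.tree(ape::as.phylo(ord$tree))
}
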
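#' Adjacent gene pairs of a genome
#'
#' Consecutive coordinate-sorted genes per contig. The intergenic distance is
#' `start(downstream) - end(upstream) - 1` under 1-based inclusive
#' coordinates, negative when the genes overlap. Opposite-strand pairs are
#' retained with `same_strand = FALSE`: they are automatic operon negatives
#' and the boundary training material for [train_operon_model()]. No pair is
#' formed across contigs.
#'
#' @param genome Genome table data.frame (see [read_genome_table()]).
#' @return data.frame with columns `upstream`, `downstream`, `contig_id`,
#'   `same_strand`, `distance`, in (contig, coordinate) order.
#' @export
adjacent_pairs <- function(genome) {
  genome <- validate_genome_table(genome)
  if (nrow(genome) == 0L) stop("genome table is empty")
  key <- paste(genome$contig_id, genome$start, genome$end)
  if (anyDuplicated(key))
    stop("overlapping identical coordinates for gene ",
         genome$gene_id[duplicated(key)][1L])
  i <- seq_len(nrow(genome) - 1L)
  if (length(i) == 0L)
    return(data.frame(upstream = character(), downstream = character(),
                      contig_id = character(), same_strand = logical(),
                      distance = integer()))
  same_contig <- genome$contig_id[i] == genome$contig_id[i + 1L]
  i <- i[same_contig]
  data.frame(
    upstream = genome$gene_id[i],
    downstream = genome$gene_id[i + 1L],
    contig_id = genome$contig_id[i],
    same_strand = genome$strand[i] == genome$strand[i + 1L],
    distance = genome$start[i + 1L] - genome$end[i] - 1L,
    stringsAsFactors = FALSE)
}

#' Default intergenic-distance histogram breaks
#'
#' Bins of width 10 bp on \[-50, 600) plus open terminal bins, covering gene
#' overlaps down to any size and long intergenic gaps.
#' @return Numeric vector of breaks including `-Inf` and `Inf`.
#' @export
default_distance_breaks <- function() c(-Inf, seq(-50, 600, by = 10), Inf)

#' Train the naive-Bayes operon model
#'
#' The model couples an intergenic-distance likelihood with a per-reference
#' conserved-adjacency ("barcode") likelihood. Training is comparative and
#' needs no experimental data: same-strand adjacent pairs whose adjacency is
#' conserved in at least half of the reference genomes serve as operonic
#' seeds, and opposite-strand pairs as transcription-boundary proxies. All
#' counts receive Laplace (+1) smoothing. The prior is the fraction of
#' adjacent pairs lying on the same strand (the directon statistic), unless
#' overridden.
#'
#' @param pairs Adjacent-pair table from [adjacent_pairs()].
#' @param barcode Logical matrix, one row per pair (same order as `pairs`),
#'   one column per reference genome: is the pair's ortholog adjacency
#'   conserved there?
#' @param breaks Distance histogram breaks (default
#'   [default_distance_breaks()]).
#' @param prior Optional prior probability that a same-strand pair is
#'   operonic; default the directon statistic.
#' @return An object of class `OperonModel`: prior, breaks, the two
#'   normalized distance histograms, and per-reference conservation
#'   probabilities for each class.
#' @export
train_operon_model <- function(pairs, barcode,
                               breaks = default_distance_breaks(),
                               prior = NULL) {
  barcode <- as.matrix(barcode) * 1L
  if (nrow(barcode) != nrow(pairs))
    stop("barcode must have one row per adjacent pair")
  ss <- pairs$same_strand
  if (sum(ss) < 50L || sum(!ss) < 50L)
    stop("too few training pairs (need >= 50 same-strand and >= 50 ",
         "opposite-strand); supply pooled or built-in priors instead")
  R <- ncol(barcode)
  conserved_major <- rowSums(barcode) >= R / 2
  pos <- ss & conserved_major
  neg <- !ss
  if (sum(pos) == 0L)
    stop("no conserved same-strand pairs to seed operonic training")
  nb <- length(breaks) - 1L
  bin_counts <- function(dd) tabulate(findInterval(dd, breaks,
                                                   rightmost.closed = FALSE),
                                      nbins = nb)
  f_operonic <- (bin_counts(pairs$distance[pos]) + 1) / (sum(pos) + nb)
  f_boundary <- (bin_counts(pairs$distance[neg]) + 1) / (sum(neg) + nb)
  p_cons_operonic <- (colSums(barcode[pos, , drop = FALSE]) + 1) /
    (sum(pos) + 2)
  p_cons_boundary <- (colSums(barcode[neg, , drop = FALSE]) + 1) /
    (sum(neg) + 2)
  if (is.null(prior)) prior <- mean(ss)
  if (prior <= 0 || prior >= 1) stop("prior must lie strictly in (0, 1)")
  structure(list(prior = prior, breaks = breaks,
                 f_operonic = f_operonic, f_boundary = f_boundary,
                 p_cons_operonic = p_cons_operonic,
                 p_cons_boundary = p_cons_boundary,
                 n_operonic_seeds = sum(pos), n_boundary = sum(neg)),
            class = "OperonModel")
}

#' @export
print.OperonModel <- function(x, ...) {
  cat(sprintf("OperonModel: prior %.3f, %d distance bins, %d references\n",
              x$prior, length(x$f_operonic), length(x$p_cons_operonic)))
  cat(sprintf("trained on %d operonic seeds / %d boundary pairs\n",
              x$n_operonic_seeds, x$n_boundary))
  invisible(x)
}

#' Posterior probability that adjacent pairs are operonic
#'
#' Naive Bayes in log space:
#' `P(O | d, c) = pi f(d|O) prod_r g(c_r|O) /
#'  [pi f(d|O) prod_r g(c_r|O) + (1 - pi) f(d|B) prod_r g(c_r|B)]`.
#' Opposite-strand pairs are operon negatives by definition and get
#' posterior 0. Distances beyond the histogram support fall in the open
#' terminal bins.
#'
#' @param pairs Adjacent-pair table.
#' @param barcode Logical matrix of conserved adjacency (rows match `pairs`).
#' @param model An `OperonModel`.
#' @return Numeric posterior per pair, in \[0, 1\].
#' @export
pair_posterior <- function(pairs, barcode, model) {
  barcode <- as.matrix(barcode) * 1
  if (nrow(barcode) != nrow(pairs))
    stop("barcode must have one row per adjacent pair")
  if (ncol(barcode) != length(model$p_cons_operonic))
    stop("barcode reference count does not match the model")
  bin <- findInterval(pairs$distance, model$breaks, rightmost.closed = FALSE)
  lo <- log(model$prior) + log(model$f_operonic[bin]) +
    drop(barcode %*% log(model$p_cons_operonic) +
           (1 - barcode) %*% log(1 - model$p_cons_operonic))
  lb <- log(1 - model$prior) + log(model$f_boundary[bin]) +
    drop(barcode %*% log(model$p_cons_boundary) +
           (1 - barcode) %*% log(1 - model$p_cons_boundary))
  post <- stats::plogis(lo - lb)
  post[!pairs$same_strand] <- 0
  post
}

#' Call operons from pair posteriors
#'
#' A pair is positive iff it is same-strand and its posterior reaches the
#' threshold (`>=`, study value 0.5). Operons are the maximal runs of
#' consecutive positive pairs along each contig; a gene is operonic iff it
#' belongs to at least one positive pair. The positive pairs are exactly
#' partitioned by the runs: `sum(run length - 1) = positive pair count`.
#'
#' @param pairs Adjacent-pair table in genome order (from
#'   [adjacent_pairs()]).
#' @param posteriors Posterior per pair (from [pair_posterior()]).
#' @param tau Posterior threshold in (0, 1); study value 0.5.
#' @param n_genes Total gene count of the genome, for the operonic fraction;
#'   default the number of distinct genes appearing in `pairs`.
#' @return An object of class `OperonPrediction`: list with `pairs` (the
#'   input plus `posterior` and `positive` columns), `operons` (list of
#'   member-gene vectors, each length >= 2), `operonic_genes`, and `summary`
#'   (gene counts, operonic fraction, multigene operon count, positive pair
#'   count).
#' @export
call_operons <- function(pairs, posteriors, tau = 0.5, n_genes = NULL) {
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)")
  if (length(posteriors) != nrow(pairs))
    stop("one posterior per pair is required")
  positive <- pairs$same_strand & posteriors >= tau
  pairs$posterior <- posteriors
  pairs$positive <- positive
  operons <- list()
  if (nrow(pairs)) {
    consec <- c(FALSE, pairs$downstream[-nrow(pairs)] == pairs$upstream[-1L] &
                  pairs$contig_id[-nrow(pairs)] == pairs$contig_id[-1L])
    run_id <- cumsum(!(positive & consec & c(FALSE, positive[-length(positive)])))
    for (r in split(which(positive), run_id[positive])) {
      operons[[length(operons) + 1L]] <-
        c(pairs$upstream[r[1L]], pairs$downstream[r])
    }
  }
  operonic <- unique(c(pairs$upstream[positive], pairs$downstream[positive]))
  if (is.null(n_genes))
    n_genes <- length(unique(c(pairs$upstream, pairs$downstream)))
  structure(list(
    pairs = pairs,
    operons = operons,
    operonic_genes = operonic,
    summary = list(n_genes = n_genes,
                   operonic_genes = length(operonic),
                   operonic_fraction = length(operonic) / n_genes,
                   n_multigene_operons = length(operons),
                   n_positive_pairs = sum(positive),
                   tau = tau)),
    class = "OperonPrediction")
}

#' @export
print.OperonPrediction <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "OperonPrediction: %d/%d operonic genes (%.1f%%), %d multigene operons\n",
    s$operonic_genes, s$n_genes, 100 * s$operonic_fraction,
    s$n_multigene_operons))
  invisible(x)
}

#' End-to-end operon prediction for one genome
#'
#' Convenience wrapper: adjacent pairs, model training on the genome's own
#' pairs and barcode (unless a trained model is supplied), posteriors, and
#' operon calls.
#'
#' @param genome Genome table data.frame.
#' @param barcode Logical conserved-adjacency matrix, one row per adjacent
#'   pair of `genome` in [adjacent_pairs()] order.
#' @param model Optional pre-trained `OperonModel`.
#' @param tau Posterior threshold (study value 0.5).
#' @return An `OperonPrediction` (the trained model is attached as attribute
#'   `"model"`).
#' @export
predict_operons <- function(genome, barcode, model = NULL, tau = 0.5) {
  pairs <- adjacent_pairs(genome)
  if (is.null(model)) model <- train_operon_model(pairs, barcode)
  post <- pair_posterior(pairs, barcode, model)
  out <- call_operons(pairs, post, tau = tau, n_genes = nrow(genome))
  attr(out, "model") <- model
  out
}
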
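#' Select an on/off intensity threshold
#'
#' The study fixes dataset-specific thresholds (800 for the strain 195
#' arrays, 100 for the KB-1 arrays), chosen from the frequency distribution
#' of intensity values. `strategy = "fixed"` returns the configured value.
#' `strategy = "distribution"` estimates the threshold from the data as the
#' antimode (minimum-density point) between the two modes of the pooled
#' log10-intensity histogram, so synthetic analyses need not hard-code the
#' study's values.
#'
#' @param x An `ExpressionMatrix` or named numeric matrix.
#' @param strategy `"fixed"` or `"distribution"`.
#' @param fixed_value The configured threshold for `"fixed"`.
#' @param bins Histogram bin count for `"distribution"` (default 50).
#' @return A single intensity threshold (original scale).
#' @export
select_threshold <- function(x, strategy = c("fixed", "distribution"),
                             fixed_value = NULL, bins = 50L) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value) || fixed_value <= 0)
      stop("`fixed_value` must be a positive number for strategy = 'fixed'")
    return(fixed_value)
  }
  v <- as.vector(as_intensity_matrix(x))
  v <- v[v > 0]
  if (length(unique(v)) < 2L)
    stop("distribution strategy needs at least 2 distinct positive values")
  lv <- log10(v)
  h <- graphics::hist(lv, breaks = seq(min(lv), max(lv), length.out = bins + 1L),
                      plot = FALSE)
  cnt <- h$counts
  # light smoothing so single-bin jitter does not spawn spurious modes
  k <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  k[is.na(k)] <- cnt[is.na(k)]
  k <- as.numeric(k)
  n <- length(k)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) k[i - 1L] else -Inf
    right <- if (i < n) k[i + 1L] else -Inf
    k[i] > 0 && k[i] >= left && k[i] >= right && (k[i] > left || k[i] > right)
  }, logical(1L))
  peaks <- which(is_max)
  # a mode must be non-trivial: at least 5% of the dominant peak's height
  peaks <- peaks[k[peaks] >= 0.05 * max(k[peaks])]
  if (length(peaks) < 2L)
    stop("pooled intensity distribution looks unimodal; ",
         "use strategy = 'fixed' with a configured threshold")
  top2 <- peaks[order(-k[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- seq.int(lo + 1L, hi - 1L)
  if (length(between) == 0L)
    stop("the two modes are adjacent; use strategy = 'fixed'")
  anti <- between[which.min(k[between])]
  # the valley must actually separate the modes, not just ripple noise
  if (k[anti] > 0.5 * min(k[top2]))
    stop("no clear antimode between the two candidate modes; ",
         "use strategy = 'fixed' with a configured threshold")
  10^h$mids[anti]
}

#' Call genes on/off against an intensity threshold
#'
#' A gene is called "on" in a sample iff its intensity strictly exceeds the
#' threshold; equality is "off" (the conservative completion of the
#' `<thr = off, >thr = on` rule). Calls are made per sample, and each gene is
#' summarized as `on_in_all` (on in every sample), `off_in_all` (on in none),
#' or `on_in_some`; the three classes partition the gene set.
#'
#' @param x An `ExpressionMatrix` or named numeric matrix.
#' @param threshold Positive intensity threshold (e.g. 800 or 100).
#' @return An object of class `TranscriptionCallSet`: list with `calls`
#'   (logical genes x samples matrix), `summary` (factor per gene), and
#'   `threshold`.
#' @export
call_on_off <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number")
  m <- as_intensity_matrix(x)
  calls <- m > threshold
  n_on <- rowSums(calls)
  summary <- factor(
    ifelse(n_on == ncol(calls), "on_in_all",
           ifelse(n_on == 0L, "off_in_all", "on_in_some")),
    levels = c("on_in_all", "on_in_some", "off_in_all"))
  names(summary) <- rownames(calls)
  structure(list(calls = calls, summary = summary, threshold = threshold),
            class = "TranscriptionCallSet")
}

#' @export
print.TranscriptionCallSet <- function(x, ...) {
  cat(sprintf("TranscriptionCallSet: %d genes x %d samples, threshold %g\n",
              nrow(x$calls), ncol(x$calls), x$threshold))
  print(table(x$summary))
  invisible(x)
}

#' Cross-tabulate transcription calls against proteomic evidence
#'
#' Builds the 3 x 2 count table over transcription summary class
#' (`on_in_all` / `on_in_some` / `off_in_all`) and proteomic-evidence status
#' (with / without), restricted to a chosen gene subset (all genes,
#' hypothetical proteins, metabolic genes, ...). Genes present in the
#' evidence list but absent from the array are not silently dropped: they are
#' recorded in the `"off_array_evidence"` attribute.
#'
#' @param calls A `TranscriptionCallSet`.
#' @param evidence Character vector of gene ids with proteomic evidence.
#' @param subset Gene-id subset to tabulate; default all called genes. Every
#'   subset gene must be present in `calls`.
#' @return A 3 x 2 integer matrix of class `EvidenceCrossTable` with rows
#'   `on_in_all`, `on_in_some`, `off_in_all` and columns `with_evidence`,
#'   `without_evidence`.
#' @export
cross_tabulate <- function(calls, evidence, subset = NULL) {
  genes <- names(calls$summary)
  if (is.null(subset)) subset <- genes
  missing <- setdiff(subset, genes)
  if (length(missing))
    stop("subset gene absent from calls: ", missing[1L])
  cls <- calls$summary[subset]
  has_ev <- factor(subset %in% evidence, levels = c(TRUE, FALSE),
                   labels = c("with_evidence", "without_evidence"))
  tab <- table(cls, has_ev)
  out <- matrix(as.integer(tab), nrow = 3L,
                dimnames = list(levels(cls), colnames(tab)))
  structure(out, off_array_evidence = setdiff(evidence, genes),
            subset_size = length(subset),
            class = c("EvidenceCrossTable", "matrix"))
}
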
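#' Row z-score normalization
#'
#' Relative (normalized) expression for heat-map display: per gene,
#' `(intensity - row mean) / row standard deviation`. The standard deviation
#' uses the sample (n-1) denominator by default, matching the spreadsheet
#' convention of the formula's ecosystem; `sd_denom = "n"` switches to the
#' population denominator. Constant rows (sd = 0) cannot be scaled: they are
#' returned as all-zero and flagged.
#'
#' @param x An `ExpressionMatrix` or named numeric matrix with >= 2 samples.
#' @param sd_denom `"n-1"` (default) or `"n"`.
#' @return An object of class `NormalizedMatrix`: list with `values`
#'   (genes x samples numeric matrix) and `degenerate` (named logical flag
#'   per gene).
#' @export
row_zscore <- function(x, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  m <- as_intensity_matrix(x)
  k <- ncol(m)
  if (k < 2L) stop("row z-scores need at least 2 samples")
  mu <- rowMeans(m)
  centered <- m - mu
  denom <- if (sd_denom == "n-1") k - 1L else k
  s <- sqrt(rowSums(centered^2) / denom)
  degenerate <- s == 0
  s[degenerate] <- 1  # rows are exactly zero after centering anyway
  z <- centered / s
  z[degenerate, ] <- 0
  structure(list(values = z, degenerate = degenerate),
            class = "NormalizedMatrix")
}

#' Write a normalized (heat-map-ready) matrix as TSV
#' @param x A `NormalizedMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized_matrix <- function(x, path) {
  m <- x$values
  out <- cbind(gene_id = rownames(m),
               apply(m, 2L, function(col) sprintf("%.17g", col)),
               degenerate = ifelse(x$degenerate, "1", "0"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample-level principal component analysis
#'
#' PCA of the transposed gene x sample matrix: samples are the observations
#' and genes the variables. Variables are centered but not scaled to unit
#' variance (covariance PCA). Scores are returned for
#' `min(samples - 1, genes)` components.
#'
#' @param x An `ExpressionMatrix` or named numeric matrix with >= 2 samples
#'   and >= 2 genes.
#' @return An object of class `PcaResult`: list with `scores`
#'   (samples x components), `var_explained` (percent, non-increasing), and
#'   `sdev`.
#' @export
pca_samples <- function(x) {
  m <- as_intensity_matrix(x)
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop("PCA needs at least 2 samples and 2 genes")
  p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  if (total <= .Machine$double.eps) {
    warning("all samples are identical; zero-variance PCA result")
    ve <- rep(0, length(p$sdev))
  } else {
    ve <- 100 * p$sdev^2 / total
  }
  k <- min(ncol(m) - 1L, nrow(m))
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 sdev = p$sdev[seq_len(k)],
                 total_variance = total),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$var_explained, 5L)),
            collapse = ", "), "...\n")
  invisible(x)
}
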
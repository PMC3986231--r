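#' Construct an expression matrix
#'
#' The core container of the pipeline: a gene-by-sample matrix of absolute
#' (non-negative) fluorescence intensities, with unique gene and sample
#' identifiers and an optional mapping from samples to experimental
#' condition labels (e.g. `"TCEM"`, `"LS"`).
#'
#' @param intensities Numeric matrix (genes x samples) with unique, non-empty
#'   rownames (gene ids) and colnames (sample ids). All values must be finite
#'   and >= 0. Missing cells are a hard error, never imputed: the pipeline
#'   analyzes pre-processed complete matrices.
#' @param conditions Optional named character vector mapping sample id to
#'   condition label. Names must cover all sample ids.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `intensities` (the validated matrix) and `conditions`.
#' @export
expression_matrix <- function(intensities, conditions = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  gid <- rownames(intensities)
  sid <- colnames(intensities)
  if (is.null(gid) || anyNA(gid) || any(gid == ""))
    stop("gene identifiers (rownames) are required and must be non-empty")
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    stop("sample identifiers (colnames) are required and must be non-empty")
  if (anyDuplicated(gid))
    stop("duplicate gene identifier: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample identifier: ", sid[duplicated(sid)][1L])
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("all intensities must be finite; missing values are not imputed")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  if (!is.null(conditions)) {
    conditions <- vapply(conditions, as.character, character(1L))
    missing <- setdiff(sid, names(conditions))
    if (length(missing))
      stop("no condition label for sample: ", missing[1L])
    conditions <- conditions[sid]
  }
  structure(list(intensities = intensities, conditions = conditions),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  if (!is.null(x$conditions))
    cat("conditions:", paste(unique(x$conditions), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$intensities)

#' Gene and sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$intensities)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$intensities)

# Accept either an ExpressionMatrix or a bare named numeric matrix.
as_intensity_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) return(x$intensities)
  expression_matrix(x)$intensities
}

#' Read an expression matrix from a delimited file
#'
#' Expects a header row; the first column holds gene ids and every remaining
#' column one sample's intensities.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param conditions Optional named character vector of sample conditions,
#'   passed through to [expression_matrix()].
#' @return An `ExpressionMatrix`, with row order preserved from the file.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"),
                                   conditions = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expected a gene_id column plus at least one sample column in ", path)
  gid <- df[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene identifier in ", path, ": ",
         gid[duplicated(gid)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric intensity at row %d (gene %s), column %s",
                 bad[1L], gid[bad[1L]], colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(gid, colnames(vals))
  expression_matrix(num, conditions = conditions)
}

#' Write an expression matrix to a delimited file
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip is value-identical.
#'
#' @param x An `ExpressionMatrix` or named numeric matrix.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  m <- as_intensity_matrix(x)
  out <- cbind(gene_id = rownames(m),
               apply(m, 2L, function(col) sprintf("%.17g", col)))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a gene-to-subsystem mapping
#'
#' Maps each gene to exactly one functional category: one of the metabolic
#' model's subsystems, or `"unknown function"` / `"non-metabolic function"`.
#' The category vocabulary is taken from the file itself; labels are opaque
#' strings.
#'
#' @param path Two-column TSV with header `gene_id` and `category`.
#' @return Named character vector: `gene_id -> category`.
#' @export
read_subsystem_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (!all(c("gene_id", "category") %in% colnames(df)))
    stop("subsystem map must have columns gene_id and category")
  if (anyDuplicated(df$gene_id))
    stop("gene mapped to more than one category: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  stats::setNames(df$category, df$gene_id)
}

#' Write a gene-to-subsystem mapping
#' @param map Named character vector `gene_id -> category`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subsystem_map <- function(map, path) {
  utils::write.table(
    data.frame(gene_id = names(map), category = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proteomic-evidence gene list
#'
#' @param path One-column TSV with header `gene_id`.
#' @param provenance Free-text provenance tag attached to the result.
#' @return Character vector of gene ids with attribute `"provenance"`.
#'   Subset relations to a gene universe are checked where the list is used,
#'   not at construction.
#' @export
read_evidence_list <- function(path, provenance = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (!"gene_id" %in% colnames(df))
    stop("evidence list must have a gene_id column")
  structure(unique(df$gene_id), provenance = provenance)
}

#' Write a proteomic-evidence gene list
#' @param ids Character vector of gene ids.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence_list <- function(ids, path) {
  utils::write.table(data.frame(gene_id = ids), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_genome_table <- function(df) {
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(req %in% colnames(df)))
    stop("genome table needs columns: ", paste(req, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-integer gene coordinates")
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("start > end for gene ", df$gene_id[bad[1L]])
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         setdiff(unique(df$strand), c("+", "-"))[1L])
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene identifier: ", df$gene_id[duplicated(df$gene_id)][1L])
  df <- df[order(df$contig_id, df$start, df$end), req]
  rownames(df) <- NULL
  df
}

#' Read a genome gene table
#'
#' Gene coordinates are 1-based inclusive throughout (GFF3 convention).
#' Two dialects are supported: GFF3 (rows of type `gene`, falling back to
#' `CDS` when no `gene` rows exist, identified by their `ID` attribute) and a
#' flat TSV with columns `gene_id`, `contig_id`, `start`, `end`, `strand`.
#'
#' @param path File path.
#' @param dialect `"flat_tsv"` or `"gff3"`.
#' @return A data.frame sorted by (contig_id, start) with the five columns
#'   above.
#' @export
read_genome_table <- function(path, dialect = c("flat_tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- gr[gr$type == "gene"]
    if (length(keep) == 0L) keep <- gr[gr$type == "CDS"]
    if (length(keep) == 0L)
      stop("no gene or CDS records in ", path)
    strand <- as.character(BiocGenerics::strand(keep))
    if (any(strand == "*"))
      stop("unknown strand symbol: *")
    df <- data.frame(
      gene_id = as.character(keep$ID),
      contig_id = as.character(GenomicRanges::seqnames(keep)),
      start = BiocGenerics::start(keep),
      end = BiocGenerics::end(keep),
      strand = strand,
      stringsAsFactors = FALSE)
  }
  validate_genome_table(df)
}

#' Write a genome gene table as flat TSV
#' @param genome Genome table data.frame (see [read_genome_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(genome, path) {
  genome <- validate_genome_table(genome)
  utils::write.table(genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pooled GC content of nucleotide sequences
#'
#' Computes (G+C)/(A+C+G+T) pooled over all sequences; `N` bases are excluded
#' from both numerator and denominator. Case-insensitive, and invariant under
#' sequence concatenation order. Used to verify draft-genome contig sets
#' against their reported GC fraction.
#'
#' @param sequences Character vector of sequences over \{A,C,G,T,N\}, or a
#'   [Biostrings::DNAStringSet] (e.g. from [Biostrings::readDNAStringSet()]).
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- toupper(as.character(sequences))
    bad <- gsub("[ACGTN]", "", paste(sequences, collapse = ""))
    if (nchar(bad) > 0L)
      stop("sequences may contain only A, C, G, T, N; found: ",
           substr(bad, 1L, 1L))
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  freq <- colSums(Biostrings::alphabetFrequency(sequences, baseOnly = TRUE))
  counted <- sum(freq[c("A", "C", "G", "T")])
  if (counted == 0L)
    stop("no countable (non-N) bases in the pool")
  unname(sum(freq[c("G", "C")]) / counted)
}
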
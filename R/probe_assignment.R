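#' Analysis tags for the three-way probe assignment
#'
#' The community shotgun-array probes are screened by three independent
#' alignments: against the non-redundant nucleotide database (`blastn`),
#' against the non-redundant protein database (`blastx`), and against the
#' draft composite genome. A probe is kept only when the three analyses
#' agree that it is \emph{Dehalococcoides mccartyi}.
#' @export
ANALYSIS_TAGS <- c("nt_nucleotide", "nr_protein", "composite_genome")

#' Construct a hit table
#'
#' @param query_id,subject_id Character vectors.
#' @param percent_identity Numeric in \[0, 100\].
#' @param bitscore Numeric.
#' @param taxon_label Character; pre-resolved taxon of the subject.
#' @param analysis_tag One of [ANALYSIS_TAGS], fixed for the whole table.
#' @return A data.frame of class `HitTable` with attribute `analysis_tag`.
#' @export
hit_table <- function(query_id, subject_id, percent_identity, bitscore,
                      taxon_label, analysis_tag) {
  analysis_tag <- match.arg(analysis_tag, ANALYSIS_TAGS)
  if (any(percent_identity < 0 | percent_identity > 100))
    stop("percent_identity must lie in [0, 100]")
  df <- data.frame(query_id = as.character(query_id),
                   subject_id = as.character(subject_id),
                   percent_identity = as.numeric(percent_identity),
                   bitscore = as.numeric(bitscore),
                   taxon_label = as.character(taxon_label),
                   stringsAsFactors = FALSE)
  structure(df, analysis_tag = analysis_tag,
            class = c("HitTable", "data.frame"))
}

#' Read an alignment hit table (tabular, outfmt-6 style)
#'
#' Expects the 12 standard tabular alignment columns plus one appended
#' column holding the subject's pre-resolved taxon label. No header.
#'
#' @param path File path.
#' @param analysis_tag One of [ANALYSIS_TAGS].
#' @return A `HitTable`.
#' @export
read_hit_table <- function(path, analysis_tag) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) != 13L)
    stop("expected 12 tabular alignment columns plus a taxon label in ", path)
  hit_table(query_id = df[[1L]], subject_id = df[[2L]],
            percent_identity = df[[3L]], bitscore = df[[12L]],
            taxon_label = df[[13L]], analysis_tag = analysis_tag)
}

#' Write a hit table in the 13-column tabular dialect
#' @param table A `HitTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(table, path) {
  out <- data.frame(table$query_id, table$subject_id,
                    sprintf("%.17g", table$percent_identity),
                    0L, 0L, 0L, 0L, 0L, 0L, 0L, 0,
                    sprintf("%.17g", table$bitscore), table$taxon_label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Best hit per query
#'
#' Per query, the row with the maximal bitscore. Ties are broken
#' deterministically: higher percent identity, then lexicographically
#' smallest subject id.
#'
#' @param table A `HitTable` (nonempty).
#' @return A `HitTable` with one row per query id.
#' @export
best_hit <- function(table) {
  if (nrow(table) == 0L) stop("hit table is empty")
  ord <- order(table$query_id, -table$bitscore, -table$percent_identity,
               table$subject_id, method = "radix")
  out <- table[ord, , drop = FALSE][!duplicated(table$query_id[ord]), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  structure(out, analysis_tag = attr(table, "analysis_tag"),
            class = c("HitTable", "data.frame"))
}

#' Per-analysis pass/fail verdict on best hits
#'
#' A best hit passes iff its taxon label is \emph{D. mccartyi} AND its
#' identity strictly exceeds the threshold for the table's analysis tag
#' (the identity rules are strict `>`: a nucleotide hit at exactly 85.0
#' fails).
#'
#' @param best A `HitTable` of best hits (see [best_hit()]).
#' @param config A [pipeline_config()]; carries `identity_nt` (85),
#'   `identity_aa` (95), `identity_composite` (95) and `dhc_labels`.
#' @return Character vector (`"pass"`/`"fail"`) named by query id.
#' @export
hit_verdict <- function(best, config = pipeline_config()) {
  tag <- attr(best, "analysis_tag")
  thr <- switch(tag,
                nt_nucleotide = config$identity_nt,
                nr_protein = config$identity_aa,
                composite_genome = config$identity_composite,
                stop("unknown analysis tag: ", tag))
  ok <- best$taxon_label %in% config$dhc_labels &
    best$percent_identity > thr
  stats::setNames(ifelse(ok, "pass", "fail"), best$query_id)
}

#' Three-way consensus probe assignment
#'
#' Compares the verdicts of the three analyses per probe. In the default
#' (`consensus_mode = "majority"`) reading, a probe is consensus-assigned to
#' \emph{D. mccartyi} when no analysis that produced a hit contradicts it and
#' at least two analyses affirm it; some probes lack protein hits by design.
#' `consensus_mode = "strict"` requires all three analyses to pass.
#'
#' @param tables List of three `HitTable`s with distinct, complete analysis
#'   tags.
#' @param config A [pipeline_config()].
#' @return A data.frame of class `AssignmentResult` with per-probe verdicts
#'   (`"pass"`, `"fail"`, `"no_hit"`) per analysis and the final `consensus`
#'   logical; attribute `"n_assigned"` carries the consensus-true count.
#' @export
consensus_assign <- function(tables, config = pipeline_config()) {
  tags <- vapply(tables, attr, character(1L), "analysis_tag")
  if (anyDuplicated(tags))
    stop("duplicate analysis tag: ", tags[duplicated(tags)][1L])
  if (!setequal(tags, ANALYSIS_TAGS))
    stop("the three analysis tags must be exactly: ",
         paste(ANALYSIS_TAGS, collapse = ", "))
  names(tables) <- tags
  verdicts <- lapply(tables, function(tb) hit_verdict(best_hit(tb), config))
  queries <- sort(unique(unlist(lapply(verdicts, names))))
  vmat <- vapply(ANALYSIS_TAGS, function(tag) {
    v <- verdicts[[tag]][queries]
    ifelse(is.na(v), "no_hit", v)
  }, character(length(queries)))
  if (length(queries) == 1L) vmat <- matrix(vmat, nrow = 1L,
                                            dimnames = list(NULL, ANALYSIS_TAGS))
  rownames(vmat) <- NULL
  n_pass <- rowSums(vmat == "pass")
  n_fail <- rowSums(vmat == "fail")
  consensus <- if (identical(config$consensus_mode, "strict")) {
    n_pass == 3L
  } else {
    n_fail == 0L & n_pass >= 2L
  }
  out <- data.frame(query_id = queries,
                    nt_nucleotide = vmat[, "nt_nucleotide"],
                    nr_protein = vmat[, "nr_protein"],
                    composite_genome = vmat[, "composite_genome"],
                    consensus = consensus,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_assigned = sum(consensus),
            consensus_mode = config$consensus_mode,
            class = c("AssignmentResult", "data.frame"))
}
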
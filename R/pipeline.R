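#' Pipeline configuration
#'
#' One auditable container for every numeric threshold the analysis fixes:
#' the dataset-specific on/off intensity thresholds (800 for the pure-culture
#' strain 195 arrays, 100 for the KB-1 community arrays), the QT clustering
#' diameter and minimum size (0.06 and 7), the enrichment significance level
#' (0.05), the operon posterior threshold (0.5), and the probe-assignment
#' identity cut-offs (>85 nucleotide, >95 amino acid, >95 for the composite
#' genome). The configuration is echoed verbatim into every output
#' directory's manifest.
#'
#' @param threshold_strain195 On/off intensity threshold for strain 195 data.
#' @param threshold_kb1 On/off intensity threshold for KB-1 data.
#' @param qt_max_diameter QT cluster diameter bound on the `1 - rho_s` scale.
#' @param qt_min_size Minimum QT cluster size.
#' @param alpha Enrichment significance level.
#' @param operon_tau Operon posterior threshold.
#' @param identity_nt,identity_aa,identity_composite Strict (`>`) identity
#'   thresholds for the three probe analyses.
#' @param consensus_mode `"majority"` (no contradicting hit, >= 2 affirming)
#'   or `"strict"` (all three analyses pass).
#' @param universe Enrichment universe: `"clustered_genes"` or `"all_genes"`.
#' @param sd_denom Row z-score standard-deviation denominator.
#' @param dhc_labels Taxon labels accepted as \emph{D. mccartyi}.
#' @param seed Integer seed for stages that draw random numbers.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(threshold_strain195 = 800,
                            threshold_kb1 = 100,
                            qt_max_diameter = 0.06,
                            qt_min_size = 7L,
                            alpha = 0.05,
                            operon_tau = 0.5,
                            identity_nt = 85,
                            identity_aa = 95,
                            identity_composite = 95,
                            consensus_mode = c("majority", "strict"),
                            universe = c("clustered_genes", "all_genes"),
                            sd_denom = c("n-1", "n"),
                            dhc_labels = c("Dehalococcoides mccartyi",
                                           "D. mccartyi"),
                            seed = 1L) {
  cfg <- list(threshold_strain195 = as.numeric(threshold_strain195),
              threshold_kb1 = as.numeric(threshold_kb1),
              qt_max_diameter = as.numeric(qt_max_diameter),
              qt_min_size = as.integer(qt_min_size),
              alpha = as.numeric(alpha),
              operon_tau = as.numeric(operon_tau),
              identity_nt = as.numeric(identity_nt),
              identity_aa = as.numeric(identity_aa),
              identity_composite = as.numeric(identity_composite),
              consensus_mode = match.arg(consensus_mode),
              universe = match.arg(universe),
              sd_denom = match.arg(sd_denom),
              dhc_labels = dhc_labels,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$threshold_strain195 > 0, "threshold_strain195 must be > 0")
  chk(cfg$threshold_kb1 > 0, "threshold_kb1 must be > 0")
  chk(cfg$qt_max_diameter >= 0, "qt_max_diameter must be >= 0")
  chk(cfg$qt_min_size >= 1L, "qt_min_size must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  chk(cfg$operon_tau > 0 && cfg$operon_tau < 1, "operon_tau must be in (0, 1)")
  for (f in c("identity_nt", "identity_aa", "identity_composite"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 100, paste(f, "must be in [0, 100]"))
  invisible(cfg)
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are an
#' error. Values for numeric fields are coerced; `dhc_labels` may be a
#' comma-separated list.
#'
#' @param path File path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  defaults <- formals(pipeline_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown configuration key: ", unknown[1L])
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("threshold_strain195", "threshold_kb1", "qt_max_diameter",
                    "qt_min_size", "alpha", "operon_tau", "identity_nt",
                    "identity_aa", "identity_composite", "seed")
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  if ("dhc_labels" %in% names(args))
    args$dhc_labels <- trimws(strsplit(args$dhc_labels, ",")[[1L]])
  do.call(pipeline_config, args)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, cfg, inputs, stages) {
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  sums <- tools::md5sum(files)
  entries <- c(
    paste0("package_version\t", as.character(utils::packageVersion("dhcmeta"))),
    paste0("stages\t", paste(stages, collapse = ",")),
    paste0("config.", names(unclass(cfg)), "\t",
           vapply(unclass(cfg), function(v) paste(v, collapse = ","), "")),
    paste0("input.", names(inputs), "\t", unlist(inputs)),
    paste0("md5.", substring(files, nchar(outdir) + 2L), "\t", unname(sums)))
  writeLines(c("key\tvalue", entries), file.path(outdir, "manifest.tsv"))
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind one entry point. `stage = "simulate"`
#' writes a complete synthetic input set (expression matrix, subsystem map,
#' evidence list, genome table, adjacency barcode, hit tables, truth files)
#' under `outdir/inputs`. The analysis stages read their inputs from
#' `input_dir` (default `outdir/inputs`) and write TSV outputs plus a
#' deterministic run manifest (configuration echo, input checksums, package
#' version) to `outdir`. `stage = "all"` simulates and then runs every
#' analysis stage. Given the same configuration, seed, and inputs, all
#' outputs are byte-identical across runs.
#'
#' @param config A `PipelineConfig`.
#' @param stage One of `"all"`, `"simulate"`, `"assign"`, `"calls"`,
#'   `"cluster"`, `"enrich"`, `"operons"`.
#' @param outdir Output directory (created if needed).
#' @param input_dir Directory holding the stage inputs; defaults to
#'   `file.path(outdir, "inputs")`.
#' @param sim_args Optional list of overrides passed to
#'   [simulate_expression()] / [simulate_genome()] /
#'   [simulate_hit_tables()] (names: `expression`, `genome`, `hits`).
#' @return Invisibly, a list of the stage results; outputs are on disk.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stage = c("all", "simulate", "assign", "calls",
                                   "cluster", "enrich", "operons"),
                         outdir,
                         input_dir = file.path(outdir, "inputs"),
                         sim_args = list()) {
  stage <- match.arg(stage)
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "assign", "calls", "cluster", "enrich", "operons")
  else stage
  results <- list()

  need <- function(name) {
    p <- file.path(input_dir, name)
    if (!file.exists(p))
      stop("missing input file: ", p,
           " (run the simulate stage or point input_dir at your data)")
    p
  }

  if ("simulate" %in% stages) {
    dir.create(input_dir, recursive = TRUE, showWarnings = FALSE)
    ex <- do.call(simulate_expression,
                  c(list(seed = config$seed,
                         truth_threshold = config$threshold_strain195),
                    sim_args$expression))
    write_expression_matrix(ex$matrix, file.path(input_dir, "expression.tsv"))
    write_tsv(data.frame(sample_id = sample_ids(ex$matrix),
                         condition = unname(ex$matrix$conditions)),
              file.path(input_dir, "conditions.tsv"))
    write_subsystem_map(ex$subsystems, file.path(input_dir, "subsystems.tsv"))
    # proteomic evidence: a sample of genes realized on-in-all, plus strays
    on_all <- ex$class_truth$gene_id[ex$class_truth$realized == "on_in_all"]
    ev <- sort(sample(on_all, size = max(1L, round(0.6 * length(on_all)))))
    write_evidence_list(ev, file.path(input_dir, "evidence.tsv"))
    write_tsv(ex$cluster_truth, file.path(input_dir, "truth_clusters.tsv"))
    write_tsv(ex$class_truth, file.path(input_dir, "truth_classes.tsv"))

    gn <- do.call(simulate_genome,
                  c(list(seed = config$seed + 1L,
                         n_references = 27L),
                    sim_args$genome))
    write_genome_table(gn$genome, file.path(input_dir, "genome.tsv"))
    write_tsv(as.data.frame(gn$barcode * 1L),
              file.path(input_dir, "barcode.tsv"))
    write_tsv(gn$pair_truth, file.path(input_dir, "truth_pairs.tsv"))

    ht <- do.call(simulate_hit_tables,
                  c(list(seed = config$seed + 2L), sim_args$hits))
    for (tag in ANALYSIS_TAGS)
      write_hit_table(ht$tables[[tag]],
                      file.path(input_dir, paste0("hits_", tag, ".tsv")))
    write_tsv(ht$truth, file.path(input_dir, "truth_probes.tsv"))
    results$simulate <- list(expression = ex, genome = gn, hits = ht)
  }

  if ("assign" %in% stages) {
    tables <- lapply(ANALYSIS_TAGS, function(tag)
      read_hit_table(need(paste0("hits_", tag, ".tsv")), tag))
    asg <- consensus_assign(tables, config)
    write_tsv(asg, file.path(outdir, "assignment.tsv"))
    results$assign <- asg
  }

  mat <- NULL
  read_mat <- function() {
    if (is.null(mat))
      mat <<- read_expression_matrix(need("expression.tsv"))
    mat
  }

  if ("calls" %in% stages) {
    m <- read_mat()
    calls <- call_on_off(m, config$threshold_strain195)
    ev <- read_evidence_list(need("evidence.tsv"))
    xt <- cross_tabulate(calls, ev)
    write_tsv(data.frame(gene_id = names(calls$summary),
                         summary = as.character(calls$summary),
                         n_on = rowSums(calls$calls)),
              file.path(outdir, "calls_summary.tsv"))
    xt_df <- data.frame(summary = rep(rownames(xt), times = ncol(xt)),
                        evidence = rep(colnames(xt), each = nrow(xt)),
                        count = as.integer(xt))
    write_tsv(xt_df, file.path(outdir, "evidence_crosstab.tsv"))
    results$calls <- list(calls = calls, crosstab = xt)
  }

  qt <- NULL
  if ("cluster" %in% stages) {
    m <- read_mat()
    nm <- row_zscore(m, sd_denom = config$sd_denom)
    write_normalized_matrix(nm, file.path(outdir, "normalized.tsv"))
    pca <- pca_samples(m)
    write_tsv(cbind(data.frame(sample_id = rownames(pca$scores)),
                    as.data.frame(pca$scores)),
              file.path(outdir, "pca_scores.tsv"))
    write_tsv(data.frame(component = seq_along(pca$var_explained),
                         var_explained_pct = pca$var_explained),
              file.path(outdir, "pca_variance.tsv"))
    d <- spearman_distance(m)
    qt <- qt_clustering(d, config$qt_max_diameter, config$qt_min_size)
    write_tsv(qt_members(qt, include_unclustered = TRUE),
              file.path(outdir, "qt_clusters.tsv"))
    trees <- vapply(qt$clusters, function(cl)
      cluster_newick(hierarchical_order(cl$members, d)), character(1L))
    writeLines(trees, file.path(outdir, "cluster_trees.nwk"))
    results$cluster <- list(qt = qt, pca = pca)
  }

  if ("enrich" %in% stages) {
    if (is.null(qt)) {
      m <- read_mat()
      d <- spearman_distance(m)
      qt <- qt_clustering(d, config$qt_max_diameter, config$qt_min_size)
    }
    subs <- read_subsystem_map(need("subsystems.tsv"))
    enr <- enrich_clusters(qt, subs, universe = config$universe,
                           alpha = config$alpha)
    write_tsv(as.data.frame(enr), file.path(outdir, "enrichment.tsv"))
    results$enrich <- enr
  }

  if ("operons" %in% stages) {
    genome <- read_genome_table(need("genome.tsv"), "flat_tsv")
    bc <- as.matrix(utils::read.table(need("barcode.tsv"), header = TRUE,
                                      sep = "\t")) > 0
    op <- predict_operons(genome, bc, tau = config$operon_tau)
    write_tsv(op$pairs, file.path(outdir, "operon_pairs.tsv"))
    op_df <- if (length(op$operons)) data.frame(
      operon_id = rep(seq_along(op$operons),
                      lengths(op$operons)),
      gene_id = unlist(op$operons)) else
        data.frame(operon_id = integer(), gene_id = character())
    write_tsv(op_df, file.path(outdir, "operons.tsv"))
    s <- op$summary
    write_tsv(data.frame(genome = "input", n_genes = s$n_genes,
                         operonic_genes = s$operonic_genes,
                         operonic_fraction = s$operonic_fraction,
                         multigene_operons = s$n_multigene_operons,
                         positive_pairs = s$n_positive_pairs),
              file.path(outdir, "operon_summary.tsv"))
    results$operons <- op
  }

  write_manifest(outdir, config,
                 inputs = list(dir = basename(input_dir)),
                 stages = stages)
  invisible(results)
}
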
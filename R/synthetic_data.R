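#' Default subsystem vocabulary for simulations
#'
#' Seven metabolic functional categories in the style of the pan-genome
#' metabolic model, plus the two catch-all categories used for genes outside
#' the model.
#' @return Character vector of category labels.
#' @export
default_subsystems <- function() {
  c("Central Carbon Metabolism", "Amino Acid Metabolism",
    "Nucleotide Metabolism", "Lipid Metabolism",
    "Cofactor and Vitamin Metabolism", "Energy Metabolism", "Transport",
    "unknown function", "non-metabolic function")
}

#' Default planted co-expression clusters
#'
#' Eight clusters spanning the study's observed cluster-size range (7-31
#' genes) with a stringent within-cluster Spearman target of 0.97, each
#' tagged with a functional category so enrichment is recoverable.
#' @return List of cluster specifications for [simulate_expression()].
#' @export
default_planted_clusters <- function() {
  sizes <- c(31L, 25L, 20L, 16L, 12L, 10L, 8L, 7L)
  cats <- default_subsystems()[c(1:7, 1L)]
  mapply(function(s, cat) list(size = s, rho = 0.97, category = cat),
         sizes, cats, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Simulate an expression matrix with known ground truth
#'
#' Emulates the structure of the study's absolute-intensity arrays: a
#' gene-by-sample matrix over replicated conditions, a right-skewed bimodal
#' intensity pool (log-normal off and on components), planted co-expressed
#' gene clusters with controllable within-cluster Spearman correlation, and
#' a gene-to-subsystem map. Defaults mirror the pure-culture dataset's
#' shape: 1560 genes, 9 conditions x 3 replicates = 27 samples, roughly 15%
#' of genes off in all samples and 26% on in only some, with off intensities
#' centred near 50 and on intensities near 2000 on either side of the 800
#' threshold.
#'
#' Planted co-expression uses a shared condition-level latent profile per
#' cluster plus Gaussian jitter; the latent weight is chosen through the
#' Gaussian rank-correlation identity (`r = 2 sin(pi * rho_s / 6)`) so the
#' realized pairwise Spearman correlation matches the target. All remaining
#' "on" genes share a weak array-wide condition effect (so replicate samples
#' group in PCA) but are otherwise independent.
#'
#' @param n_genes Total gene count.
#' @param conditions Named integer vector: replicate count per condition.
#' @param clusters List of planted clusters, each
#'   `list(size =, rho =, category =)` with `rho` the target within-cluster
#'   Spearman correlation in (0, 1].
#' @param off_fraction,some_fraction Intended fractions of genes off in all
#'   samples / on in only some samples (the remainder is intended on in all).
#' @param off_meanlog,off_sdlog,on_meanlog,on_sdlog Log-normal intensity
#'   component parameters (natural-log scale); the `sdlog` values are the
#'   between-gene spread of per-gene base levels.
#' @param within_gene_sdlog Within-gene, per-sample log-scale noise around a
#'   gene's base level. Keeping this well below the between-gene spread is
#'   what lets an always-on gene actually stay above the threshold in all
#'   samples.
#' @param condition_effect_sd Standard deviation of the shared per-condition
#'   effect on the log intensity of "on" genes.
#' @param truth_threshold Intensity threshold used to record the realized
#'   on/off class of every gene (default the study's 800).
#' @param seed Integer seed; fixes all randomness.
#' @return List with `matrix` (an `ExpressionMatrix` with condition labels),
#'   `cluster_truth` (data.frame `gene_id`, `cluster`; 0 = background),
#'   `class_truth` (data.frame `gene_id`, `intended`, `realized` at
#'   `truth_threshold`), `subsystems` (named vector), and `params`.
#' @export
simulate_expression <- function(n_genes = 1560,
                                conditions = stats::setNames(
                                  rep(3L, 9L),
                                  c("EE", "LE", "TR", "ES", "LS", "HighB12",
                                    "LowB12", "ANASmedium", "ANASspent")),
                                clusters = default_planted_clusters(),
                                off_fraction = 0.15,
                                some_fraction = 0.26,
                                off_meanlog = log(50), off_sdlog = 0.5,
                                on_meanlog = log(2000), on_sdlog = 0.6,
                                within_gene_sdlog = 0.2,
                                condition_effect_sd = 0.25,
                                truth_threshold = 800,
                                seed = 1L) {
  stopifnot(n_genes >= 1L, all(conditions >= 1L),
            off_fraction >= 0, some_fraction >= 0,
            off_fraction + some_fraction <= 1)
  csize <- vapply(clusters, function(cl) as.integer(cl$size), integer(1L))
  crho <- vapply(clusters, function(cl) as.numeric(cl$rho), numeric(1L))
  if (any(crho <= 0 | crho > 1))
    stop("cluster rho targets must lie in (0, 1]")
  if (sum(csize) > n_genes)
    stop("planted cluster sizes exceed the gene count")
  set.seed(seed)
  n_samples <- sum(conditions)
  cond_of <- rep(names(conditions), conditions)
  sample_ids <- paste0(cond_of, "_r",
                       unlist(lapply(conditions, seq_len), use.names = FALSE))
  names(cond_of) <- sample_ids
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))

  # intended class layout: cluster members must be on-in-all genes
  n_off <- round(off_fraction * n_genes)
  n_some <- round(some_fraction * n_genes)
  n_all <- n_genes - n_off - n_some
  if (sum(csize) > n_all)
    stop("planted clusters (", sum(csize), " genes) exceed the on-in-all ",
         "pool (", n_all, "); raise n_genes or lower off/some fractions")
  intended <- rep(c("on_in_all", "on_in_some", "off_in_all"),
                  c(n_all, n_some, n_off))
  intended <- sample(intended)
  # place cluster members on on_in_all genes, deterministically post-shuffle
  on_all_idx <- which(intended == "on_in_all")
  member_of <- integer(n_genes)  # 0 = background
  used <- 0L
  for (ci in seq_along(clusters)) {
    take <- on_all_idx[used + seq_len(csize[ci])]
    member_of[take] <- ci
    used <- used + csize[ci]
  }

  cond_effect <- stats::rnorm(length(conditions), 0, condition_effect_sd)
  names(cond_effect) <- names(conditions)
  sample_effect <- cond_effect[cond_of]

  logm <- matrix(NA_real_, n_genes, n_samples,
                 dimnames = list(gene_ids, sample_ids))
  # cluster latents: one standardized condition-level profile per cluster
  latents <- lapply(seq_along(clusters), function(ci) {
    u <- stats::rnorm(length(conditions))
    # condition-level signal plus a per-sample component shared by all
    # members: members agree on full sample ranks, replicates still group
    v <- u[match(cond_of, names(conditions))] +
      0.35 * stats::rnorm(n_samples)
    (v - mean(v)) / stats::sd(v)
  })
  for (g in seq_len(n_genes)) {
    ci <- member_of[g]
    if (ci > 0L) {
      # overshoot the target by ~1.3 sampling sd so realized pairwise
      # Spearman stays >= target for the vast majority of member pairs
      rho_adj <- min(0.999999,
                     crho[ci] + 1.3 * (1 - crho[ci]^2) / sqrt(n_samples))
      r <- 2 * sin(pi * rho_adj / 6)
      prof <- sqrt(r) * latents[[ci]] +
        sqrt(1 - r) * stats::rnorm(n_samples)
      gene_base <- on_meanlog + on_sdlog * stats::rnorm(1L)
      logm[g, ] <- gene_base + within_gene_sdlog * prof
    } else {
      # every gene has a stable base level (between-gene law) and smaller
      # per-sample noise, so intended classes realize with high probability
      base <- switch(intended[g],
        off_in_all = off_meanlog + off_sdlog * stats::rnorm(1L) +
          within_gene_sdlog * stats::rnorm(n_samples),
        on_in_all = on_meanlog + on_sdlog * stats::rnorm(1L) +
          sample_effect + within_gene_sdlog * stats::rnorm(n_samples),
        on_in_some = {
          n_on <- sample(seq_len(n_samples - 1L), 1L)
          on_s <- sample(n_samples, n_on)
          v <- off_meanlog + off_sdlog * stats::rnorm(1L) +
            within_gene_sdlog * stats::rnorm(n_samples)
          v[on_s] <- on_meanlog + on_sdlog * stats::rnorm(1L) +
            sample_effect[on_s] + within_gene_sdlog * stats::rnorm(n_on)
          v
        })
      logm[g, ] <- base
    }
  }
  intens <- exp(logm)

  # realized class bookkeeping by an independent straight-line scan
  realized <- character(n_genes)
  for (g in seq_len(n_genes)) {
    on <- intens[g, ] > truth_threshold
    realized[g] <- if (all(on)) "on_in_all"
                   else if (!any(on)) "off_in_all" else "on_in_some"
  }

  pool <- default_subsystems()
  subsystems <- sample(pool, n_genes, replace = TRUE,
                       prob = c(rep(0.06, 7), 0.33, 0.25))
  for (ci in seq_along(clusters)) {
    idx <- which(member_of == ci)
    lab <- clusters[[ci]]$category
    keep <- stats::runif(length(idx)) < 0.9  # 90% category purity
    subsystems[idx[keep]] <- lab
  }
  names(subsystems) <- gene_ids

  list(matrix = expression_matrix(intens, conditions = cond_of),
       cluster_truth = data.frame(gene_id = gene_ids, cluster = member_of,
                                  stringsAsFactors = FALSE),
       class_truth = data.frame(gene_id = gene_ids, intended = intended,
                                realized = realized,
                                stringsAsFactors = FALSE),
       subsystems = subsystems,
       params = list(n_genes = n_genes, conditions = conditions,
                     clusters = clusters, truth_threshold = truth_threshold,
                     seed = seed))
}

#' Simulate a genome with planted operons and adjacency barcode
#'
#' Genes are laid out along one (or more) contigs as alternating
#' transcription units whose sizes follow a shifted geometric law. Genes
#' within a unit share a strand and are separated by the within-operon
#' intergenic distance law; unit boundaries use the boundary distance law and
#' flip strand with a configurable probability. For every adjacent pair, a
#' conserved-adjacency barcode over `R` reference genomes is drawn Bernoulli
#' with class-conditional conservation probabilities. The defaults plant a
#' genome in the study regime: ~1500 genes, 27 references, ~58% of adjacent
#' pairs truly operonic, ~80% of genes in multigene units.
#'
#' @param n_genes Gene count.
#' @param mean_unit_size Mean transcription-unit size (>= 1); unit sizes are
#'   `1 + Geometric`.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (bp); lengths are floored at 100 bp.
#' @param operonic_distance_mean,operonic_distance_sd Normal law of
#'   within-operon intergenic distance (bp), truncated at
#'   `>= operonic_distance_min`.
#' @param operonic_distance_min Lower truncation (default -20 bp: modest
#'   overlaps happen).
#' @param boundary_distance_mean,boundary_distance_sd Normal law of
#'   between-unit distance, truncated at `>= 1`.
#' @param strand_flip_prob Probability that the strand flips at a unit
#'   boundary.
#' @param n_references Barcode width `R` (study value 27).
#' @param p_cons_operonic,p_cons_boundary Per-reference conservation
#'   probability for operonic / boundary pairs.
#' @param n_contigs Number of contigs to split the genes over.
#' @param seed Integer seed.
#' @return List with `genome` (genome table data.frame), `barcode` (logical
#'   pairs x R matrix, rows in [adjacent_pairs()] order), `pair_truth`
#'   (data.frame with the pair genes and the planted `operonic` flag), and
#'   `params`.
#' @export
simulate_genome <- function(n_genes = 1500, mean_unit_size = 2.4,
                            gene_length_meanlog = log(800),
                            gene_length_sdlog = 0.35,
                            operonic_distance_mean = 25,
                            operonic_distance_sd = 15,
                            operonic_distance_min = -20,
                            boundary_distance_mean = 150,
                            boundary_distance_sd = 80,
                            strand_flip_prob = 0.5,
                            n_references = 27L,
                            p_cons_operonic = 0.75,
                            p_cons_boundary = 0.15,
                            n_contigs = 1L,
                            seed = 1L) {
  stopifnot(n_genes >= 2L, mean_unit_size >= 1, n_references >= 1L,
            strand_flip_prob >= 0, strand_flip_prob <= 1,
            p_cons_operonic > 0, p_cons_operonic < 1,
            p_cons_boundary > 0, p_cons_boundary < 1)
  set.seed(seed)
  rtrunc_norm <- function(n, mean, sd, lower) {
    x <- round(stats::rnorm(n, mean, sd))
    while (any(x < lower))
      x[x < lower] <- round(stats::rnorm(sum(x < lower), mean, sd))
    as.integer(x)
  }
  # transcription unit sizes: 1 + Geometric(p), E = 1/p
  p_geom <- 1 / mean_unit_size
  sizes <- integer(0)
  while (sum(sizes) < n_genes)
    sizes <- c(sizes, 1L + stats::rgeom(max(64L, n_genes %/% 2L), p_geom))
  cut <- which(cumsum(sizes) >= n_genes)[1L]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (sum(sizes) - n_genes)
  if (sizes[cut] == 0L) sizes <- sizes[-cut]
  n_units <- length(sizes)
  unit_of <- rep(seq_len(n_units), sizes)

  unit_strand <- character(n_units)
  unit_strand[1L] <- sample(c("+", "-"), 1L)
  if (n_units > 1L) {
    flips <- stats::runif(n_units - 1L) < strand_flip_prob
    for (u in 2L:n_units)
      unit_strand[u] <- if (flips[u - 1L])
        setdiff(c("+", "-"), unit_strand[u - 1L]) else unit_strand[u - 1L]
  }
  strand <- unit_strand[unit_of]

  lens <- pmax(100L, as.integer(round(stats::rlnorm(
    n_genes, gene_length_meanlog, gene_length_sdlog))))
  within_unit <- c(FALSE, unit_of[-1L] == unit_of[-n_genes])
  gaps <- integer(n_genes)
  gaps[within_unit] <- rtrunc_norm(sum(within_unit), operonic_distance_mean,
                                   operonic_distance_sd,
                                   operonic_distance_min)
  gaps[!within_unit] <- rtrunc_norm(sum(!within_unit),
                                    boundary_distance_mean,
                                    boundary_distance_sd, 1L)
  contig_of <- sort(rep_len(seq_len(n_contigs), n_genes))
  start <- integer(n_genes)
  end <- integer(n_genes)
  pos <- 0L
  for (g in seq_len(n_genes)) {
    if (g > 1L && contig_of[g] != contig_of[g - 1L]) pos <- 0L
    start[g] <- pos + gaps[g] + 1L
    if (g == 1L || contig_of[g] != contig_of[g - 1L]) start[g] <- 1L
    end[g] <- start[g] + lens[g] - 1L
    pos <- end[g]
  }
  gene_ids <- sprintf("SYN%04d", seq_len(n_genes))
  genome <- data.frame(gene_id = gene_ids,
                       contig_id = sprintf("contig_%02d", contig_of),
                       start = start, end = end, strand = strand,
                       stringsAsFactors = FALSE)
  genome <- validate_genome_table(genome)

  pairs <- adjacent_pairs(genome)
  # planted truth: a pair is operonic iff both genes share a unit
  unit_by_gene <- stats::setNames(unit_of, gene_ids)
  operonic <- unit_by_gene[pairs$upstream] == unit_by_gene[pairs$downstream]
  p_cons <- ifelse(operonic, p_cons_operonic, p_cons_boundary)
  barcode <- matrix(stats::runif(nrow(pairs) * n_references) <
                      rep(p_cons, n_references),
                    nrow = nrow(pairs),
                    dimnames = list(NULL,
                                    sprintf("ref%02d", seq_len(n_references))))
  list(genome = genome, barcode = barcode,
       pair_truth = data.frame(upstream = pairs$upstream,
                               downstream = pairs$downstream,
                               same_strand = pairs$same_strand,
                               operonic = unname(operonic),
                               stringsAsFactors = FALSE),
       params = list(n_genes = n_genes, mean_unit_size = mean_unit_size,
                     strand_flip_prob = strand_flip_prob,
                     n_references = n_references, seed = seed))
}

#' Simulate three-way alignment hit tables with known truth
#'
#' Fabricates the three analysis-tagged hit tables the consensus probe
#' assignment consumes. True \emph{D. mccartyi} probes receive hits labelled
#' with the target taxon and identities drawn near the class means; other
#' probes receive hits from a pool of other community taxa. A decoy
#' lower-bitscore row per hit exercises best-hit selection; protein-database
#' hits are produced only with probability `hit_prob_nr` (shotgun probes may
#' miss protein hits by design).
#'
#' @param n_probes Probe count.
#' @param dhc_fraction Fraction of probes truly \emph{D. mccartyi}.
#' @param identity_true Named numeric: mean identity per analysis tag for
#'   true probes.
#' @param identity_other Mean identity of non-target probes' hits.
#' @param identity_sd Identity standard deviation.
#' @param hit_prob_nr Probability a probe has any protein-database hit.
#' @param dhc_label Taxon label used for the target species.
#' @param seed Integer seed.
#' @return List with `tables` (list of three `HitTable`s) and `truth`
#'   (data.frame `query_id`, `is_dhc`).
#' @export
simulate_hit_tables <- function(n_probes = 500,
                                dhc_fraction = 0.5,
                                identity_true = c(nt_nucleotide = 97,
                                                  nr_protein = 98.5,
                                                  composite_genome = 98),
                                identity_other = 80,
                                identity_sd = 1.5,
                                hit_prob_nr = 0.9,
                                dhc_label = "Dehalococcoides mccartyi",
                                seed = 1L) {
  set.seed(seed)
  qid <- sprintf("PROBE%05d", seq_len(n_probes))
  is_dhc <- stats::runif(n_probes) < dhc_fraction
  other_taxa <- c("Methanosarcina barkeri", "Geobacter lovleyi",
                  "Acetobacterium woodii", "Desulfovibrio vulgaris")
  clip <- function(x) pmin(100, pmax(0, x))
  make_table <- function(tag) {
    has_hit <- if (tag == "nr_protein")
      stats::runif(n_probes) < hit_prob_nr else rep(TRUE, n_probes)
    idx <- which(has_hit)
    mu <- ifelse(is_dhc[idx], identity_true[[tag]], identity_other)
    ident <- clip(stats::rnorm(length(idx), mu, identity_sd))
    taxon <- ifelse(is_dhc[idx], dhc_label,
                    sample(other_taxa, length(idx), replace = TRUE))
    score <- 2 * ident + stats::runif(length(idx))
    # decoy secondary hits with strictly lower bitscore
    hit_table(
      query_id = c(qid[idx], qid[idx]),
      subject_id = c(sprintf("%s_best", taxon),
                     sprintf("decoy_%05d", idx)),
      percent_identity = c(ident, clip(ident - 10)),
      bitscore = c(score, score - 50),
      taxon_label = c(taxon,
                      sample(other_taxa, length(idx), replace = TRUE)),
      analysis_tag = tag)
  }
  tables <- lapply(ANALYSIS_TAGS, make_table)
  names(tables) <- ANALYSIS_TAGS
  list(tables = tables,
       truth = data.frame(query_id = qid, is_dhc = is_dhc,
                          stringsAsFactors = FALSE))
}
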
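dhc <- "Dehalococcoides mccartyi"

test_that("best_hit takes the maximal bitscore with deterministic tie-breaks", {
  tb <- hit_table(query_id = c("q1", "q1"), subject_id = c("a", "b"),
                  percent_identity = c(99, 90), bitscore = c(50, 80),
                  taxon_label = dhc, analysis_tag = "nt_nucleotide")
  expect_equal(best_hit(tb)$subject_id, "b")
  # equal bitscore: higher identity wins
  tb2 <- hit_table("q1", c("a", "b"), c(90, 95), c(70, 70), dhc,
                   "nt_nucleotide")
  expect_equal(best_hit(tb2)$percent_identity, 95)
  # equal bitscore and identity: lexicographically smallest subject
  tb3 <- hit_table("q1", c("zzz", "aaa"), 95, 70, dhc, "nt_nucleotide")
  expect_equal(best_hit(tb3)$subject_id, "aaa")
})

test_that("best_hit agrees with an exhaustive per-query max scan", {
  set.seed(7)
  n <- 100L
  tb <- hit_table(query_id = sample(sprintf("q%02d", 1:20), n, replace = TRUE),
                  subject_id = sprintf("s%03d", sample(500, n)),
                  percent_identity = round(runif(n, 60, 100), 1),
                  bitscore = sample(50:300, n, replace = TRUE),
                  taxon_label = dhc, analysis_tag = "nt_nucleotide")
  bh <- best_hit(tb)
  for (q in unique(tb$query_id)) {
    rows <- tb[tb$query_id == q, ]
    rows <- rows[rows$bitscore == max(rows$bitscore), ]
    rows <- rows[rows$percent_identity == max(rows$percent_identity), ]
    expect_equal(bh$subject_id[bh$query_id == q], min(rows$subject_id))
  }
})

test_that("identity verdicts are strict and taxon-gated", {
  mk <- function(ident, taxon, tag) best_hit(
    hit_table("q", "s", ident, 100, taxon, tag))
  cfg <- pipeline_config()
  expect_equal(unname(hit_verdict(mk(85.0, dhc, "nt_nucleotide"), cfg)),
               "fail")  # boundary: >85 means 85.0 itself fails
  expect_equal(unname(hit_verdict(mk(86.2, dhc, "nt_nucleotide"), cfg)),
               "pass")
  expect_equal(unname(hit_verdict(mk(99, "Geobacter lovleyi", "nr_protein"),
                                  cfg)), "fail")
  expect_equal(unname(hit_verdict(mk(95.0, dhc, "nr_protein"), cfg)), "fail")
  expect_equal(unname(hit_verdict(mk(95.1, dhc, "nr_protein"), cfg)), "pass")
})

test_that("consensus combines the three analyses as specified", {
  mk_tb <- function(tag, ident, taxon = dhc)
    hit_table("q", "s", ident, 100, taxon, tag)
  all_pass <- list(mk_tb("nt_nucleotide", 99), mk_tb("nr_protein", 99),
                   mk_tb("composite_genome", 99))
  expect_true(consensus_assign(all_pass)$consensus)
  # fails nr (non-target taxon), passes the other two -> not consensus
  one_fail <- list(mk_tb("nt_nucleotide", 99),
                   mk_tb("nr_protein", 99, "Geobacter lovleyi"),
                   mk_tb("composite_genome", 99))
  expect_false(consensus_assign(one_fail)$consensus)
  # nr produced no hit: majority mode accepts, strict mode does not
  no_nr <- list(mk_tb("nt_nucleotide", 99),
                hit_table("other", "s", 99, 100, dhc, "nr_protein"),
                mk_tb("composite_genome", 99))
  maj <- consensus_assign(no_nr)
  expect_true(maj$consensus[maj$query_id == "q"])
  expect_equal(maj$nr_protein[maj$query_id == "q"], "no_hit")
  strict <- consensus_assign(no_nr,
                             pipeline_config(consensus_mode = "strict"))
  expect_false(strict$consensus[strict$query_id == "q"])
  # duplicate analysis tags are rejected
  expect_error(consensus_assign(list(mk_tb("nt_nucleotide", 99),
                                     mk_tb("nt_nucleotide", 99),
                                     mk_tb("composite_genome", 99))),
               "duplicate|tags")
})

test_that("raising identity thresholds never grows the consensus set", {
  ht <- simulate_hit_tables(n_probes = 300, seed = 11)
  base <- consensus_assign(ht$tables, pipeline_config())
  for (bump in list(c(identity_nt = 95), c(identity_aa = 99),
                    c(identity_composite = 99))) {
    cfg <- do.call(pipeline_config, as.list(bump))
    tighter <- consensus_assign(ht$tables, cfg)
    expect_true(all(tighter$consensus <= base$consensus))
  }
})

test_that("consensus is order-independent and matches simulator truth", {
  ht <- simulate_hit_tables(n_probes = 500, seed = 23)
  res <- consensus_assign(ht$tables)
  shuffled <- lapply(ht$tables, function(tb) {
    s <- tb[sample(nrow(tb)), ]
    structure(s, analysis_tag = attr(tb, "analysis_tag"),
              class = class(tb))
  })
  res2 <- consensus_assign(shuffled)
  expect_identical(res, res2)
  # decisions match truth whenever identities are >= 5 points off thresholds
  truth <- ht$truth[match(res$query_id, ht$truth$query_id), ]
  margins <- sapply(ht$tables, function(tb) {
    bh <- best_hit(tb)
    m <- rep(Inf, nrow(res))
    thr <- c(nt_nucleotide = 85, nr_protein = 95, composite_genome = 95)
    idx <- match(bh$query_id, res$query_id)
    m[idx] <- abs(bh$percent_identity - thr[[attr(tb, "analysis_tag")]])
    m
  })
  clear <- apply(margins, 1, min) >= 5
  expect_gt(sum(clear), 0)  # the margin condition is non-vacuous
  expect_identical(res$consensus[clear], truth$is_dhc[clear])
  expect_gt(mean(res$consensus == truth$is_dhc), 0.95)
})

test_that("hit tables round trip through the 13-column tabular dialect", {
  ht <- simulate_hit_tables(n_probes = 30, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(ht$tables$nt_nucleotide, f)
  back <- read_hit_table(f, "nt_nucleotide")
  orig <- ht$tables$nt_nucleotide
  expect_equal(back$query_id, orig$query_id)
  expect_equal(back$percent_identity, orig$percent_identity)
  expect_equal(back$bitscore, orig$bitscore)
  expect_equal(back$taxon_label, orig$taxon_label)
})
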
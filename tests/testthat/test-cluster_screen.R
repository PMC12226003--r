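test_that("family assignment applies trusted cutoffs and max-score tie rules", {
  cuts <- c(phnJ = 100, phnC = 90, phnD = 90)
  hits <- data.frame(
    gene_id = c("g1", "g2", "g3", "g3", "g4", "g4"),
    family = c("phnJ", "phnJ", "phnC", "phnD", "phnD", "phnC"),
    bit_score = c(120, 80, 150, 140, 95, 95),
    e_value = 1e-20
  )
  a <- assign_families(hits, cuts)
  expect_equal(a$family[a$gene_id == "g1"], "phnJ")        # above cutoff
  expect_false("g2" %in% a$gene_id)                        # below cutoff
  expect_equal(a$family[a$gene_id == "g3"], "phnC")        # max score wins
  expect_equal(a$family[a$gene_id == "g4"], "phnC")        # tie -> lexicographic
  expect_equal(nrow(assign_families(hits[0, ], cuts)), 0L)
})

test_that("a compact full cluster is called valid", {
  fams <- PHN_FAMILIES[1:11]                       # phnC..phnM
  lay <- tandem_layout(rep(1000L, 11), rep(100L, 11))
  feats <- contig_features(fams, lay$starts, lay$ends)
  calls <- scan_contig(feats, contig_assignments(feats, fams))
  expect_equal(nrow(calls), 1L)
  expect_true(calls$valid)
  expect_true(calls$core_ok)
  expect_lte(calls$span_nt, 16000L)
})

test_that("missing core gene invalidates an otherwise dense cluster", {
  fams <- c("phnG", "phnH", "phnI", "phnJ", "phnL", "phnM")  # no phnK
  lay <- tandem_layout(rep(1200L, 6), rep(300L, 6))
  feats <- contig_features(fams, lay$starts, lay$ends)
  calls <- scan_contig(feats, contig_assignments(feats, fams))
  expect_equal(nrow(calls), 1L)
  expect_false(calls$valid)
  expect_false(calls$core_ok)
  expect_true(calls$window_ok)
})

test_that("fewer than five distinct families is invalid even with the core present", {
  fams <- c("phnJ", "phnK", "phnL", "phnM")
  lay <- tandem_layout(rep(1500L, 4), rep(300L, 4))
  feats <- contig_features(fams, lay$starts, lay$ends)
  calls <- scan_contig(feats, contig_assignments(feats, fams))
  expect_false(any(calls$valid))
  expect_true(all(calls$core_ok))
  expect_true(all(calls$n_families < 5))
})

test_that("duplicate paralogs of one family count once toward the minimum", {
  # 5 genes but only 2 distinct families
  fams <- c("phnK", "phnK", "phnL", "phnL", "phnL")
  lay <- tandem_layout(rep(800L, 5), rep(100L, 5))
  feats <- contig_features(fams, lay$starts, lay$ends)
  calls <- scan_contig(feats, contig_assignments(feats, fams))
  expect_false(any(calls$valid))
  expect_equal(max(calls$n_families), 2L)
})

test_that("genes spread beyond any window produce no valid call", {
  fams <- PHN_FAMILIES[1:7]
  lay <- tandem_layout(rep(800L, 7), rep(5500L, 7))   # span > 40 kb
  feats <- contig_features(fams, lay$starts, lay$ends)
  ass <- contig_assignments(feats, fams)
  calls <- scan_contig(feats, ass)
  expect_false(any(calls$valid))
  expect_equal(nrow(brute_force_scan(feats, ass)), 0L)
})

test_that("assignments referencing unknown genes are a consistency error", {
  feats <- contig_features("phnJ", 100, 900)
  ass <- rbind(contig_assignments(feats, "phnJ"),
               data.frame(gene_id = "ghost", family = "phnK", bit_score = 200))
  expect_error(scan_contig(feats, ass), "unknown gene_id.*ghost")
})

test_that("verdicts are invariant to input row order", {
  set.seed(421)
  for (i in 1:20) {
    rc <- random_phn_contig(sample(5:15, 1))
    base <- any(scan_contig(rc$features, rc$assignments)$valid)
    perm_f <- rc$features[sample(nrow(rc$features)), ]
    perm_a <- rc$assignments[sample(nrow(rc$assignments)), ]
    expect_identical(any(scan_contig(perm_f, perm_a)$valid), base)
  }
})

test_that("enlarging the window never destroys a positive, shrinking never creates one", {
  set.seed(422)
  violations <- 0L; positives_seen <- 0L
  for (i in 1:30) {
    rc <- if (i %% 2) random_phn_contig(sample(5:15, 1)) else
      dense_phn_contig(sample(2:8, 1))
    v_small <- any(scan_contig(rc$features, rc$assignments, W = 8000L)$valid)
    v_mid <- any(scan_contig(rc$features, rc$assignments, W = 16000L)$valid)
    v_big <- any(scan_contig(rc$features, rc$assignments, W = 32000L)$valid)
    positives_seen <- positives_seen + v_mid
    if (v_small && !v_mid) violations <- violations + 1L
    if (v_mid && !v_big) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
  expect_gt(positives_seen, 0L)   # the case mix must exercise positives
})

test_that("adding a phn gene never turns a positive contig negative", {
  set.seed(423)
  violations <- 0L; positives_seen <- 0L
  for (i in 1:20) {
    rc <- dense_phn_contig(sample(2:8, 1))
    if (!any(scan_contig(rc$features, rc$assignments)$valid)) next
    positives_seen <- positives_seen + 1L
    extra_start <- sample(1:60000, 1)
    fam <- sample(PHN_FAMILIES, 1)
    extra <- contig_features(fam, extra_start, extra_start + 900)
    extra$gene_id <- "extra_gene"
    feats2 <- rbind(rc$features, extra)
    ass2 <- rbind(rc$assignments,
                  data.frame(gene_id = "extra_gene", family = fam,
                             bit_score = 200))
    if (!any(scan_contig(feats2, ass2)$valid)) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
  expect_gt(positives_seen, 0L)
})

test_that("genome screening aggregates contigs and keeps invalid calls auditable", {
  fams_ok <- PHN_FAMILIES[1:11]
  lay <- tandem_layout(rep(1000L, 11), rep(100L, 11))
  f1 <- contig_features(fams_ok, lay$starts, lay$ends, contig = "c3")
  f2 <- contig_features(c("phnJ", "phnK"), c(100, 2000), c(900, 2900),
                        contig = "c7")
  feats <- rbind(f1, f2)
  ass <- rbind(contig_assignments(f1, fams_ok),
               contig_assignments(f2, c("phnJ", "phnK")))
  res <- screen_genome(data.frame(genome_id = "G1"), feats, ass)
  expect_true(res$positive)
  expect_true(any(!res$calls$valid))     # the c7 candidate is kept
  expect_setequal(unique(res$calls$contig_id), c("c3", "c7"))

  none <- screen_genome(data.frame(genome_id = "G2"), f1[0, ], ass[0, ])
  expect_false(none$positive)
  expect_equal(nrow(none$calls), 0L)
})

test_that("survey summary reproduces printed prevalence fractions as count ratios", {
  n_fw <- 1153; n_tot <- 16671
  rec <- data.frame(
    genome_id = sprintf("g%05d", seq_len(n_tot)),
    habitat = c(rep("freshwater", n_fw), rep("soil", n_tot - n_fw)),
    lineage = "d__Bacteria;p__Pseudomonadota;c__G;o__Burkholderiales;f__;g__;s__"
  )
  pos_ids <- c(sprintf("g%05d", 1:127),                       # freshwater positives
               sprintf("g%05d", n_fw + seq_len(1445 - 127)))  # the rest
  s <- summarize_survey(rec, setNames(rec$genome_id %in% pos_ids,
                                      rec$genome_id))
  expect_equal(s$positive_genomes, 1445)
  expect_equal(s$prevalence_pct, 8.7)
  expect_equal(format_approx_pct(s$prevalence_pct), "≈9%")
  fw <- s$by_habitat[s$by_habitat$habitat == "freshwater", ]
  expect_equal(fw$total, 1153)
  expect_equal(fw$positive, 127)
  expect_equal(fw$pct, 11.0)
})

test_that("survey summary conserves totals and validates inputs", {
  spec <- genome_sim_spec(n_genomes = 40, seed = 13)
  sim <- simulate_survey(spec)
  res <- run_survey_pipeline(sim$features, sim$hits, sim$records, sim$cutoffs)
  s <- res$summary
  expect_equal(sum(s$by_habitat$total), s$total_genomes)
  expect_equal(sum(s$by_habitat$positive), s$positive_genomes)
  phy <- s$by_rank[s$by_rank$rank == "phylum", ]
  expect_equal(sum(phy$total), s$total_genomes)
  expect_equal(sum(phy$positive), s$positive_genomes)
  expect_true(all(s$by_habitat$positive <= s$by_habitat$total))

  expect_error(summarize_survey(sim$records[0, ], logical(0)), "no genomes")
  expect_error(summarize_survey(sim$records, c(NOPE = TRUE)), "absent")
})

test_that("rare taxa collapse to 'other' in reports but never in counts", {
  rollup <- data.frame(taxon = c("A", "B", "C"),
                       total = c(900, 90, 10),
                       positive = c(450, 45, 1),
                       pct = c(50, 50, 10))
  collapsed <- collapse_rare(rollup, min_pct = 1)
  expect_true("other" %in% collapsed$taxon)
  expect_equal(sum(collapsed$positive), sum(rollup$positive))
  expect_equal(sum(collapsed$total), sum(rollup$total))
})
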
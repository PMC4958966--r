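test_that("pre-attachment filter keeps early-expressed transcripts only", {
  tab <- data.frame(
    transcript_id = rep(c("t1", "t2", "t3"), each = 3),
    stage = rep(c("0G", "2G", "4.1G"), 3),
    abundance = c(5, 0, 0,   0, 0, 30,   0, 0, 0))
  kept <- filter_pre_attachment(tab)
  expect_identical(kept, "t1")
  expect_error(filter_pre_attachment(tab, pre_attachment = c("0G", "9G")),
               "not in the table")
  expect_identical(filter_pre_attachment(tab, min_abundance = 10), character())
})

test_that("alien ratio uses strict threshold and handles missing-side hits", {
  p <- test_partition()
  v <- compute_alien_ratio(rbind(
    mk_hit("q", "SIR|x", "Sisymbrium_irio", 240),
    mk_hit("q", "MIG|y", "Mimulus_guttatus", 180)), p)
  expect_equal(v$ratio, 240 / 180)
  expect_true(v$candidate)

  v2 <- compute_alien_ratio(rbind(
    mk_hit("q", "SIR|x", "Sisymbrium_irio", 120),
    mk_hit("q", "MIG|y", "Mimulus_guttatus", 100)), p)
  expect_equal(v2$ratio, 1.2)
  expect_false(v2$candidate)  # exactly 1.2 is not a candidate

  v3 <- compute_alien_ratio(mk_hit("q", "SIR|x", "Sisymbrium_irio", 120), p)
  expect_identical(v3$ratio, Inf)
  expect_true(v3$candidate)
  expect_match(v3$flags, "no_ingroup_hit")

  v4 <- compute_alien_ratio(mk_hit("q", "MIG|y", "Mimulus_guttatus", 120), p)
  expect_false(v4$candidate)
  expect_match(v4$flags, "no_outgroup_hit")

  # self hits never enter scoring
  v5 <- compute_alien_ratio(rbind(
    mk_hit("q", "PAE|self", "Phelipanche_aegyptiaca", 900),
    mk_hit("q", "SIR|x", "Sisymbrium_irio", 240),
    mk_hit("q", "MIG|y", "Mimulus_guttatus", 180)), p)
  expect_equal(v5$ratio, 240 / 180)

  expect_error(compute_alien_ratio(rbind(
    mk_hit("q1", "SIR|x", "Sisymbrium_irio", 1),
    mk_hit("q2", "SIR|x", "Sisymbrium_irio", 1)), p), "one query")
})

test_that("nucleotide-level relative filter triggers only on the designated relative", {
  p <- test_partition()
  expect_true(nt_relative_filter(mk_hit("q", "MIG|y", "Mimulus_guttatus", 120), p))
  expect_false(nt_relative_filter(mk_hit("q", "ATH|y", "Arabidopsis_thaliana", 120), p))
  expect_false(nt_relative_filter(NULL, p))       # no NT similarity passes
  expect_false(nt_relative_filter(empty_hits <- mk_hit("q", "x", "y", 1)[0, ], p))
  # best over all taxa decides, not presence of any relative hit
  expect_false(nt_relative_filter(rbind(
    mk_hit("q", "MIG|y", "Mimulus_guttatus", 80),
    mk_hit("q", "SIR|x", "Sisymbrium_irio", 200)), p))
})

test_that("putative donor is the best outgroup hit with deterministic tie-break", {
  p <- test_partition()
  expect_identical(assign_putative_donor(rbind(
    mk_hit("q", "SIR|x", "Sisymbrium_irio", 850),
    mk_hit("q", "BRA|x", "Brassica_rapa", 800)), p), "Sisymbrium_irio")
  expect_null(assign_putative_donor(
    mk_hit("q", "MIG|y", "Mimulus_guttatus", 100), p))
  tie <- rbind(mk_hit("q", "b_sub", "Brassica_rapa", 500, evalue = 1e-40),
               mk_hit("q", "a_sub", "Sisymbrium_irio", 500, evalue = 1e-40))
  expect_identical(assign_putative_donor(tie, p), "Sisymbrium_irio")
})

test_that("run_screen applies filters in order and annotates the first failure", {
  ds <- make_screen_dataset(sim_config(seed = 4, n_native = 4, n_foreign = 2,
                                       n_contaminant = 2))
  v <- run_screen(ds$transcripts, ds$stage_table, ds$protein_hits,
                  ds$nt_hits, ds$partition)
  expect_identical(sort(v$transcript_id[v$candidate]),
                   sort(ds$manifest$transcript_id[ds$manifest$class == "foreign"]))
  contam <- v[grepl("contam", v$transcript_id), ]
  expect_true(all(contam$flags == "stage_filtered"))
  expect_true(all(is.na(contam$ratio)))
  # a transcript with no long ORF is length_filtered before any scoring
  tr <- c(ds$transcripts, short_orf = random_cds(90, seed = 1))
  st <- rbind(ds$stage_table,
              data.frame(transcript_id = "short_orf", stage = "0G",
                         abundance = 10))
  v2 <- run_screen(tr, st, ds$protein_hits, ds$nt_hits, ds$partition)
  expect_identical(v2$flags[v2$transcript_id == "short_orf"], "length_filtered")
  expect_error(run_screen(tr, st, NULL, ds$nt_hits, ds$partition),
               "protein_hits")
})

test_that("verdicts are scale-free and monotone in the threshold", {
  ds <- make_screen_dataset(sim_config(seed = 6, n_native = 6, n_foreign = 2,
                                       n_contaminant = 1))
  v <- run_screen(ds$transcripts, ds$stage_table, ds$protein_hits,
                  ds$nt_hits, ds$partition)
  scaled <- ds
  scaled$protein_hits$bitscore <- scaled$protein_hits$bitscore * 7.3
  scaled$nt_hits$bitscore <- scaled$nt_hits$bitscore * 7.3
  v_scaled <- run_screen(scaled$transcripts, scaled$stage_table,
                         scaled$protein_hits, scaled$nt_hits, ds$partition)
  expect_identical(v$candidate, v_scaled$candidate)
  expect_equal(v$ratio, v_scaled$ratio)

  prev <- NULL
  for (th in c(1.0, 1.2, 1.5, 2.0)) {
    cand <- run_screen(ds$transcripts, ds$stage_table, ds$protein_hits,
                       ds$nt_hits, ds$partition, threshold = th)
    ids <- cand$transcript_id[cand$candidate]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("verdicts are invariant under hit and transcript permutation", {
  ds <- make_screen_dataset(sim_config(seed = 8, n_native = 5, n_foreign = 2,
                                       n_contaminant = 1))
  v <- run_screen(ds$transcripts, ds$stage_table, ds$protein_hits,
                  ds$nt_hits, ds$partition)
  set.seed(1)
  ph <- ds$protein_hits[sample(nrow(ds$protein_hits)), ]
  nh <- ds$nt_hits[sample(nrow(ds$nt_hits)), ]
  tr <- ds$transcripts[sample(length(ds$transcripts))]
  v2 <- run_screen(tr, ds$stage_table, ph, nh, ds$partition)
  v2 <- v2[match(v$transcript_id, v2$transcript_id), ]
  expect_equal(v$candidate, v2$candidate)
  expect_equal(v$ratio, v2$ratio)
})
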
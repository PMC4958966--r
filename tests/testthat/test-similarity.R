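test_that("local alignment reproduces hand-verified and degenerate cases", {
  sch <- scoring_scheme("nucleotide", match = 3, mismatch = -3,
                        gap_open = -2, gap_extend = -2)
  h <- local_align("TGTTACGG", "GGTTGACTA", sch)
  expect_equal(h$raw_score, 13)

  s <- random_nt(100)
  set.seed(1)
  h2 <- local_align(s, s, scoring_scheme("nucleotide", match = 1, mismatch = -1))
  expect_equal(h2$raw_score, 100)
  expect_equal(h2$percent_identity, 100)

  expect_null(local_align(strrep("A", 30), strrep("C", 30),
                          scoring_scheme("nucleotide")))
  expect_error(local_align("ACGT", "MKWV", scoring_scheme("nucleotide")),
               "non-nucleotide")
})

test_that("local alignment score equals the brute-force oracle on short pairs", {
  set.seed(42)
  sch <- scoring_scheme("nucleotide", match = 2, mismatch = -3,
                        gap_open = -4, gap_extend = -1)
  for (k in 1:25) {
    a <- random_nt(sample(4:9, 1))
    b <- random_nt(sample(4:9, 1))
    expected <- bf_local_score(a, b, 2, -3, -4, -1)
    got <- local_align(a, b, sch)
    got_score <- if (is.null(got)) 0 else got$raw_score
    expect_equal(got_score, expected,
                 info = sprintf("a=%s b=%s", a, b))
  }
})

test_that("local alignment agrees with Biostrings pairwiseAlignment", {
  # Biostrings charges gapOpening + gapExtension for a length-1 gap, so a
  # scheme with gap_open = open + ext reproduces its model
  set.seed(7)
  for (k in 1:10) {
    a <- random_nt(60); b <- mutate_seq(random_nt(60), 0.2)
    sch <- scoring_scheme("nucleotide", match = 2, mismatch = -2,
                          gap_open = -5, gap_extend = -2)
    got <- local_align(a, b, sch)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 3, gapExtension = 2)
    expect_equal(if (is.null(got)) 0 else got$raw_score,
                 max(0, Biostrings::score(ref)))
  }
})

test_that("percent identity is symmetric for the built-in aligner", {
  set.seed(9)
  sch <- scoring_scheme("nucleotide")
  for (k in 1:10) {
    a <- random_nt(80)
    b <- mutate_seq(a, 0.15)
    ab <- local_align(a, b, sch); ba <- local_align(b, a, sch)
    expect_equal(ab$percent_identity, ba$percent_identity)
    expect_equal(ab$raw_score, ba$raw_score)
  }
})

test_that("hit table parsing assigns taxa and rejects malformed rows", {
  path <- tempfile(fileext = ".tsv")
  row <- paste("q1", "ATH|AT3G17260", "83.0", "373", "60", "2",
               "1", "373", "10", "380", "1e-150", "240", sep = "\t")
  writeLines(row, path)
  hits <- read_hit_table(path, c(ATH = "Arabidopsis_thaliana"))
  expect_identical(hits$subject_taxon, "Arabidopsis_thaliana")
  expect_equal(hits$bitscore, 240)
  expect_equal(hits$percent_identity, 83)

  writeLines(character(), path)
  expect_identical(nrow(read_hit_table(path, c(ATH = "x"))), 0L)

  writeLines(paste(strsplit(row, "\t")[[1]][1:11], collapse = "\t"), path)
  expect_error(read_hit_table(path, c(ATH = "x")), "row\\(s\\) 1")

  writeLines(row, path)
  expect_error(read_hit_table(path, c(MIG = "Mimulus_guttatus")),
               "matches no taxon-map prefix")
  expect_identical(
    read_hit_table(path, c(MIG = "Mimulus_guttatus"),
                   on_unmapped = "unknown")$subject_taxon, "unknown")
})

test_that("best_hit maximises bitscore with evalue and id tie-breaks, order-invariantly", {
  hits <- rbind(mk_hit("q", "s1", "tA", 240), mk_hit("q", "s2", "tB", 180))
  expect_identical(best_hit(hits)$subject_id, "s1")
  expect_null(best_hit(hits, restrict_to = "tZ"))
  tie <- rbind(mk_hit("q", "s1", "tA", 200, evalue = 1e-40),
               mk_hit("q", "s2", "tB", 200, evalue = 1e-50))
  expect_identical(best_hit(tie)$subject_id, "s2")
  tie2 <- rbind(mk_hit("q", "sB", "tA", 200), mk_hit("q", "sA", "tB", 200))
  expect_identical(best_hit(tie2)$subject_id, "sA")
  # permutation invariance
  set.seed(3)
  big <- do.call(rbind, lapply(1:12, function(i)
    mk_hit("q", paste0("s", i), "tA", sample(100:110, 1))))
  ref <- best_hit(big)
  for (k in 1:5) {
    perm <- best_hit(big[sample(nrow(big)), ])
    expect_identical(perm$subject_id, ref$subject_id)
    expect_identical(perm$bitscore, ref$bitscore)
  }
})

test_that("bitscore conversion follows (lambda*raw - ln K)/ln 2", {
  sch <- scoring_scheme("protein")
  a <- "MKWVTFISLLLLFSSAYS"
  h <- local_align(a, a, sch)
  expect_equal(h$bitscore, (0.267 * h$raw_score - log(0.041)) / log(2))
})
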
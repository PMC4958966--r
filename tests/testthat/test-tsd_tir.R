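test_that("window extraction clamps flanks and adds intergenic segments", {
  genome <- random_nt(20000)
  gc <- data.frame(gene_id = "g1", start = 6000L, end = 8000L)
  w <- extract_windows(genome, gc, flank = 5000L)
  expect_identical(w$start, 1000L)
  expect_identical(w$end, 13000L)
  expect_identical(w$sequence, substr(genome, 1001, 13000))

  gc2 <- data.frame(gene_id = "g2", start = 100L, end = 300L)
  w2 <- extract_windows(genome, gc2, flank = 5000L)
  expect_identical(w2$start, 0L)

  gc3 <- data.frame(gene_id = c("gA", "gB"),
                    start = c(2000L, 5000L), end = c(3000L, 6000L))
  w3 <- extract_windows(genome, gc3, flank = 500L)
  inter <- w3[grepl("intergenic", w3$id), ]
  expect_identical(nrow(inter), 1L)
  expect_identical(c(inter$start, inter$end), c(3000L, 5000L))

  expect_identical(nrow(extract_windows(genome, gc3[0, ])), 0L)
})

test_that("TIR composition rule excludes one- and two-letter repeats", {
  expect_false(composition_ok("ATATATAT"))
  expect_true(composition_ok("GATTACAG"))
  expect_false(composition_ok("AAGGAAGG"))
  expect_false(composition_ok("AANNAANN"))  # N does not count as a type
  expect_true(composition_ok("ACGACGAC"))
})

test_that("TSD consensus is scanned at all offsets, matching a brute-force scan", {
  expect_true(tsd_consensus_match("TAAAGCCC"))
  expect_false(tsd_consensus_match("GGGGGGGG"))
  expect_error(tsd_consensus_match("TAAAG"), "exactly 8")
  brute <- function(tsd) {
    ok <- function(p) substr(tsd, p, p) %in% c("T", "C") &&
      substr(tsd, p + 1, p + 1) == "A" &&
      substr(tsd, p + 2, p + 2) %in% c("A", "G") &&
      substr(tsd, p + 4, p + 4) == "G"
    any(vapply(1:4, ok, logical(1)))
  }
  expect_identical(tsd_consensus_match("CCCAGAGT"), brute("CCCAGAGT"))
  set.seed(17)
  for (k in 1:200) {
    tsd <- random_nt(8)
    expect_identical(tsd_consensus_match(tsd), brute(tsd), info = tsd)
  }
})

test_that("constructed fixtures behave as specified", {
  fx <- fixture_windows()
  s <- find_tsd_tir(fx$perfect)
  expect_identical(nrow(s), 1L)
  expect_identical(s$tsd_seq, "ACGTACGT")
  expect_identical(s$tir_len, 8L)
  expect_false(s$imperfect_first_base)
  expect_identical(s$interior_len, 10L)

  s2 <- find_tsd_tir(fx$first_base_mismatch)
  expect_identical(nrow(s2), 1L)
  expect_true(s2$imperfect_first_base)
  expect_identical(nrow(find_tsd_tir(fx$first_base_mismatch,
                                     allow_first_base_mismatch = FALSE)), 0L)

  expect_identical(nrow(find_tsd_tir(fx$composition_excluded)), 0L)
  expect_identical(nrow(find_tsd_tir(fx$tsd_mismatch)), 0L)  # exact-TSD rule
})

test_that("finder equals the brute-force oracle on seeded random windows", {
  set.seed(101)
  for (k in 1:30) {
    w <- random_nt(sample(200:300, 1))
    if (k %% 3 == 0) {  # plant a structure so positives are exercised too
      p <- plant_te(w, tsd = random_nt(8), tir = "GCATTAGC",
                    interior = 30, position = sample(0:150, 1), seed = k)
      w <- p$sequence
    }
    expect_identical(find_tsd_tir(w), tsd_tir_oracle(w), info = paste("window", k))
  }
})

test_that("strand symmetry: the reverse complement yields mirrored structures", {
  mirror <- function(s, L) {
    data.frame(left_tsd_start = L - (s$right_tsd_start + 8L),
               tir_len = s$tir_len,
               right_tir_start = L - (s$left_tir_start + s$tir_len),
               imperfect_first_base = s$imperfect_first_base)
  }
  set.seed(55)
  for (k in 1:10) {
    w <- plant_te(random_nt(300), tsd = random_nt(8), tir = "GATTACAGGT",
                  interior = 40, position = 120,
                  lesion = if (k %% 2) "outer_tir_base" else NULL,
                  seed = k)$sequence
    fwd <- find_tsd_tir(w)
    rev <- find_tsd_tir(revcomp(w))
    m <- mirror(rev, nchar(w))
    o <- order(m$left_tsd_start, m$tir_len, m$right_tir_start)
    expect_equal(fwd[, c("left_tsd_start", "tir_len", "right_tir_start",
                         "imperfect_first_base")],
                 m[o, ], ignore_attr = TRUE)
  }
})

test_that("tightening tir_max or raising min_interior never adds structures", {
  set.seed(77)
  w <- plant_te(random_nt(400), tsd = random_nt(8), tir = "GCATTAGCAAT",
                interior = 60, position = 150)$sequence
  key <- function(s) sprintf("%d:%d:%d", s$left_tsd_start, s$tir_len,
                             s$right_tir_start)
  full <- find_tsd_tir(w)
  expect_true(all(key(find_tsd_tir(w, tir_max = 12L)) %in% key(full)))
  expect_true(all(key(find_tsd_tir(w, min_interior = 50L)) %in% key(full)))
  short <- find_tsd_tir(random_nt(20))
  expect_identical(nrow(short), 0L)
  expect_error(tsd_tir_oracle(random_nt(600)), "guard")
})
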
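test_that("mutation model: identity, forced substitution, and rate calibration", {
  s <- random_cds(100, seed = 1)
  expect_identical(mutate_seq(s, 0, 0, seed = 2), s)
  m1 <- mutate_seq(s, 1, 0, seed = 3)
  v0 <- strsplit(s, "")[[1]]; v1 <- strsplit(m1, "")[[1]]
  expect_true(all(v0 != v1))
  # observed mismatch fraction within 3 binomial SDs of the rate
  long <- random_cds(3400, seed = 4)  # ~10 kb
  n <- nchar(long)
  m <- mutate_seq(long, 0.1, 0, seed = 5)
  frac <- mean(strsplit(long, "")[[1]] != strsplit(m, "")[[1]])
  sd3 <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), sd3)
  # indels change length; determinism under a fixed seed
  mi <- mutate_seq(long, 0, 0.01, seed = 6)
  expect_false(nchar(mi) == nchar(long))
  expect_identical(mutate_seq(long, 0.2, 0.01, seed = 7),
                   mutate_seq(long, 0.2, 0.01, seed = 7))
})

test_that("planted elements round-trip through the finder; TSD lesions kill detection", {
  set.seed(13)
  bg <- random_nt(600)
  p <- plant_te(bg, tsd = "TACGGATC", tir = "GCATTAGC", interior = 50,
                position = 250, seed = 1)
  f <- find_tsd_tir(p$sequence)
  m <- p$manifest
  hit <- f[f$left_tsd_start == m$left_tsd_start &
             f$tir_len == m$tir_len &
             f$right_tir_start == m$right_tir_start, ]
  expect_identical(nrow(hit), 1L)
  expect_false(hit$imperfect_first_base)

  p2 <- plant_te(bg, tsd = "TACGGATC", tir = "GCATTAGC", interior = 50,
                 position = 250, lesion = "outer_tir_base", seed = 1)
  f2 <- find_tsd_tir(p2$sequence)
  hit2 <- f2[f2$left_tsd_start == m$left_tsd_start & f2$tir_len == m$tir_len, ]
  expect_true(all(hit2$imperfect_first_base))
  expect_gte(nrow(hit2), 1L)

  p3 <- plant_te(bg, tsd = "TACGGATC", tir = "GCATTAGC", interior = 50,
                 position = 250, lesion = "tsd_mismatch", seed = 1)
  f3 <- find_tsd_tir(p3$sequence)
  expect_identical(nrow(f3[f3$left_tsd_start == m$left_tsd_start &
                             f3$tir_len == m$tir_len, ]), 0L)

  expect_error(plant_te(bg, tsd = "TACGGATC", tir = "ATATATAT",
                        interior = 10, position = 10), "undetectable")
})

test_that("screen dataset generation is deterministic and honours counts", {
  cfg <- sim_config(seed = 9, n_native = 3, n_foreign = 1, n_contaminant = 1)
  d1 <- make_screen_dataset(cfg)
  d2 <- make_screen_dataset(cfg)
  expect_identical(d1$transcripts, d2$transcripts)
  expect_identical(d1$protein_hits, d2$protein_hits)
  expect_identical(d1$stage_table, d2$stage_table)

  dir1 <- tempfile(); dir2 <- tempfile()
  write_screen_dataset(d1, dir1); write_screen_dataset(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)

  expect_identical(nrow(d1$manifest), 5L)
  expect_identical(sum(d1$manifest$class == "foreign"), 1L)

  empty <- make_screen_dataset(sim_config(n_native = 0, n_foreign = 0,
                                          n_contaminant = 0))
  expect_identical(length(empty$transcripts), 0L)
  expect_identical(nrow(empty$manifest), 0L)
})

test_that("a dataset without foreign genes yields zero candidates", {
  ds <- make_screen_dataset(sim_config(seed = 15, n_native = 5,
                                       n_foreign = 0, n_contaminant = 2))
  v <- run_screen(ds$transcripts, ds$stage_table, ds$protein_hits,
                  ds$nt_hits, ds$partition)
  expect_identical(sum(v$candidate), 0L)
})

test_that("written dataset round-trips through the file readers", {
  ds <- make_screen_dataset(sim_config(seed = 21, n_native = 2,
                                       n_foreign = 1, n_contaminant = 1))
  dir <- tempfile()
  write_screen_dataset(ds, dir)
  tr <- read_fasta(file.path(dir, "transcripts.fasta"))
  expect_identical(tr, ds$transcripts)
  tmap <- read.table(file.path(dir, "taxon_map.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  hits <- read_hit_table(file.path(dir, "protein_hits.tsv"), tmap)
  expect_identical(hits$query_id, ds$protein_hits$query_id)
  expect_identical(hits$subject_taxon, ds$protein_hits$subject_taxon)
  expect_equal(hits$bitscore, ds$protein_hits$bitscore, tolerance = 0.01)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$manifest$class, ds$manifest$class)
  expect_true(is.numeric(man$config_hash) || is.integer(man$config_hash))
})
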
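# Independent oracles and fixture builders shared across tests.

# Brute-force local alignment by exhaustive recursion over all alignments
# (exponential; only for sequences of length <= 12). A gap of length L costs
# gap_open + (L - 1) * gap_extend; the alignment must start and end on an
# aligned pair, and the empty alignment scores 0.
bf_local_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  rec <- function(i, j, state) {
    res <- 0  # stop extending here (alignment ended on the last pair)
    if (state != "m") res <- -Inf  # must end on an aligned pair
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      res <- max(res, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      g <- if (state == "ga") gap_extend else gap_open
      res <- max(res, g + rec(i + 1, j, "ga"))
    }
    if (j <= length(bv)) {
      g <- if (state == "gb") gap_extend else gap_open
      res <- max(res, g + rec(i, j + 1, "gb"))
    }
    res
  }
  for (i in seq_along(av)) for (j in seq_along(bv)) {
    s <- (if (av[i] == bv[j]) match else mismatch) + rec(i + 1, j + 1, "m")
    best <- max(best, s)
  }
  best
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# constructed TSD-TIR fixture windows (all share TSD ACGTACGT, TIR GATTACAG)
fixture_windows <- function() {
  tsd <- "ACGTACGT"; tir <- "GATTACAG"; interior <- strrep("C", 10)
  list(
    perfect = paste0("AAAA", tsd, tir, interior, revcomp(tir), tsd, "AAAA"),
    first_base_mismatch = paste0("AAAA", tsd, paste0("T", substr(tir, 2, 8)),
                                 interior, revcomp(tir), tsd, "AAAA"),
    composition_excluded = paste0("AAAA", tsd, "ATATATAT", interior,
                                  revcomp("ATATATAT"), tsd, "AAAA"),
    tsd_mismatch = paste0("AAAA", tsd, tir, interior, revcomp(tir),
                          paste0("T", substr(tsd, 2, 8)), "AAAA"))
}

# one-row hit builder for screen tests
mk_hit <- function(query_id, subject_id, taxon, bitscore, evalue = 1e-50) {
  data.frame(query_id = query_id, subject_id = subject_id,
             subject_taxon = taxon, percent_identity = 80,
             alignment_length = 100L, mismatches = 20L, gap_openings = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             evalue = evalue, bitscore = bitscore, raw_score = NA_real_,
             stringsAsFactors = FALSE)
}

test_partition <- function() {
  taxonomy_partition(ingroup = c("Mimulus_guttatus", "Antirrhinum_majus"),
                     outgroup = c("Sisymbrium_irio", "Arabidopsis_thaliana",
                                  "Brassica_rapa"),
                     self = "Phelipanche_aegyptiaca",
                     relative = "Mimulus_guttatus")
}

# plant premature stops (codon substitutions) and frameshift deletions /
# insertions into a copy of a stop-free reference; returns the candidate plus
# the expected lesion table in candidate coordinates
plant_lesions <- function(ref, stop_codons = integer(),
                          fs = data.frame(pos = integer(), len = integer(),
                                          op = character())) {
  n_codons <- nchar(ref) %/% 3L
  cand <- ref
  for (cd in stop_codons) {
    start <- 3L * (cd - 1L) + 1L
    substr(cand, start, start + 2L) <- "TGA"
  }
  # apply indels right-to-left so earlier coordinates stay valid
  if (nrow(fs)) {
    ord <- order(-fs$pos)
    for (k in ord) {
      p <- fs$pos[k]; len <- fs$len[k]
      if (fs$op[k] == "del") {
        cand <- paste0(substr(cand, 1L, p - 1L), substr(cand, p + len, nchar(cand)))
      } else {
        ins <- strrep("G", len)  # G-run; reference is random so shifts are local
        cand <- paste0(substr(cand, 1L, p), ins, substr(cand, p + 1L, nchar(cand)))
      }
    }
  }
  # expected positions in candidate coordinates (shift by upstream indels)
  expected <- list()
  for (cd in stop_codons)
    expected[[length(expected) + 1L]] <- data.frame(
      kind = "premature_stop", position = cd, stringsAsFactors = FALSE)
  if (nrow(fs)) {
    ord <- order(fs$pos)
    shift <- 0L
    for (k in ord) {
      p <- fs$pos[k]
      cand_pos <- if (fs$op[k] == "del") p + shift else p + shift + 1L
      expected[[length(expected) + 1L]] <- data.frame(
        kind = "frameshift_indel", position = cand_pos,
        stringsAsFactors = FALSE)
      shift <- shift + if (fs$op[k] == "del") -fs$len[k] else fs$len[k]
    }
  }
  list(candidate = cand,
       expected = if (length(expected)) do.call(rbind, expected)
                  else data.frame(kind = character(), position = integer()))
}
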
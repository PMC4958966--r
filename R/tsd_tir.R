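#' Extract genomic search windows around genes of interest
#'
#' For each gene interval, one window covering `flank` bp in each direction
#' (clamped to the sequence); for each pair of adjacent genes with a gap,
#' additionally the intergenic segment as its own window. Intervals are
#' 0-based half-open.
#'
#' @param genome Single genome/scaffold sequence (character string).
#' @param gene_coords data.frame with columns gene_id, start, end (0-based
#'   half-open, within the genome after clamping).
#' @param flank Flank size in bp (default 5000).
#' @param genome_id Id used in window provenance.
#' @return data.frame with columns id, sequence, origin, start, end
#'   (window coordinates on the genome, 0-based half-open).
#' @export
extract_windows <- function(genome, gene_coords, flank = 5000L,
                            genome_id = "genome") {
  assert_nucleotide(genome, "genome")
  L <- nchar(genome)
  if (is.null(gene_coords) || nrow(gene_coords) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      origin = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gc <- gene_coords[order(gene_coords$start), , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(gc))) {
    s <- max(0L, gc$start[k] - flank)
    e <- min(L, gc$end[k] + flank)
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(gc$gene_id[k], "_flank"),
      sequence = substr(genome, s + 1L, e),
      origin = sprintf("%s: gene %s +/-%d bp", genome_id, gc$gene_id[k], flank),
      start = s, end = e, stringsAsFactors = FALSE)
  }
  if (nrow(gc) > 1L) {
    for (k in seq_len(nrow(gc) - 1L)) {
      s <- gc$end[k]; e <- gc$start[k + 1L]
      if (e > s) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(gc$gene_id[k], "--", gc$gene_id[k + 1L], "_intergenic"),
          sequence = substr(genome, s + 1L, e),
          origin = sprintf("%s: intergenic segment between %s and %s",
                           genome_id, gc$gene_id[k], gc$gene_id[k + 1L]),
          start = s, end = e, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Nucleotide-composition check for a terminal inverted repeat
#'
#' TIRs composed of only one or two nucleotide types are simple repeats,
#' not credible transposon termini, and are excluded.
#'
#' @param tir Nucleotide string (length >= 1).
#' @return `TRUE` iff the TIR contains at least three distinct nucleotides
#'   (N excluded from the count).
#' @export
composition_ok <- function(tir) {
  stopifnot(nchar(tir) >= 1L)
  chars <- setdiff(unique(strsplit(tir, "")[[1]]), "N")
  length(chars) >= 3L
}

#' Match an 8-bp target-site duplication against the hAT consensus
#'
#' The degenerate consensus (T/C)A(A/G)NG is 5 nt long and cannot anchor an
#' 8-nt TSD uniquely, so it is scanned at all offsets 0-3 within the TSD.
#' This is an annotation, never a filter.
#'
#' @param tsd 8-nt string without N.
#' @return `TRUE` iff the consensus occurs at some offset.
#' @export
tsd_consensus_match <- function(tsd) {
  if (nchar(tsd) != 8L)
    stop("TSD must be exactly 8 nt", call. = FALSE)
  grepl("[TC]A[AG][ACGT]G", tsd)
}

# compare a left TIR to the reverse complement of a right TIR;
# N never matches anything. Returns integer positions of mismatching columns.
tir_mismatch_positions <- function(left_tir, right_tir) {
  la <- strsplit(left_tir, "")[[1]]
  rb <- strsplit(revcomp(right_tir), "")[[1]]
  which(la != rb | la == "N" | rb == "N")
}

tsd_tir_empty <- function() {
  data.frame(window_id = character(), tsd_seq = character(),
             left_tsd_start = integer(), left_tir_start = integer(),
             right_tir_start = integer(), right_tsd_start = integer(),
             tir_len = integer(), interior_len = integer(),
             imperfect_first_base = logical(), consensus_match = logical(),
             stringsAsFactors = FALSE)
}

tsd_tir_row <- function(window_id, seq, i, t, r,
                        imperfect, tsd_len) {
  tsd <- substr(seq, i + 1L, i + tsd_len)
  data.frame(window_id = window_id, tsd_seq = tsd,
             left_tsd_start = i, left_tir_start = i + tsd_len,
             right_tir_start = r, right_tsd_start = r + t,
             tir_len = t, interior_len = r - (i + tsd_len + t),
             imperfect_first_base = imperfect,
             consensus_match = tsd_consensus_match(tsd),
             stringsAsFactors = FALSE)
}

check_structure <- function(seq, i, t, r, tsd_len, allow_first_base_mismatch) {
  # TSD copies identical, N-free
  left_tsd <- substr(seq, i + 1L, i + tsd_len)
  right_tsd <- substr(seq, r + t + 1L, r + t + tsd_len)
  if (grepl("N", left_tsd) || left_tsd != right_tsd) return(NULL)
  left_tir <- substr(seq, i + tsd_len + 1L, i + tsd_len + t)
  right_tir <- substr(seq, r + 1L, r + t)
  mm <- tir_mismatch_positions(left_tir, right_tir)
  imperfect <- FALSE
  if (length(mm) == 1L && mm == 1L && allow_first_base_mismatch) {
    imperfect <- TRUE
  } else if (length(mm) > 0L) return(NULL)
  if (!composition_ok(left_tir)) return(NULL)
  list(imperfect = imperfect)
}

#' Search a window for TSD-TIR ... TIR-TSD border structures
#'
#' Finds every structure of the form
#' TSD - TIR - interior - revcomp(TIR) - TSD where the two 8-bp TSD copies
#' match exactly, the TIRs (8-23 bp) are reverse complements with at most
#' one tolerated mismatch at the outermost TIR base, and the TIR contains
#' at least three distinct nucleotides. Overlapping and nested structures
#' are all reported. `N` never matches anything, including `N`.
#'
#' @param window Window sequence (character string).
#' @param window_id Window id for the report.
#' @param tsd_len TSD length (default 8).
#' @param tir_min,tir_max TIR length bounds (default 8 and 23).
#' @param allow_first_base_mismatch Tolerate a single mismatch at the
#'   outermost base of the TIR comparison (default TRUE).
#' @param min_interior Minimum interior length in bp (default 0).
#' @return data.frame of structures with 0-based segment starts, tir_len,
#'   interior_len, imperfect_first_base and consensus_match, sorted by
#'   (left_tsd_start, tir_len, right_tir_start). Shorter-than-minimum
#'   windows yield an empty result.
#' @export
find_tsd_tir <- function(window, window_id = "window", tsd_len = 8L,
                         tir_min = 8L, tir_max = 23L,
                         allow_first_base_mismatch = TRUE,
                         min_interior = 0L) {
  assert_nucleotide(window, "window")
  L <- nchar(window)
  if (L < 2L * tsd_len + 2L * tir_min + min_interior) return(tsd_tir_empty())
  # index exact (N-free) tsd_len-mers; candidate TSD pairs are equal k-mers
  n_kmers <- L - tsd_len + 1L
  kmers <- substring(window, seq_len(n_kmers), seq_len(n_kmers) + tsd_len - 1L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  groups <- split(which(valid) - 1L, kmers[valid])  # 0-based positions
  groups <- groups[lengths(groups) >= 2L]
  rows <- list()
  for (pos in groups) {
    np <- length(pos)
    for (ai in seq_len(np - 1L)) {
      i <- pos[ai]
      for (bi in (ai + 1L):np) {
        j <- pos[bi]  # right TSD start
        for (t in tir_min:tir_max) {
          r <- j - t  # right TIR start
          interior <- r - (i + tsd_len + t)
          if (interior < max(0L, min_interior)) next
          chk <- check_structure(window, i, t, r, tsd_len,
                                 allow_first_base_mismatch)
          if (is.null(chk)) next
          rows[[length(rows) + 1L]] <-
            tsd_tir_row(window_id, window, i, t, r, chk$imperfect, tsd_len)
        }
      }
    }
  }
  if (length(rows) == 0L) return(tsd_tir_empty())
  res <- unique(do.call(rbind, rows))
  res <- res[order(res$left_tsd_start, res$tir_len, res$right_tir_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exhaustive brute-force oracle for the TSD-TIR search
#'
#' Enumerates all (left TSD start, TIR length, right TIR start) tuples
#' directly and applies the structure invariants; identical output contract
#' to [find_tsd_tir()]. Guarded to small windows.
#'
#' @inheritParams find_tsd_tir
#' @param max_window Guard on window length (default 500).
#' @return Same as [find_tsd_tir()].
#' @export
tsd_tir_oracle <- function(window, window_id = "window", tsd_len = 8L,
                           tir_min = 8L, tir_max = 23L,
                           allow_first_base_mismatch = TRUE,
                           min_interior = 0L, max_window = 500L) {
  assert_nucleotide(window, "window")
  L <- nchar(window)
  if (L > max_window)
    stop(sprintf("oracle guard: window length %d exceeds %d", L, max_window),
         call. = FALSE)
  if (L < 2L * tsd_len + 2L * tir_min + min_interior) return(tsd_tir_empty())
  rows <- list()
  for (i in 0:(L - 2L * tsd_len - 2L * tir_min - min_interior)) {
    left_tsd <- substr(window, i + 1L, i + tsd_len)
    if (grepl("N", left_tsd, fixed = TRUE)) next
    for (t in tir_min:tir_max) {
      r_min <- i + tsd_len + t + max(0L, min_interior)
      r_max <- L - t - tsd_len
      if (r_max < r_min) next
      rr <- r_min:r_max
      # vectorised pre-filter on exact TSD equality before the full check
      right_tsds <- substring(window, rr + t + 1L, rr + t + tsd_len)
      for (r in rr[right_tsds == left_tsd]) {
        chk <- check_structure(window, i, t, r, tsd_len,
                               allow_first_base_mismatch)
        if (is.null(chk)) next
        rows[[length(rows) + 1L]] <-
          tsd_tir_row(window_id, window, i, t, r, chk$imperfect, tsd_len)
      }
    }
  }
  if (length(rows) == 0L) return(tsd_tir_empty())
  res <- unique(do.call(rbind, rows))
  res <- res[order(res$left_tsd_start, res$tir_len, res$right_tir_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a TSD-TIR structure report as TSV (1-based coordinates)
#'
#' @param structures data.frame from [find_tsd_tir()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsd_tir_report <- function(structures, path) {
  rep <- data.frame(
    window_id = structures$window_id,
    tsd_seq = structures$tsd_seq,
    left_tsd_start = structures$left_tsd_start + 1L,
    left_tir_start = structures$left_tir_start + 1L,
    right_tir_start = structures$right_tir_start + 1L,
    right_tsd_start = structures$right_tsd_start + 1L,
    tir_len = structures$tir_len,
    interior_len = structures$interior_len,
    imperfect_first_base = structures$imperfect_first_base,
    consensus_match = structures$consensus_match,
    stringsAsFactors = FALSE)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
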
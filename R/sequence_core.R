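#' @useDynLib hgtscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

NUC_CHARS <- c("A", "C", "G", "T", "N")

# standard genetic code, codon -> one-letter amino acid ('*' = stop)
GENETIC_CODE_1 <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

assert_nucleotide <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop(sprintf("%s contains non-nucleotide characters (allowed: A,C,G,T,N)",
                 what), call. = FALSE)
  invisible(seq)
}

#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header line;
#' sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1L)
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. An involution:
#' `revcomp(revcomp(s)) == s`.
#'
#' @param seq Nucleotide string over A,C,G,T,N (uppercase).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  assert_nucleotide(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Translate a nucleotide sequence in a given reading frame
#'
#' Frames `+1,+2,+3` read the forward strand with offsets 0-2; `-1,-2,-3`
#' read the reverse complement likewise. The trailing incomplete codon is
#' dropped. Stop codons are rendered `*`; any codon containing `N` renders
#' `X` (`X` never counts as a stop).
#'
#' @param seq Nucleotide string.
#' @param frame One of `+1,+2,+3,-1,-2,-3` (integer).
#' @return Peptide string (possibly empty).
#' @export
translate_frame <- function(seq, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  assert_nucleotide(seq)
  s <- if (frame < 0) revcomp(seq) else seq
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  if (n < 3L) return("")
  n_codon <- n %/% 3L
  starts <- off + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- GENETIC_CODE_1[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Find open reading frames across six frames
#'
#' An ORF is a maximal stop-free translated stretch (no start-codon
#' requirement). Only ORFs strictly longer than `min_aa` amino acids are
#' returned. Coordinates are 0-based half-open on the forward strand of the
#' transcript; re-extracting `[start, end)` and translating it in the stated
#' frame reproduces the peptide.
#'
#' @param seq Nucleotide sequence of one transcript.
#' @param id Transcript id.
#' @param min_aa Minimum length in amino acids, applied strictly (`>`).
#'   Pipeline default 100: a 100-aa stretch is rejected, 101 aa is kept.
#' @return data.frame with columns transcript_id, frame, start, end,
#'   length_aa, peptide, sorted by (start, frame).
#' @export
find_orfs <- function(seq, id = "seq", min_aa = 100L) {
  assert_nucleotide(seq)
  L <- nchar(seq)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_frame(seq, frame)
    if (nchar(pep) == 0L) next
    aa <- strsplit(pep, "")[[1]]
    is_stop <- aa == "*"
    # run-length over stop/non-stop to get maximal stop-free stretches
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(!r$values & r$lengths > min_aa)
    for (k in keep) {
      aa_start <- starts[k]; aa_len <- r$lengths[k]
      off <- abs(frame) - 1L
      # nt coords on the translated strand, 0-based half-open
      nt_start <- off + 3L * (aa_start - 1L)
      nt_end <- nt_start + 3L * aa_len
      if (frame < 0) {  # map to forward strand
        fwd_start <- L - nt_end
        fwd_end <- L - nt_start
      } else {
        fwd_start <- nt_start
        fwd_end <- nt_end
      }
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = id, frame = frame,
        start = fwd_start, end = fwd_end,
        length_aa = aa_len,
        peptide = substr(pep, aa_start, aa_start + aa_len - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(transcript_id = character(), frame = integer(),
                      start = integer(), end = integer(),
                      length_aa = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an ORF report as TSV (1-based inclusive coordinates)
#'
#' @param orfs data.frame from [find_orfs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orf_report <- function(orfs, path) {
  rep <- data.frame(
    transcript_id = orfs$transcript_id,
    frame = orfs$frame,
    start_1based = orfs$start + 1L,
    end_1based = orfs$end,
    length_aa = orfs$length_aa,
    peptide = orfs$peptide,
    stringsAsFactors = FALSE)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
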
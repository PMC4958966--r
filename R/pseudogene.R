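#' Assess a candidate coding sequence against an intact reference
#'
#' The candidate is aligned to an in-frame reference CDS (affine-gap
#' overlap alignment: free end gaps, so partial candidates are assessed on
#' the aligned region only). Two kinds of disabling lesion are called:
#'
#' * `frameshift_indel` — each contiguous internal gap (in either sequence)
#'   whose length is not a multiple of 3. Gaps are tested per run, not
#'   summed: two separate 1-nt and 2-nt gaps are two lesions even though
#'   they restore the global frame downstream, because each disrupts local
#'   coding. Clean in-frame (multiple-of-3) indels are not lesions.
#' * `premature_stop` — a stop codon in the candidate aligned to a
#'   reference codon strictly before the reference's final codon (a stop
#'   aligned to the reference's own terminator is not a lesion).
#'
#' Status is `pseudogene` iff at least one lesion is found, `undetermined`
#' when the aligned fraction of the reference falls below
#' `min_aligned_fraction`, and `intact` otherwise.
#'
#' @param candidate Candidate nucleotide sequence.
#' @param reference In-frame reference CDS: length divisible by 3, no
#'   internal stop codon.
#' @param gene_id Id for the report.
#' @param match,mismatch,gap_open,gap_extend Alignment parameters
#'   (non-positive gap penalties; a gap of length L costs
#'   `gap_open + (L-1)*gap_extend`).
#' @param min_aligned_fraction Minimum fraction of reference bases that
#'   must be aligned for a determinate call (default 0.5).
#' @return List of class `coding_assessment`: gene_id, status, lesions
#'   (data.frame kind, position, indel_len), aligned_fraction. Premature
#'   stop positions are 1-based codon indices on the reference; frameshift
#'   positions are 1-based nucleotide offsets in the candidate.
#' @export
assess_coding <- function(candidate, reference, gene_id = "candidate",
                          match = 2, mismatch = -3,
                          gap_open = -10, gap_extend = -1,
                          min_aligned_fraction = 0.5) {
  assert_nucleotide(candidate, "candidate")
  assert_nucleotide(reference, "reference")
  if (nchar(reference) %% 3L != 0L)
    stop("reference CDS length must be divisible by 3", call. = FALSE)
  ref_pep <- translate_frame(reference, 1L)
  n_codons <- nchar(ref_pep)
  if (grepl("\\*", substr(ref_pep, 1L, n_codons - 1L)))
    stop("reference CDS contains an internal stop codon", call. = FALSE)

  scheme <- scoring_scheme("nucleotide", match = match, mismatch = mismatch,
                           gap_open = gap_open, gap_extend = gap_extend)
  res <- .align_dp_cpp(candidate, reference, scheme$submat,
                       scheme$gap_open, scheme$gap_extend, "overlap")
  ca <- strsplit(res$a_aln, "")[[1]]
  ra <- strsplit(res$b_aln, "")[[1]]
  n_ref_aligned <- sum(ra != "-")
  aligned_fraction <- n_ref_aligned / nchar(reference)

  lesions <- data.frame(kind = character(), position = integer(),
                        indel_len = integer(), stringsAsFactors = FALSE)

  if (length(ca) > 0L) {
    # candidate coordinate at each column (coordinate of the base, or of the
    # last consumed base for gap columns)
    cand_pos <- res$a_start - 1L + cumsum(ca != "-")
    # frameshift lesions: per contiguous gap run in either sequence
    gap_in <- ifelse(ca == "-", "cand", ifelse(ra == "-", "ref", "none"))
    r <- rle(gap_in)
    col_end <- cumsum(r$lengths)
    col_start <- col_end - r$lengths + 1L
    for (k in which(r$values != "none")) {
      len <- r$lengths[k]
      if (len %% 3L == 0L) next
      pos <- if (r$values[k] == "cand") {
        cand_pos[col_start[k]] + 1L   # candidate base following the deletion
      } else {
        cand_pos[col_start[k]]        # first inserted candidate base
      }
      lesions <- rbind(lesions, data.frame(
        kind = "frameshift_indel", position = pos, indel_len = len,
        stringsAsFactors = FALSE))
    }
    # premature stops: reference codons with exactly 3 aligned candidate bases
    ref_idx <- cumsum(ra != "-")           # 1-based ref coordinate per column
    ref_cols <- which(ra != "-")
    cols_by_codon <- split(ref_cols, (ref_idx[ref_cols] - 1L) %/% 3L + 1L)
    for (codon_chr in names(cols_by_codon)) {
      codon <- as.integer(codon_chr)
      if (codon >= n_codons) next          # strictly before the final codon
      cols <- cols_by_codon[[codon_chr]]
      if (length(cols) != 3L) next
      bases <- ca[cols]
      if (any(bases == "-")) next
      aa <- GENETIC_CODE_1[paste(bases, collapse = "")]
      if (!is.na(aa) && aa == "*") {
        lesions <- rbind(lesions, data.frame(
          kind = "premature_stop", position = codon, indel_len = NA_integer_,
          stringsAsFactors = FALSE))
      }
    }
  }

  status <- if (aligned_fraction < min_aligned_fraction) {
    "undetermined"
  } else if (nrow(lesions) > 0L) "pseudogene" else "intact"
  structure(list(gene_id = gene_id, status = status, lesions = lesions,
                 aligned_fraction = aligned_fraction),
            class = "coding_assessment")
}

#' @export
print.coding_assessment <- function(x, ...) {
  cat(sprintf("coding assessment for %s: %s (aligned fraction %.2f)\n",
              x$gene_id, x$status, x$aligned_fraction))
  if (nrow(x$lesions)) {
    cat(sprintf("  %d lesion(s): %s\n", nrow(x$lesions),
                serialize_lesions(x$lesions)))
  }
  invisible(x)
}

serialize_lesions <- function(lesions) {
  if (nrow(lesions) == 0L) return("")
  paste(ifelse(is.na(lesions$indel_len),
               sprintf("%s:%d", lesions$kind, lesions$position),
               sprintf("%s:%d:%d", lesions$kind, lesions$position,
                       lesions$indel_len)),
        collapse = ";")
}

#' Assess many candidates and write a TSV report
#'
#' @param candidates Named character vector of candidate sequences.
#' @param reference Reference CDS (shared by all candidates).
#' @param path Output TSV path, or `NULL` to skip writing.
#' @param ... Passed to [assess_coding()].
#' @return data.frame: gene_id, status, lesions (serialised
#'   `kind:pos[:len]` joined by `;`), aligned_fraction.
#' @export
assess_coding_set <- function(candidates, reference, path = NULL, ...) {
  rows <- lapply(names(candidates), function(id) {
    a <- assess_coding(candidates[[id]], reference, gene_id = id, ...)
    data.frame(gene_id = id, status = a$status,
               lesions = serialize_lesions(a$lesions),
               aligned_fraction = a$aligned_fraction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
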
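#' Construct a scoring scheme for the built-in aligner
#'
#' Nucleotide mode uses a match/mismatch matrix over A,C,G,T,N (N scores as a
#' mismatch against everything, including itself); protein mode defaults to
#' BLOSUM62. Gap penalties are non-positive; a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. `lambda` and `K` convert raw scores to
#' bitscores as `(lambda * raw - log(K)) / log(2)`.
#'
#' @param mode "nucleotide" or "protein".
#' @param match,mismatch Nucleotide match/mismatch scores (defaults +1/-2).
#' @param submat Protein substitution matrix (default BLOSUM62 from
#'   Biostrings); ignored in nucleotide mode.
#' @param gap_open,gap_extend Non-positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters for the bit conversion.
#'   Defaults are standard gapped-protein values (0.267, 0.041) in protein
#'   mode and ungapped +1/-2 values (1.28, 0.46) in nucleotide mode.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 1, mismatch = -2, submat = NULL,
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    m <- matrix(mismatch, 5, 5, dimnames = list(NUC_CHARS, NUC_CHARS))
    diag(m) <- match
    m["N", "N"] <- mismatch
    if (is.null(gap_open)) gap_open <- -5
    if (is.null(gap_extend)) gap_extend <- -2
    if (is.null(lambda)) lambda <- 1.28
    if (is.null(K)) K <- 0.46
  } else {
    if (is.null(submat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
    } else m <- submat
    if (is.null(gap_open)) gap_open <- -11
    if (is.null(gap_extend)) gap_extend <- -1
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
  }
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be non-positive")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(mode = mode, submat = m, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

raw_to_bits <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_taxon = character(), percent_identity = numeric(),
             alignment_length = integer(), mismatches = integer(),
             gap_openings = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             raw_score = numeric(), stringsAsFactors = FALSE)
}

#' Best local alignment between two sequences
#'
#' Full affine-gap dynamic programming (no heuristic seeding; intended for
#' test-scale inputs). Percent identity uses the BLAST convention: identical
#' aligned columns divided by all alignment columns, gaps included. Returns
#' `NULL` (the "no hit" sentinel) when the best local score is not positive.
#'
#' @param a,b Named character vectors of length one (names are the ids), or
#'   unnamed strings.
#' @param scheme A [scoring_scheme()] matching the sequence alphabets.
#' @param query_id,subject_id Ids; default to the names of `a`/`b`.
#' @return One-row hit data.frame (see [read_hit_table()] for columns) or
#'   `NULL` if there is no positive-scoring local alignment.
#' @export
local_align <- function(a, b, scheme = scoring_scheme("nucleotide"),
                        query_id = NULL, subject_id = NULL) {
  if (is.null(query_id)) query_id <- if (!is.null(names(a))) names(a)[1] else "query"
  if (is.null(subject_id)) subject_id <- if (!is.null(names(b))) names(b)[1] else "subject"
  a <- unname(a); b <- unname(b)
  if (scheme$mode == "nucleotide") {
    assert_nucleotide(a, "a"); assert_nucleotide(b, "b")
  }
  res <- .align_dp_cpp(a, b, scheme$submat, scheme$gap_open,
                       scheme$gap_extend, "local")
  if (res$n_cols == 0L) return(NULL)
  aln_a <- strsplit(res$a_aln, "")[[1]]
  aln_b <- strsplit(res$b_aln, "")[[1]]
  data.frame(
    query_id = query_id, subject_id = subject_id,
    subject_taxon = NA_character_,
    percent_identity = 100 * res$n_ident / res$n_cols,
    alignment_length = res$n_cols,
    mismatches = sum(aln_a != aln_b & aln_a != "-" & aln_b != "-"),
    gap_openings = sum(diff(c(FALSE, aln_a == "-")) == 1L) +
      sum(diff(c(FALSE, aln_b == "-")) == 1L),
    q_start = res$a_start, q_end = res$a_end,
    s_start = res$b_start, s_end = res$b_end,
    evalue = NA_real_,
    bitscore = raw_to_bits(res$score, scheme),
    raw_score = res$score,
    stringsAsFactors = FALSE)
}

#' Read a 12-column BLAST-style tabular hit table
#'
#' Columns (tab-separated, no header): query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore. The
#' subject taxon is assigned from `taxon_map` by the longest subject-id
#' prefix that matches.
#'
#' @param path Path to the hit table (may be empty).
#' @param taxon_map Named character vector or two-column data.frame
#'   (prefix, taxon) mapping subject-id prefixes to taxon labels.
#' @param on_unmapped "error" (default) or "unknown" (assign taxon
#'   "unknown").
#' @return Hit data.frame, one row per input row.
#' @export
read_hit_table <- function(path, taxon_map, on_unmapped = c("error", "unknown")) {
  on_unmapped <- match.arg(on_unmapped)
  if (is.data.frame(taxon_map))
    taxon_map <- setNames(as.character(taxon_map[[2]]), as.character(taxon_map[[1]]))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop(sprintf("malformed hit table row(s) %s: expected 12 tab-separated columns",
                 paste(which(nf != 12L), collapse = ", ")), call. = FALSE)
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    subject_taxon = NA_character_,
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_openings = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    raw_score = NA_real_, stringsAsFactors = FALSE)
  bad <- which(!is.finite(hits$bitscore) | is.na(hits$percent_identity))
  if (length(bad))
    stop(sprintf("malformed hit table row(s) %s: non-numeric scores",
                 paste(bad, collapse = ", ")), call. = FALSE)
  hits$subject_taxon <- map_taxon(hits$subject_id, taxon_map, on_unmapped)
  hits
}

map_taxon <- function(subject_ids, taxon_map, on_unmapped = "error") {
  prefixes <- names(taxon_map)
  vapply(subject_ids, function(sid) {
    hit <- prefixes[startsWith(sid, prefixes)]
    if (length(hit) == 0L) {
      if (on_unmapped == "error")
        stop(sprintf("subject id '%s' matches no taxon-map prefix", sid),
             call. = FALSE)
      return("unknown")
    }
    unname(taxon_map[[hit[which.max(nchar(hit))]]])
  }, character(1), USE.NAMES = FALSE)
}

#' Best hit by bitscore within an optional taxon restriction
#'
#' Ties on bitscore are broken by lower e-value (missing e-values sort
#' last), then lexicographically by subject id; the result is therefore
#' invariant under permutation of the hit list.
#'
#' @param hits Hit data.frame.
#' @param restrict_to Character vector of taxon labels to keep, or `NULL`
#'   for all.
#' @return One-row data.frame, or `NULL` if no hit survives the restriction.
#' @export
best_hit <- function(hits, restrict_to = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (!is.null(restrict_to))
    hits <- hits[hits$subject_taxon %in% restrict_to, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  ev <- hits$evalue
  ev[is.na(ev)] <- Inf
  ord <- order(-hits$bitscore, ev, hits$subject_id)
  hits[ord[1], , drop = FALSE]
}

#' Write hits in BLAST tabular format 6
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  ev <- ifelse(is.na(hits$evalue), 0, hits$evalue)
  tab <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$percent_identity),
                    hits$alignment_length, hits$mismatches, hits$gap_openings,
                    hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                    format(ev, scientific = TRUE, digits = 3),
                    sprintf("%.1f", hits$bitscore))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
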
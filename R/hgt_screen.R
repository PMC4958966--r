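#' Define a taxonomy partition for the alien score-ratio screen
#'
#' Every taxon that can appear in the hit evidence is classed as `self`
#' (the screened species itself; its hits never enter scoring), `ingroup`
#' (relatives of the recipient, e.g. Lamiales for a broomrape) or
#' `outgroup` (everything else, the potential donors). One ingroup taxon is
#' designated the closest relative (e.g. Mimulus guttatus) for the
#' nucleotide-level filter.
#'
#' @param self,ingroup,outgroup Character vectors of taxon labels; classes
#'   must not overlap.
#' @param relative The designated closest ingroup relative; must be in
#'   `ingroup`.
#' @return An object of class `taxonomy_partition`.
#' @export
taxonomy_partition <- function(ingroup, outgroup, self = character(),
                               relative = ingroup[1]) {
  all_tax <- c(self, ingroup, outgroup)
  if (anyDuplicated(all_tax))
    stop("a taxon may belong to exactly one of self/ingroup/outgroup")
  if (!relative %in% ingroup)
    stop("'relative' must be one of the ingroup taxa")
  structure(list(self = self, ingroup = ingroup, outgroup = outgroup,
                 relative = relative),
            class = "taxonomy_partition")
}

taxon_class <- function(taxa, partition) {
  cls <- rep(NA_character_, length(taxa))
  cls[taxa %in% partition$self] <- "self"
  cls[taxa %in% partition$ingroup] <- "ingroup"
  cls[taxa %in% partition$outgroup] <- "outgroup"
  if (anyNA(cls))
    stop(sprintf("taxa not covered by the partition: %s",
                 paste(unique(taxa[is.na(cls)]), collapse = ", ")),
         call. = FALSE)
  cls
}

#' Transcripts expressed before host attachment
#'
#' Host-contaminant transcripts cannot be expressed in seedlings that have
#' not yet attached to a host, so only transcripts with abundance above
#' `min_abundance` in at least one pre-attachment stage are retained.
#'
#' @param stage_table data.frame with columns transcript_id, stage,
#'   abundance (FPKM), or a matrix with transcripts as rows and stages as
#'   columns.
#' @param pre_attachment Character vector of pre-attachment stage labels
#'   (default `c("0G", "2G")`: imbibed seeds and unattached seedlings).
#' @param min_abundance Abundance must be strictly greater than this
#'   (default 0: any positive abundance counts as expressed).
#' @return Character vector of retained transcript ids.
#' @export
filter_pre_attachment <- function(stage_table, pre_attachment = c("0G", "2G"),
                                  min_abundance = 0) {
  stopifnot(min_abundance >= 0)
  if (is.matrix(stage_table)) {
    stage_table <- data.frame(
      transcript_id = rep(rownames(stage_table), ncol(stage_table)),
      stage = rep(colnames(stage_table), each = nrow(stage_table)),
      abundance = as.vector(stage_table), stringsAsFactors = FALSE)
  }
  stages <- unique(stage_table$stage)
  missing <- setdiff(pre_attachment, stages)
  if (length(missing))
    stop(sprintf("pre-attachment stage(s) not in the table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(stage_table$abundance < 0))
    stop("abundances must be nonnegative")
  pre <- stage_table[stage_table$stage %in% pre_attachment, , drop = FALSE]
  unique(pre$transcript_id[pre$abundance > min_abundance])
}

#' Alien score ratio for one transcript
#'
#' The ratio of the best outgroup bitscore to the best ingroup bitscore,
#' self hits excluded. A transcript is a candidate when the ratio is
#' strictly greater than `threshold` (default 1.2; a ratio of exactly 1.2
#' is not a candidate). With outgroup hits but no ingroup hit the ratio is
#' `Inf` and the transcript is a flagged candidate; with no outgroup hit it
#' is not a candidate.
#'
#' @param hits Hit data.frame for a single query.
#' @param partition A [taxonomy_partition()].
#' @param threshold Strict ratio threshold (> 0).
#' @return One-row data.frame: transcript_id, best_ingroup_bitscore,
#'   best_outgroup_bitscore, ratio, flags (semicolon-joined), candidate,
#'   putative_donor.
#' @export
compute_alien_ratio <- function(hits, partition, threshold = 1.2) {
  stopifnot(threshold > 0)
  if (!is.null(hits) && nrow(hits) > 0 &&
      length(unique(hits$query_id)) > 1L)
    stop("hits must all share one query id")
  qid <- if (!is.null(hits) && nrow(hits) > 0) hits$query_id[1] else NA_character_
  if (!is.null(hits) && nrow(hits) > 0) {
    cls <- taxon_class(hits$subject_taxon, partition)
    hits <- hits[cls != "self", , drop = FALSE]
  }
  bi <- best_hit(hits, restrict_to = partition$ingroup)
  bo <- best_hit(hits, restrict_to = partition$outgroup)
  flags <- character()
  donor <- assign_putative_donor(hits, partition)
  if (is.null(bo)) {
    ratio <- NA_real_
    flags <- c(flags, "no_outgroup_hit")
    candidate <- FALSE
  } else if (is.null(bi)) {
    ratio <- Inf
    flags <- c(flags, "no_ingroup_hit")
    candidate <- TRUE
  } else {
    ratio <- bo$bitscore / bi$bitscore
    candidate <- ratio > threshold
  }
  data.frame(
    transcript_id = qid,
    best_ingroup_bitscore = if (is.null(bi)) NA_real_ else bi$bitscore,
    best_outgroup_bitscore = if (is.null(bo)) NA_real_ else bo$bitscore,
    ratio = ratio,
    flags = paste(flags, collapse = ";"),
    candidate = candidate,
    putative_donor = if (is.null(donor)) NA_character_ else donor,
    stringsAsFactors = FALSE)
}

#' Nucleotide-level closest-relative filter
#'
#' A transcript is filtered out when its best nucleotide-level hit over all
#' taxa belongs to the designated closest ingroup relative: strong
#' nucleotide similarity to the nearest relative indicates a native gene
#' (or recent shared ancestry), not a transfer. Transcripts with no
#' nucleotide hits pass (no significant nucleotide similarity is the
#' expected signature of a diverged foreign gene).
#'
#' @param nt_hits Nucleotide-level hit data.frame for one query (may be
#'   `NULL` or empty).
#' @param partition A [taxonomy_partition()].
#' @return `TRUE` if the transcript is filtered out, else `FALSE`.
#' @export
nt_relative_filter <- function(nt_hits, partition) {
  if (is.null(nt_hits) || nrow(nt_hits) == 0L) return(FALSE)
  cls <- taxon_class(nt_hits$subject_taxon, partition)
  nt_hits <- nt_hits[cls != "self", , drop = FALSE]
  bh <- best_hit(nt_hits)
  if (is.null(bh)) return(FALSE)
  identical(bh$subject_taxon, partition$relative)
}

#' Putative donor taxon from the best outgroup hit
#'
#' @param hits Hit data.frame for one query.
#' @param partition A [taxonomy_partition()].
#' @return Taxon label of the best outgroup hit, or `NULL` when there is
#'   none. Ties on bitscore resolve by lower e-value, then lexicographic
#'   subject id.
#' @export
assign_putative_donor <- function(hits, partition) {
  bo <- best_hit(hits, restrict_to = partition$outgroup)
  if (is.null(bo)) return(NULL)
  bo$subject_taxon
}

#' Run the full foreign-gene screen
#'
#' Applies, in order: (1) pre-attachment expression filter (host
#' contamination), (2) ORF length filter (longest stop-free stretch must
#' exceed `min_aa` amino acids), (3) alien score ratio with strict
#' threshold, (4) nucleotide-level closest-relative filter. Every
#' transcript receives a verdict row with the first failing stage flagged;
#' candidates are the transcripts that pass all four stages.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param stage_table Stage-expression data.frame (transcript_id, stage,
#'   abundance).
#' @param protein_hits,nt_hits Hit data.frames (protein- and
#'   nucleotide-level evidence, all queries together).
#' @param partition A [taxonomy_partition()].
#' @param threshold Alien-ratio threshold (strict; default 1.2).
#' @param min_aa ORF length threshold in amino acids (strict; default 100).
#' @param pre_attachment Pre-attachment stage labels.
#' @param min_abundance Expression threshold for the stage filter.
#' @return data.frame with one row per transcript: scores, ratio, flags,
#'   candidate, putative_donor.
#' @export
run_screen <- function(transcripts, stage_table, protein_hits, nt_hits,
                       partition, threshold = 1.2, min_aa = 100L,
                       pre_attachment = c("0G", "2G"), min_abundance = 0) {
  for (nm in c("stage_table", "protein_hits", "nt_hits"))
    if (is.null(get(nm)))
      stop(sprintf("missing evidence table: %s", nm), call. = FALSE)
  ids <- names(transcripts)
  pre_ok <- filter_pre_attachment(stage_table, pre_attachment, min_abundance)
  rows <- lapply(ids, function(id) {
    flags <- character()
    candidate <- FALSE
    ratio <- NA_real_; b_in <- NA_real_; b_out <- NA_real_
    donor <- NA_character_
    if (!id %in% pre_ok) {
      flags <- "stage_filtered"
    } else {
      orfs <- find_orfs(transcripts[[id]], id = id, min_aa = min_aa)
      if (nrow(orfs) == 0L) {
        flags <- "length_filtered"
      } else {
        ph <- protein_hits[protein_hits$query_id == id, , drop = FALSE]
        v <- compute_alien_ratio(ph, partition, threshold)
        ratio <- v$ratio; b_in <- v$best_ingroup_bitscore
        b_out <- v$best_outgroup_bitscore; donor <- v$putative_donor
        flags <- setdiff(strsplit(v$flags, ";")[[1]], "")
        if (v$candidate) {
          nh <- nt_hits[nt_hits$query_id == id, , drop = FALSE]
          if (nt_relative_filter(nh, partition)) {
            flags <- c(flags, "nt_relative_filtered")
          } else {
            candidate <- TRUE
          }
        }
      }
    }
    data.frame(transcript_id = id,
               best_ingroup_bitscore = b_in,
               best_outgroup_bitscore = b_out,
               ratio = ratio,
               flags = paste(flags, collapse = ";"),
               candidate = candidate,
               putative_donor = donor,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
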
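ANCHOR_LABELS <- c("a", "b", "1", "2", "3", "4")

#' Build a gene-order table
#'
#' One row per locus in chromosomal order. `anchor` labels the six
#' conserved flanking anchors ("a","b" upstream, "1"-"4" downstream of the
#' transposase tandem) or a transposase-gene label ("BO1","BO2a","BO2b");
#' `NA` marks other loci.
#'
#' @param species Species name.
#' @param locus_id Locus ids in chromosomal order.
#' @param anchor Anchor / transposase labels, `NA` for other loci.
#' @param strand "+" or "-".
#' @return data.frame of class `gene_order_table`.
#' @export
gene_order_table <- function(species, locus_id, anchor = NA_character_,
                             strand = "+") {
  stopifnot(all(strand %in% c("+", "-")))
  n <- length(locus_id)
  out <- data.frame(species = species, position = seq_len(n),
                    locus_id = locus_id,
                    anchor = rep_len(as.character(anchor), n),
                    strand = rep_len(strand, n), stringsAsFactors = FALSE)
  class(out) <- c("gene_order_table", "data.frame")
  out
}

is_bo_label <- function(x) !is.na(x) & grepl("^BO", x)

#' Map species loci to the six reference anchor genes by best hit
#'
#' Each anchor maps to its highest-bitscore locus above `min_bitscore`;
#' one locus per anchor (when two anchors best-hit the same locus the
#' higher-bitscore anchor keeps it and the other is recorded as lost, with
#' the conflict logged in the result). Anchors with no qualifying hit are
#' lost.
#'
#' @param hits Hit data.frame with query_id = anchor reference id,
#'   subject_id = species locus.
#' @param anchor_refs Named character vector mapping anchor labels
#'   ("a","b","1".."4") to reference gene ids.
#' @param min_bitscore Minimum bitscore for an assignment (default 50).
#' @return List with `assignment` (named character: locus id per anchor
#'   label, NA when lost), `lost` (character vector of lost anchors) and
#'   `conflicts` (character vector of logged conflicts).
#' @export
assign_anchors <- function(hits, anchor_refs, min_bitscore = 50) {
  assignment <- setNames(rep(NA_character_, length(anchor_refs)),
                         names(anchor_refs))
  score <- setNames(rep(-Inf, length(anchor_refs)), names(anchor_refs))
  conflicts <- character()
  for (lab in names(anchor_refs)) {
    h <- hits[hits$query_id == anchor_refs[[lab]] &
                hits$bitscore >= min_bitscore, , drop = FALSE]
    bh <- best_hit(h)
    if (!is.null(bh)) {
      assignment[[lab]] <- bh$subject_id
      score[[lab]] <- bh$bitscore
    }
  }
  # enforce one locus per anchor: best bitscore wins
  taken <- assignment[!is.na(assignment)]
  for (locus in unique(taken)) {
    labs <- names(taken)[taken == locus]
    if (length(labs) > 1L) {
      winner <- labs[which.max(score[labs])]
      losers <- setdiff(labs, winner)
      assignment[losers] <- NA_character_
      conflicts <- c(conflicts, sprintf(
        "locus %s claimed by anchors %s; kept %s",
        locus, paste(labs, collapse = ","), winner))
      taken <- assignment[!is.na(assignment)]
    }
  }
  list(assignment = assignment,
       lost = names(assignment)[is.na(assignment)],
       conflicts = conflicts)
}

#' Compare a species gene-order table to the reference arrangement
#'
#' Reports anchor losses, order conservation over the anchors present
#' (losses do not break order; a full block reversal counts as conserved
#' and is flagged), orientation flips after normalising for block
#' reversal, the number of transposase (BO) genes, and whether they are
#' arranged in tandem between anchors b and 1 (adjacent or separated only
#' by non-anchor loci).
#'
#' @param table Species [gene_order_table()].
#' @param reference Reference table containing all six anchors.
#' @return List: species, anchors_present, anchors_lost, order_conserved,
#'   block_reversed, orientation_flips, bo_gene_count, tandem_bo.
#' @export
compare_to_reference <- function(table, reference) {
  ref_anchors <- reference$anchor[reference$anchor %in% ANCHOR_LABELS]
  if (!all(ANCHOR_LABELS %in% ref_anchors))
    stop("reference must contain all six anchors", call. = FALSE)
  sp_anchors <- table$anchor[table$anchor %in% ANCHOR_LABELS]
  anchors_present <- intersect(ANCHOR_LABELS, sp_anchors)
  anchors_lost <- setdiff(ANCHOR_LABELS, sp_anchors)

  ref_order <- ref_anchors[ref_anchors %in% anchors_present]
  order_conserved <- identical(sp_anchors, ref_order)
  block_reversed <- FALSE
  if (!order_conserved && identical(sp_anchors, rev(ref_order))) {
    order_conserved <- TRUE
    block_reversed <- TRUE
  }

  # orientation: compare strands per label, normalising for block reversal
  labelled <- table[!is.na(table$anchor), , drop = FALSE]
  ref_lab <- reference[!is.na(reference$anchor), , drop = FALSE]
  flips <- character()
  for (k in seq_len(nrow(labelled))) {
    lab <- labelled$anchor[k]
    ref_strand <- ref_lab$strand[ref_lab$anchor == lab]
    if (length(ref_strand) == 0L) next
    expected <- if (block_reversed) flip_strand(ref_strand[1]) else ref_strand[1]
    if (labelled$strand[k] != expected) flips <- c(flips, lab)
  }

  bo <- table[is_bo_label(table$anchor), , drop = FALSE]
  bo_gene_count <- nrow(bo)
  tandem_bo <- FALSE
  if (bo_gene_count > 0L) {
    between <- bo$position
    # no anchor locus may fall between the first and last transposase gene
    anchors_between <- table$anchor[table$position > min(between) &
                                      table$position < max(between)]
    no_anchor_interruption <-
      !any(anchors_between %in% ANCHOR_LABELS, na.rm = TRUE)
    # keyed to the b ... 1 interval of the reference arrangement
    pos_b <- table$position[!is.na(table$anchor) & table$anchor == "b"]
    pos_1 <- table$position[!is.na(table$anchor) & table$anchor == "1"]
    if (block_reversed) { tmp <- pos_b; pos_b <- pos_1; pos_1 <- tmp }
    lo <- if (length(pos_b)) pos_b[1] else -Inf
    hi <- if (length(pos_1)) pos_1[1] else Inf
    tandem_bo <- no_anchor_interruption &&
      all(between > lo & between < hi)
  }

  list(species = table$species[1],
       anchors_present = anchors_present,
       anchors_lost = anchors_lost,
       order_conserved = order_conserved,
       block_reversed = block_reversed,
       orientation_flips = flips,
       bo_gene_count = bo_gene_count,
       tandem_bo = tandem_bo)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Synteny report for several species against one reference
#'
#' @param tables List of species [gene_order_table()]s.
#' @param reference Reference table.
#' @param path Optional TSV output path.
#' @return data.frame, one species per row: anchors lost, order
#'   conservation, flips, transposase-gene count and tandem arrangement.
#' @export
synteny_report <- function(tables, reference, path = NULL) {
  rows <- lapply(tables, function(tab) {
    r <- compare_to_reference(tab, reference)
    data.frame(species = r$species,
               anchors_present = paste(r$anchors_present, collapse = ","),
               anchors_lost = paste(r$anchors_lost, collapse = ","),
               order_conserved = r$order_conserved,
               block_reversed = r$block_reversed,
               orientation_flips = paste(r$orientation_flips, collapse = ","),
               bo_gene_count = r$bo_gene_count,
               tandem_bo = r$tandem_bo,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(path))
    write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
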
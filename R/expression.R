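#' FPKM from fragment counts
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fragments * 1e9 / (effective_length_bp * total_mapped_fragments)`.
#' Linear in fragments, inverse-linear in length and library size.
#'
#' @param fragments Fragment count (>= 0); vectorised.
#' @param effective_length_bp Transcript effective length in bp (>= 1). By
#'   default the annotated transcript length (no fragment-length
#'   correction).
#' @param total_mapped_fragments Library size in mapped fragments (>= 1).
#' @return FPKM value(s).
#' @export
fpkm <- function(fragments, effective_length_bp, total_mapped_fragments) {
  if (any(effective_length_bp < 1))
    stop("effective length must be >= 1 bp", call. = FALSE)
  if (any(total_mapped_fragments < 1))
    stop("total mapped fragments must be >= 1", call. = FALSE)
  fragments * 1e9 / (effective_length_bp * total_mapped_fragments)
}

#' Reference expression level from usable isoforms
#'
#' The reference gene (actin) may assemble into several isoforms of which
#' only some carry the qPCR primer sites; the reference level is the sum
#' of the FPKM values of the usable isoforms.
#'
#' @param isoform_fpkms Numeric vector of isoform FPKM values.
#' @param usable Logical mask, same length (e.g. contains both primer
#'   sequences).
#' @return Sum of usable FPKMs. Warns when the usable isoforms sum to zero
#'   (downstream ratios undefined); errors when no isoform is usable.
#' @export
reference_level <- function(isoform_fpkms, usable) {
  stopifnot(length(isoform_fpkms) == length(usable))
  if (!any(usable))
    stop("no usable reference isoform", call. = FALSE)
  s <- sum(isoform_fpkms[usable])
  if (s == 0)
    warning("usable reference isoforms have zero FPKM; ratios undefined")
  s
}

#' Expression relative to a reference gene
#'
#' @param gene_fpkm Gene FPKM (>= 0).
#' @param reference_fpkm Reference FPKM (> 0).
#' @return `gene_fpkm / reference_fpkm`.
#' @export
relative_level <- function(gene_fpkm, reference_fpkm) {
  if (any(reference_fpkm <= 0))
    stop("reference FPKM must be positive (ratio undefined)", call. = FALSE)
  gene_fpkm / reference_fpkm
}

#' Relative expression by the comparative CT method
#'
#' `2^-(Ct_target - Ct_reference)` within one condition. No calibrator
#' condition is baked in: cross-condition ratios are obtained by dividing
#' within-condition values. Satisfies
#' `comparative_ct(a, b) * comparative_ct(b, a) == 1`.
#'
#' @param ct_target Mean Ct of the target gene (cycles).
#' @param ct_reference Mean Ct of the reference gene (cycles).
#' @return Relative expression level.
#' @export
comparative_ct <- function(ct_target, ct_reference) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference))
  2^(-(ct_target - ct_reference))
}

#' Tidy relative-expression table from an FPKM table
#'
#' @param fpkm_table data.frame with columns gene_id, condition, fpkm.
#' @param reference_table data.frame with columns condition, reference_fpkm.
#' @return data.frame gene_id, condition, fpkm, reference_fpkm,
#'   relative_level.
#' @export
relative_expression_table <- function(fpkm_table, reference_table) {
  m <- merge(fpkm_table, reference_table, by = "condition")
  m$relative_level <- relative_level(m$fpkm, m$reference_fpkm)
  m[order(m$gene_id, m$condition),
    c("gene_id", "condition", "fpkm", "reference_fpkm", "relative_level")]
}
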
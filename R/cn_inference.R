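# Interstitial-deletion inference: an intrachromosomal fusion joining two
# same-strand, colinearly transcribable genes implies that the genomic
# segment between the retained portions has been lost. Genes wholly inside
# the lost interval (e.g. a tumor suppressor bracketed by the two partners)
# are reported as encompassed.

new_deletion_call <- function(chrom, start, end, encompassed, fusion_id, approximate) {
  stopifnot(start <= end)
  structure(list(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 size_bp = as.integer(end - start + 1L),
                 encompassed_genes = encompassed,
                 evidence_fusion = fusion_id, approximate = approximate),
            class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> %s:%d-%d (%s bp, %.1f Mb)%s; encompasses: %s\n",
              x$chrom, x$start, x$end, format(x$size_bp, big.mark = ","),
              x$size_bp / 1e6, if (x$approximate) " [approximate]" else "",
              if (length(x$encompassed_genes) > 0L) paste(x$encompassed_genes, collapse = ", ") else "none"))
  invisible(x)
}

#' Infer the interstitial deletion implied by a flanking-gene fusion
#'
#' Applicable only to intrachromosomal fusions whose partners sit on the
#' same gene strand in colinear, transcribable orientation (donor upstream
#' of acceptor in transcriptional direction). The lost interval runs from
#' one base past the junction-proximal boundary of the upstream retained
#' segment to one base before the junction-proximal boundary of the
#' downstream retained segment, in forward-genome coordinates. When the
#' breakpoints are intronic or missing, the facing gene boundaries are used
#' and the call is tagged `approximate`.
#'
#' @param fusion a single-row `fusion_set` (or list with the same fields).
#' @param models a `gene_model_set` used to resolve partners and to list
#'   encompassed genes; genes wholly inside the interval are reported.
#' @param use_gene_boundaries force the gene-boundary approximation even
#'   when breakpoints look exonic (default `FALSE`).
#' @return a `deletion_call`, or an object of class `no_deletion` carrying
#'   `$reason` when the fusion implies no deletion (`"interchromosomal"`,
#'   `"strand_mismatch"`, `"no_loss_orientation"`, `"empty_gap"`,
#'   `"unknown_partner"`).
#' @export
infer_interstitial_deletion <- function(fusion, models, use_gene_boundaries = FALSE) {
  none <- function(reason) structure(list(reason = reason), class = "no_deletion")
  ch5 <- norm_chrom(fusion$chrom5[1]); ch3 <- norm_chrom(fusion$chrom3[1])
  if (ch5 != ch3) return(none("interchromosomal"))
  g5 <- model_for_symbol(models, fusion$gene5[1])
  g3 <- model_for_symbol(models, fusion$gene3[1])
  if (is.null(g5) || is.null(g3)) return(none("unknown_partner"))
  if (g5$strand != g3$strand) return(none("strand_mismatch"))
  fwd <- g5$strand == "+"

  # colinear transcribable orientation: the donor must lie upstream of the
  # acceptor in transcriptional direction, otherwise the junction implies a
  # duplication/inversion, not a loss
  donor_upstream <- if (fwd) gene_end(g5) < gene_start(g3) else gene_start(g5) > gene_end(g3)
  if (!donor_upstream) return(none("no_loss_orientation"))

  p5 <- fusion$pos5[1]; p3 <- fusion$pos3[1]
  approx <- isTRUE(use_gene_boundaries)
  exonic5 <- !is.na(p5) && !is.na(exon_index_at(g5, p5))
  exonic3 <- !is.na(p3) && !is.na(exon_index_at(g3, p3))
  if (!exonic5 || !exonic3) approx <- TRUE
  if (approx) {
    # facing boundaries of the two partner spans
    p5 <- if (fwd) gene_end(g5) else gene_start(g5)
    p3 <- if (fwd) gene_start(g3) else gene_end(g3)
  }

  # retained segments in forward coordinates: donor keeps its prefix up to
  # p5, acceptor keeps from p3 on
  if (fwd) { lost_lo <- p5 + 1L; lost_hi <- p3 - 1L }
  else     { lost_lo <- p3 + 1L; lost_hi <- p5 - 1L }
  if (lost_lo > lost_hi) return(none("empty_gap"))

  inside <- models_overlapping(models, ch5, lost_lo, lost_hi, type = "within")
  encompassed <- sort(unique(vapply(inside, `[[`, "", "gene_id")))
  fid <- sprintf("%s--%s", fusion$gene5[1], fusion$gene3[1])
  new_deletion_call(ch5, lost_lo, lost_hi, encompassed, fid, approx)
}

#' Compare an inferred deletion with copy-number segments
#'
#' @param deletion a `deletion_call`.
#' @param segments data.table of CN segments as from [read_cn_segments()]
#'   (`chrom`, `start`, `end`, `copy_number`), sorted and non-overlapping
#'   per chromosome.
#' @param min_cover fraction of the deletion that a segment class must cover
#'   (default 0.5).
#' @return `"supported"` when loss segments (copy_number < 2) cover at least
#'   `min_cover` of the interval, `"contradicted"` when neutral/gain
#'   segments do, `"untested"` otherwise.
#' @export
intersect_with_cn_segments <- function(deletion, segments, min_cover = 0.5) {
  seg <- as.data.table(segments)
  if (any(seg$start > seg$end)) stopf("value error: malformed CN segment (start > end)")
  seg <- seg[norm_chrom(seg$chrom) == norm_chrom(deletion$chrom), ]
  if (nrow(seg) == 0L) return("untested")
  ov <- pmax(0L, pmin(seg$end, deletion$end) - pmax(seg$start, deletion$start) + 1L)
  loss_cov <- sum(ov[seg$copy_number < 2]) / deletion$size_bp
  neutral_cov <- sum(ov[seg$copy_number >= 2]) / deletion$size_bp
  if (loss_cov >= min_cover) return("supported")
  if (neutral_cov >= min_cover) return("contradicted")
  "untested"
}
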
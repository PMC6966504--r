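# Junction consequence annotation: reading frame, partner orientation,
# acceptor-exon-skipping isoforms, fusion-protein extent and junction
# microhomology.
#
# Frame bookkeeping uses two quantities:
#   c5 — coding nucleotides of the 5' partner retained upstream of (and
#        including) the junction, along transcription;
#   s3 — coding nucleotides of the 3' partner upstream of (removed by) the
#        junction.
# The junction preserves the reading frame iff c5 = s3 (mod 3).

# total CDS overlap of a gene model's exons with genomic window [lo, hi]
cds_overlap <- function(g, lo, hi) {
  if (!is_coding(g)) return(0L)
  lo <- max(lo, g$cds_start); hi <- min(hi, g$cds_end)
  if (lo > hi) return(0L)
  sum(pmax(0L, pmin(g$exons$end, hi) - pmax(g$exons$start, lo) + 1L))
}

exon_index_at <- function(g, pos) {
  hit <- which(pos >= g$exons$start & pos <= g$exons$end)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# Snap an intronic breakpoint to the splice-consistent exon boundary.
# Donor junctions move to the nearest exon end upstream in transcription;
# acceptor junctions to the nearest exon start downstream (the spliced-
# fusion assumption: the transcript joins exon to exon even when the genomic
# breakpoint lies in an intron). Returns NA when snapping is impossible or
# would move the breakpoint more than `max_move` bp.
snap_breakpoint <- function(g, pos, role = c("donor", "acceptor"), max_move = 500000L) {
  role <- match.arg(role)
  if (pos < gene_start(g) || pos > gene_end(g)) {
    stopf("contract violation: breakpoint %d outside span of gene %s (%d-%d)",
          pos, g$gene_id, gene_start(g), gene_end(g))
  }
  if (!is.na(exon_index_at(g, pos))) return(pos)
  fwd <- g$strand == "+"
  upstream_end <- if (fwd) {
    cand <- g$exons$end[g$exons$end < pos]
    if (length(cand) > 0L) max(cand) else NA_integer_
  } else {
    cand <- g$exons$start[g$exons$start > pos]
    if (length(cand) > 0L) min(cand) else NA_integer_
  }
  downstream_start <- if (fwd) {
    cand <- g$exons$start[g$exons$start > pos]
    if (length(cand) > 0L) min(cand) else NA_integer_
  } else {
    cand <- g$exons$end[g$exons$end < pos]
    if (length(cand) > 0L) max(cand) else NA_integer_
  }
  snapped <- if (role == "donor") upstream_end else downstream_start
  if (is.na(snapped) || abs(snapped - pos) > max_move) return(NA_integer_)
  snapped
}

new_frame_result <- function(status, c5 = NA_integer_, s3 = NA_integer_) {
  stopifnot(status %in% c("in_frame", "out_of_frame", "promoter_swap",
                          "noncoding", "undetermined"))
  structure(list(status = status, c5 = c5, s3 = s3), class = "frame_result")
}

#' @export
print.frame_result <- function(x, ...) {
  cat(sprintf("<frame_result> %s (c5 = %s, s3 = %s)\n", x$status, x$c5, x$s3))
  invisible(x)
}

#' Classify partner orientation in the fused transcript
#'
#' A partner is `conserved` when the fused transcript traverses it along its
#' native 5'->3' direction (the junction strand equals the gene strand) and
#' `inverted` otherwise. Derived purely from the candidate's junction
#' strands and the gene-model strands.
#'
#' @param fusion a single-row `fusion_set`.
#' @param g5,g3 `gene_model`s of the 5' and 3' partners.
#' @return list with `orient5` and `orient3` (`"conserved"`/`"inverted"`).
#' @export
classify_orientation <- function(fusion, g5, g3) {
  list(orient5 = if (orient_conserved(fusion$strand5[1], g5$strand)) "conserved" else "inverted",
       orient3 = if (orient_conserved(fusion$strand3[1], g3$strand)) "conserved" else "inverted")
}

#' Determine the reading frame at a chimeric junction
#'
#' Computes `c5` (coding bases of the donor at or 5' of `pos5` along
#' transcription) and `s3` (coding bases of the acceptor strictly 5' of
#' `pos3`), snapping intronic breakpoints to splice-consistent exon
#' boundaries first. Status:
#' \itemize{
#'   \item `noncoding` — either model lacks a CDS;
#'   \item `promoter_swap` — the acceptor junction lies at or upstream of
#'     the acceptor CDS start (the donor contributes promoter/5'UTR and the
#'     acceptor ORF is intact);
#'   \item `in_frame` — both junctions lie inside their CDS and
#'     `c5 == s3 (mod 3)`;
#'   \item `out_of_frame` — junctions inside the gene but the frame is not
#'     preserved, including an inverted (antisense) acceptor and junctions
#'     in UTRs that truncate the chimeric ORF;
#'   \item `undetermined` — an intronic breakpoint could not be snapped
#'     (no exon in the required direction or > 500 kb away) or the donor is
#'     inverted, so no spliced donor prefix exists.
#' }
#' Breakpoints outside the gene span are a contract violation (such
#' candidates carry the `unreliable_structure` flag and are not annotated).
#'
#' @inheritParams classify_orientation
#' @return a `frame_result` with `status`, `c5`, `s3`.
#' @export
determine_frame <- function(fusion, g5, g3) {
  ori <- classify_orientation(fusion, g5, g3)
  if (ori$orient5 == "inverted") return(new_frame_result("undetermined"))
  if (!is_coding(g5) || !is_coding(g3)) return(new_frame_result("noncoding"))
  p5 <- snap_breakpoint(g5, fusion$pos5[1], "donor")
  p3 <- snap_breakpoint(g3, fusion$pos3[1], "acceptor")
  if (is.na(p5) || is.na(p3)) return(new_frame_result("undetermined"))

  fwd5 <- g5$strand == "+"
  c5 <- if (fwd5) cds_overlap(g5, 1L, p5) else cds_overlap(g5, p5, .Machine$integer.max)
  fwd3 <- g3$strand == "+"
  s3 <- if (fwd3) cds_overlap(g3, 1L, p3 - 1L) else cds_overlap(g3, p3 + 1L, .Machine$integer.max)

  if (ori$orient3 == "inverted") return(new_frame_result("out_of_frame", c5, s3))

  # acceptor junction at or upstream of its CDS start: promoter swap
  acc_upstream_of_cds <- if (fwd3) p3 <= g3$cds_start else p3 >= g3$cds_end
  if (acc_upstream_of_cds) return(new_frame_result("promoter_swap", c5, s3))

  # junctions must fall inside both CDS regions for a fusion ORF
  donor_in_cds <- if (fwd5) (p5 >= g5$cds_start && p5 <= g5$cds_end)
                  else (p5 <= g5$cds_end && p5 >= g5$cds_start)
  acc_in_cds <- p3 >= g3$cds_start && p3 <= g3$cds_end
  if (!donor_in_cds || !acc_in_cds) return(new_frame_result("out_of_frame", c5, s3))

  if ((c5 %% 3L) == (s3 %% 3L)) new_frame_result("in_frame", c5, s3)
  else new_frame_result("out_of_frame", c5, s3)
}

#' Enumerate acceptor exon-skipping isoforms of a fusion
#'
#' A fusion junction that lands in acceptor exon *j* is frequently expressed
#' as several splicing isoforms in which 1, 2, ... acceptor exons
#' immediately downstream of the junction are skipped. Isoform "type 1"
#' keeps all acceptor exons from *j* on; "type k+1" skips *k* exons (the
#' acceptor restarts at exon *j + k*). The list is capped by exon
#' availability: with `r` acceptor exons remaining from *j*, at most
#' `min(max_skip, r - 1) + 1` isoforms exist. Each isoform carries its own
#' frame call.
#'
#' @inheritParams classify_orientation
#' @param max_skip maximum number of skipped acceptor exons (default 2).
#' @return list of isoform records: `label`, `skipped_acceptor_exons`,
#'   `junction` (5' exon index, 3' exon index), `frame` (a `frame_result`).
#' @export
enumerate_isoforms <- function(fusion, g5, g3, max_skip = 2L) {
  if (!is_count(max_skip)) stopf("value error: max_skip must be a non-negative integer")
  p5 <- snap_breakpoint(g5, fusion$pos5[1], "donor")
  p3 <- snap_breakpoint(g3, fusion$pos3[1], "acceptor")
  if (is.na(p3) || is.na(p5)) {
    return(list(list(label = "type 1", skipped_acceptor_exons = 0L,
                     junction = c(NA_integer_, NA_integer_),
                     frame = new_frame_result("undetermined"))))
  }
  e5 <- exon_index_at(g5, p5)
  j <- exon_index_at(g3, p3)
  n <- nrow(g3$exons)
  n_iso <- min(max_skip, (n - j + 1L) - 1L) + 1L
  out <- vector("list", n_iso)
  for (s in seq_len(n_iso) - 1L) {
    acc_exon <- j + s
    if (s == 0L) {
      new_pos3 <- p3
    } else {
      # transcription start of the (j+s)-th acceptor exon
      new_pos3 <- if (g3$strand == "+") g3$exons$start[acc_exon] else g3$exons$end[acc_exon]
    }
    f2 <- list(pos5 = fusion$pos5[1], strand5 = fusion$strand5[1],
               pos3 = new_pos3, strand3 = fusion$strand3[1])
    out[[s + 1L]] <- list(label = sprintf("type %d", s + 1L),
                          skipped_acceptor_exons = s,
                          junction = c(e5, acc_exon),
                          frame = determine_frame(f2, g5, g3))
  }
  out
}

#' Extent of the predicted fusion protein
#'
#' For an in-frame fusion, the chimeric protein consists of the donor's
#' N-terminal residues up to the junction and the acceptor's C-terminal
#' residues from the junction on.
#'
#' @param fr a `frame_result` with `status == "in_frame"` (anything else is
#'   a contract violation).
#' @param g5,g3 `gene_model`s of the partners.
#' @return list with `residues5` (`floor(c5/3)`, counting the initiator),
#'   `residues3` (`total_acceptor_residues - floor(s3/3)`, clamped at 0),
#'   `total_acceptor_residues` (acceptor protein length, stop codon
#'   excluded), `first_acceptor_codon` (index of the first acceptor codon in
#'   the fusion, `floor(s3/3) + 1`), and `junction_codon_donor_bases`
#'   (`c5 mod 3`; non-zero means the junction codon is a donor/acceptor
#'   hybrid, reported as an annotation rather than a frame failure).
#' @export
fusion_protein_extent <- function(fr, g5, g3) {
  if (!identical(fr$status, "in_frame")) {
    stopf("contract violation: fusion_protein_extent requires an in_frame result (got %s)", fr$status)
  }
  total <- cds_length(g3) %/% 3L - 1L  # exclude the stop codon
  residues5 <- fr$c5 %/% 3L
  residues3 <- max(0L, total - fr$s3 %/% 3L)
  list(residues5 = residues5, residues3 = residues3,
       total_acceptor_residues = total,
       first_acceptor_codon = fr$s3 %/% 3L + 1L,
       junction_codon_donor_bases = fr$c5 %% 3L)
}

#' Microhomology length at a fusion junction
#'
#' Identical bases on both sides of a breakpoint junction make its exact
#' position ambiguous: sliding the junction left by up to `k` positions
#' yields the identical fused sequence iff the donor's last `k` bases equal
#' the `k` bases immediately 5' of the acceptor junction. This returns the
#' largest such `k <= max_k` (the longest common suffix of the two
#' contexts).
#'
#' @param donor_context bases of the 5' partner ending at the junction,
#'   5'->3' in fused-transcript orientation.
#' @param acceptor_context bases immediately 5' of the acceptor junction
#'   (i.e. the acceptor bases removed by the fusion), 5'->3' in
#'   fused-transcript orientation.
#' @param max_k cap on the reported homology (default 20). Both contexts
#'   must supply at least `max_k` bases; when the cap is hit the result
#'   carries attribute `capped = TRUE`.
#' @return integer microhomology length.
#' @export
microhomology_length <- function(donor_context, acceptor_context, max_k = 20L) {
  a <- toupper(donor_context); b <- toupper(acceptor_context)
  if (!is_count(max_k) || max_k < 1L) stopf("value error: max_k must be a positive integer")
  if (nchar(a) < max_k || nchar(b) < max_k) {
    stopf("value error: junction contexts shorter than max_k = %d bases", max_k)
  }
  av <- rev(strsplit(a, "")[[1]]); bv <- rev(strsplit(b, "")[[1]])
  k <- 0L
  while (k < max_k && av[k + 1L] == bv[k + 1L]) k <- k + 1L
  if (k == max_k) attr(k, "capped") <- TRUE
  k
}

#' Two-sided junction ambiguity
#'
#' The breakpoint can slide left over the microhomology between donor suffix
#' and acceptor pre-junction bases, and right over the homology between the
#' donor's continuation and the acceptor's post-junction bases. The total
#' ambiguity (left + right) is a property of the junction itself and is
#' invariant under reverse-complementing the whole junction (left and right
#' swap roles).
#'
#' @param donor_up,donor_down donor bases ending at / continuing past the
#'   junction (5'->3').
#' @param acceptor_up,acceptor_down acceptor bases preceding / starting at
#'   the junction (5'->3').
#' @param max_k per-side cap (default 20).
#' @return list with `left`, `right`, `total`.
#' @export
junction_ambiguity <- function(donor_up, donor_down, acceptor_up, acceptor_down,
                               max_k = 20L) {
  left <- microhomology_length(donor_up, acceptor_up, max_k)
  # right side: longest common prefix = common suffix of reversed strings
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  right <- microhomology_length(rev_str(donor_down), rev_str(acceptor_down), max_k)
  list(left = as.integer(left), right = as.integer(right),
       total = as.integer(left) + as.integer(right))
}
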
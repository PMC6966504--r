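# Tier-1 evidence: is a fusion explained by a cytogenetically observed
# event? Band matching is deliberately coarse: chromosome-banding breakpoint
# calls are one-major-band accurate at best, so distance is computed on
# major-band integers of the same arm and the default tolerance is 1
# (karyotypes in practice report e.g. q21 for a gene that maps at q22.3).

#' Resolve the cytoband of a gene model
#'
#' The band containing the gene midpoint; when the gene spans a band
#' boundary, the band holding the larger share of the gene.
#'
#' @param g a `gene_model`.
#' @param map a `cytoband_map`.
#' @return a band label (e.g. `"q22.3"`).
#' @export
gene_to_band <- function(g, map) {
  ch <- norm_chrom(g$chrom)
  sub <- map[map$chrom == ch, ]
  if (nrow(sub) == 0L) stopf("chromosome %s absent from cytoband map", ch)
  s <- gene_start(g); e <- gene_end(g)
  ov <- pmax(0L, pmin(sub$end, e) - pmax(sub$start, s) + 1L)
  if (all(ov == 0L)) return(band_at(map, ch, (s + e) %/% 2L))
  sub$band[which.max(ov)]
}

new_concordance <- function(matched, event = NULL, band5 = NA_character_,
                            band3 = NA_character_, band_distance = NA_integer_) {
  structure(list(matched = matched, event = event, band5 = band5,
                 band3 = band3, band_distance = band_distance),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<concordance> matched %s (bands %s / %s, distance %s)\n",
                x$event$raw, x$band5, x$band3, x$band_distance))
  } else {
    cat("<concordance> no cytogenetic match (cryptic)\n")
  }
  invisible(x)
}

# distance between a cytogenetic band call (possibly a range) and a resolved
# gene band; Inf when incomparable
event_band_distance <- function(event_band, gene_band) {
  band_distance(event_band, gene_band)
}

#' Match a fusion candidate against a karyotype
#'
#' A fusion is concordant when some translocation-like event of the
#' karyotype pairs the two partner chromosomes and each cytogenetic band
#' lies within `tolerance` major bands (same arm) of the partner's resolved
#' band. Inversions match only intrachromosomal fusions whose two
#' breakpoints fall in (within tolerance of) the two inversion bands.
#' Matching is symmetric in partner order and considers the union of all
#' clones.
#'
#' @param fusion a single-row `fusion_set` (or list with `chrom5`, `pos5`,
#'   `chrom3`, `pos3`).
#' @param karyotype a `karyotype`.
#' @param map a `cytoband_map`.
#' @param tolerance maximum major-band distance (default 1).
#' @return a `concordance_result` with fields `matched`, `event`, `band5`,
#'   `band3`, `band_distance`.
#' @export
match_fusion_to_karyotype <- function(fusion, karyotype, map, tolerance = 1L) {
  ch5 <- norm_chrom(fusion$chrom5[1]); ch3 <- norm_chrom(fusion$chrom3[1])
  b5 <- tryCatch(band_at(map, ch5, fusion$pos5[1]), error = function(e) NA_character_)
  b3 <- tryCatch(band_at(map, ch3, fusion$pos3[1]), error = function(e) NA_character_)
  if (is.na(b5) || is.na(b3)) return(new_concordance(FALSE, band5 = b5, band3 = b3))
  events <- extract_translocation_like(karyotype)
  best <- NULL
  for (ev in events) {
    evch <- norm_chrom(ev$chroms)
    if (ev$kind == "translocation") {
      # assign the two partners to two distinct event slots
      idx5 <- which(evch == ch5); idx3 <- which(evch == ch3)
      for (i in idx5) for (j in idx3) {
        if (i == j) next
        d5 <- event_band_distance(ev$bands[i], b5)
        d3 <- event_band_distance(ev$bands[j], b3)
        if (d5 <= tolerance && d3 <= tolerance) {
          d <- max(d5, d3)
          if (is.null(best) || d < best$band_distance) {
            best <- new_concordance(TRUE, ev, b5, b3, as.integer(d))
          }
        }
      }
    } else if (ev$kind == "inversion") {
      if (ch5 != ch3 || length(evch) != 1L || evch != ch5 || length(ev$bands) != 2L) next
      d_a <- max(event_band_distance(ev$bands[1], b5), event_band_distance(ev$bands[2], b3))
      d_b <- max(event_band_distance(ev$bands[1], b3), event_band_distance(ev$bands[2], b5))
      d <- min(d_a, d_b)
      if (d <= tolerance && (is.null(best) || d < best$band_distance)) {
        best <- new_concordance(TRUE, ev, b5, b3, as.integer(d))
      }
    }
  }
  if (is.null(best)) new_concordance(FALSE, band5 = b5, band3 = b3) else best
}
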
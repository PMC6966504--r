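# Gene models: per-transcript exon/CDS structure read from GTF.
#
# All coordinates are 1-based inclusive on the forward genomic strand. Exons
# of a model are stored in transcription order: ascending genomic start on
# "+", descending on "-".

#' Construct a single gene model
#'
#' @param gene_id gene symbol / identifier.
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons a two-column matrix or data.frame (`start`, `end`) of 1-based
#'   inclusive exon intervals; any row order is accepted and rows are sorted
#'   into transcription order.
#' @param cds_start,cds_end genomic bounds of the coding region, or `NA` for a
#'   non-coding model. The bounds must lie within the exon union.
#' @param band optional cytoband label.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds_start = NA, cds_end = NA, band = NA_character_) {
  ex <- as.data.table(exons)
  setnames(ex, 1:2, c("start", "end"))
  ex[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(ex$start > ex$end)) stopf("gene model %s: exon start > end", transcript_id)
  setorder(ex, start)
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
    stopf("gene model %s: overlapping exons", transcript_id)
  }
  if (!strand %in% c("+", "-")) stopf("gene model %s: strand must be + or -", transcript_id)
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  cds_start <- suppressWarnings(as.integer(cds_start))
  cds_end <- suppressWarnings(as.integer(cds_end))
  if (!is.na(cds_start) && !is.na(cds_end)) {
    if (cds_start > cds_end) stopf("gene model %s: cds_start > cds_end", transcript_id)
    covered <- sum(pmax(0L, pmin(ex$end, cds_end) - pmax(ex$start, cds_start) + 1L))
    span_inside <- cds_start >= min(ex$start) && cds_end <= max(ex$end)
    if (!span_inside || covered == 0L) {
      stopf("gene model %s: CDS outside exon union", transcript_id)
    }
  } else {
    cds_start <- NA_integer_; cds_end <- NA_integer_
  }
  structure(list(gene_id = as.character(gene_id),
                 transcript_id = as.character(transcript_id),
                 chrom = norm_chrom(chrom), strand = strand, exons = ex,
                 cds_start = cds_start, cds_end = cds_end, band = band),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding" else sprintf("CDS %d-%d", x$cds_start, x$cds_end)
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d (%s), %d exon(s), %s\n",
              x$gene_id, x$transcript_id, x$chrom, gene_start(x), gene_end(x),
              x$strand, nrow(x$exons), cds))
  invisible(x)
}

gene_start <- function(g) min(g$exons$start)
gene_end <- function(g) max(g$exons$end)
gene_span <- function(g) c(gene_start(g), gene_end(g))
is_coding <- function(g) !is.na(g$cds_start)
cds_length <- function(g) {
  if (!is_coding(g)) return(0L)
  sum(pmax(0L, pmin(g$exons$end, g$cds_end) - pmax(g$exons$start, g$cds_start) + 1L))
}

#' Read gene models from a GTF file
#'
#' Parses `exon` and `CDS` features into one [gene_model()] per transcript.
#' Both Ensembl-style (`gene_name`) and RefSeq-style attribute blocks are
#' accepted; the gene symbol is taken from `gene_name` when present, else
#' `gene_id`. The returned set is indexed by (case-insensitive) symbol and by
#' genomic interval.
#'
#' @param path path to a GTF file.
#' @param cytobands optional `cytoband_map`; when given, each model is
#'   annotated with the band of its midpoint.
#' @return an object of class `gene_model_set` with elements
#'   `models` (named list by transcript id), `by_symbol` (list: symbol ->
#'   transcript ids), and `ranges` (a `GRanges` of transcript spans used for
#'   interval queries).
#' @export
read_gene_models <- function(path, cytobands = NULL) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  dt <- as.data.table(as.data.frame(gr))
  if (!"transcript_id" %in% names(dt)) stopf("GTF %s: no transcript_id attribute", path)
  dt <- dt[dt$type %in% c("exon", "CDS"), ]
  if (nrow(dt) == 0L) stopf("GTF %s: no exon/CDS features", path)
  sym <- if ("gene_name" %in% names(dt)) ifelse(is.na(dt$gene_name), dt$gene_id, dt$gene_name) else dt$gene_id
  dt[, symbol := sym]
  models <- list()
  for (tx in unique(dt$transcript_id)) {
    sub <- dt[dt$transcript_id == tx, ]
    ex <- sub[sub$type == "exon", c("start", "end")]
    cds <- sub[sub$type == "CDS", ]
    if (nrow(ex) == 0L) stopf("GTF model error: transcript %s has CDS but no exons", tx)
    cs <- if (nrow(cds) > 0L) min(cds$start) else NA_integer_
    ce <- if (nrow(cds) > 0L) max(cds$end) else NA_integer_
    g <- tryCatch(
      gene_model(sub$symbol[1L], tx, as.character(sub$seqnames[1L]),
                 as.character(sub$strand[1L]), ex, cs, ce),
      error = function(e) stopf("GTF model error in transcript %s: %s", tx, conditionMessage(e)))
    if (!is.null(cytobands)) {
      mid <- (gene_start(g) + gene_end(g)) %/% 2L
      g$band <- tryCatch(band_at(cytobands, g$chrom, mid), error = function(e) NA_character_)
    }
    models[[tx]] <- g
  }
  new_gene_model_set(models)
}

new_gene_model_set <- function(models) {
  stopifnot(length(models) > 0L)
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  syms <- norm_symbol(vapply(models, `[[`, "", "gene_id"))
  by_symbol <- split(names(models), syms)
  ranges <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(models, gene_start, 0L),
                              end = vapply(models, gene_end, 0L)),
    transcript_id = names(models), symbol = syms)
  structure(list(models = models, by_symbol = by_symbol, ranges = ranges),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d transcript(s), %d gene symbol(s)\n",
              length(x$models), length(x$by_symbol)))
  invisible(x)
}

#' Retrieve gene models by symbol
#'
#' @param set a `gene_model_set`.
#' @param symbol gene symbol; matching is case-insensitive and ignores a
#'   trailing version suffix.
#' @return list of `gene_model` objects (possibly empty).
#' @export
models_by_symbol <- function(set, symbol) {
  ids <- set$by_symbol[[norm_symbol(symbol)]]
  if (is.null(ids)) return(list())
  set$models[ids]
}

#' Pick one representative model for a symbol
#'
#' The transcript with the longest CDS (longest exonic span among non-coding
#' ties) is chosen; deterministic for a fixed set.
#'
#' @inheritParams models_by_symbol
#' @return a `gene_model` or `NULL` when the symbol is unknown.
#' @export
model_for_symbol <- function(set, symbol) {
  ms <- models_by_symbol(set, symbol)
  if (length(ms) == 0L) return(NULL)
  score <- vapply(ms, function(g) cds_length(g) * 1e9 + (gene_end(g) - gene_start(g)), 0)
  ms[[order(-score, vapply(ms, `[[`, "", "transcript_id"))[1L]]]
}

#' Query gene models overlapping a genomic interval
#'
#' @param set a `gene_model_set`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @param type `"any"` (overlap) or `"within"` (model span wholly inside the
#'   query interval).
#' @return list of `gene_model` objects.
#' @export
models_overlapping <- function(set, chrom, start, end, type = c("any", "within")) {
  type <- match.arg(type)
  q <- GenomicRanges::GRanges(norm_chrom(chrom), IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(set$ranges, q, type = if (type == "within") "within" else "any")
  ids <- set$ranges$transcript_id[S4Vectors::queryHits(hits)]
  set$models[unique(ids)]
}
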
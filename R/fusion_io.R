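# Reading and writing fusion-candidate tables and final reports.
#
# Internal representation: a "fusion_set" is a data.table with one row per
# candidate junction. pos5 is the last retained base of the 5' partner and
# pos3 the first retained base of the 3' partner, both 1-based on the forward
# genomic strand regardless of gene strand. Filter decisions accumulate in
# the `flags` column (semicolon-separated labels) instead of dropping rows.

FUSION_COLS <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                 "chrom3", "pos3", "strand3", "split_reads", "spanning_reads",
                 "driver_score", "caller", "annotated5", "annotated3", "flags")

CHIMERASCAN_COLS <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                      "chrom3", "pos3", "strand3", "split_reads", "spanning_reads",
                      "driver_score")

DEFUSE_COLS <- c("cluster_id", "sample_id", "gene_name1", "gene_name2",
                 "chromosome1", "genomic_break_pos1", "genomic_strand1",
                 "chromosome2", "genomic_break_pos2", "genomic_strand2",
                 "splitr_count", "span_count", "probability")

#' The closed vocabulary of filter flags
#'
#' Core flags: `no_split_reads`, `unannotated_partner`, `healthy_panel`,
#' `unreliable_structure`. Cohort flags: `promiscuous_gene`, `readthrough`,
#' `cohort_recurrent`. `ds_conflict` marks a caller merge whose driver
#' scores disagreed by more than 0.05 (warning only; it never rejects).
#'
#' @return character vector of the recognized flag labels.
#' @export
filter_flags <- function() {
  c("no_split_reads", "unannotated_partner", "healthy_panel",
    "unreliable_structure", "promiscuous_gene", "readthrough",
    "cohort_recurrent", "ds_conflict")
}

# rejection-relevant flags (ds_conflict is informational)
rejecting_flags <- function() setdiff(filter_flags(), "ds_conflict")

new_fusion_set <- function(dt) {
  dt <- as.data.table(dt)
  for (col in setdiff(FUSION_COLS, names(dt))) {
    dt[[col]] <- switch(col,
      driver_score = NA_real_,
      annotated5 = NA, annotated3 = NA,
      flags = "",
      caller = "other",
      NA)
  }
  dt <- dt[, FUSION_COLS, with = FALSE]
  # unparseable numerics become NA here and explicit errors just below
  dt[, `:=`(sample_id = as.character(sample_id),
            gene5 = as.character(gene5), gene3 = as.character(gene3),
            chrom5 = norm_chrom(chrom5), chrom3 = norm_chrom(chrom3),
            pos5 = suppressWarnings(as.integer(pos5)),
            pos3 = suppressWarnings(as.integer(pos3)),
            strand5 = as.character(strand5), strand3 = as.character(strand3),
            split_reads = suppressWarnings(as.integer(split_reads)),
            spanning_reads = suppressWarnings(as.integer(spanning_reads)),
            driver_score = suppressWarnings(as.numeric(driver_score)),
            caller = as.character(caller),
            annotated5 = as.logical(annotated5), annotated3 = as.logical(annotated3),
            flags = ifelse(is.na(flags), "", as.character(flags)))]
  bad_pos <- which(is.na(dt$pos5) | is.na(dt$pos3) | dt$pos5 < 1L | dt$pos3 < 1L)
  if (length(bad_pos) > 0L) {
    stopf("fusion table value error: unparseable or non-positive breakpoint position in row(s) %s",
          paste(bad_pos, collapse = ", "))
  }
  bad_reads <- which(is.na(dt$split_reads) | is.na(dt$spanning_reads) |
                       dt$split_reads < 0L | dt$spanning_reads < 0L)
  if (length(bad_reads) > 0L) {
    stopf("fusion table value error: negative or unparseable read count in row(s) %s",
          paste(bad_reads, collapse = ", "))
  }
  bad_ds <- which(!is.na(dt$driver_score) & (dt$driver_score < 0 | dt$driver_score > 1))
  if (length(bad_ds) > 0L) {
    stopf("fusion table value error: driver_score outside [0,1] in row(s) %s",
          paste(bad_ds, collapse = ", "))
  }
  structure(dt, class = c("fusion_set", class(dt)))
}

#' Read a fusion-candidate table
#'
#' Two tab-separated dialects are supported, modeled on the outputs of common
#' fusion callers:
#' \describe{
#'   \item{chimerascan}{columns `sample_id, gene5, gene3, chrom5, pos5,
#'     strand5, chrom3, pos3, strand3, split_reads, spanning_reads,
#'     driver_score` (driver_score may be empty).}
#'   \item{defuse}{columns `cluster_id, sample_id, gene_name1, gene_name2,
#'     chromosome1, genomic_break_pos1, genomic_strand1, chromosome2,
#'     genomic_break_pos2, genomic_strand2, splitr_count, span_count,
#'     probability`. Rows reporting both orientations of one event are
#'     deduplicated by unordered partner pair and positions.}
#' }
#' Reading performs no filtering: zero split reads, missing driver scores and
#' unknown partners are all kept and dealt with downstream.
#'
#' @param path path to the TSV file.
#' @param dialect `"chimerascan"` or `"defuse"`.
#' @return a `fusion_set` (data.table, one row per candidate).
#' @export
read_fusion_table <- function(path, dialect = c("chimerascan", "defuse")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("fusion table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = c("", "NA"))
  want <- if (dialect == "chimerascan") CHIMERASCAN_COLS else DEFUSE_COLS
  missing <- setdiff(want, names(dt))
  if (length(missing) > 0L) {
    stopf("fusion table format error (%s dialect): missing column(s) %s",
          dialect, paste(missing, collapse = ", "))
  }
  if (dialect == "chimerascan") {
    out <- dt[, CHIMERASCAN_COLS, with = FALSE]
    out[, caller := "chimerascan"]
  } else {
    out <- dt[, .(sample_id, gene5 = gene_name1, gene3 = gene_name2,
                  chrom5 = chromosome1, pos5 = genomic_break_pos1, strand5 = genomic_strand1,
                  chrom3 = chromosome2, pos3 = genomic_break_pos2, strand3 = genomic_strand2,
                  split_reads = splitr_count, spanning_reads = span_count,
                  driver_score = probability)]
    out[, caller := "defuse"]
    key <- defuse_dedup_key(out)
    out <- out[!duplicated(key), ]
  }
  new_fusion_set(out)
}

# unordered partner pair + unordered positions identify a deFuse event
# reported in both orientations
defuse_dedup_key <- function(dt) {
  g <- mapply(function(a, b) paste(sort(c(norm_symbol(a), norm_symbol(b))), collapse = "|"),
              dt$gene5, dt$gene3)
  p <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"), dt$pos5, dt$pos3)
  paste(dt$sample_id, g, p)
}

#' Write a fusion set as a chimerascan-dialect TSV
#'
#' Canonical form used for round-tripping: rows ordered by sample, partner
#' pair, then positions.
#'
#' @param fusions a `fusion_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fusion_table <- function(fusions, path) {
  out <- as.data.table(fusions)[, CHIMERASCAN_COLS, with = FALSE]
  setorder(out, sample_id, gene5, gene3, pos5, pos3)
  fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a two-column sample/karyotype table
#'
#' @param path TSV with columns `sample_id`, `iscn_string` (clones joined
#'   with `/`).
#' @return named list of [parse_karyotype()] results, one per sample.
#' @export
read_karyotypes <- function(path) {
  if (!file.exists(path)) stopf("karyotype table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("sample_id", "iscn_string") %in% names(dt))) {
    stopf("karyotype table format error: need columns sample_id, iscn_string")
  }
  ks <- lapply(seq_len(nrow(dt)), function(i) parse_karyotype(dt$iscn_string[i], dt$sample_id[i]))
  names(ks) <- dt$sample_id
  ks
}

#' Read a healthy-panel fusion list
#'
#' @param path TSV with columns `geneA`, `geneB`; one unordered pair per row.
#' @return character vector of canonical pair keys (sorted, "|"-joined,
#'   normalized symbols).
#' @export
read_healthy_panel <- function(path) {
  if (!file.exists(path)) stopf("healthy panel not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("geneA", "geneB") %in% names(dt))) {
    stopf("healthy panel format error: need columns geneA, geneB")
  }
  unique(pair_key(dt$geneA, dt$geneB))
}

pair_key <- function(a, b) {
  mapply(function(x, y) paste(sort(c(norm_symbol(x), norm_symbol(y))), collapse = "|"), a, b,
         USE.NAMES = FALSE)
}

#' Read a one-symbol-per-line gene list (e.g. tumor suppressors)
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  norm_symbol(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read copy-number segments
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `copy_number`
#'   (1-based inclusive).
#' @return data.table of segments, sorted; malformed segments (start > end)
#'   are an error.
#' @export
read_cn_segments <- function(path) {
  if (!file.exists(path)) stopf("CN segment file not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "copy_number")
  if (!all(need %in% names(dt))) {
    stopf("CN segment format error: need columns %s", paste(need, collapse = ", "))
  }
  dt[, `:=`(chrom = norm_chrom(chrom), start = as.integer(start), end = as.integer(end),
            copy_number = as.numeric(copy_number))]
  if (any(dt$start > dt$end)) stopf("CN segment value error: start > end")
  setorder(dt, chrom, start)
  dt[]
}
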
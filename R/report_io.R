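# Final report serialization: a flat TSV (one row per candidate) plus a
# BEDPE companion of surviving (tier-assigned) fusions. Row order is
# canonical — sample_id, then gene5--gene3 lexicographic, then positions —
# so identical report lists always serialize to identical bytes.

REPORT_COLS <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                 "chrom3", "pos3", "strand3", "tier", "concordant_event",
                 "frame", "n_isoforms", "microhomology", "deletion_interval",
                 "driver_score", "split_reads", "spanning_reads", "flags", "reasons")

#' Flatten tier reports to a data.table
#'
#' @param reports list of `tier_report` objects.
#' @return a data.table with one row per report, canonically ordered.
#' @export
reports_to_table <- function(reports) {
  if (length(reports) == 0L) {
    proto <- data.table(sample_id = character(), gene5 = character(), gene3 = character(),
                        chrom5 = character(), pos5 = integer(), strand5 = character(),
                        chrom3 = character(), pos3 = integer(), strand3 = character(),
                        tier = character(), concordant_event = character(),
                        frame = character(), n_isoforms = integer(),
                        microhomology = integer(), deletion_interval = character(),
                        driver_score = numeric(), split_reads = integer(),
                        spanning_reads = integer(), flags = character(), reasons = character())
    return(proto)
  }
  rows <- lapply(reports, function(r) {
    f <- r$fusion
    del <- if (!is.null(r$deletion)) {
      sprintf("%s:%d-%d", r$deletion$chrom, r$deletion$start, r$deletion$end)
    } else ""
    data.table(sample_id = f$sample_id[1], gene5 = f$gene5[1], gene3 = f$gene3[1],
               chrom5 = f$chrom5[1], pos5 = f$pos5[1], strand5 = f$strand5[1],
               chrom3 = f$chrom3[1], pos3 = f$pos3[1], strand3 = f$strand3[1],
               tier = r$tier,
               concordant_event = if (isTRUE(r$concordance$matched)) r$concordance$event$raw else "",
               frame = r$frame$status %||% "undetermined",
               n_isoforms = length(r$isoforms %||% list()),
               microhomology = r$microhomology %||% NA_integer_,
               deletion_interval = del,
               driver_score = f$driver_score[1],
               split_reads = f$split_reads[1], spanning_reads = f$spanning_reads[1],
               flags = f$flags[1], reasons = paste(r$reasons, collapse = "|"))
  })
  out <- rbindlist(rows)
  setorder(out, sample_id, gene5, gene3, pos5, pos3)
  out[]
}

#' Write the triage report (TSV + BEDPE companion)
#'
#' @param reports list of `tier_report` objects (or an already flattened
#'   report table).
#' @param path output TSV path.
#' @param bedpe_path output path for the BEDPE of surviving fusions
#'   (default: `path` with extension replaced by `.bedpe`).
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, bedpe_path = NULL) {
  tab <- if (is.data.frame(reports)) as.data.table(reports) else reports_to_table(reports)
  if (nrow(tab) > 0L) setorder(tab, sample_id, gene5, gene3, pos5, pos3)
  fwrite(tab, path, sep = "\t", na = "", quote = FALSE)
  if (is.null(bedpe_path)) bedpe_path <- sub("\\.[^.]*$", ".bedpe", path)
  surv <- tab[tab$tier %in% c("tier1", "tier2", "tier3"), ]
  bed <- data.table(chrom1 = surv$chrom5, start1 = surv$pos5 - 1L, end1 = surv$pos5,
                    chrom2 = surv$chrom3, start2 = surv$pos3 - 1L, end2 = surv$pos3,
                    name = sprintf("%s|%s--%s", surv$sample_id, surv$gene5, surv$gene3),
                    score = surv$split_reads, strand1 = surv$strand5, strand2 = surv$strand3)
  header <- paste(c("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "name", "score", "strand1", "strand2"), collapse = "\t")
  writeLines(c(header, if (nrow(bed) > 0L) do.call(paste, c(bed, sep = "\t"))), bedpe_path)
  invisible(path)
}

#' Read a triage report written by [write_report()]
#'
#' @param path report TSV path.
#' @return the report data.table (canonical form).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stopf("report not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
              colClasses = list(character = c("sample_id", "gene5", "gene3", "chrom5",
                                              "chrom3", "strand5", "strand3", "tier",
                                              "concordant_event", "frame",
                                              "deletion_interval", "flags", "reasons")))
  dt[, `:=`(pos5 = as.integer(pos5), pos3 = as.integer(pos3),
            n_isoforms = as.integer(n_isoforms), microhomology = as.integer(microhomology),
            driver_score = as.numeric(driver_score),
            split_reads = as.integer(split_reads), spanning_reads = as.integer(spanning_reads))]
  for (cc in c("concordant_event", "deletion_interval", "flags", "reasons")) {
    dt[[cc]][is.na(dt[[cc]])] <- ""
  }
  setorder(dt, sample_id, gene5, gene3, pos5, pos3)
  dt[]
}
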
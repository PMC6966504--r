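# Tier assignment and cohort summary statistics.
#
# Tier precedence is 1 > 2 > 3:
#   tier 1 — the fusion is explained by a cytogenetically observed event;
#   tier 2 — cryptic but with driver score >= threshold;
#   tier 3 — out-of-frame, low/absent driver score, but a tumor suppressor
#            gene is involved (loss-of-function rescue).
# Any rejecting filter flag forces "rejected" regardless of evidence.

#' Assign a priority tier to one fusion candidate
#'
#' @param fusion a single-row `fusion_set` (filters applied).
#' @param concordance a `concordance_result` for this fusion and its
#'   sample's karyotype.
#' @param frame a `frame_result`.
#' @param tsg character vector of tumor-suppressor gene symbols.
#' @param cfg a [filter_config()] (supplies `ds_threshold`).
#' @return a `tier_report`: list with `fusion`, `tier` (`"tier1"`,
#'   `"tier2"`, `"tier3"` or `"rejected"`), `concordance`, `frame`, and
#'   `reasons` (ordered rule firings, machine-readable).
#' @export
assign_tier <- function(fusion, concordance, frame, tsg = character(),
                        cfg = filter_config()) {
  fl <- strsplit(fusion$flags[1] %||% "", ";", fixed = TRUE)[[1]]
  fl <- fl[nzchar(fl)]
  rejecting <- intersect(fl, rejecting_flags())
  reasons <- character()
  ds <- fusion$driver_score[1]
  tsg <- norm_symbol(tsg)
  in_tsg <- norm_symbol(fusion$gene5[1]) %in% tsg || norm_symbol(fusion$gene3[1]) %in% tsg

  if (length(rejecting) > 0L) {
    tier <- "rejected"
    reasons <- paste0("filter:", rejecting)
    # counterfactual logging: record tier evidence the candidate would have had
    if (isTRUE(concordance$matched)) reasons <- c(reasons, "counterfactual:concordant")
  } else if (isTRUE(concordance$matched)) {
    tier <- "tier1"
    reasons <- sprintf("tier1:concordant_with:%s", concordance$event$raw)
  } else if (!is.na(ds) && ds >= cfg$ds_threshold) {
    tier <- "tier2"
    reasons <- sprintf("tier2:driver_score:%.3f>=%.3f", ds, cfg$ds_threshold)
  } else if (identical(frame$status, "out_of_frame") && in_tsg &&
             (is.na(ds) || ds < cfg$ds_threshold)) {
    tier <- "tier3"
    reasons <- "tier3:out_of_frame_tsg_rescue"
  } else {
    tier <- "rejected"
    reasons <- c("no_tier:not_concordant",
                 if (is.na(ds)) "no_tier:driver_score_absent"
                 else sprintf("no_tier:driver_score:%.3f<%.3f", ds, cfg$ds_threshold),
                 if (!identical(frame$status, "out_of_frame")) sprintf("no_tier:frame:%s", frame$status),
                 if (!in_tsg) "no_tier:no_tsg_partner")
  }
  structure(list(fusion = fusion, tier = tier, concordance = concordance,
                 frame = frame, isoforms = NULL, deletion = NULL,
                 microhomology = NA_integer_, reasons = reasons),
            class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat(sprintf("<tier_report> %s: %s--%s -> %s [%s]\n",
              x$fusion$sample_id[1], x$fusion$gene5[1], x$fusion$gene3[1],
              x$tier, paste(x$reasons, collapse = "; ")))
  invisible(x)
}

#' Read a cohort characteristics / mutation-status table
#'
#' CSV with one row per patient. Recognized metadata columns: `case`,
#' `gender`, `age`, `who_class`; every other column is a mutation-status
#' field with values in `POS`, `NEG`, `VARIANT`, `NA`, except columns ending
#' in `_VAF` which carry a VAF class (`>0.5`, `<0.5`, `NA`).
#'
#' @param path CSV path.
#' @return a `cohort_table` data.table.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stopf("cohort table not found: %s", path)
  dt <- fread(path, header = TRUE, colClasses = "character", na.strings = c("", "NA"))
  if (!all(c("case", "age") %in% names(dt))) {
    stopf("cohort table format error: need at least columns case, age")
  }
  dt[, age := as.numeric(age)]
  status_cols <- setdiff(names(dt), c("case", "gender", "age", "who_class"))
  status_cols <- status_cols[!endsWith(status_cols, "_VAF")]
  for (cc in status_cols) {
    v <- toupper(dt[[cc]])
    v[v == "VARIANTE"] <- "VARIANT"  # as printed in some source tables
    bad <- !is.na(v) & !v %in% c("POS", "NEG", "VARIANT")
    if (any(bad)) stopf("cohort table value error: column %s has value(s) %s",
                        cc, paste(unique(dt[[cc]][bad]), collapse = ", "))
    dt[[cc]] <- v
  }
  structure(dt, class = c("cohort_table", class(dt)))
}

# columns belonging to one gene: exact name or name with a _SUFFIX
gene_status_columns <- function(tbl, gene) {
  cols <- setdiff(names(tbl), c("case", "gender", "age", "who_class"))
  cols <- cols[!endsWith(cols, "_VAF")]
  cols[norm_symbol(sub("_.*$", "", cols)) == norm_symbol(gene)]
}

#' Summarize a patient cohort table
#'
#' Computes the median age (lower median for even n), the per-gene altered
#' fraction (a patient is altered when any status field of that gene is
#' `POS`; patients with all fields `NA` for the gene are excluded from the
#' denominator), and the count of patients with an ITD alone (ITD positive,
#' TKD not positive) at variant allele frequency class `>0.5`.
#'
#' @param tbl a `cohort_table`.
#' @return list with `n`, `median_age`, `genes` (data.table: gene, altered,
#'   evaluable, fraction), `itd_alone_high_vaf`.
#' @export
cohort_summary <- function(tbl) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0L) stopf("value error: empty cohort table")
  ages <- sort(tbl$age[!is.na(tbl$age)])
  med <- ages[floor((length(ages) + 1) / 2)]  # lower median

  cols <- setdiff(names(tbl), c("case", "gender", "age", "who_class"))
  cols <- cols[!endsWith(cols, "_VAF")]
  genes <- unique(norm_symbol(sub("_.*$", "", cols)))
  gsum <- rbindlist(lapply(genes, function(g) {
    gc <- gene_status_columns(tbl, g)
    m <- as.matrix(tbl[, gc, with = FALSE])
    evaluable <- apply(m, 1L, function(r) !all(is.na(r)))
    altered <- apply(m, 1L, function(r) any(r == "POS", na.rm = TRUE))
    data.table(gene = g, altered = sum(altered & evaluable), evaluable = sum(evaluable),
               fraction = if (sum(evaluable) > 0L) sum(altered & evaluable) / sum(evaluable) else 0)
  }))

  itd <- 0L
  itd_col <- cols[endsWith(toupper(cols), "_ITD")]
  tkd_col <- cols[endsWith(toupper(cols), "_TKD")]
  vaf_col <- names(tbl)[endsWith(toupper(names(tbl)), "_ITD_VAF")]
  if (length(itd_col) == 1L) {
    itd_pos <- tbl[[itd_col]] == "POS"
    tkd_pos <- if (length(tkd_col) == 1L) tbl[[tkd_col]] == "POS" else rep(FALSE, nrow(tbl))
    hi_vaf <- if (length(vaf_col) == 1L) gsub(",", ".", tbl[[vaf_col]]) == ">0.5" else rep(NA, nrow(tbl))
    itd <- sum(itd_pos & !(tkd_pos %in% TRUE) & hi_vaf %in% TRUE, na.rm = TRUE)
  }
  list(n = nrow(tbl), median_age = med, genes = gsum, itd_alone_high_vaf = as.integer(itd))
}
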
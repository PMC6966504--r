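# The removal cascade. Decisions are recorded as flags on each candidate;
# rows are never deleted, because the tier-3 rescue needs low-driver-score
# fusions to survive until tiering. A candidate "passes" iff no rejecting
# flag is set (see filter_flags()).

#' Filter configuration
#'
#' @param min_split_reads minimum split-read support; candidates below it get
#'   flag `no_split_reads`. Default 1: a fusion must be supported by at least
#'   one read spanning the junction itself.
#' @param healthy_panel character vector of unordered gene-pair keys as
#'   produced by [read_healthy_panel()] (or `character()`).
#' @param promiscuous_static gene symbols flagged as promiscuously fused
#'   regardless of the cohort. Default `HBB, HBA, HBD, MPO, DLG2` —
#'   highly expressed blood genes that recurrently show up fused to many
#'   partners as library artifacts.
#' @param promiscuous_partner_threshold K: a gene with >= K distinct partners
#'   across the cohort is flagged promiscuous. Default 3.
#' @param readthrough_max_gap maximum inter-gene gap (bp) for the
#'   read-through (conjoined-gene) flag. Default 200000.
#' @param ds_threshold driver-score cutoff used at tiering (tier 2 requires
#'   DS >= threshold; tier-3 rescue requires DS < threshold). Default 0.7.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_split_reads = 1L,
                          healthy_panel = character(),
                          promiscuous_static = c("HBB", "HBA", "HBD", "MPO", "DLG2"),
                          promiscuous_partner_threshold = 3L,
                          readthrough_max_gap = 200000L,
                          ds_threshold = 0.7) {
  stopifnot(is_count(min_split_reads), is_count(promiscuous_partner_threshold),
            is_count(readthrough_max_gap),
            is.numeric(ds_threshold), ds_threshold >= 0, ds_threshold <= 1)
  structure(list(min_split_reads = as.integer(min_split_reads),
                 healthy_panel = as.character(healthy_panel),
                 promiscuous_static = norm_symbol(promiscuous_static),
                 promiscuous_partner_threshold = as.integer(promiscuous_partner_threshold),
                 readthrough_max_gap = as.integer(readthrough_max_gap),
                 ds_threshold = as.numeric(ds_threshold)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  min_split_reads:               %d\n", x$min_split_reads))
  cat(sprintf("  healthy_panel:                 %d pair(s)\n", length(x$healthy_panel)))
  cat(sprintf("  promiscuous_static:            %s\n", paste(x$promiscuous_static, collapse = ", ")))
  cat(sprintf("  promiscuous_partner_threshold: %d\n", x$promiscuous_partner_threshold))
  cat(sprintf("  readthrough_max_gap:           %d bp\n", x$readthrough_max_gap))
  cat(sprintf("  ds_threshold:                  %.3f\n", x$ds_threshold))
  invisible(x)
}

has_flag <- function(fusions, flag) {
  vapply(strsplit(fusions$flags, ";", fixed = TRUE), function(fl) flag %in% fl, TRUE)
}

add_flag <- function(flags, flag, where) {
  cur <- strsplit(flags, ";", fixed = TRUE)
  out <- vapply(seq_along(cur), function(i) {
    fl <- cur[[i]][nzchar(cur[[i]])]
    if (where[i] && !flag %in% fl) fl <- c(fl, flag)
    paste(fl, collapse = ";")
  }, "")
  out
}

#' Does a candidate pass all rejecting filters?
#'
#' @param fusions a `fusion_set` after [apply_core_filters()] and
#'   [apply_cohort_filters()].
#' @return logical vector, `TRUE` where no rejecting flag is set.
#' @export
passes_filters <- function(fusions) {
  keep <- rep(TRUE, nrow(fusions))
  for (fl in rejecting_flags()) keep <- keep & !has_flag(fusions, fl)
  keep
}

#' Merge per-caller candidate lists
#'
#' Candidates from different callers that describe the same unordered partner
#' pair in the same sample, with both breakpoints within 10 bp, are merged
#' into one record keeping the maximum read support and any present driver
#' score; the caller set is recorded as a comma-joined label. Driver scores
#' disagreeing by more than 0.05 add the warning flag `ds_conflict` and the
#' maximum is kept.
#'
#' @param ... one or more `fusion_set` objects (or a single list of them).
#' @param tol_bp breakpoint tolerance in bp (default 10).
#' @return a merged `fusion_set`.
#' @export
merge_callsets <- function(..., tol_bp = 10L) {
  ins <- list(...)
  if (length(ins) == 1L && !inherits(ins[[1]], "fusion_set")) ins <- ins[[1]]
  all <- rbindlist(lapply(ins, as.data.table), use.names = TRUE, fill = TRUE)
  if (nrow(all) == 0L) return(new_fusion_set(all))
  all[, grp := paste(sample_id, pair_key(gene5, gene3))]
  out <- list()
  for (g in unique(all$grp)) {
    sub <- all[all$grp == g, ]
    taken <- rep(FALSE, nrow(sub))
    for (i in seq_len(nrow(sub))) {
      if (taken[i]) next
      # same-orientation mates within tol_bp of row i
      mate <- !taken & sub$gene5 == sub$gene5[i] &
        abs(sub$pos5 - sub$pos5[i]) <= tol_bp & abs(sub$pos3 - sub$pos3[i]) <= tol_bp
      grp <- sub[mate, ]
      taken[mate] <- TRUE
      ds <- grp$driver_score[!is.na(grp$driver_score)]
      conflict <- length(ds) > 1L && (max(ds) - min(ds)) > 0.05
      rec <- grp[1L, ]
      rec$split_reads <- max(grp$split_reads)
      rec$spanning_reads <- max(grp$spanning_reads)
      rec$driver_score <- if (length(ds) > 0L) max(ds) else NA_real_
      rec$caller <- paste(sort(unique(unlist(strsplit(grp$caller, ",")))), collapse = ",")
      if (conflict) rec$flags <- add_flag(rec$flags, "ds_conflict", TRUE)
      out <- c(out, list(rec))
    }
  }
  merged <- rbindlist(out)
  merged[, grp := NULL]
  setorder(merged, sample_id, gene5, gene3, pos5, pos3)
  new_fusion_set(merged)
}

# orientation helpers ---------------------------------------------------

# TRUE when the fused transcript traverses the partner along its native
# 5'->3' direction (junction strand equals the gene strand)
orient_conserved <- function(junction_strand, gene_strand) {
  junction_strand == gene_strand
}

#' Apply the per-candidate (core) filters
#'
#' Adds flags from `no_split_reads`, `unannotated_partner`, `healthy_panel`,
#' `unreliable_structure` and resolves `annotated5`/`annotated3` against the
#' gene models. Structure reliability requires (a) both breakpoints inside
#' the genomic span of their named gene and (b) a transcribable 5'->3'
#' chimera: the 5' partner must be traversed in its native direction so that
#' it contributes its transcript prefix from its own promoter (an inverted 3'
#' partner is tolerated — it yields an antisense suffix, which the frame
#' annotation classifies as out-of-frame). Filters never raise on data.
#'
#' @param fusions a `fusion_set`.
#' @param models a `gene_model_set`.
#' @param cfg a [filter_config()].
#' @return the `fusion_set` with flags and annotation fields filled.
#' @export
apply_core_filters <- function(fusions, models, cfg = filter_config()) {
  dt <- copy(as.data.table(fusions))
  n <- nrow(dt)
  if (n == 0L) return(new_fusion_set(dt))
  g5 <- lapply(dt$gene5, function(s) model_for_symbol(models, s))
  g3 <- lapply(dt$gene3, function(s) model_for_symbol(models, s))
  dt$annotated5 <- !vapply(g5, is.null, TRUE)
  dt$annotated3 <- !vapply(g3, is.null, TRUE)

  dt$flags <- add_flag(dt$flags, "no_split_reads", dt$split_reads < cfg$min_split_reads)
  dt$flags <- add_flag(dt$flags, "unannotated_partner", !(dt$annotated5 & dt$annotated3))
  in_panel <- pair_key(dt$gene5, dt$gene3) %in% cfg$healthy_panel
  dt$flags <- add_flag(dt$flags, "healthy_panel", in_panel)

  unreliable <- vapply(seq_len(n), function(i) {
    m5 <- g5[[i]]; m3 <- g3[[i]]
    if (is.null(m5) || is.null(m3)) return(FALSE)  # already unannotated
    inside5 <- dt$chrom5[i] == m5$chrom && dt$pos5[i] >= gene_start(m5) && dt$pos5[i] <= gene_end(m5)
    inside3 <- dt$chrom3[i] == m3$chrom && dt$pos3[i] >= gene_start(m3) && dt$pos3[i] <= gene_end(m3)
    donor_fwd <- orient_conserved(dt$strand5[i], m5$strand)
    !(inside5 && inside3 && donor_fwd)
  }, TRUE)
  dt$flags <- add_flag(dt$flags, "unreliable_structure", unreliable)
  new_fusion_set(dt)
}

#' Apply the cohort-level filters
#'
#' Adds flags from `promiscuous_gene`, `readthrough`, `cohort_recurrent`:
#' \itemize{
#'   \item `promiscuous_gene`: either partner is in the static promiscuous
#'     list, or has at least K distinct partners across the whole cohort.
#'   \item `readthrough`: partners on the same chromosome and gene strand,
#'     the 5' partner upstream of the 3' partner in transcriptional
#'     direction, inter-gene gap at most `readthrough_max_gap` — the
#'     geometry of transcriptional read-through into the downstream
#'     neighbor.
#'   \item `cohort_recurrent`: the identical unordered partner pair appears
#'     in two or more samples (in a small heterogeneous cohort a genuinely
#'     recurrent rare fusion is implausible; recurrence signals an
#'     artifact).
#' }
#'
#' @inheritParams apply_core_filters
#' @param fusions the full-cohort `fusion_set` (all samples together).
#' @return the `fusion_set` with cohort flags added.
#' @export
apply_cohort_filters <- function(fusions, models, cfg = filter_config()) {
  dt <- copy(as.data.table(fusions))
  n <- nrow(dt)
  if (n == 0L) return(new_fusion_set(dt))
  s5 <- norm_symbol(dt$gene5); s3 <- norm_symbol(dt$gene3)

  # partner diversity across the cohort
  edges <- unique(data.table(a = c(s5, s3), b = c(s3, s5)))
  div <- edges[, .(n_partners = length(unique(b))), by = a]
  promiscuous_syms <- union(cfg$promiscuous_static,
                            div$a[div$n_partners >= cfg$promiscuous_partner_threshold])
  dt$flags <- add_flag(dt$flags, "promiscuous_gene",
                       s5 %in% promiscuous_syms | s3 %in% promiscuous_syms)

  rt <- vapply(seq_len(n), function(i) {
    m5 <- model_for_symbol(models, dt$gene5[i])
    m3 <- model_for_symbol(models, dt$gene3[i])
    if (is.null(m5) || is.null(m3)) return(FALSE)
    if (m5$chrom != m3$chrom || m5$strand != m3$strand) return(FALSE)
    if (m5$strand == "+") {
      gap <- gene_start(m3) - gene_end(m5) - 1L
    } else {
      gap <- gene_start(m5) - gene_end(m3) - 1L
    }
    gap >= 0L && gap <= cfg$readthrough_max_gap
  }, TRUE)
  dt$flags <- add_flag(dt$flags, "readthrough", rt)

  keys <- pair_key(dt$gene5, dt$gene3)
  n_samples <- vapply(keys, function(k) length(unique(dt$sample_id[keys == k])), 0L)
  dt$flags <- add_flag(dt$flags, "cohort_recurrent", n_samples >= 2L)
  new_fusion_set(dt)
}
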
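# End-to-end orchestration: read -> merge -> core filters -> cohort filters
# -> concordance -> consequence -> deletion inference -> tiering -> report.
# A run is a pure function of its inputs: identical inputs and config yield
# byte-identical reports.

#' Read and validate a run configuration
#'
#' The configuration is a JSON object (see the bundle `config.json` written
#' by [generate_cohort()] / [paper_fixture()] for a template) with relative
#' or absolute input paths: `fusion_tables` (list of `{path, dialect}`),
#' `gtf`, `cytoband`, `karyotypes`, `healthy_panel`, `tsg`, and optional
#' `cn_segments`, `genome`, `cohort_csv`; plus `tolerance` (band-match
#' tolerance, default 1), `max_skip` (isoform enumeration, default 2) and a
#' `filter` block passed to [filter_config()].
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @param base_dir directory against which relative paths are resolved
#'   (defaults to the config file's directory).
#' @return validated config list with absolute paths.
#' @export
read_run_config <- function(config, base_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    if (is.null(base_dir)) base_dir <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (is.null(base_dir)) base_dir <- getwd()
  stopifnot(is.list(config))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
    p
  }
  for (f in c("gtf", "cytoband", "karyotypes", "healthy_panel", "tsg",
              "cn_segments", "genome", "cohort_csv")) {
    config[[f]] <- resolve(config[[f]])
  }
  config$fusion_tables <- lapply(config$fusion_tables, function(ft) {
    ft$path <- resolve(ft$path); ft
  })
  required <- c("gtf", "cytoband", "karyotypes")
  for (f in required) {
    if (is.null(config[[f]])) stopf("config error: missing required input '%s'", f)
  }
  if (length(config$fusion_tables) == 0L) stopf("config error: no fusion_tables declared")
  for (ft in config$fusion_tables) {
    if (!ft$dialect %in% c("chimerascan", "defuse")) {
      stopf("config error: unknown fusion table dialect '%s'", ft$dialect)
    }
    if (!file.exists(ft$path)) stopf("config error: fusion table not found: %s", ft$path)
  }
  for (f in c("gtf", "cytoband", "karyotypes", "healthy_panel", "tsg",
              "cn_segments", "genome", "cohort_csv")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stopf("config error: input '%s' not found: %s", f, config[[f]])
    }
  }
  config$tolerance <- as.integer(config$tolerance %||% 1L)
  config$max_skip <- as.integer(config$max_skip %||% 2L)
  config
}

pipeline_filter_config <- function(config, healthy_panel) {
  fc <- config$filter %||% list()
  filter_config(
    min_split_reads = fc$min_split_reads %||% 1L,
    healthy_panel = healthy_panel,
    promiscuous_static = unlist(fc$promiscuous_static) %||% c("HBB", "HBA", "HBD", "MPO", "DLG2"),
    promiscuous_partner_threshold = fc$promiscuous_partner_threshold %||% 3L,
    readthrough_max_gap = fc$readthrough_max_gap %||% 200000L,
    ds_threshold = fc$ds_threshold %||% 0.7)
}

# junction-proximal genomic contexts for microhomology, strand-aware
fusion_mh_contexts <- function(seqs, fusion, k = 20L) {
  nm <- norm_chrom(names(seqs))
  get <- function(chrom, a, b, rc) {
    i <- match(norm_chrom(chrom), nm)
    if (is.na(i)) return(NULL)
    if (a < 1L || b > Biostrings::width(seqs)[i]) return(NULL)
    s <- as.character(Biostrings::subseq(seqs[[i]], a, b))
    if (rc) revcomp(s) else s
  }
  donor <- if (fusion$strand5[1] == "+") get(fusion$chrom5[1], fusion$pos5[1] - k + 1L, fusion$pos5[1], FALSE)
           else get(fusion$chrom5[1], fusion$pos5[1], fusion$pos5[1] + k - 1L, TRUE)
  acc <- if (fusion$strand3[1] == "+") get(fusion$chrom3[1], fusion$pos3[1] - k, fusion$pos3[1] - 1L, FALSE)
         else get(fusion$chrom3[1], fusion$pos3[1] + 1L, fusion$pos3[1] + k, TRUE)
  if (is.null(donor) || is.null(acc)) return(NULL)
  list(donor_up = donor, acceptor_up = acc)
}

#' Run the full triage pipeline
#'
#' Executes all stages on the configured inputs and writes `report.tsv`,
#' `report.bedpe` and `manifest.json` into `out_dir`. Candidates are never
#' dropped: every input junction appears in the report with its tier (or
#' `rejected`) and the complete flag/reason trail.
#'
#' @param config a config list or path to a JSON config (see
#'   [read_run_config()]).
#' @param out_dir output directory (default: `out` next to the inputs).
#' @param dry_run validate inputs and config, write nothing.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `table` (the report data.table),
#'   `reports` (per-fusion `tier_report`s), `summary` (cohort summary or
#'   `NULL`) and `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL, dry_run = FALSE, quiet = FALSE) {
  cfgp <- if (is.character(config)) config else NULL
  config <- read_run_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- "read"
  result <- tryCatch({
    say("[read] loading inputs")
    models <- read_gene_models(config$gtf)
    bmap <- read_cytobands(config$cytoband)
    karyos <- read_karyotypes(config$karyotypes)
    panel <- if (!is.null(config$healthy_panel)) read_healthy_panel(config$healthy_panel) else character()
    tsg <- if (!is.null(config$tsg)) read_gene_list(config$tsg) else character()
    segs <- if (!is.null(config$cn_segments)) read_cn_segments(config$cn_segments) else NULL
    genome <- if (!is.null(config$genome)) Biostrings::readDNAStringSet(config$genome) else NULL
    cohort <- if (!is.null(config$cohort_csv)) read_cohort_table(config$cohort_csv) else NULL
    callsets <- lapply(config$fusion_tables, function(ft) read_fusion_table(ft$path, ft$dialect))
    fcfg <- pipeline_filter_config(config, panel)
    if (dry_run) {
      say("[dry-run] inputs valid; nothing written")
      stop_early <- TRUE
    } else stop_early <- FALSE
    if (stop_early) {
      list(table = NULL, reports = NULL, summary = NULL, paths = NULL)
    } else {

    stage <- "merge"
    say("[merge] %d callset(s)", length(callsets))
    fused <- merge_callsets(callsets)

    stage <- "filters"
    fused <- apply_core_filters(fused, models, fcfg)
    fused <- apply_cohort_filters(fused, models, fcfg)
    say("[filters] %d/%d candidate(s) pass", sum(passes_filters(fused)), nrow(fused))

    stage <- "annotate"
    reports <- vector("list", nrow(fused))
    for (i in seq_len(nrow(fused))) {
      row <- fused[i]
      k <- karyos[[row$sample_id]]
      cr <- if (is.null(k)) new_concordance(FALSE)
            else match_fusion_to_karyotype(row, k, bmap, config$tolerance)
      g5 <- model_for_symbol(models, row$gene5)
      g3 <- model_for_symbol(models, row$gene3)
      annotatable <- !is.null(g5) && !is.null(g3) &&
        !has_flag(row, "unreliable_structure") && !has_flag(row, "unannotated_partner")
      fr <- if (annotatable) determine_frame(row, g5, g3) else new_frame_result("undetermined")
      rep <- assign_tier(row, cr, fr, tsg, fcfg)
      if (annotatable) {
        rep$isoforms <- enumerate_isoforms(row, g5, g3, config$max_skip)
        del <- infer_interstitial_deletion(row, models)
        if (inherits(del, "deletion_call")) {
          if (!is.null(segs)) del$cn_support <- intersect_with_cn_segments(del, segs)
          rep$deletion <- del
        }
        if (!is.null(genome)) {
          ctx <- fusion_mh_contexts(genome, row)
          if (!is.null(ctx)) {
            rep$microhomology <- as.integer(microhomology_length(ctx$donor_up, ctx$acceptor_up))
          }
        }
      }
      reports[[i]] <- rep
    }

    stage <- "report"
    if (is.null(out_dir)) {
      base <- if (!is.null(cfgp)) dirname(normalizePath(cfgp)) else getwd()
      out_dir <- file.path(base, "out")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report_path <- file.path(out_dir, "report.tsv")
    bedpe_path <- file.path(out_dir, "report.bedpe")
    write_report(reports, report_path, bedpe_path)
    summ <- if (!is.null(cohort)) cohort_summary(cohort) else NULL
    manifest <- list(
      package = "fusiontriage",
      version = as.character(utils::packageVersion("fusiontriage")),
      config = config,
      input_md5 = as.list(tools::md5sum(unlist(c(
        vapply(config$fusion_tables, `[[`, "", "path"),
        config$gtf, config$cytoband, config$karyotypes,
        config$healthy_panel, config$tsg, config$cn_segments,
        config$genome, config$cohort_csv)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("[done] report written to %s", report_path)
    list(table = read_report(report_path), reports = reports,
         summary = summ,
         paths = list(report = report_path, bedpe = bedpe_path,
                      manifest = file.path(out_dir, "manifest.json")))
    }
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}

#' Command-line interface
#'
#' Subcommands: `run --config <json> [--out <dir>] [--dry-run]`,
#' `simulate --seed <int> --out <dir> [--samples <n>]`, `show-config`,
#' `validate --config <json>`.
#'
#' @param args character vector of CLI arguments (default: the process's
#'   trailing command-line arguments).
#' @return exit status (0 on success), invisibly.
#' @export
fusion_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fusiontriage <command> [options]",
    "  run         --config <json> [--out <dir>] [--dry-run]",
    "  simulate    --seed <int> --out <dir> [--samples <n>]",
    "  show-config",
    "  validate    --config <json>", sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    if (i[1] == length(args)) stopf("missing value for %s", flag)
    args[i[1] + 1L]
  }
  status <- tryCatch({
    if (length(args) == 0L) { cat(usage, "\n"); return(invisible(1L)) }
    cmd <- args[1L]
    switch(cmd,
      "run" = {
        run_pipeline(opt("--config") %||% stopf("run: --config required"),
                     out_dir = opt("--out"), dry_run = "--dry-run" %in% args)
        0L
      },
      "simulate" = {
        generate_cohort(as.integer(opt("--seed", "1")),
                        n_samples = as.integer(opt("--samples", "4")),
                        out_dir = opt("--out") %||% stopf("simulate: --out required"))
        0L
      },
      "show-config" = { print(filter_config()); 0L },
      "validate" = {
        read_run_config(opt("--config") %||% stopf("validate: --config required"))
        message("config valid")
        0L
      },
      { cat(usage, "\n"); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
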
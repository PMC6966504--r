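# Synthetic cohorts with planted ground truth.
#
# The generator emits a fully self-contained bundle (mini genome, gene
# models, cytobands, karyotypes, caller tables, panels, CN segments, cohort
# CSV) in which every pipeline branch is exercised by construction: one
# fusion per artifact class and planted tier-1/2/3 events whose frame,
# microhomology and implied deletion are known exactly. Planted truth is
# derived by independent base-level enumeration over the generated gene
# structures, not by calling the annotation code under test.

SYNTH_CATEGORIES <- c("tier1", "tier2", "tier3", "readthrough_artifact",
                      "promiscuous_artifact", "healthy_panel",
                      "no_split_support", "unreliable", "cohort_recurrent")

# --- synthetic gene helpers -------------------------------------------

synth_gene <- function(name, chrom, start, strand, n_exons = 4L,
                       exon_len = 120L, intron_len = 480L, utr = 30L) {
  starts <- start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  ex <- data.table(start = as.integer(starts), end = as.integer(starts + exon_len - 1L))
  list(name = name, chrom = chrom, strand = strand, exons = ex,
       cds_start = as.integer(min(ex$start) + utr),
       cds_end = as.integer(max(ex$end) - utr))
}

# genomic positions of the transcript in transcription order
synth_tx_positions <- function(g) {
  per <- lapply(seq_len(nrow(g$exons)), function(i) g$exons$start[i]:g$exons$end[i])
  pos <- unlist(per)
  if (g$strand == "-") pos <- rev(pos)
  pos
}

# coding bases at-or-before (inclusive=TRUE) / strictly-before a junction,
# by explicit enumeration — the ground-truth counter for planted frames
synth_coding_upstream <- function(g, pos, inclusive) {
  tx <- synth_tx_positions(g)
  idx <- match(pos, tx)
  stopifnot(!is.na(idx))
  upto <- if (inclusive) idx else idx - 1L
  if (upto < 1L) return(0L)
  sum(tx[seq_len(upto)] >= g$cds_start & tx[seq_len(upto)] <= g$cds_end)
}

# transcription-order index helpers for junction placement
synth_pos_at_tx_index <- function(g, idx) synth_tx_positions(g)[idx]

# choose a donor breakpoint near the end of exon 2 so that the junction has
# the requested frame relative to the acceptor's s3
synth_pick_donor_pos <- function(g5, s3, want_in_frame, exon_len = 120L) {
  base_idx <- 2L * exon_len  # transcription end of exon 2
  for (shift in 0:2) {
    pos <- synth_pos_at_tx_index(g5, base_idx - shift)
    c5 <- synth_coding_upstream(g5, pos, inclusive = TRUE)
    ok <- (c5 %% 3L) == (s3 %% 3L)
    if (ok == want_in_frame) return(list(pos = pos, c5 = c5))
  }
  stop("internal: could not plant requested frame")
}

synth_write_gtf <- function(genes, path) {
  lines <- character()
  for (g in genes) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                     g$name, g$name, g$name)
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, as.integer(g$exons$start[i]),
                                as.integer(g$exons$end[i]), g$strand, attrs))
      cs <- max(g$exons$start[i], g$cds_start); ce <- min(g$exons$end[i], g$cds_end)
      if (!is.na(g$cds_start) && cs <= ce) {
        lines <- c(lines, sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  g$chrom, as.integer(cs), as.integer(ce), g$strand, attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# strand-aware junction contexts on the forward-genome sequence set
genome_context <- function(seqs, chrom, pos, k, side = c("donor_up", "acceptor_up"),
                           strand) {
  side <- match.arg(side)
  s <- seqs[[chrom]]
  sub <- function(a, b) substr(s, a, b)
  if (side == "donor_up") {
    if (strand == "+") sub(pos - k + 1L, pos) else revcomp(sub(pos, pos + k - 1L))
  } else {
    if (strand == "+") sub(pos - k, pos - 1L) else revcomp(sub(pos + 1L, pos + k))
  }
}

# overwrite the k+1 acceptor bases immediately 5' of the junction so the
# microhomology with the donor context is exactly m
plant_microhomology <- function(seqs, donor, pos5, acceptor, pos3, m, max_k = 20L) {
  du <- strsplit(genome_context(seqs, donor$chrom, pos5, m + 1L, "donor_up", donor$strand), "")[[1]]
  mism <- setdiff(c("A", "C", "G", "T"), du[1])[1]
  target <- paste0(mism, paste(du[-1], collapse = ""))  # length m+1, mismatch first
  s <- seqs[[acceptor$chrom]]
  if (acceptor$strand == "+") {
    substr(s, pos3 - m - 1L, pos3 - 1L) <- target
  } else {
    substr(s, pos3 + 1L, pos3 + m + 1L) <- revcomp(target)
  }
  seqs[[acceptor$chrom]] <- s
  seqs
}

# --- the generator ----------------------------------------------------

#' Generate a synthetic fusion cohort with planted ground truth
#'
#' Writes a self-contained bundle into `out_dir`:
#' `genome.fa`, `genes.gtf`, `cytobands.txt` (UCSC dialect, 0-based — the
#' conversion path is exercised deliberately), `karyotypes.tsv`,
#' `chimerascan.tsv` / `defuse.tsv`, `healthy_panel.tsv`, `tsg.txt`,
#' `cn_segments.tsv`, `cohort.csv`, `config.json` and `truth.json`.
#'
#' Planted events (one per category unless noted): a karyotype-concordant
#' interchromosomal fusion (tier 1, reported by both callers including a
#' swapped-orientation deFuse duplicate), a cryptic high-driver-score fusion
#' (tier 2) plus one fusion at exactly the driver-score threshold (pins the
#' `>=` comparison), an out-of-frame tumor-suppressor fusion whose partners
#' flank an NF1-like gene (tier 3, with the implied interstitial deletion
#' and a supporting CN loss segment), a read-through pair, a promiscuous
#' (static-list) fusion, a healthy-panel pair, a zero-split-read candidate,
#' a candidate with a breakpoint outside its gene, and a pair recurring in
#' two samples. Junction sequences are engineered to the intended
#' microhomology lengths. Deterministic for a fixed seed.
#'
#' Because contigs are small (160 kb), the emitted filter config scales the
#' read-through gap down to 20 kb; the tier-3 flanking-gene gap (~88 kb) is
#' far above it, as the 1 Mb real-genome case is above the 200 kb default.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_samples number of samples (>= 2; default 4).
#' @param out_dir output directory (created if needed).
#' @param params optional overrides: `mh_tier1`, `mh_tier2`, `mh_straddle`
#'   (planted microhomology lengths), `contig_len`.
#' @return invisibly, a list with `dir`, `truth` (data.table) and `config`.
#' @export
generate_cohort <- function(seed, n_samples = 4L, out_dir = tempfile("cohort"),
                            params = list()) {
  if (!is_count(n_samples) || n_samples < 2L) {
    stopf("config error: n_samples must be >= 2 (cohort recurrence needs two samples)")
  }
  p <- modifyList(list(mh_tier1 = 3L, mh_tier2 = 1L, mh_straddle = 2L,
                       contig_len = 160000L), params)
  if (p$contig_len < 120000L) stopf("config error: contig_len too small for planted layout")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- sprintf("S%d", seq_len(n_samples))
  contigs <- paste0("chr", 1:4)
  L <- as.integer(p$contig_len)

  # genome
  seqs <- setNames(lapply(contigs, function(cc) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }), contigs)

  # cytobands: 6 bands per contig, written 0-based UCSC later
  band_tab <- rbindlist(lapply(contigs, function(cc) {
    bounds <- as.integer(round(seq(0L, L, length.out = 7L)))
    data.table(chrom = cc, band = c("p12", "p11", "q11", "q21", "q22", "q23"),
               start = bounds[-7] + 1L, end = bounds[-1])
  }))
  bmap <- new_cytoband_map(band_tab)

  # gene layout: 10 slots per contig on chr1-3, manual layout on chr4
  slot <- function(i) as.integer(4000L + (i - 1L) * 8000L)
  genes <- list()
  addg <- function(name, chrom, start, strand, ...) {
    genes[[name]] <<- synth_gene(name, chrom, start, strand, ...)
  }
  addg("T1A", "chr1", slot(2), "+"); addg("RC1", "chr1", slot(3), "+")
  addg("T2A", "chr1", slot(5), "+"); addg("PX1", "chr1", slot(8), "+")
  addg("UN2", "chr1", slot(9), "+")
  addg("T1B", "chr2", slot(2), "+"); addg("RT1", "chr2", slot(4), "+")
  addg("RT2", "chr2", slot(5), "+"); addg("T2C", "chr2", slot(7), "+")
  addg("T2B", "chr3", slot(2), "+"); addg("MPO", "chr3", slot(5), "+")
  addg("RC2", "chr3", slot(6), "+"); addg("HP1", "chr3", slot(7), "+")
  addg("NS1", "chr3", slot(8), "+"); addg("UN1", "chr3", slot(9), "+")
  # deletion trio on chr4 (minus strand, donor downstream in genome)
  addg("DELACC", "chr4", 10000L, "-"); addg("NF1L", "chr4", 60000L, "-")
  addg("DELDON", "chr4", 100000L, "-")
  addg("T2D", "chr4", 130000L, "+"); addg("HP2", "chr4", 140000L, "+")
  addg("NS2", "chr4", 150000L, "+")
  # filler genes so the interval index has something to chew on
  fill_strands <- sample(c("+", "-"), 12L, replace = TRUE)
  k <- 0L
  for (cc in c("chr1", "chr2", "chr3")) {
    for (i in c(1L, 6L, 7L, 10L)) {
      k <- k + 1L
      addg(sprintf("FILL%02d", k), cc, slot(i), fill_strands[k])
    }
  }

  # --- plant fusions --------------------------------------------------
  mk_junction <- function(donor, acceptor, want_in_frame) {
    # acceptor junction at the transcription start of its exon 2
    pos3 <- synth_pos_at_tx_index(genes[[acceptor]], 120L + 1L)
    s3 <- synth_coding_upstream(genes[[acceptor]], pos3, inclusive = FALSE)
    d <- synth_pick_donor_pos(genes[[donor]], s3, want_in_frame)
    list(pos5 = d$pos, pos3 = pos3, c5 = d$c5, s3 = s3,
         frame = if ((d$c5 %% 3L) == (s3 %% 3L)) "in_frame" else "out_of_frame")
  }
  srd <- function() as.integer(sample(3:40, 1L))

  plan <- list(
    list(sample = samples[1], g5 = "T1A", g3 = "T1B", cat = "tier1",
         ds = NA_real_, mh = p$mh_tier1, in_frame = TRUE, both_callers = TRUE),
    list(sample = samples[2], g5 = "T2A", g3 = "T2B", cat = "tier2",
         ds = round(runif(1, 0.75, 0.98), 3), mh = p$mh_tier2, in_frame = FALSE,
         both_callers = TRUE),
    list(sample = samples[2], g5 = "T2C", g3 = "T2D", cat = "tier2",
         ds = 0.7, mh = p$mh_straddle, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[3], g5 = "DELDON", g3 = "DELACC", cat = "tier3",
         ds = round(runif(1, 0.1, 0.6), 3), mh = 0L, in_frame = FALSE,
         both_callers = FALSE),
    list(sample = samples[1], g5 = "RT1", g3 = "RT2", cat = "readthrough_artifact",
         ds = round(runif(1, 0.05, 0.3), 3), mh = NA, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[2], g5 = "MPO", g3 = "PX1", cat = "promiscuous_artifact",
         ds = round(runif(1, 0.05, 0.3), 3), mh = NA, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[min(4L, n_samples)], g5 = "HP1", g3 = "HP2", cat = "healthy_panel",
         ds = NA_real_, mh = NA, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[min(4L, n_samples)], g5 = "NS1", g3 = "NS2", cat = "no_split_support",
         ds = NA_real_, mh = NA, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[3], g5 = "UN1", g3 = "UN2", cat = "unreliable",
         ds = NA_real_, mh = NA, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[1], g5 = "RC1", g3 = "RC2", cat = "cohort_recurrent",
         ds = NA_real_, mh = NA, in_frame = TRUE, both_callers = FALSE),
    list(sample = samples[2], g5 = "RC1", g3 = "RC2", cat = "cohort_recurrent",
         ds = NA_real_, mh = NA, in_frame = TRUE, both_callers = FALSE)
  )

  rows <- list(); truth <- list()
  rc_junction <- NULL
  for (pl in plan) {
    gd <- genes[[pl$g5]]; ga <- genes[[pl$g3]]
    if (pl$cat == "cohort_recurrent" && !is.null(rc_junction)) {
      j <- rc_junction
    } else {
      j <- mk_junction(pl$g5, pl$g3, pl$in_frame)
      if (pl$cat == "cohort_recurrent") rc_junction <- j
    }
    pos5 <- j$pos5; frame <- j$frame
    if (pl$cat == "unreliable") {
      pos5 <- gene_end_synth(gd) + 5000L
      frame <- NA_character_
    }
    if (!is.na(pl$mh)) {
      seqs <- plant_microhomology(seqs, gd, pos5, ga, j$pos3, as.integer(pl$mh))
    }
    deletion <- NULL
    if (pl$cat == "tier3") {
      # minus-strand flanking pair: lost interval between retained segments
      deletion <- list(chrom = norm_chrom(gd$chrom), start = j$pos3 + 1L, end = pos5 - 1L)
    }
    rows[[length(rows) + 1L]] <- data.table(
      sample_id = pl$sample, gene5 = pl$g5, gene3 = pl$g3,
      chrom5 = gd$chrom, pos5 = pos5, strand5 = gd$strand,
      chrom3 = ga$chrom, pos3 = j$pos3, strand3 = ga$strand,
      split_reads = if (pl$cat == "no_split_support") 0L else srd(),
      spanning_reads = as.integer(sample(2:20, 1L)),
      driver_score = pl$ds, both_callers = isTRUE(pl$both_callers))
    truth[[length(truth) + 1L]] <- list(
      id = sprintf("%s|%s--%s", pl$sample, pl$g5, pl$g3),
      sample_id = pl$sample, gene5 = pl$g5, gene3 = pl$g3,
      category = pl$cat,
      expected_tier = if (pl$cat %in% c("tier1", "tier2", "tier3")) pl$cat else "rejected",
      frame = frame, microhomology = if (is.na(pl$mh)) NULL else as.integer(pl$mh),
      deletion = deletion, driver_score = if (is.na(pl$ds)) NULL else pl$ds)
  }
  tab <- rbindlist(rows)

  # --- write bundle ---------------------------------------------------
  fa <- Biostrings::DNAStringSet(unlist(seqs))
  names(fa) <- names(seqs)
  Biostrings::writeXStringSet(fa, file.path(out_dir, "genome.fa"), width = 80L)
  synth_write_gtf(genes, file.path(out_dir, "genes.gtf"))
  write_cytobands(bmap, file.path(out_dir, "cytobands.txt"))

  # karyotypes: tier-1 sample carries the matching translocation
  t1 <- tab[1L]
  b5 <- band_at(bmap, t1$chrom5, t1$pos5); b3 <- band_at(bmap, t1$chrom3, t1$pos3)
  kar <- data.table(sample_id = samples,
                    iscn_string = ifelse(samples == t1$sample_id,
                      sprintf("46,XX,t(%s;%s)(%s;%s)[18]/46,XX[2]",
                              norm_chrom(t1$chrom5), norm_chrom(t1$chrom3), b5, b3),
                      "46,XY[20]"))
  fwrite(kar, file.path(out_dir, "karyotypes.tsv"), sep = "\t")

  # caller tables: everything in the chimerascan dialect; tier-1/2 also in
  # defuse, the tier-1 event additionally as a swapped-orientation duplicate
  cs <- tab[, .(sample_id, gene5, gene3, chrom5, pos5, strand5,
                chrom3, pos3, strand3, split_reads, spanning_reads, driver_score)]
  fwrite(cs, file.path(out_dir, "chimerascan.tsv"), sep = "\t", na = "", quote = FALSE)
  df_rows <- tab[tab$both_callers == TRUE, ]
  df <- data.table(cluster_id = sprintf("c%d", seq_len(nrow(df_rows))),
                   sample_id = df_rows$sample_id,
                   gene_name1 = df_rows$gene5, gene_name2 = df_rows$gene3,
                   chromosome1 = df_rows$chrom5, genomic_break_pos1 = df_rows$pos5,
                   genomic_strand1 = df_rows$strand5,
                   chromosome2 = df_rows$chrom3, genomic_break_pos2 = df_rows$pos3,
                   genomic_strand2 = df_rows$strand3,
                   splitr_count = df_rows$split_reads, span_count = df_rows$spanning_reads,
                   probability = df_rows$driver_score)
  swap <- copy(df[1L])
  swap[, `:=`(cluster_id = "c0r",
              gene_name1 = df$gene_name2[1L], gene_name2 = df$gene_name1[1L],
              chromosome1 = df$chromosome2[1L], genomic_break_pos1 = df$genomic_break_pos2[1L],
              genomic_strand1 = df$genomic_strand2[1L],
              chromosome2 = df$chromosome1[1L], genomic_break_pos2 = df$genomic_break_pos1[1L],
              genomic_strand2 = df$genomic_strand1[1L])]
  fwrite(rbind(df, swap), file.path(out_dir, "defuse.tsv"), sep = "\t", na = "", quote = FALSE)

  fwrite(data.table(geneA = c("HP1", "FILL01"), geneB = c("HP2", "FILL02")),
         file.path(out_dir, "healthy_panel.tsv"), sep = "\t")
  writeLines(c("DELACC", "NF1L"), file.path(out_dir, "tsg.txt"))

  del <- truth[[which(vapply(truth, function(x) x$category, "") == "tier3")[1]]]$deletion
  cn <- data.table(chrom = c("chr4", "chr1"),
                   start = c(max(1L, del$start - 500L), 1L),
                   end = c(min(L, del$end + 500L), L),
                   copy_number = c(1, 2))
  fwrite(cn, file.path(out_dir, "cn_segments.tsv"), sep = "\t")

  cohort <- data.table(case = samples,
                       gender = sample(c("male", "female"), n_samples, replace = TRUE),
                       age = as.integer(sample(30:80, n_samples, replace = TRUE)),
                       who_class = "AML NOS",
                       FLT3_TKD = sample(c("POS", "NEG"), n_samples, replace = TRUE),
                       FLT3_ITD = sample(c("POS", "NEG"), n_samples, replace = TRUE),
                       FLT3_ITD_VAF = sample(c(">0.5", "<0.5", NA), n_samples, replace = TRUE),
                       TET2 = sample(c("POS", "NEG", "VARIANT", NA), n_samples, replace = TRUE))
  fwrite(cohort, file.path(out_dir, "cohort.csv"), na = "NA")

  config <- list(
    fusion_tables = list(
      list(path = "chimerascan.tsv", dialect = "chimerascan"),
      list(path = "defuse.tsv", dialect = "defuse")),
    gtf = "genes.gtf", cytoband = "cytobands.txt", karyotypes = "karyotypes.tsv",
    healthy_panel = "healthy_panel.tsv", tsg = "tsg.txt",
    cn_segments = "cn_segments.tsv", genome = "genome.fa", cohort_csv = "cohort.csv",
    tolerance = 1L, max_skip = 2L,
    filter = list(min_split_reads = 1L, promiscuous_partner_threshold = 3L,
                  readthrough_max_gap = 20000L, ds_threshold = 0.7))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  truth_dt <- rbindlist(lapply(truth, function(x) {
    data.table(id = x$id, sample_id = x$sample_id, gene5 = x$gene5, gene3 = x$gene3,
               category = x$category, expected_tier = x$expected_tier,
               frame = x$frame %||% NA_character_,
               microhomology = x$microhomology %||% NA_integer_,
               del_start = if (is.null(x$deletion)) NA_integer_ else x$deletion$start,
               del_end = if (is.null(x$deletion)) NA_integer_ else x$deletion$end)
  }))
  invisible(list(dir = out_dir, truth = truth_dt, config = config))
}

gene_end_synth <- function(g) max(g$exons$end)
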
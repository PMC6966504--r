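# Shared builders and independent oracles. Everything is constructed in
# code; no stored fixtures.

# one-row candidate table
mk_fusion <- function(sample_id = "S1", gene5 = "GA", gene3 = "GB",
                      chrom5 = "chr1", pos5 = 1000L, strand5 = "+",
                      chrom3 = "chr2", pos3 = 2000L, strand3 = "+",
                      split_reads = 10L, spanning_reads = 5L,
                      driver_score = NA_real_, caller = "chimerascan",
                      flags = "") {
  fusiontriage:::new_fusion_set(data.table::data.table(
    sample_id = sample_id, gene5 = gene5, gene3 = gene3,
    chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
    chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
    split_reads = split_reads, spanning_reads = spanning_reads,
    driver_score = driver_score, caller = caller,
    annotated5 = NA, annotated3 = NA, flags = flags))
}

# a simple single-exon coding gene: whole exon is CDS
mk_cds_gene <- function(name, chrom, start, len, strand = "+") {
  gene_model(name, paste0(name, ".t1"), chrom, strand,
             data.frame(start = start, end = start + len - 1L),
             cds_start = start, cds_end = start + len - 1L)
}

mk_model_set <- function(...) fusiontriage:::new_gene_model_set(list(...))

mk_band_map <- function(chrom = "chr1", labels = c("p11", "q11", "q21", "q22"),
                        bounds = c(0L, 100L, 200L, 300L, 400L)) {
  fusiontriage:::new_cytoband_map(data.table::data.table(
    chrom = chrom, band = labels,
    start = head(bounds, -1) + 1L, end = bounds[-1]))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# --- independent oracles ----------------------------------------------

# microhomology by explicit junction sliding: the fused sequence with the
# junction moved left by j must be identical to the original
oracle_microhomology <- function(donor_up, acceptor_up, acceptor_down, max_k) {
  fused <- paste0(donor_up, acceptor_down)
  nD <- nchar(donor_up); nB <- nchar(acceptor_up)
  k <- 0L
  for (j in seq_len(max_k)) {
    slid <- paste0(substr(donor_up, 1L, nD - j),
                   substr(acceptor_up, nB - j + 1L, nB), acceptor_down)
    if (identical(slid, fused)) k <- j else break
  }
  k
}

# frame by translating the concatenated retained CDS fragments: in-frame
# iff the acceptor's terminal stop is reached on a codon boundary with no
# premature stop (a stop in the donor/acceptor hybrid junction codon is
# excepted, mirroring the junction-substitution rule)
oracle_frame <- function(donor_cds, acceptor_cds, c5, s3) {
  fused <- paste0(substr(donor_cds, 1L, c5), substr(acceptor_cds, s3 + 1L, nchar(acceptor_cds)))
  n <- nchar(fused)
  if (n %% 3L != 0L) return("out_of_frame")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(fused),
                                           if.fuzzy.codon = "X"))
  codons <- strsplit(aa, "")[[1]]
  junction_codon <- if (c5 %% 3L != 0L) c5 %/% 3L + 1L else NA_integer_
  stops <- which(codons == "*")
  stops <- setdiff(stops, junction_codon)
  if (length(stops) == 0L) return("out_of_frame")        # no terminal stop reached
  if (min(stops) == length(codons)) "in_frame" else "out_of_frame"
}

# random codon sequence free of stop codons, terminated by one stop
rand_cds <- function(n_codons) {
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), n_codons * 3L, replace = TRUE),
                         ncol = 3L), 1L, paste, collapse = "")
  codons[codons %in% c("TAA", "TAG", "TGA")] <- "AAA"
  paste0(paste(codons, collapse = ""), "TAA")
}

# linear scan band lookup
oracle_band_at <- function(map, chrom, pos) {
  for (i in seq_len(nrow(map))) {
    if (fusiontriage::norm_chrom(map$chrom[i]) == fusiontriage::norm_chrom(chrom) &&
        pos >= map$start[i] && pos <= map$end[i]) return(map$band[i])
  }
  NA_character_
}

# random ISCN strings from the supported grammar
rand_iscn <- function() {
  tok <- function() {
    switch(sample(6, 1),
      sprintf("t(%d;%d)(q%d;p%d)", sample(22, 1), sample(22, 1), sample(30, 1), sample(20, 1)),
      sprintf("inv(%d)(p%dq%d)", sample(22, 1), sample(15, 1), sample(30, 1)),
      sprintf("del(%d)(q%dq%d)", sample(22, 1), sample(15, 1), sample(30, 1)),
      sprintf("+%d", sample(22, 1)),
      sprintf("-%d", sample(22, 1)),
      sprintf("der(%d)t(%d;%d)(q%d;q%d)", sample(22, 1), sample(22, 1), sample(22, 1),
              sample(30, 1), sample(30, 1)))
  }
  n_clones <- sample(1:2, 1)
  paste(vapply(seq_len(n_clones), function(i) {
    toks <- vapply(seq_len(sample(0:4, 1)), function(j) tok(), "")
    sprintf("46,%s%s[%d]", sample(c("XX", "XY"), 1),
            if (length(toks) > 0) paste0(",", paste(toks, collapse = ",")) else "",
            sample(1:30, 1))
  }, ""), collapse = "/")
}

# the eight cohort karyotypes used across tests
fixture_karyotype_strings <- function() fusiontriage:::aml_fixture_karyotypes()$iscn_string
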
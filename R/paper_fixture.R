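# A non-random bundle encoding the published AML cohort this package was
# validated against: eight ISCN karyotypes, gene stubs at the printed
# GRCh37 coordinates where coordinates were printed (UTP6, CRLF3, NF1,
# ZEB2/BCL11B breakpoints), band-consistent synthetic placements elsewhere,
# the validated fusion candidates of the cohort, and the five-patient
# clinical/mutation table. Gene structures other than the pinned
# coordinates are synthetic stubs engineered to reproduce the reported
# junction arithmetic (e.g. 24 donor residues / first acceptor codon 20 for
# the ZEB2-BCL11B chimera, three acceptor splicing isoforms).

aml_fixture_genes <- function() {
  g <- function(name, chrom, strand, exons, cds_start, cds_end) {
    ex <- as.data.table(matrix(exons, ncol = 2, byrow = TRUE))
    setnames(ex, c("start", "end"))
    list(name = name, chrom = chrom, strand = strand, exons = ex,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
  }
  list(
    # donor of the t(2;14) chimera: junction in exon 2, 72 coding nt retained
    g("ZEB2", "chr2", "-", c(145276000, 145277958,
                             145230800, 145231400,
                             145180000, 145180500), 145180100, 145231126),
    # acceptor: 4 exons, CDS 2469 nt, junction in exon 2 with 57 coding nt
    # upstream (codon 20 first fused); exons 3/4 support the skip isoforms
    g("BCL11B", "chr14", "-", c(99737500, 99738000,
                                99735000, 99736900,
                                99730000, 99730499,
                                99725000, 99725999), 99725817, 99736785),
    g("CNOT2", "chr12", "+", c(96000000, 96000999, 96005000, 96005999), 96000100, 96005900),
    g("WT1", "chr11", "-", c(3005000, 3005999, 3000000, 3000999), 3000100, 3005900),
    g("CPD", "chr17", "+", c(28705953, 28706952, 28750000, 28750999), 28706053, 28750800),
    g("PXT1", "chr6", "+", c(36360000, 36360499, 36365000, 36365999), 36360100, 36365900),
    g("SAV1", "chr14", "+", c(51000000, 51000999, 51005000, 51005999), 51000100, 51005900),
    g("GYPB", "chr4", "-", c(145105000, 145105999, 145100000, 145100999), 145100100, 145105900),
    g("OAZ1", "chr19", "+", c(2260000, 2260999, 2265000, 2265999), 2260100, 2265900),
    g("MAFK", "chr7", "-", c(1575000, 1575999, 1570000, 1570999), 1570100, 1575900),
    # printed spans: UTP6 chr17:30188190-30230729 (-), CRLF3 chr17:29107702-29153778 (-)
    g("UTP6", "chr17", "-", c(30230000, 30230729, 30188190, 30189000), 30188200, 30230500),
    g("CRLF3", "chr17", "-", c(29152900, 29153778, 29107702, 29108500), 29107800, 29153750),
    # printed span: NF1 chr17:29421945-29709134, forward strand
    g("NF1", "chr17", "+", c(29421945, 29425000, 29700000, 29709134), 29422000, 29705000),
    g("PUF60", "chr8", "-", c(144905000, 144905999, 144900000, 144900999), 144900100, 144905900),
    g("TYW1", "chr7", "+", c(66500000, 66500999, 66505000, 66505999), 66500100, 66505900),
    g("CBFB", "chr16", "+", c(67100000, 67100999, 67105000, 67105999), 67100100, 67105900),
    g("MYH11", "chr16", "-", c(15805000, 15805999, 15800000, 15800999), 15800100, 15805900)
  )
}

aml_fixture_cytobands <- function() {
  b <- function(chrom, labels, bounds) {
    data.table(chrom = chrom, band = labels,
               start = as.integer(head(bounds, -1) + 1), end = as.integer(bounds[-1]))
  }
  rbindlist(list(
    b("chr2", c("p11", "q21", "q22.3", "q31"), c(0, 93e6, 141e6, 149e6, 243e6)),
    b("chr4", c("p11", "q21", "q31", "q35"), c(0, 50e6, 140e6, 160e6, 191e6)),
    b("chr6", c("p21", "p12", "q11", "q27"), c(0, 40e6, 60e6, 100e6, 171e6)),
    b("chr7", c("p22", "p11", "q11", "q36"), c(0, 8e6, 60e6, 80e6, 159e6)),
    b("chr8", c("p11", "q21", "q24.3"), c(0, 45e6, 120e6, 146e6)),
    b("chr11", c("p15", "p13", "q13"), c(0, 10e6, 50e6, 135e6)),
    b("chr12", c("p13", "q15", "q22", "q24"), c(0, 35e6, 93e6, 98e6, 134e6)),
    b("chr14", c("p11", "q22", "q31", "q32.2"), c(0, 20e6, 60e6, 99e6, 107e6)),
    b("chr16", c("p13", "p11", "q12", "q22", "q24"), c(0, 17e6, 37e6, 65e6, 70e6, 90e6)),
    b("chr17", c("p11", "q11.2", "q21", "q25"), c(0, 24e6, 32e6, 50e6, 81e6)),
    b("chr19", c("p13.3", "p12", "q13"), c(0, 7e6, 28e6, 59e6))
  ))
}

aml_fixture_karyotypes <- function() {
  data.table(
    sample_id = c("59810", "20", "21", "32", "84", "68187", "63569", "125"),
    iscn_string = c(
      "46,XX,t(2;14)(q21;q32),t(11;12)(p15;q22)[17]/46,XX[3]",
      "46,XY,t(6;17)(p21;q11)[20]",
      "46,XY,t(3;12)(p22;q24),+4,-15,+mar[19]/46,XY[1]",
      paste0("45,XY,der(12)t(12;18)(p13;q12),-18[12]/",
             "45,XY,t(4;16)(q31;q22),der(12)t(12;18)(p13;q12),-18[4]/",
             "45,XY,der(6)t(6;12;18)(p21;p13,q12),-18[3]/46,XY[1]"),
      "47,XX,+8,del(11)(p11p15),t(15;17)(q24q25),inv(16)(p13q22)[20]",
      "46,XX,add(8)(p23),der(16)t(1;16)(q11;q11)[18]/46,XX[2]",
      "46,XY[20]/46,XY,add(10)(p15)[9]/46,XY,add(10)(p15),t(1;8)(p36;q13)[2]",
      "46,XX[11]/44~47,XX,t(4;17)(p15;q21),del(5)(q13q33),-7,-18,der(X),+1~3mar[9]"))
}

aml_fixture_fusions <- function() {
  data.table(
    sample_id = c("59810", "59810", "20", "20", "21", "68187", "125", "84"),
    gene5 = c("ZEB2", "CNOT2", "CPD", "SAV1", "OAZ1", "UTP6", "PUF60", "CBFB"),
    gene3 = c("BCL11B", "WT1", "PXT1", "GYPB", "MAFK", "CRLF3", "TYW1", "MYH11"),
    chrom5 = c("chr2", "chr12", "chr17", "chr14", "chr19", "chr17", "chr8", "chr16"),
    pos5 = c(145231055L, 96005500L, 28750500L, 51005500L, 2265500L,
             30188250L, 144900500L, 67105500L),
    strand5 = c("-", "+", "+", "+", "+", "-", "-", "+"),
    chrom3 = c("chr14", "chr11", "chr6", "chr4", "chr7", "chr17", "chr7", "chr16"),
    pos3 = c(99736728L, 3000500L, 36365101L, 145105501L, 1575501L,
             29153700L, 66505101L, 15805501L),
    strand3 = c("-", "+", "+", "-", "-", "-", "+", "-"),
    split_reads = c(24L, 11L, 17L, 9L, 13L, 8L, 7L, 31L),
    spanning_reads = c(12L, 6L, 9L, 5L, 7L, 4L, 3L, 16L),
    driver_score = c(NA, NA, NA, 0.87, 0.82, 0.35, 0.41, NA))
}

aml_fixture_cohort <- function() {
  # the five patients with the confirmed t(2;14) rearrangement
  dt <- data.table(
    case = c("11942", "11944", "11954", "11945", "59810"),
    gender = c("male", "male", "male", "male", "female"),
    age = c(58L, 79L, 85L, 59L, 40L),
    who_class = c("AML NOS", "AUL", "AML with mutated RUNX1", "T/myeloid MPAL",
                  "AML NOS, without maturation"),
    ASXL1 = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    BCOR = c("NEG", "NEG", NA, "NEG", "NEG"),
    CALR = c("NEG", "NEG", NA, "NEG", "NEG"),
    CBL = c("NEG", "NEG", NA, "NEG", "NEG"),
    CSF3R = c("NEG", "NEG", NA, "NEG", "NEG"),
    CSNK1A1 = c("NEG", "NEG", NA, "NEG", "NEG"),
    DNMT3A = c("NEG", "NEG", "NEG", "POS", "NEG"),
    ETNK1 = c("NEG", "NEG", NA, "NEG", "NEG"),
    ETV6 = c("NEG", "NEG", NA, "NEG", "NEG"),
    EZH2 = c("NEG", "NEG", NA, "NEG", "NEG"),
    FLT3_TKD = c("NEG", "NEG", "NEG", "POS", "POS"),
    FLT3_ITD = c("NEG", "POS", "POS", "POS", "POS"),
    FLT3_ITD_VAF = c(NA, ">0.5", ">0.5", "<0.5", "<0.5"),
    GATA1 = c("NEG", "NEG", NA, "NEG", "NEG"),
    GATA2 = c("NEG", "NEG", NA, "POS", "NEG"),
    IDH1 = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    IDH2 = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    JAK2 = c("NEG", "NEG", "POS", "NEG", "NEG"),
    KIT = c("NEG", "NEG", NA, "NEG", "NEG"),
    KRAS = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    MPL = c("NEG", "NEG", NA, "NEG", "NEG"),
    NPM1 = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    NRAS = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    PHF6 = c("NEG", "NEG", NA, "NEG", "NEG"),
    PTPN11 = c("NEG", "NEG", NA, "NEG", "NEG"),
    RUNX1 = c("NEG", "VARIANT", "POS", "VARIANT", "NEG"),
    SETBP1 = c("NEG", "VARIANT", NA, "NEG", "NEG"),
    SF3B1 = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    SRSF2 = c("NEG", "POS", NA, "NEG", "NEG"),
    STAG2 = c("NEG", NA, NA, "NEG", "NEG"),
    STAT3 = c("NEG", "NEG", NA, NA, "NEG"),
    STAT5B = c("NEG", "NEG", NA, NA, "NEG"),
    TET2 = c("VARIANT", "POS", "NEG", "NEG", "POS"),
    TP53 = c("NEG", "NEG", "NEG", "NEG", "NEG"),
    U2AF1 = c("NEG", "NEG", NA, "NEG", "NEG"),
    WT1 = c("NEG", "NEG", NA, "NEG", "NEG"),
    ZRSR2 = c("NEG", "NEG", NA, "NEG", "NEG"))
  dt
}

#' Write the published-cohort fixture bundle
#'
#' Produces a non-random bundle with the eight cohort karyotypes, gene stubs
#' (pinned printed coordinates for UTP6/CRLF3/NF1 and the t(2;14) junction;
#' band-consistent synthetic stubs elsewhere), the eight validated fusion
#' candidates with their reported driver scores, a tumor-suppressor list, a
#' healthy panel, and the five-patient clinical/mutation CSV. No genome
#' FASTA is included: sequence-dependent checks run on explicit fixture
#' sequences instead.
#'
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dir` and a ready [run_pipeline()] config.
#' @export
paper_fixture <- function(out_dir = tempfile("amlfix")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  synth_write_gtf(aml_fixture_genes(), file.path(out_dir, "genes.gtf"))
  write_cytobands(new_cytoband_map(aml_fixture_cytobands()),
                  file.path(out_dir, "cytobands.txt"))
  fwrite(aml_fixture_karyotypes(), file.path(out_dir, "karyotypes.tsv"), sep = "\t")
  fwrite(aml_fixture_fusions(), file.path(out_dir, "chimerascan.tsv"),
         sep = "\t", na = "", quote = FALSE)
  fwrite(data.table(geneA = "DECOYA", geneB = "DECOYB"),
         file.path(out_dir, "healthy_panel.tsv"), sep = "\t")
  writeLines(c("SAV1", "PUF60", "CNOT2", "WT1", "CRLF3", "NF1"),
             file.path(out_dir, "tsg.txt"))
  fwrite(aml_fixture_cohort(), file.path(out_dir, "cohort.csv"), na = "NA")
  config <- list(
    fusion_tables = list(list(path = "chimerascan.tsv", dialect = "chimerascan")),
    gtf = "genes.gtf", cytoband = "cytobands.txt", karyotypes = "karyotypes.tsv",
    healthy_panel = "healthy_panel.tsv", tsg = "tsg.txt",
    tolerance = 1L, max_skip = 2L,
    filter = list(min_split_reads = 1L, promiscuous_partner_threshold = 3L,
                  readthrough_max_gap = 200000L, ds_threshold = 0.7))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir, config = config))
}
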
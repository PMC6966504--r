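test_that("chimerascan dialect reads row-per-candidate with positions intact", {
  f <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(data.table::data.table(
    sample_id = c("A", "A", "B"), gene5 = c("G1", "G2", "G3"), gene3 = c("H1", "H2", "H3"),
    chrom5 = "chr1", pos5 = c(100L, 200L, 300L), strand5 = "+",
    chrom3 = "chr2", pos3 = c(900L, 800L, 700L), strand3 = "-",
    split_reads = c(5L, 0L, 2L), spanning_reads = c(1L, 2L, 3L),
    driver_score = c(0.9, NA, 0.1)), f, sep = "\t", na = "")
  fs <- read_fusion_table(f, "chimerascan")
  expect_equal(nrow(fs), 3L)
  expect_true(all(fs$caller == "chimerascan"))
  # reading is not filtering: zero split reads are kept
  expect_equal(fs$split_reads[fs$gene5 == "G2"], 0L)
  expect_true(is.na(fs$driver_score[2]))
  expect_equal(fs$chrom5, rep("1", 3))  # chr prefix normalized
})

test_that("missing columns and bad values are named errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene5\tgene3", "A\tG\tH"), f)
  expect_error(read_fusion_table(f, "chimerascan"), "missing column")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("sample_id","gene5","gene3","chrom5","pos5","strand5","chrom3",
                       "pos3","strand3","split_reads","spanning_reads","driver_score"),
                     collapse = "\t"),
               "A\tG\tH\tchr1\t10\t+\tchr2\t20\t-\t-3\t1\t"), f2)
  expect_error(read_fusion_table(f2, "chimerascan"), "row")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("sample_id","gene5","gene3","chrom5","pos5","strand5","chrom3",
                       "pos3","strand3","split_reads","spanning_reads","driver_score"),
                     collapse = "\t"),
               "A\tG\tH\tchr1\toops\t+\tchr2\t20\t-\t3\t1\t"), f3)
  expect_error(read_fusion_table(f3, "chimerascan"), "breakpoint")
})

test_that("defuse dialect maps columns and deduplicates swapped orientations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- c("cluster_id","sample_id","gene_name1","gene_name2","chromosome1",
           "genomic_break_pos1","genomic_strand1","chromosome2","genomic_break_pos2",
           "genomic_strand2","splitr_count","span_count","probability")
  writeLines(c(paste(hdr, collapse = "\t"),
               "c1\tA\tG1\tH1\tchr1\t100\t+\tchr2\t900\t-\t7\t3\t0.8",
               "c1r\tA\tH1\tG1\tchr2\t900\t-\tchr1\t100\t+\t7\t3\t0.8",
               "c2\tA\tG2\tH2\tchr3\t50\t+\tchr4\t60\t+\t4\t2\t"), f)
  fs <- read_fusion_table(f, "defuse")
  expect_equal(nrow(fs), 2L)
  expect_equal(fs$gene5[fs$gene3 == "H1"], "G1")  # first-seen orientation kept
  expect_equal(fs$driver_score[fs$gene5 == "G1"], 0.8)
})

test_that("fusion tables round-trip through write/read on generated fixtures", {
  gc <- generate_cohort(7, out_dir = withr::local_tempdir())
  fs <- read_fusion_table(file.path(gc$dir, "chimerascan.tsv"), "chimerascan")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_table(fs, f2)
  fs2 <- read_fusion_table(f2, "chimerascan")
  cols <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
            "chrom3", "pos3", "strand3", "split_reads", "spanning_reads", "driver_score")
  a <- data.table::setorder(data.table::as.data.table(fs)[, cols, with = FALSE],
                            sample_id, gene5, gene3)
  b <- data.table::setorder(data.table::as.data.table(fs2)[, cols, with = FALSE],
                            sample_id, gene5, gene3)
  expect_equal(a, b)
  # and byte-identical on a second write
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_table(fs2, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("cytoband conversion is involutive and validates contiguity", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\tp11\tgneg", "chr1\t100\t200\tq11\tgpos50"), f)
  m <- read_cytobands(f)
  expect_equal(m$start, c(1L, 101L))
  expect_equal(m$end, c(100L, 200L))
  f2 <- withr::local_tempfile()
  write_cytobands(m, f2)
  m2 <- read_cytobands(f2)
  expect_equal(data.table::as.data.table(m), data.table::as.data.table(m2))
  # out-of-order bands are sorted; gaps are errors
  f3 <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\tq11\tgneg", "chr1\t0\t100\tp11\tgneg"), f3)
  expect_equal(read_cytobands(f3)$band, c("p11", "q11"))
  f4 <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\tp11\tgneg", "chr1\t150\t200\tq11\tgneg"), f4)
  expect_error(read_cytobands(f4), "gap or overlap")
})

test_that("band lookup agrees with a linear-scan oracle", {
  map <- mk_band_map(labels = c("p12", "p11", "q21", "q22.3"),
                     bounds = c(0L, 70L, 150L, 300L, 444L))
  for (pos in c(1L, 70L, 71L, 150L, 299L, 300L, 301L, 444L)) {
    expect_identical(band_at(map, "chr1", pos), oracle_band_at(map, "chr1", pos),
                     label = sprintf("pos %d", pos))
  }
  expect_true(is.na(band_at(map, "chr1", 445L)))
  expect_error(band_at(map, "chr9", 10L), "absent")
})

test_that("gene model reading indexes by symbol and by interval", {
  d <- withr::local_tempdir()
  gtf <- file.path(d, "g.gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t199\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1"; gene_name "GA";',
    'chr1\tx\texon\t300\t399\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1"; gene_name "GA";',
    'chr1\tx\texon\t500\t599\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1"; gene_name "GA";',
    'chr1\tx\texon\t700\t799\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1"; gene_name "GA";',
    'chr1\tx\tCDS\t150\t199\t.\t+\t0\tgene_id "GA"; transcript_id "GA.t1"; gene_name "GA";',
    'chr1\tx\tCDS\t300\t399\t.\t+\t0\tgene_id "GA"; transcript_id "GA.t1"; gene_name "GA";',
    'chr1\tx\texon\t2000\t2499\t.\t-\t.\tgene_id "GB"; transcript_id "GB.t1";'), gtf)
  ms <- read_gene_models(gtf)
  g <- model_for_symbol(ms, "ga")  # case-insensitive
  expect_equal(nrow(g$exons), 4L)
  expect_equal(c(g$cds_start, g$cds_end), c(150L, 399L))
  hits <- models_overlapping(ms, "chr1", 350, 2100)
  expect_setequal(vapply(hits, `[[`, "", "gene_id"), c("GA", "GB"))
})

test_that("UTP6/CRLF3-style printed coordinates are retrievable by symbol", {
  d <- withr::local_tempdir()
  fx <- paper_fixture(d)
  ms <- read_gene_models(file.path(d, "genes.gtf"))
  utp6 <- model_for_symbol(ms, "UTP6")
  crlf3 <- model_for_symbol(ms, "CRLF3")
  expect_equal(c(fusiontriage:::gene_start(utp6), fusiontriage:::gene_end(utp6)),
               c(30188190L, 30230729L))
  expect_equal(c(fusiontriage:::gene_start(crlf3), fusiontriage:::gene_end(crlf3)),
               c(29107702L, 29153778L))
  expect_equal(utp6$strand, "-")
  expect_equal(crlf3$strand, "-")
})

test_that("interval queries agree with a brute-force scan over all models", {
  set.seed(42)
  genes <- lapply(seq_len(150), function(i) {
    st <- sample(1:50000, 1)
    mk_cds_gene(sprintf("G%03d", i), sample(c("chr1", "chr2"), 1), st, sample(50:500, 1))
  })
  ms <- fusiontriage:::new_gene_model_set(genes)
  for (rep in 1:20) {
    chrom <- sample(c("chr1", "chr2"), 1)
    a <- sample(1:50000, 1); b <- a + sample(10:5000, 1)
    got <- sort(unname(vapply(models_overlapping(ms, chrom, a, b), `[[`, "", "gene_id")))
    want <- sort(unlist(lapply(genes, function(g) {
      if (g$chrom == fusiontriage::norm_chrom(chrom) &&
          fusiontriage:::gene_start(g) <= b && fusiontriage:::gene_end(g) >= a) g$gene_id
    })))
    expect_equal(got, if (is.null(want)) character(0) else want,
                 label = sprintf("query %s:%d-%d", chrom, a, b))
  }
})

test_that("report lists round-trip and serialize canonically", {
  gc <- generate_cohort(11, out_dir = withr::local_tempdir())
  res <- run_pipeline(file.path(gc$dir, "config.json"), quiet = TRUE,
                      out_dir = withr::local_tempdir())
  tab <- res$table
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_report(res$reports, f1)
  # shuffled input order yields byte-identical output
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(rev(res$reports), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_report(f1), tab)
  # empty list -> header-only files
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_report(list(), f3)
  expect_equal(length(readLines(f3)), 1L)
  expect_equal(length(readLines(sub("\\.tsv$", ".bedpe", f3))), 1L)
})

test_that("BEDPE companion carries the planted junction coordinates", {
  gc <- generate_cohort(3, out_dir = withr::local_tempdir())
  out <- withr::local_tempdir()
  res <- run_pipeline(file.path(gc$dir, "config.json"), quiet = TRUE, out_dir = out)
  bed <- data.table::fread(file.path(out, "report.bedpe"), skip = 1L, header = FALSE)
  truth <- gc$truth[gc$truth$expected_tier != "rejected", ]
  expect_equal(nrow(bed), nrow(truth))
  tab <- res$table[res$table$tier != "rejected", ]
  expect_setequal(bed$V3, tab$pos5)   # end1 = pos5 (1-based inclusive)
  expect_setequal(bed$V6, tab$pos3)
})
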
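# frame determination -------------------------------------------------

test_that("frame congruence drives in/out-of-frame calls", {
  # donor: single 900 nt exon, all CDS; acceptor likewise
  g5 <- mk_cds_gene("D", "chr1", 1001L, 900L)
  g3 <- mk_cds_gene("A", "chr2", 5001L, 900L)
  # c5 = 300 (junction after 300 coding bases), s3 = 33
  f <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1300L, chrom3 = "chr2", pos3 = 5034L)
  fr <- determine_frame(f, g5, g3)
  expect_equal(fr$status, "in_frame")
  expect_equal(c(fr$c5, fr$s3), c(300L, 33L))
  f2 <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1301L, chrom3 = "chr2", pos3 = 5034L)
  expect_equal(determine_frame(f2, g5, g3)$status, "out_of_frame")
})

test_that("promoter swap, noncoding and inverted partners are classified", {
  g5 <- mk_cds_gene("D", "chr1", 1001L, 900L)
  g3 <- gene_model("A", "A.t1", "chr2", "+", data.frame(start = 5001L, end = 5900L),
                   cds_start = 5301L, cds_end = 5900L)
  # acceptor junction at the CDS start or upstream of it: promoter swap
  f <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1300L, chrom3 = "chr2", pos3 = 5100L)
  expect_equal(determine_frame(f, g5, g3)$status, "promoter_swap")
  f_at <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1300L, chrom3 = "chr2", pos3 = 5301L)
  expect_equal(determine_frame(f_at, g5, g3)$status, "promoter_swap")
  # non-coding acceptor
  nc <- gene_model("N", "N.t1", "chr2", "+", data.frame(start = 5001L, end = 5900L))
  expect_equal(determine_frame(f, g5, nc)$status, "noncoding")
  # inverted acceptor reads antisense: out of frame (the CNOT2/WT1 pattern)
  gm <- mk_cds_gene("W", "chr2", 5001L, 900L, strand = "-")
  f_inv <- mk_fusion(gene5 = "D", gene3 = "W", pos5 = 1300L, chrom3 = "chr2",
                     pos3 = 5500L, strand3 = "+")
  expect_equal(determine_frame(f_inv, g5, gm)$status, "out_of_frame")
  # inverted donor has no spliced prefix: undetermined
  f_dinv <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1300L, strand5 = "-",
                      chrom3 = "chr2", pos3 = 5400L)
  expect_equal(determine_frame(f_dinv, g5, g3)$status, "undetermined")
  # breakpoint outside the gene span is a contract violation
  f_out <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 99999L, chrom3 = "chr2", pos3 = 5400L)
  expect_error(determine_frame(f_out, g5, g3), "contract violation")
})

test_that("intronic breakpoints snap to splice-consistent exon boundaries", {
  g5 <- gene_model("D", "D.t1", "chr1", "+",
                   data.frame(start = c(1001L, 2001L), end = c(1300L, 2600L)),
                   cds_start = 1001L, cds_end = 2600L)
  g3 <- gene_model("A", "A.t1", "chr2", "+",
                   data.frame(start = c(5001L, 6001L), end = c(5300L, 6600L)),
                   cds_start = 5001L, cds_end = 6600L)
  # donor breakpoint in the intron: snaps back to exon-1 end (c5 = 300)
  # acceptor breakpoint in the intron: snaps forward to exon-2 start (s3 = 300)
  f <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1700L, chrom3 = "chr2", pos3 = 5600L)
  fr <- determine_frame(f, g5, g3)
  expect_equal(c(fr$c5, fr$s3), c(300L, 300L))
  expect_equal(fr$status, "in_frame")
})

test_that("the engineered t(2;14) junction reproduces the reported arithmetic", {
  d <- withr::local_tempdir()
  paper_fixture(d)
  ms <- read_gene_models(file.path(d, "genes.gtf"))
  zeb2 <- model_for_symbol(ms, "ZEB2")
  bcl11b <- model_for_symbol(ms, "BCL11B")
  f <- mk_fusion(gene5 = "ZEB2", gene3 = "BCL11B", chrom5 = "chr2", pos5 = 145231055L,
                 strand5 = "-", chrom3 = "chr14", pos3 = 99736728L, strand3 = "-")
  fr <- determine_frame(f, zeb2, bcl11b)
  expect_equal(fr$status, "in_frame")
  expect_equal(c(fr$c5, fr$s3), c(72L, 57L))
  ext <- fusion_protein_extent(fr, zeb2, bcl11b)
  expect_equal(ext$residues5, 24L)            # twenty-four donor residues
  expect_equal(ext$residues3, 803L)           # acceptor residues in the chimera
  expect_equal(ext$first_acceptor_codon, 20L) # codon 20 first involved
  # junction lands in exon 2 of both partners
  iso <- enumerate_isoforms(f, zeb2, bcl11b, max_skip = 2L)
  expect_equal(iso[[1]]$junction, c(2L, 2L))
})

test_that("frame calls equal the translate-and-scan oracle on random transcript pairs", {
  set.seed(1234)
  n_ok <- 0L
  for (i in 1:200) {
    len5 <- sample(20:80, 1) * 3L
    len3 <- sample(20:80, 1) * 3L
    c5 <- sample(seq_len(len5 - 4L), 1)
    s3 <- sample(seq_len(len3 - 7L), 1)
    g5 <- mk_cds_gene("D", "chr1", 1001L, len5)
    g3 <- mk_cds_gene("A", "chr2", 5001L, len3)
    f <- mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1000L + c5,
                   chrom3 = "chr2", pos3 = 5000L + s3 + 1L)
    got <- determine_frame(f, g5, g3)$status
    want <- oracle_frame(rand_cds(len5 %/% 3L - 1L), rand_cds(len3 %/% 3L - 1L), c5, s3)
    expect_equal(got, want, label = sprintf("c5=%d s3=%d", c5, s3))
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 200L)
})

# orientation -----------------------------------------------------------

test_that("orientation is derived from junction strand vs gene strand", {
  gp <- mk_cds_gene("P", "chr1", 1001L, 300L)
  gm <- mk_cds_gene("M", "chr2", 5001L, 300L, strand = "-")
  f <- mk_fusion(gene5 = "P", gene3 = "M", pos5 = 1100L, chrom3 = "chr2",
                 pos3 = 5100L, strand3 = "+")
  o <- classify_orientation(f, gp, gm)
  expect_equal(o, list(orient5 = "conserved", orient3 = "inverted"))
  f2 <- mk_fusion(strand5 = "-", pos5 = 1100L, chrom3 = "chr2", pos3 = 5100L, strand3 = "-")
  expect_equal(classify_orientation(f2, gp, gm),
               list(orient5 = "inverted", orient3 = "conserved"))
  f3 <- mk_fusion(pos5 = 1100L, chrom3 = "chr2", pos3 = 5100L, strand3 = "+")
  gm2 <- mk_cds_gene("M2", "chr2", 5001L, 300L)
  expect_equal(classify_orientation(f3, gp, gm2),
               list(orient5 = "conserved", orient3 = "conserved"))
})

# isoform enumeration ---------------------------------------------------

test_that("acceptor exon skipping yields capped, frame-annotated isoform lists", {
  d <- withr::local_tempdir()
  paper_fixture(d)
  ms <- read_gene_models(file.path(d, "genes.gtf"))
  zeb2 <- model_for_symbol(ms, "ZEB2"); bcl11b <- model_for_symbol(ms, "BCL11B")
  f <- mk_fusion(gene5 = "ZEB2", gene3 = "BCL11B", chrom5 = "chr2", pos5 = 145231055L,
                 strand5 = "-", chrom3 = "chr14", pos3 = 99736728L, strand3 = "-")
  iso <- enumerate_isoforms(f, zeb2, bcl11b, max_skip = 2L)
  expect_length(iso, 3L)
  expect_equal(vapply(iso, `[[`, "", "label"), c("type 1", "type 2", "type 3"))
  expect_equal(lapply(iso, `[[`, "junction"),
               list(c(2L, 2L), c(2L, 3L), c(2L, 4L)))
  expect_equal(iso[[1]]$frame$status, "in_frame")
  # skip-s frame equals determine_frame at the shifted junction
  shifted <- mk_fusion(gene5 = "ZEB2", gene3 = "BCL11B", chrom5 = "chr2",
                       pos5 = 145231055L, strand5 = "-", chrom3 = "chr14",
                       pos3 = 99730499L, strand3 = "-")
  expect_equal(iso[[2]]$frame$status, determine_frame(shifted, zeb2, bcl11b)$status)
  # max_skip = 0 -> single isoform; capping by exon availability
  expect_length(enumerate_isoforms(f, zeb2, bcl11b, max_skip = 0L), 1L)
  expect_length(enumerate_isoforms(f, zeb2, bcl11b, max_skip = 5L), 3L)
  expect_error(enumerate_isoforms(f, zeb2, bcl11b, max_skip = -1L), "max_skip")
})

# fusion protein extent --------------------------------------------------

test_that("protein extent counts initiator, clamps boundaries, conserves length", {
  g5 <- mk_cds_gene("D", "chr1", 1001L, 300L)
  g3 <- mk_cds_gene("A", "chr2", 5001L, 300L)  # 99 aa + stop
  fr <- determine_frame(mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1003L,
                                  chrom3 = "chr2", pos3 = 5004L), g5, g3)
  expect_equal(fr$status, "in_frame")
  ext <- fusion_protein_extent(fr, g5, g3)
  expect_equal(ext$residues5, 1L)   # initiator only
  expect_equal(ext$residues3, ext$total_acceptor_residues - 1L)
  expect_error(fusion_protein_extent(list(status = "out_of_frame"), g5, g3),
               "contract violation")
  # length conservation across random in-frame junctions
  set.seed(7)
  for (i in 1:25) {
    s3 <- sample(1:90, 1) * 3L
    fr2 <- determine_frame(mk_fusion(gene5 = "D", gene3 = "A", pos5 = 1003L,
                                     chrom3 = "chr2", pos3 = 5001L + s3), g5, g3)
    if (fr2$status != "in_frame") next
    e <- fusion_protein_extent(fr2, g5, g3)
    expect_equal(e$residues3 + fr2$s3 %/% 3L,
                 max(e$total_acceptor_residues, fr2$s3 %/% 3L))
  }
})

# microhomology ----------------------------------------------------------

test_that("microhomology equals the longest shared junction-proximal run", {
  expect_equal(microhomology_length("GGGACCC", "AATTCCC", max_k = 4L), 3L)
  expect_equal(microhomology_length("AACGC", "ATTTT", max_k = 4L), 0L)
  full <- microhomology_length("CCCC", "CCCC", max_k = 4L)
  expect_equal(as.integer(full), 4L)
  expect_true(isTRUE(attr(full, "capped")))
  expect_error(microhomology_length("AC", "ACGTACGT", max_k = 5L), "value error")
})

test_that("microhomology equals the junction-sliding oracle on random contexts", {
  set.seed(2024)
  for (i in 1:300) {
    donor_up <- rand_dna(30L)
    acceptor_up <- rand_dna(30L)
    # bias towards non-zero homology half the time
    if (i %% 2L == 0L) {
      m <- sample(0:8, 1)
      if (m > 0) {
        substr(acceptor_up, 31L - m, 30L) <- substr(donor_up, 31L - m, 30L)
      }
    }
    acceptor_down <- rand_dna(30L)
    got <- as.integer(microhomology_length(donor_up, acceptor_up, max_k = 20L))
    want <- oracle_microhomology(donor_up, acceptor_up, acceptor_down, 20L)
    expect_equal(got, want, label = sprintf("trial %d", i))
  }
})

test_that("total junction ambiguity is invariant under reverse-complement", {
  set.seed(31)
  for (i in 1:50) {
    d_up <- rand_dna(25L); d_down <- rand_dna(25L)
    a_up <- rand_dna(25L); a_down <- rand_dna(25L)
    fwd <- junction_ambiguity(d_up, d_down, a_up, a_down, max_k = 20L)
    # the reciprocal-orientation junction swaps roles and strands
    rc <- junction_ambiguity(revcomp(a_down), revcomp(a_up),
                             revcomp(d_down), revcomp(d_up), max_k = 20L)
    expect_equal(fwd$total, rc$total)
    expect_equal(fwd$left, rc$right)
    expect_equal(fwd$right, rc$left)
  }
})
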
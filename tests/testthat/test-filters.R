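# gene layout used across these tests: two chr1 neighbors on "+" (GA, GB),
# a far gene on chr2 (GC, "-"), and a promiscuous-list gene (MPO)
filters_model_set <- function() {
  mk_model_set(
    mk_cds_gene("GA", "chr1", 1000L, 900L),
    mk_cds_gene("GB", "chr1", 12000L, 900L),
    mk_cds_gene("GC", "chr2", 5000L, 900L, strand = "-"),
    mk_cds_gene("MPO", "chr2", 40000L, 900L))
}

test_that("core filters flag exactly the offending candidates", {
  ms <- filters_model_set()
  cfg <- filter_config(healthy_panel = fusiontriage:::pair_key("GA", "GC"))
  fs <- rbind(
    mk_fusion(gene5 = "GA", gene3 = "GC", pos5 = 1500L, chrom3 = "chr2",
              pos3 = 5500L, strand3 = "-", split_reads = 0L),   # no split + panel
    mk_fusion(gene5 = "GA", gene3 = "NOPE", pos5 = 1500L, pos3 = 100L),  # unannotated
    mk_fusion(gene5 = "GA", gene3 = "GC", pos5 = 99999L, chrom3 = "chr2",
              pos3 = 5500L, strand3 = "-"),                     # pos5 outside span
    mk_fusion(gene5 = "GA", gene3 = "GC", pos5 = 1500L, chrom3 = "chr2",
              pos3 = 5500L, strand3 = "-", strand5 = "-"))      # inverted donor
  out <- apply_core_filters(fusiontriage:::new_fusion_set(fs), ms, cfg)
  expect_true(fusiontriage:::has_flag(out[1], "no_split_reads"))
  expect_true(fusiontriage:::has_flag(out[1], "healthy_panel"))
  expect_true(fusiontriage:::has_flag(out[2], "unannotated_partner"))
  expect_false(out$annotated3[2])
  expect_true(fusiontriage:::has_flag(out[3], "unreliable_structure"))
  expect_true(fusiontriage:::has_flag(out[4], "unreliable_structure"))
  # a clean configuration (pair not in the panel) passes everything
  clean <- apply_core_filters(mk_fusion(gene5 = "GB", gene3 = "GC", pos5 = 12500L,
                                        chrom3 = "chr2", pos3 = 5500L, strand3 = "-"),
                              ms, cfg)
  expect_true(passes_filters(clean))
})

test_that("cohort filters: promiscuous static/diversity, read-through, recurrence", {
  ms <- filters_model_set()
  cfg <- filter_config(readthrough_max_gap = 200000L, promiscuous_partner_threshold = 3L)
  fs <- rbind(
    mk_fusion(sample_id = "S1", gene5 = "MPO", gene3 = "GA", chrom5 = "chr2",
              pos5 = 40100L, pos3 = 1500L),
    mk_fusion(sample_id = "S1", gene5 = "GA", gene3 = "GB", pos5 = 1500L,
              chrom3 = "chr1", pos3 = 12500L),                    # colinear neighbors
    mk_fusion(sample_id = "S1", gene5 = "GA", gene3 = "GC", pos5 = 1500L,
              chrom3 = "chr2", pos3 = 5500L, strand3 = "-"),
    mk_fusion(sample_id = "S2", gene5 = "GC", gene3 = "GA", chrom5 = "chr2",
              pos5 = 5500L, strand5 = "-", chrom3 = "chr1", pos3 = 1500L))
  out <- apply_cohort_filters(fusiontriage:::new_fusion_set(fs), ms, cfg)
  expect_true(fusiontriage:::has_flag(out[1], "promiscuous_gene"))   # static list
  expect_true(fusiontriage:::has_flag(out[2], "readthrough"))
  # GA has partners MPO, GB, GC -> hits the diversity threshold K=3
  expect_true(all(fusiontriage:::has_flag(out, "promiscuous_gene")))
  # recurrence is symmetric in partner order: GA-GC in S1, GC-GA in S2
  expect_true(fusiontriage:::has_flag(out[3], "cohort_recurrent"))
  expect_true(fusiontriage:::has_flag(out[4], "cohort_recurrent"))
  # single-sample interchromosomal fusion with K=4 would carry no cohort flags
  out2 <- apply_cohort_filters(mk_fusion(gene5 = "GA", gene3 = "GC", pos5 = 1500L,
                                         chrom3 = "chr2", pos3 = 5500L, strand3 = "-"),
                               ms, filter_config(promiscuous_partner_threshold = 4L))
  expect_identical(out2$flags, "")
})

test_that("read-through needs colinear transcriptional order and a small gap", {
  ms <- filters_model_set()
  cfg <- filter_config(readthrough_max_gap = 5000L)
  # gap GA->GB is 12000 - 1900 - 1 = 10100 > 5 kb: not read-through
  out <- apply_cohort_filters(mk_fusion(gene5 = "GA", gene3 = "GB", pos5 = 1500L,
                                        chrom3 = "chr1", pos3 = 12500L), ms, cfg)
  expect_false(fusiontriage:::has_flag(out, "readthrough"))
  # reversed roles (GB upstream gene as donor): not colinear
  out2 <- apply_cohort_filters(mk_fusion(gene5 = "GB", gene3 = "GA", pos5 = 12500L,
                                         chrom3 = "chr1", pos3 = 1500L), ms,
                               filter_config(readthrough_max_gap = 200000L))
  expect_false(fusiontriage:::has_flag(out2, "readthrough"))
})

test_that("filtering is flag-monotone and core/cohort filters commute", {
  ms <- filters_model_set()
  cfg <- filter_config(healthy_panel = fusiontriage:::pair_key("GA", "GC"),
                       readthrough_max_gap = 200000L)
  fs <- rbind(
    mk_fusion(sample_id = "S1", gene5 = "GA", gene3 = "GB", pos5 = 1500L,
              chrom3 = "chr1", pos3 = 12500L, split_reads = 0L),
    mk_fusion(sample_id = "S1", gene5 = "GA", gene3 = "GC", pos5 = 1500L,
              chrom3 = "chr2", pos3 = 5500L, strand3 = "-"),
    mk_fusion(sample_id = "S2", gene5 = "MPO", gene3 = "ZZ", chrom5 = "chr2",
              pos5 = 40100L, pos3 = 7L))
  fs <- fusiontriage:::new_fusion_set(fs)
  a <- apply_cohort_filters(apply_core_filters(fs, ms, cfg), ms, cfg)
  b <- apply_core_filters(apply_cohort_filters(fs, ms, cfg), ms, cfg)
  norm_flags <- function(x) lapply(strsplit(x$flags, ";"), sort)
  expect_equal(norm_flags(a), norm_flags(b))
  # idempotence
  a2 <- apply_cohort_filters(apply_core_filters(a, ms, cfg), ms, cfg)
  expect_equal(norm_flags(a2), norm_flags(a))
})

test_that("merge_callsets merges same-junction calls and keeps distinct ones", {
  cs <- mk_fusion(gene5 = "GA", gene3 = "GB", pos5 = 1000L, pos3 = 2000L,
                  split_reads = 5L, spanning_reads = 2L, driver_score = 0.8)
  df <- mk_fusion(gene5 = "GA", gene3 = "GB", pos5 = 1004L, pos3 = 1997L,
                  split_reads = 9L, spanning_reads = 1L, driver_score = 0.8,
                  caller = "defuse")
  m <- merge_callsets(cs, df)
  expect_equal(nrow(m), 1L)
  expect_equal(m$split_reads, 9L)
  expect_equal(m$spanning_reads, 2L)
  expect_equal(m$caller, "chimerascan,defuse")
  expect_false(fusiontriage:::has_flag(m, "ds_conflict"))
  # breakpoints 5 kb apart stay separate
  far <- mk_fusion(gene5 = "GA", gene3 = "GB", pos5 = 6000L, pos3 = 2000L,
                   caller = "defuse")
  expect_equal(nrow(merge_callsets(cs, far)), 2L)
  # disagreeing driver scores: max kept, ds_conflict warned
  df2 <- mk_fusion(gene5 = "GA", gene3 = "GB", pos5 = 1000L, pos3 = 2000L,
                   driver_score = 0.6, caller = "defuse")
  m2 <- merge_callsets(cs, df2)
  expect_equal(m2$driver_score, 0.8)
  expect_true(fusiontriage:::has_flag(m2, "ds_conflict"))
  expect_true(passes_filters(m2))  # ds_conflict is informational
})

test_that("merged count equals planted truth count on a generated cohort", {
  gc <- generate_cohort(5, out_dir = withr::local_tempdir())
  cs <- read_fusion_table(file.path(gc$dir, "chimerascan.tsv"), "chimerascan")
  df <- read_fusion_table(file.path(gc$dir, "defuse.tsv"), "defuse")
  m <- merge_callsets(cs, df)
  expect_equal(nrow(m), nrow(gc$truth))
})
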
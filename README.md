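# fusiontriage

Triage of candidate fusion transcripts from RNA-seq fusion callers in
acute-leukemia-style cohorts: filter the predictable artifact classes,
check each survivor against the sample's chromosome-banding karyotype, and
assign a three-tier priority with full junction annotation.

## Who this is for

Groups running ChimeraScan/deFuse-style fusion callers on small AML (or
similar) cohorts where each sample also has an ISCN karyotype and,
optionally, an upstream driver-score prioritizer (Pegasus/Oncofuse-style
probability, consumed as input and never computed here). The output is a
short, auditable candidate list for RT-PCR/Sanger validation, with a
machine-readable reason for every rejection.

## The model

Candidates from all callers are merged (same sample, same unordered pair,
breakpoints within 10 bp), then flagged — never deleted — by two filter
layers:

* core: no split-read support; unannotated partner; pair present in a
  healthy-sample panel; unreliable structure (breakpoint outside the gene,
  or the 5' partner read against its own transcription);
* cohort: promiscuous partner (static list `HBB HBA HBD MPO DLG2`, or ≥ K
  partners across the cohort, K = 3); read-through geometry (same strand,
  colinear, gap ≤ 200 kb); identical pair recurring in ≥ 2 samples.

Unflagged candidates get the highest tier they qualify for:

| tier | gate |
|------|------|
| 1 | a karyotype translocation/inversion pairs the partner chromosomes, bands within 1 major band (same arm) |
| 2 | cryptic, driver score DS ≥ 0.7 |
| 3 | out-of-frame, DS < 0.7 or absent, and a partner is a tumor suppressor (loss-of-function rescue) |

Junction annotation: with `c5` the donor coding bases retained at/5' of the
junction and `s3` the acceptor coding bases removed by it, the chimera is
in frame iff `c5 ≡ s3 (mod 3)` (both junctions inside their CDS); acceptor
exon-skipping isoforms "type 1..k"; fusion-protein extent
(`floor(c5/3)` donor residues, `total − floor(s3/3)` acceptor residues);
junction microhomology = longest common suffix of donor context and the
bases 5' of the acceptor junction (the junction-sliding definition); and,
for intrachromosomal colinear flanking-gene fusions, the implied
interstitial deletion with the genes it encompasses.

## Worked example

The packaged `paper_fixture()` encodes a published eight-sample AML cohort:
its karyotypes, the validated fusions with their reported driver scores,
and gene stubs at the printed GRCh37 coordinates.

```r
library(fusiontriage)
fx  <- paper_fixture()
res <- run_pipeline(file.path(fx$dir, "config.json"), quiet = TRUE)
res$table[, c("sample_id","gene5","gene3","tier","frame","n_isoforms","deletion_interval")]
#>    sample_id  gene5  gene3   tier        frame n_isoforms    deletion_interval
#> 1:       125  PUF60   TYW1  tier3 out_of_frame          1
#> 2:        20    CPD   PXT1  tier1     in_frame          1
#> 3:        20   SAV1   GYPB  tier2     in_frame          2
#> 4:        21   OAZ1   MAFK  tier2     in_frame          2
#> 5:     59810  CNOT2    WT1  tier1 out_of_frame          1
#> 6:     59810   ZEB2 BCL11B  tier1     in_frame          3
#> 7:     68187   UTP6  CRLF3  tier3 out_of_frame          2 17:29153701-30188249
#> 8:        84   CBFB  MYH11  tier1     in_frame          2
```

Reading the table: the three karyotype-concordant fusions (including the
inv(16) positive control in sample 84) are tier 1 regardless of driver
score; the two cryptic high-DS fusions (0.87, 0.82) are tier 2; the two
out-of-frame tumor-suppressor fusions (DS 0.35, 0.41) are rescued as
tier 3. The ZEB2–BCL11B junction is expressed as 3 acceptor-exon-skipping
isoforms, and the UTP6–CRLF3 row carries an inferred interstitial deletion.
That deletion, recomputed from the printed gene boundaries:

```r
ms <- read_gene_models(file.path(fx$dir, "genes.gtf"))
f  <- data.frame(gene5 = "UTP6", gene3 = "CRLF3",
                 chrom5 = "chr17", pos5 = 30188190L, strand5 = "-",
                 chrom3 = "chr17", pos3 = 29153778L, strand3 = "-")
infer_interstitial_deletion(f, ms)
#> <deletion_call> 17:29153779-30188189 (1,034,411 bp, 1.0 Mb); encompasses: NF1
```

The clinical side of the same cohort:

```r
s <- cohort_summary(read_cohort_table(file.path(fx$dir, "cohort.csv")))
#> median age: 59 | FLT3 altered: 0.8 | ITD-alone VAF>0.5: 2
```

Synthetic cohorts with planted ground truth (every filter branch, planted
tiers, engineered microhomologies, a planted deletion) come from
`generate_cohort(seed)`; `run_pipeline()` on the emitted `config.json`
recovers the truth exactly — this is the backbone of the test suite.

There is also a small CLI: `fusion_cli(c("simulate","--seed","1","--out","d"))`,
`fusion_cli(c("run","--config","d/config.json"))`, plus `validate` and
`show-config`.

## Layout

- `R/` — readers (fusion tables in two caller dialects, GTF, UCSC
  cytobands, karyotypes, panels, CN segments), ISCN parser, filters,
  concordance, consequence annotation, deletion inference, tiering,
  synthetic-data generator, pipeline + CLI.
- `tests/testthat/` — unit, property and acceptance suites (oracle-backed:
  junction-sliding microhomology, translate-and-scan frame, brute-force
  interval queries, 20-seed planted-truth recovery).
- `vignettes/fusion-triage-methods.Rmd` — the model, its assumptions,
  parameter defaults and limitations.
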
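---
title: "Methods: fusion-transcript triage, tiering and junction annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion-transcript triage, tiering and junction annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusiontriage)
```

## The problem

RNA-seq fusion callers (ChimeraScan, deFuse and kin) emit hundreds to
thousands of candidate chimeric junctions per leukemia sample, most of which
are read-through transcripts, template-switching artifacts, mapping biases
or library contamination. Wet-lab validation is only feasible for a handful
of candidates, so the practical problem is triage: remove the predictable
artifact classes, then rank what remains by independent evidence.
`fusiontriage` implements that triage as a deterministic, fully inspectable
pipeline for small AML-style cohorts where each sample also has a
chromosome-banding karyotype.

## The filter cascade

Candidates from all callers are merged (same sample, same unordered partner
pair, breakpoints within 10 bp collapse to one record keeping maximal read
support; driver scores disagreeing by more than 0.05 raise the informational
`ds_conflict` flag). Filters then *flag* rather than delete — the tier-3
rescue below needs low-scoring fusions to survive until tiering, and a
flagged row with its reason trail is more auditable than an absent one.

Per-candidate (core) flags:

* `no_split_reads` — fewer than `min_split_reads` (default 1) reads carry
  the junction itself. Spanning pairs alone locate a junction only to within
  a fragment length and are compatible with many artifacts.
* `unannotated_partner` — a partner symbol absent from the gene models.
  Unknown symbols are a filter criterion, not an input error.
* `healthy_panel` — the unordered pair occurs in a user-supplied list of
  fusions seen in healthy samples.
* `unreliable_structure` — a breakpoint falls outside the named gene's span,
  or the junction strand runs against the 5' partner's transcription
  direction. The 5' partner must contribute a transcript prefix driven by
  its own promoter; an inverted *donor* has no such prefix. An inverted
  *acceptor* is tolerated here (the genomic junction still transcribes) and
  is handled by the frame annotation instead — see below.

Cohort-level flags:

* `promiscuous_gene` — a partner in the static list (`HBB, HBA, HBD, MPO,
  DLG2`: highly expressed blood genes that recur in artifact chimeras) or
  with at least K distinct partners across the cohort. K defaults to 3: in a
  cohort of a few heterogeneous samples, three distinct partners for one
  gene is far likelier library artifact than three independent
  rearrangements. Configurable.
* `readthrough` — partners on the same chromosome and strand, the 5' gene
  upstream of the 3' gene in transcription, inter-gene gap at most
  `readthrough_max_gap` (default 200 kb). This is the geometry of
  transcription running past a terminator into the downstream neighbor, the
  single most common false-positive class.
* `cohort_recurrent` — the identical pair in two or more samples. For rare
  or previously undescribed fusions in a small heterogeneous cohort, true
  recurrence is implausible; recurrence indicates a systematic artifact.

Flags are independent predicates of the merged table, so core and cohort
filters commute and re-application adds nothing (both properties are
tested).

## Cytogenetic concordance and the tier system

Surviving candidates are assigned the highest tier whose gate they pass:

1. **Tier 1 — cytogenetically concordant.** Some translocation-like event in
   the sample's karyotype (translocations, inversions, and translocations
   embedded in derivative-chromosome tokens) pairs the two partner
   chromosomes with compatible bands. Band compatibility is computed on
   major-band integers of the same arm, ignoring sub-bands, with a default
   tolerance of one major band. The coarseness is deliberate: banding
   resolution is limited, and published karyotypes routinely call a gene at
   q22.3 as q21–q23. Tolerance 0 matches are a strict subset of tolerance 1
   matches. Inversions match only intrachromosomal junctions whose two
   breakpoints fall in the two inversion bands. Gains, losses, markers and
   any token outside the supported ISCN subset never match — the parser
   preserves them as `other` rather than guessing intent.
2. **Tier 2 — high driver score.** Cryptic at banding resolution, but the
   upstream prioritizer's oncogenicity probability (consumed as input,
   never computed here) is at least `ds_threshold` (default 0.7, the
   conventional operating point). The comparison is `>=`; the synthetic
   cohort plants a candidate at exactly 0.7 to pin it.
3. **Tier 3 — tumor-suppressor rescue.** Out-of-frame, driver score absent
   or below threshold, but either partner is on the tumor-suppressor list.
   An out-of-frame fusion is a perfectly good loss-of-function allele for a
   tumor suppressor even when no chimeric protein is made.

Any rejecting flag forces `rejected` regardless of evidence; the
counterfactual ("would have been concordant") is logged in the reason trail.
A fusion with no driver score can reach tier 1 or tier 3 but never tier 2.

## Reading frame at the junction

With `c5` the coding nucleotides of the donor retained at or 5' of the
junction (along transcription) and `s3` the acceptor coding nucleotides
removed by the junction, the chimera is in frame iff `c5 ≡ s3 (mod 3)` and
both junctions lie inside their CDS. Other statuses: `promoter_swap` when
the acceptor junction is at or upstream of the acceptor CDS start (intact
acceptor ORF under a foreign promoter), `noncoding` when either model lacks
a CDS, `undetermined` when an intronic breakpoint cannot be snapped or the
donor is inverted. An inverted acceptor yields an antisense suffix and is
reported `out_of_frame` — the same call the field makes for such junctions.

Intronic genomic breakpoints are snapped to splice-consistent exon
boundaries (donor: nearest exon end upstream in transcription; acceptor:
nearest exon start downstream), because validated fusion *transcripts* join
exon to exon even when the DNA breakpoint lies mid-intron. Snapping further
than 500 kb is refused (`undetermined`).

Fusion-protein extent, for in-frame junctions only: `residues5 =
floor(c5/3)` (counting the initiator), `residues3 = total − floor(s3/3)`
where `total` is the acceptor protein length with the stop codon excluded
(`CDS/3 − 1`). A junction falling mid-codon (`c5 mod 3 ≠ 0`) produces a
donor/acceptor hybrid codon; this is reported as an annotation
(`junction_codon_donor_bases`), never as a frame failure — single-residue
substitutions at validated junctions are documented in the literature.
Counting the stop codon in the acceptor total (as some published figures
do) would shift `total` by one; this package consistently excludes it so
that `residues3 + floor(s3/3) = total` holds exactly.

Acceptor exon-skipping isoforms: a junction in acceptor exon *j* is
enumerated as "type 1" (all exons from *j*), "type 2" (skip one), … up to
`max_skip` (default 2, matching the largest isoform family we model) and
capped by exon availability; each isoform carries its own frame call,
consistent with re-running the frame computation at the shifted junction.

## Junction microhomology

Identical bases flanking a breakpoint make its exact position ambiguous.
`microhomology_length(donor_context, acceptor_context)` returns the largest
`k ≤ max_k` (default cap 20, reported when hit) such that sliding the
junction left by 1..k yields the identical fused sequence — equivalently
the longest common suffix of the donor's terminal bases and the bases
immediately 5' of the acceptor junction. `junction_ambiguity()` adds the
right-slide side; the total is invariant under reverse-complementing the
junction (left and right swap), which is the property the tests assert.
Note one boundary consequence of the sliding definition: a single shared
terminal base is microhomology 1, not 0.

## Interstitial-deletion inference

An intrachromosomal fusion of two same-strand, colinearly transcribable
genes implies loss of everything between the retained segments: from one
base past the junction-proximal boundary of the upstream retained segment
to one base before that of the downstream one, in forward-genome
coordinates. Non-colinear geometry returns a reason (`no_loss_orientation`
etc.), never a call. When breakpoints are intronic or missing, the facing
gene boundaries stand in and the call is tagged `approximate` — the
published 1 Mb flanking-gene case is itself the inter-gene gap. Genes wholly
inside the interval are listed (the tumor-suppressor-bracketing pattern
this check exists for). Optional SNP-array segments classify a call as
`supported` / `contradicted` when loss / neutral-gain segments cover at
least 50% of the interval (a threshold the source material does not state;
50% reciprocal overlap is the package's choice), `untested` otherwise.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort(seed)` writes a fully self-contained bundle: four 160 kb
contigs, ~30 multi-exon genes (120 bp exons, 480 bp introns, 30 bp UTRs —
small but structurally faithful), six cytobands per contig emitted in the
0-based UCSC dialect deliberately to exercise the coordinate conversion,
per-sample karyotypes, both caller dialects (the tier-1 event appears in
both, once with swapped orientation to exercise deduplication), healthy
panel, CN segments and a clinical CSV. One fusion per artifact category is
planted, plus tier-1/2/3 events with frame, microhomology (engineered into
the genome sequence with a forced mismatch one base past the planted
length) and a deletion interval known by construction; planted frames are
derived by independent base-level enumeration over the generated exon
structures, not by calling the annotation code under test. Driver scores
for planted tier-2 events are drawn from U[0.75, 0.98] and one straddle
candidate sits at exactly 0.7; rejected artifacts draw from U[0.05, 0.6].
Because contigs are 160 kb, the emitted config scales the read-through gap
to 20 kb (the planted flanking-gene pair sits ~88 kb apart, preserving the
real-genome proportion where 1 Mb ≫ 200 kb).

What a green synthetic run establishes: every pipeline branch fires on the
intended candidate and only there, across seeds. What it does not
establish: behavior on real caller output (quality strings, multi-mapping
ambiguity, incomplete gene models), ISCN notations outside the supported
subset, or calibration of the driver score itself, which this package
consumes but never computes.

The companion `paper_fixture()` is non-random: it encodes the published
cohort's eight karyotypes, the printed chr17 coordinates (flanking-gene
pair and the bracketed tumor suppressor), junction stubs engineered to the
published arithmetic (72 donor coding nt = 24 residues; 57 acceptor nt
removed = first fused codon 20; 2469 nt acceptor CDS; three acceptor
isoforms), and the five-patient mutation table. Stub coordinates that the
source did not print are synthetic and band-consistent, nothing more.

## Numerical and design choices

* Coordinates are 1-based inclusive on the forward strand everywhere
  inside the package; 0-based inputs are converted at the boundary.
  `pos5` is the last retained donor base, `pos3` the first retained
  acceptor base, making microhomology and deletion arithmetic
  strand-uniform.
* Symbols match case-insensitively with version suffixes stripped.
* The run configuration is JSON (`jsonlite`), not YAML: no YAML parser is
  available in the supported dependency set, and the config is flat enough
  that the format carries no cost.
* Ties in representative-transcript selection resolve to the longest CDS,
  then transcript id — deterministic for a fixed model set.
* Karyotype clones are matched as a union; with a normal main clone and an
  abnormal sideline, the sideline's translocations still count (which clone
  drove the published tier-1 calls is not stated; the union reproduces
  them).
* Reciprocal fusions (A–B and B–A in one sample) are tiered independently;
  the report does not yet link them — a known limitation.
* Band-range tokens (`q14-q23`) match if any major band in the range is
  within tolerance.

## Known limitations

ISCN coverage is the subset needed for concordance (no `ider`, `idic`,
`ins`, fragile sites); everything else degrades to a preserved,
non-matching token. Frame calls assume the junction uses annotated exon
boundaries after snapping. The healthy-panel and tumor-suppressor lists are
inputs; the package ships none. No BAM/FASTQ processing, no caller
execution, no driver-score computation, no expression or enrichment
analysis.
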
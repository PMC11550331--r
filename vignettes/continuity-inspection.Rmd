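---
title: "Assessing telomere-to-telomere continuity from curated long-read coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing telomere-to-telomere continuity from curated long-read coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2tqc)
```

## The problem

A chromosome-scale assembly whose contig N50 equals its chromosome N50 looks
"finished" to every length-based statistic, yet can still hide unresolved
joins — rDNA arrays, centromeric satellite, segmental duplications — that no
raw read actually spans. Because N50, NG50 and auN are computed from the
assembly alone, they are also inflatable by simply deleting or papering over
gap characters. The only way to certify local continuity is to return to the
evidence: long reads mapped back onto the assembly. `t2tqc` does exactly
that, at single-base resolution, and condenses the outcome into a 0–100
continuity score per genome and per chromosome.

The guiding principle is *positive evidence over anomaly detection*. Rather
than flagging statistical outliers in raw coverage (which confounds
sequencing bias, mapping bias and real assembly error), the pipeline first
reduces the alignments to a high-confidence, multi-aligner-consistent subset
and then asks a simple question at every base: does at least a reasonable
amount of curated evidence span this position?

## Pipeline and assumptions

**Filtering.** Unmapped, secondary and supplementary alignments are
discarded; supplementary records are excluded because the clipped-fraction
rule below judges each read as a whole, and split alignments would evade it.
Three per-alignment thresholds follow, each strict in the stated direction:

| parameter          | default | rejects                            |
|--------------------|--------:|------------------------------------|
| `min_mapq`         | 30      | MAPQ 29, keeps 30                  |
| `min_identity`     | 0.90    | identity 0.899, keeps 0.900        |
| `max_clip_frac`    | 0.10    | clip fraction 0.101, keeps 0.100   |

Identity is `1 − NM / alignment columns` (matches + mismatches + inserted +
deleted bases). When a PAF lacks `NM`, the gap-compressed divergence tag
(`de`) substitutes; when neither exists the identity rule is skipped for
that record and a warning counter is reported — silently discarding every
record from an aligner that omits both tags would be worse than admitting
the rule cannot be evaluated. Hard-clipped bases count toward both the
clipped bases and the reconstructed read length, making the clip fraction
invariant to how the aligner encoded its clips.

**Two-aligner integration.** Mappers disagree most exactly where assemblies
are hardest to validate. For each read the two aligners' filtered primary
placements are compared by reciprocal overlap, measured against the *longer*
interval — the stricter symmetric choice, which also stops a short nested
fragment from trivially "agreeing" with a long placement. Consistent pairs
(≥ `min_overlap_frac`, default 0.90) contribute aligner A's interval:
taking the intersection instead would shave both ends of the supported
interval on top of the end-trimming below, double-penalizing region
boundaries. Reads placed confidently by only one aligner are rescued when
that aligner's MAPQ ≥ `rescue_mapq` (default 50); rescue consults only
alignments that already passed filtering, so a heavily clipped alignment is
never resurrected by MAPQ alone. Setting `rescue_mapq = Inf` disables the
rule. Platforms (HiFi, ONT) are curated independently and pooled by simple
union, so combined coverage at any base is at least each platform's own.

**Depth.** Every curated interval loses `trim_len` bases (default 5) from
each end before per-base counting. The trim removes residual clipped or
frayed alignment termini, so that a join is only counted as supported by
reads that genuinely extend across it. Five bases is negligible against
reads of 10–100 kb while still breaking spurious single-base chains; the
value is fully configurable, and the contract is checked against naive
per-base counting in the tests. The genome mean depth is taken over *all*
assayed bases, zeros included, giving the low-depth threshold a single
genome-wide scale; per-chromosome means are reported but not used for
calling.

**Issue calling.** Positions with depth 0 ("zero") or `0 < depth <
low_depth_frac × mean` ("low", default fraction 0.1, strict inequality) form
maximal runs. One deliberate exception: a zero run confined entirely to the
first or last `trim_len` bases of a sequence is *not* called. End-trimming
makes those bases unassayable — no alignment, however perfect, can ever
cover them — so flagging them would mark every telomere of every assembly,
including a flawless one. A genuine terminal gap that extends past the
margin is kept in full, margin bases included. Issues on the same chromosome
separated by less than `merge_dist_frac` (default 0.005, i.e. 0.5 %) of that
chromosome's own length are merged transitively; the merged category is
"zero" if any constituent was, since absence of support is the stronger
claim. Scaling the merge distance per chromosome means the same physical gap
merges on a 100 Mb chromosome and stays split on a 1 Mb scaffold, which is
the intended reading of a percentage rule.

**Curated contigs and the score.** Chromosomes are cut at the merged issues;
issues abutting a chromosome end trim the sequence rather than spawn an
empty contig, so a missing telomere does not inflate the contig count. With
`obs_N50`, `obs_num` the curated contig N50 and count and `exp_N50`,
`exp_num` the chromosome N50 and count,

$$\mathrm{score} = 100\,\log_2\!\Bigl(1 + \tfrac{\min(1,\,obs_{N50}/exp_{N50}) + exp_{num}/obs_{num}}{2}\Bigr).$$

The form was chosen for its contract, and the contract is what the tests
pin down: exactly 100 when both ratios are 1; bounded in (0, 100];
increasing in `obs_N50` and strictly decreasing in `obs_num`; still
sensitive through the count ratio after N50 saturates; invariant under
rescaling all lengths. The N50 ratio is capped at 1 because the curated
assembly is *shorter* than the original (issue bases are removed), which
lowers the half-length threshold in the N50 computation and can push the
curated N50 arithmetically above the chromosome N50 of the full-length
assembly — a saturation artifact, not extra continuity, and uncapped it
would break the 0–100 range. The formula lives in one function
(`continuity_score`) so that an alternative definition can be substituted
without touching the pipeline. Per-chromosome scores use each chromosome's
own theoretical maximum (`exp_num = 1`, `exp_N50` = chromosome length); a
chromosome retaining no curated contig at all scores 0 by convention.

One consequence worth knowing: an issue that only trims a chromosome end,
on a chromosome small enough not to carry the N50, changes neither ratio and
leaves the genome score at 100. Only the per-chromosome score registers it.

## What the synthetic data emulates — and what it does not

All tests and benchmark experiments run on generated fixtures
(`fixture_spec()`, `make_assembly()`, `make_alignments()`): random-base
multi-chromosome assemblies and tiling read alignments at a target depth,
emitted identically as PAF and SAM for both simulated aligners, with four
defect types — uncovered intervals (zero coverage), fractional low-coverage
intervals, low-MAPQ intervals (for one or both aligners), and
discordant-placement intervals where aligner B relocates reads to another
chromosome while aligner A keeps high MAPQ (the rescue path). Everything is
seed-deterministic down to the bytes.

The generator reproduces alignment *structure*, not sequencing physics: no
base-error process beyond a constant per-read `NM`, no read-length
distribution, no compositional coverage bias, no true repeats (reads are
placed, not mapped). Consequently a passing suite demonstrates that the
filtering, integration, depth, calling and scoring machinery implements its
contract — it does not demonstrate that a particular aligner/platform
combination will expose a particular biological artifact. Defect boundaries
also blur outward by up to one read spacing plus the trim length, because
dropping every read that touches a defect removes support slightly beyond
it; detection is therefore evaluated at locus level (any overlap with the
truth interval padded by 10 kb) rather than at base level, consistent with
how simulated-issue benchmarks exclude flanking regions around known loci.

For the structural-issue experiment (`injection_experiment()`), insertions
(10–50 kb, sequence copied from random donor loci) and deletions (50–100 kb)
are planted in a clean toy genome; alignments are then regenerated from the
mutated assembly with spanning support removed over each insertion and
around each deletion breakpoint — the footprint such events leave when reads
from the unmutated source are mapped back. Deletion truth loci are 1 bp
breakpoints; insertion loci are the full inserted interval.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere internally, including BED and
  BedGraph output; printed summaries are human-oriented but carry the same
  convention.
- Depth is computed by difference arrays; agreement with naive per-base
  counting is asserted over randomized instances (≤ 10 kb targets, ≤ 200
  intervals, trims 0/1/5).
- Duplicate primary alignments for one read from one aligner resolve to the
  highest MAPQ with a warning; ties keep the first encountered.
- An empty curated set yields an all-zero profile with mean 0; the low
  threshold is then 0 and only zero-runs are callable.
- Merging is idempotent and order-independent; contigs plus issues tile each
  chromosome exactly (checked base-wise).
- Problem sizes in the routine suite are deliberately small — toy
  chromosomes of 50–200 kb with 10 kb reads at depth ~10, a thousand
  randomized score-range fixtures, fifty replicates per gap count in the
  fragmentation experiment, two 1.5 Mb chromosomes in the injection
  experiment — chosen so every property is exercised (including multi-read
  pileups, merges across defects, and both platforms) while the whole suite
  runs in well under a minute of compute.

## Known limitations

- The continuity score formula is this package's own calibration of the
  stated contract; other tools computing a 0–100 continuity score need not
  agree numerically, and cross-tool comparisons should be made on the issue
  regions, which are defined unambiguously.
- Collapsed repeats do not produce zero or low curated coverage (they
  typically raise it) and are invisible here; clipping-signal and
  coverage-excess detectors are complementary.
- Highly repetitive loci such as 45S rDNA arrays may never attract
  high-confidence spanning alignments even when correctly assembled; an
  issue call is a flag for manual review, not a verdict.
- Two aligners are integrated pairwise; a third aligner would currently be
  folded pairwise against aligner A rather than by three-way consensus.
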
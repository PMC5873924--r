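---
title: "splicegauge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicegauge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

splicegauge detects genome-wide alternative-splicing changes — intron
retention (IR), its mirror image "more efficient splicing" (MES), exon
skipping, and alternative donor/acceptor site usage — together with
differentially expressed genes (DEGs), between a mutant and a wild type,
from per-replicate SAM alignments and a GFF3 annotation. The design target
is the splicing phenotype of plant splicing-factor mutants, where IR
dominates and step II (3' splice site) factors can shift acceptor choice by
only a few nucleotides; everything therefore runs on exact junction
coordinates, never fuzzy matching. This vignette records the statistical
model, the tunable parameters, and the design decisions that were genuinely
open, in enough detail to reproduce or challenge each choice.

## Evidence layers

All statistics consume three evidence layers derived from accepted
alignments:

* **per-base depth** — each base covered by an alignment block adds 1; the
  genome-wide total equals the summed block lengths (a conservation
  invariant the tests enforce);
* **junction observations** — every adjacent block pair of a spliced
  alignment yields one junction (donor = last base of the upstream block,
  acceptor = first base of the downstream block); a read with three blocks
  contributes two junctions;
* **per-gene read counts** — `total` counts any overlap with the gene span;
  `unique` requires containment in exactly one annotated gene. The
  published method does not define "unique read"; containment in a single
  gene is our reading, chosen as the conservative denominator for
  expression ratios, and is flagged here rather than presented as the
  original's intent.

Records enter these layers only after two acceptance filters taken
literally from the mapping protocol the pipeline reimplements: alignment
identity strictly greater than 0.95 with terminal exact-match runs of at
least 4 nt on both ends (applied per record; whether the original applied
the end rule per mate or per pair is unstated), and removal of any
alignment containing a block shorter than 8 nt. The boundary semantics
(0.95 rejected, 4 accepted, 8 accepted, 7 rejected) are contractual and
tested. The two mapping stages themselves (a transcriptome and a genome
aligner) are out of scope: records arrive pre-aligned and the filters are
enforced as pure, order-insensitive predicates, because the filters — not
the aligner binaries — are the reproducible part of the protocol.
Duplicate reads are not collapsed (the protocol mentions no deduplication).

## Intron retention

For intron $i$ with neighboring exons $u$ and $d$, the retention ratio in
one replicate is

$$ r_i \;=\; \frac{\overline{\mathrm{depth}}(i)}
                 {\overline{\mathrm{depth}}(u \cup d)} $$

with the flank average pooled base-wise over both exons (one average over
all flanking exonic bases, not the mean of two exon means; the alternative
reading differs only when the flanks are very unequal, and the choice is
switchable in code). A zero flank average makes the ratio undefined; the
replicate is flagged `NA` and the intron is excluded from testing and
tallied in a skip report — never coerced to 0 or infinity.

Per intron, a two-sided Welch $t$-test compares the mutant replicates'
ratios to the wild-type replicates'. An intron is called IR when
$p < 0.01$ and the mean mutant ratio is at least twice the wild-type mean,
MES when it is at most half. The test runs on raw ratios by default;
whether the original used raw or log ratios is unstated, so a log option
(`on_log`) exists. No multiple-testing correction is applied anywhere —
the published rule uses raw $p < 0.01$ thresholds throughout, and we
mirror it; the fold gate makes the combined call conservative under the
null (the tests verify a genome-wide null call fraction at or below 0.01),
but users should treat the output as a screen, not an FDR-controlled list.

Genes with multiple isoforms are handled by pooling introns over
transcripts and deduplicating by coordinates; an intron's neighboring
exons come from the transcript that contributed it. The original analysis
does not state how multi-isoform genes were collapsed; pooling is our
choice and is visible in the output metadata.

## Alternative-splicing events

Candidates are junction-defined. For every internal exon, an observed
junction joining its two flanking exons defines an exon-skipping
candidate. For every observed junction that differs from an annotated
intron's boundaries while both endpoints fall within that intron's
neighboring-exon pair (and the removed region overlaps the intron), an
alternative donor/acceptor candidate is created; the side label is
strand-aware (the donor is the 5' boundary in transcription direction),
and `alt_both` marks junctions differing at both ends.

Each candidate is scored by two per-replicate ratios:

$$ \mathrm{AS\ ratio} = \frac{S + 1}{N + 1}, \qquad
   \mathrm{expression\ ratio} = \frac{S + 1}{U + 1} $$

where $S$ is the count of supporting junction reads, $N$ of non-supporting
junction reads, and $U$ of reads unique to the gene. For exon skipping,
supporting reads use the flank-joining junction and non-supporting reads
are those linking the skipped exon to either flank; for alternative sites,
supporting reads carry the novel junction and non-supporting reads the
annotated one. The published definition's parenthetical does not say which
phrase defines which side of the ratio; our reading is the one that makes
both ratios monotone in event usage, and it is recorded here as a design
decision. The pseudocount of 1 (configurable) keeps zero-denominator
events testable and symmetric; the original takes logs of these ratios
without stating a zero policy. Both ratios are log2-transformed and
compared between conditions with Welch $t$-tests; an event is **reported**
only when both $p$-values are below 0.01, and classified *enhanced* or
*reduced* when the mean mutant expression ratio is at least twice, or at
most half, the wild-type mean. Candidates with zero supporting reads in
every replicate of both groups are untestable and never enumerated.

An optional exclusion list (gene ids or intervals) drops loci before
testing — the pipeline-level stand-in for removing second-site splice-site
mutations discovered by genome re-sequencing of a mutagenized line.

## Differential expression

Counts (unique reads per gene) are normalized by TMM — weighted trimmed
mean of M-values with the standard settings: reference sample chosen by
the 75th-percentile rule, 30% two-sided trim on M, 5% on A, inverse
asymptotic-variance weights, zero-count genes excluded, factors rescaled
to geometric mean 1. The in-package implementation follows the published
definition and is verified in the tests against an independent reference
implementation to 1e-8. logCPM uses a 0.5 prior:
$\log_2\!\big((c + 0.5)/(\mathrm{lib}\cdot f + 1) \cdot 10^6\big)$, and
RPKM is $2^{\mathrm{logCPM}} / (L/1000)$ with $L$ the union-exon gene
length (the standard denominator; the source protocol is silent). The
precision-weighting step of the upstream protocol is omitted: the DEG test
operates on the RPKM values directly and never consumes the weights. DEGs
are Welch-tested on RPKM per gene (a config switch tests
$\log_2(\mathrm{RPKM}+\varepsilon)$ instead, since "t-tests on RPKM
values" is ambiguous), and called up/down at $p < 0.01$ with fold change
$\ge 2$ (mutant over wild type). Welch's unequal-variance form is used
everywhere because $n = 3$ biological replicates with no variance pooling
is the realistic regime; the degenerate case (both groups zero variance,
equal means) is defined to $p = 1$ so identical groups never produce
calls.

## The reporter locus

The dual-intron reporter emulates a GFP-based splicing readout: one
pre-mRNA with three variants — unspliced, spliced at a canonical intron,
or spliced at a non-canonical intron whose 3' splice site lies only 3 nt
away (offset configurable; the two introns share their donor by default).
Quantification is purely junction-exact: a junction read matches at most
one variant because both boundaries must match, so the 3 nt acceptor
offset is resolved without error by construction. Unspliced evidence is a
contiguous read spanning the canonical donor boundary by at least 8 nt on
each side — the same credibility threshold as the block filter; how the
original counted unspliced transcript from RNA-seq is unstated, so this
donor-boundary rule is a declared proxy. Percentages are computed per
replicate over the three-class total and then averaged within condition;
junction reads matching neither variant are reported separately, never
merged. Default generative proportions are wild type 55/22/23 and mutant
50/47/3 (unspliced/canonical/non-canonical) — the shift this class of
step II mutant produces: canonical splicing nearly doubles while the
non-canonical variant collapses.

## The synthetic cohort generator

The generator exists so that every statistic above has a recoverable
ground truth without any external data. It emulates the study design —
two conditions, three biological replicates each, multi-exon genes,
IR-dominant planted changes, and the reporter locus — not real genomes:
sequence content is random fixed-seed nucleotides (no splice-site motifs;
no downstream stage reads sequence), there is no sequencing-error or
quality model, fragments are single-end, and genes are laid out
non-overlapping on one synthetic chromosome. Passing tests therefore
demonstrate the correctness and calibration of the statistics under the
generative model, not robustness to real-data artifacts (ambiguous
multi-gene placement, positional bias, indels).

Defaults, with units and rationale:

* `replicates = 3` per condition — the study design ("biological
  triplicates"); 2 is the floor for a $t$-test.
* `read_len = 50` nt single-end — the short-read regime of the assay this
  emulates; at fixed coverage, shorter reads mean more independent
  fragments, which is what powers replicate-level ratio tests (see the
  power note below).
* `exon_len` 150–400 nt, `intron_len` 250–450 nt — within the observed
  range for plant genes; the generator deliberately sits in the
  longer-intron regime where the retention estimator integrates enough
  fragments per intron (see below).
* `retention = 0.12` — baseline probability that a fragment retains a
  given intron, in both conditions; partial retention is ubiquitous in
  plant transcriptomes and a nonzero baseline is also what makes MES
  plantable (a retained fraction that *drops*).
* `expression` — mean fragments per gene per replicate (Poisson), with
  per-gene per-replicate log-normal noise of sd 0.1 on the log2 scale so
  $t$-tests see realistic within-group variance (exactly replicated
  replicates would make them degenerate).
* `min_anchor = 8` nt — fragment placements that would create an alignment
  block shorter than this are not drawn, mirroring the 8 nt block filter:
  a junction-spanning read with a 5 nt overhang would be generated, then
  discarded by the filter, and the generator's junction log would no
  longer round-trip through the pipeline.
* planted events: IR/MES retention fold 5, alternative-site usage
  0.05 vs 0.50, skip usage 0.05 vs 0.40, DEG fold 4 — strong but not
  caricatural effects, sized so a 3 vs 3 design can see them.

Two generator behaviours deserve emphasis because they are easy to get
wrong:

*Length-weighted isoform sampling.* Fragment counts per realized isoform
are proportional to transcript length (a shearing model). With uniform
per-isoform sampling the longer, intron-retaining isoform is
under-represented *per base*, and the measured depth ratio systematically
underestimates the generative retention fraction (we measured 0.061 for a
nominal 0.08 before adopting length weighting). With length weighting the
expected ratio equals the retention fraction, up to the transcript-end
coverage ramp: terminal exons lose roughly $(\mathrm{read\_len}-1)/2$
bases of average coverage at each transcript end, which inflates ratios of
terminal-flank introns by ~10% at these parameters. That ramp is a real
property of uniform fragmentation, not a bug; the generator oracle tests
therefore assert on introns whose flanks are internal exons.

*Anchored reporter reads.* Reporter fragments are drawn spanning their
variant's diagnostic donor boundary with at least the anchor overhang on
each side, at a uniform offset. Every reporter read is then informative,
and class counts are exactly multinomial in the generative proportions —
so the quantifier's percentages are unbiased estimates of them. Uniform
whole-transcript placement would instead bias the three-class percentages
by variant length (the unspliced transcript is the longest), conflating
abundance with geometry.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GFF3/SAM convention); any
  half-open arithmetic is internal.
* Welch $t$: two-sided; $p := 1$ when both groups have zero variance and
  equal means, $p := 0$ when zero variance and unequal means (a difference
  with no within-group noise); df by Welch–Satterthwaite.
* TMM: a sample whose finite trimmed M-values are all within $10^{-6}$ of
  zero gets factor exactly 1, so identical and globally rescaled columns
  are fixed points. Invariance of downstream calls under rescaling is
  exact only as the logCPM prior vanishes (the 0.5 pseudocount does not
  scale with the library).
* Result tables are sorted by (chrom, start/donor, gene, type) with
  explicit tie-breaks; the pipeline has no internal randomness, so
  identical config and inputs give byte-identical reports.
* Undefined ratios, all-zero samples, out-of-range indices and infeasible
  generator configurations raise typed errors or skip reports — nothing is
  silently coerced.

## Problem sizes and calibration checks

The calibration and recovery checks shipped with the package run at desk
scale, chosen to exercise the genuine statistical regime while staying
quick on one CPU: null calibration and parameter recovery each use 500
single-intron genes at 50x exon coverage, 3 vs 3 replicates; recovery
plants a 5x retention fold in 50 of 500 introns. At the default generator
settings this design gives the retention test near-complete sensitivity
with a false-call rate held under 1% by the fold gate — a figure that came
out of a design-stage power grid over read length, intron length and
baseline retention (read length is the strongest lever: at fixed coverage,
power scales with the number of retained fragments per intron,
$\mathrm{retention} \times \mathrm{depth} \times
(\mathrm{intron} + \mathrm{read}) / \mathrm{read}$). The same grid showed
that with 75–100 nt reads and 150–350 nt introns at 8% baseline retention,
3 vs 3 Welch testing cannot reach 90% sensitivity at this depth — worth
knowing when porting the thresholds to shallow real data.

## Known limitations

* Raw $p < 0.01$ with no FDR control, inherited from the published rule.
* IR testing is intron-local; a transcript-level model (e.g. isoform EM or
  PSI) would share information across junctions and is out of scope.
* The "unique read" definition, the supporting/non-supporting assignment,
  and the unspliced-reporter rule are declared readings of an
  under-specified protocol (flagged above), not reverse-engineered truth.
* The generator's realism gaps listed above bound what green tests imply
  about real libraries.
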
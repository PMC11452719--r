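---
title: "Single-cell small RNA quantification: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell small RNA quantification: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncatlas)
```

# Scope

`sncatlas` re-implements, as composable R functions, the computational
pipeline used to quantify small non-coding RNAs (sncRNAs) in single cells
from Small-seq libraries and to analyse the resulting expression matrices
in an early-embryo setting: read preprocessing, best-stratum alignment with
soft-clip rescue, directional UMI deduplication, hierarchical biotype
annotation, isomiR and tRNA-fragment classification, cell QC and Wilcoxon
differential expression, pseudotime branch alignment with pattern
clustering, pseudobulk miRNA–target anticorrelation, and a four-criterion
filter for novel miRNA candidates. A synthetic-data module generates
Small-seq-structured reads with a planted per-molecule ground truth so
every stage is verifiable end to end.

Out of scope by design: embedding/clustering (cluster labels and
pseudotimes are inputs), principal-curve fitting, hairpin discovery and
folding (only the candidate table is filtered), and target-site prediction
(the pair table is an input).

# Read model and preprocessing

A Small-seq read is modelled as

```
8 nt UMI | 2 filler bases | insert | (oligo-dA) | 3' adapter
```

`extract_umi()` moves the first 8 nt into the read name
(underscore-delimited, so it survives a SAM round trip) and discards the
next 2 bases. `trim_read()` finds the 3' adapter by semi-global matching
with mismatch budget `floor(0.1 × overlap)` and minimum overlap 3, no
indels — the dominant behaviour of cutadapt at these read lengths, where
indels are rare. A read is kept only when the remaining insert is 18–81 nt
long *and* at least 10 tail bases were removed, which guards against
reads that never reached the adapter.

**PolyA handling.** An adenosine run abutting the adapter is part of the
tail and is removed with it — but only when the run is at least 4 nt.
Runs of 1–3 terminal adenosines are left on the insert: they are exactly
the size range of biological 3' non-templated additions (NTAs), and in a
polyadenylated protocol nothing else distinguishes them from the tail.
This 4 nt boundary is the package's resolution of a genuine
identifiability limit: a terminal A-run longer than 3 nt *cannot* be
attributed between template, NTA and tail. Consequently the simulator (i)
emits adapter-only tails by default (`polya_tail_length = 0`,
configurable) and (ii) keeps A/T homopolymer runs of 4+ out of the
synthetic genome, so that on synthetic data the attribution is always
well-defined. Real genomes contain such runs; on real data molecules
ending in long templated A-runs are under-recovered by any pipeline with
this read structure, and passing the package's exact-recovery tests does
not say otherwise.

# Alignment rules

`map_full()` reports **all placements in the minimal-mismatch stratum**
with at most two counted mismatches, mirroring bowtie1
`-a --best --strata -v 2 -m 50`; a read whose best stratum holds more
than 50 placements is *suppressed*. Two length-dependent filters then
reject unreliable short placements: reads under 20 nt with any counted
mismatch, and reads of 20–40 nt with two. A mismatch at the read's
3'-terminal base is never counted — this tolerates tRNA CCA maturation
and miRNA 3' modification without losing the placement.

Unmapped reads (including filter rejections) enter `rescue_clip()`:
1, 2, then 3 nt are clipped from the 3' end, each attempt allowing one
counted mismatch, stopping at the first success; if all fail the same is
done from the 5' end of the original read. Clipped bases stay attached to
the record because they feed NTA calling. Numerical/behavioural choices:

* Total clip per end is capped at 3 nt, matching the ±3 isomiR window.
* 3' clipping is exhausted before 5' clipping; combined 3'+5' clips are
  not attempted.
* Placements mapping fewer than 17 nt are discarded; this floor is the
  only filter applied to clipped placements.
* The terminal-base exemption applies only while the original 3' base is
  part of the aligned core (so for 5' clips but not 3' clips).
* Suppression is terminal at any stage: a suppressed read is not rescued
  further, as suppressed reads never reach a bowtie unmapped output.
* Reporting order is (chromosome, start, strand), for determinism.

One behavioural consequence worth knowing: with the one-mismatch
allowance, a read with a 2 nt non-genomic tail typically maps after a
*single* clip, carrying the residual tail base as an aligned terminal
mismatch. NTA calling is designed around this (below). The aligner is a
brute-force vectorised scan — adequate and exact at the package's toy
genome scale; it makes no performance claims.

# Directional UMI deduplication

Reads are grouped per cell by (chromosome, strand, template 5' position),
the template position being the 5' end of the aligned segment adjusted
for a 5' clip; multi-mapped reads group by their lexicographically first
placement. Within a group, UMIs are clustered with the directional rule:
an edge runs from UMI *a* to UMI *b* when Hamming(a, b) ≤ 1 and
count(a) ≥ 2·count(b) − 1; clusters grow breadth-first from count maxima
processed in decreasing-count order (ties broken lexicographically), so a
UMI reachable from two maxima joins the higher-count one. Each cluster is
one molecule, represented by the highest-count UMI's first read.
Representatives are then **remapped** from scratch, restoring
multi-mapping information that the per-position grouping had collapsed;
molecules that no longer place are dropped with a tally.

# Hierarchical annotation

Each molecule is assigned to exactly one category. Over all placements,
same-strand overlapping features are collected (any overlap of ≥ 1 bp
counts — the most permissive reading, configurable in principle) and the
category highest in the fixed priority list miRNA, rRNA, snoRNA, snRNA,
tRNA, piRNA wins; mature-miRNA and piRNA assignments additionally require
the molecule to be shorter than 40 nt, and miRNA assignment requires
overlap with the *mature* interval (not just the hairpin), because isomiR
calling needs the mature reference. Within a category the feature with
the longest overlap wins, ties broken by name — the within-category tie
rule is a package decision, as no rule is prescribed. Whatever remains is
routed, in order, to protein-coding, lncRNA, repeat (each sense before
antisense), pseudogene, and finally "unannotated". Multi-placement
molecules are counted once, never fractionally, so count matrices stay
integer and comparable to a molecule-level truth.

# isomiR and tRF classification

An isomiR record holds end shifts relative to the annotated mature miRNA
(−3..+3, positive = elongation) and the 3' NTA string. The **NTA is the
maximal 3'-terminal run of read bases — soft-clipped or aligned — that
mismatch the genome at their implied positions**; the templated 3' end is
what remains, and both shifts are computed from templated ends in
mature-strand orientation. Calling NTAs from soft clips alone would
systematically miss 1–2 nt adenosine tails, which map full length (the
terminal mismatch is exempt, a second one is tolerated); re-checking
terminal bases against the genome makes the call independent of how the
aligner happened to absorb the tail. 5' clips never produce NTAs.
Molecules shifted beyond ±3 are excluded and tallied.

tRNA-derived fragments are classified by a pure rule table on
(length, shift5, shift3), shifts negative into the gene: 5' halves are
shorter than 50 nt with the 3' end shifted ≤ −10 but not the 5' end; 3'
halves are the mirror image; full-length molecules exceed 50 nt with
neither end shifted ≤ −10. Boundaries are read literally: length exactly
50 nt is unclassified, as are fragments failing all three rules (for
example short internal fragments shifted deep at both ends); both are
tallied. Non-genomic CCA ends are absorbed by the same terminal-mismatch
machinery rather than a special case.

# Expression statistics

Cells pass QC with ≥ 5×10⁵ sequenced reads, mitochondrial UMI fraction
below 25% (mitochondrial means placed on `chrM`/`MT`, configurable) and
more than 100 miRNA molecules — read as total miRNA UMIs, not distinct
species. Features are kept with ≥ 1 count in ≥ 2 cells.

Normalisation uses library-size factors centred on the per-batch median
and rescaled by each batch's depth relative to the shallowest batch, so
factors are comparable across batches and normalised values
(`log2(count/factor + 1)`) of a cell from a 2× deeper batch match its
shallow twin. This is a deliberate, documented simplification of pooled
deconvolution + multi-batch rescaling: it preserves the testable contract
(cross-batch comparability) while keeping the factor model transparent.
Like any library-size scheme it is compositional: a large planted
fraction of differential features shifts the factors and leaks opposite-
sign signal into null features, which is why the calibration tests plant
balanced, small effect fractions.

Differential expression per feature is a two-sided Wilcoxon rank-sum test
(exact enumeration for tie-free groups of ≤ 10, normal approximation with
tie correction otherwise; constant features get p = 1), BH adjustment
across features, log2 fold change as the difference of
`log2(mean(2^norm − 1) + 1)` between groups (the convention of the cited
single-cell toolkit), and a significance call at FDR < 0.05,
|log2FC| > 0.1 (0.25 for ICM-vs-TE gene contrasts) and more than a third
of cells expressing in the favoured group. Markers are one-vs-rest calls
at adjusted p < 0.001 with positive fold change.

# Pseudotime alignment, patterns, targets, novel candidates

ICM and TE pseudotimes are inferred separately and aligned with the
closed form

$$\mathrm{scale} = \frac{Psd_{TE,max} - Psd_{pre,max}}
                        {Psd_{ICM,max} - Psd_{pre,max}},\qquad
  Psd' = (Psd - Psd_{pre,max})\cdot \mathrm{scale} + Psd_{pre,max},$$

applied to ICM cells beyond the pre-lineage maximum; the rescaled ICM
maximum equals the TE maximum exactly, and the transform is the identity
when the branch maxima coincide. A coinciding ICM and pre-lineage maximum
makes the denominator vanish and is an explicit error.

Trajectory-associated miRNAs come from a per-feature linear model of
expression on pseudotime with batch as an additive covariate (a
documented substitute for the cited package-internal routine, keeping its
contract: slope test, BH across features, FDR < 0.05), intersected with
the stage-wise DE set (adjacent stages OR each later stage vs the first —
the OR reading of an ambiguous rule). Their profiles are averaged in 20
equal-width pseudotime bins (a fixed choice for determinism), z-scored
and clustered with k-means (k = 3, 25 restarts, fixed seed); centroids
are labelled C2 (largest positive last-third minus first-third mean,
low→high), C3 (most negative, high→low) and C1 (the remaining,
low→high→low).

Candidate miRNA–target pairs are scored by the Pearson correlation of
pseudobulk mean log-expression across groups, with one-sided t tests
(`t = r√(n−2)/√(1−r²)`) for negative and positive correlation; zero-
variance profiles are skipped with a reason. Novel-miRNA candidates must
jointly (1) be flagged significant by the hairpin randomisation test,
(2) have a positive discovery score, (3) be expressed in at least two
batches or timepoints, and (4) have overlapping reads in ≥ 30 cells with
≥ 75% of all overlapping reads (pooled across cells — the pooled reading
of an ambiguous criterion) in the 20–25 nt window.

# The synthetic-data generator

`sim_config()`/`emit_dataset()` build a toy genome (default 30 kb plus a
small `chrM`) with non-overlapping planted features — hairpins with
nested 21–23 nt matures, tRNAs of 72–76 nt with isotype labels, piRNAs of
28–32 nt, rRNA/snoRNA/snRNA and catch-all tracks — and draw per-cell
molecules from a day-dependent biotype mixture whose defaults follow the
qualitative developmental trends (piRNA/tRNA falling, miRNA/snoRNA rising
across E3–E7) without being calibrated to any dataset's percentages.
Marker miRNAs carry a fixed common base weight and a `2^log2FC` boost in
their lineage; because both lineages boost equally many markers the
boosted mass cancels between denominators and the realised fold change
matches the configured one in expectation. isomiR shifts, NTA runs
(1–3 adenosines) and tRF classes are drawn at configured rates; PCR
copies are 1 + Poisson; UMIs are uniform over 4⁸ or, in collision-free
mode, per-cell codes with a base-4 checksum digit (pairwise Hamming
distance ≥ 2, so the directional rule can never merge distinct
molecules). Default sizes used throughout the tests: 50 cells × 200
molecules for exact-recovery runs, 6 cells × 60 for the shared fixture —
sizes at which every planted event is still individually checkable.

Three generator constraints exist purely to make ground truth
recoverable, and are stated here because they bound what the tests show:
the genome carries no A/T homopolymer run over 3 nt (else templated
terminal A-runs merge with the tail at trimming); the ten bases spanning
each mature miRNA 3' end (covering a −3 shift through a +3 elongation
plus a 3 nt tail) are non-adenosine (else a trimmed mature ending in A
plus an A-tail is byte-identical to a less-trimmed read); and isomiR
draws whose insert would fall under 18 nt are resampled (such reads
cannot survive the length filter by construction; the censored mass at
default rates is ~10⁻³). The generator also does not model
platform-specific error profiles, quality scores, or the mRNA half of a
split-cell protocol. Passing exact-recovery tests therefore demonstrates
correctness of the pipeline's bookkeeping under identifiable conditions,
not robustness to every ambiguity of real data.

# Verification design

Every rule-bearing component is checked against an independent route:
the aligner against a Biostrings-based enumerator applying the same rules
in unrelated code; directional clustering against transitive closure on
an explicit adjacency matrix; the tRF table against a literal transcription
of the rules over the full (length, shift) grid; correlation statistics
against sum-formula Pearson plus numerical integration of the t density;
and the whole read path against planted truth with collision-free UMIs
and zero sequencing error. Statistical components are checked by
calibration (null rejection rate ≈ 5%) and power (planted log2FC = 1
at moderate dispersion, balanced directions) rather than frozen numbers.
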
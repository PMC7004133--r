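---
title: "Comparative LTR retrotransposon dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative LTR retrotransposon dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrdyn)
library(dplyr)
```

## The problem

Two closely related plant genomes — think almond (*Prunus dulcis*) and peach
(*Prunus persica*), which diverged roughly 5.88 million years ago — carry
thousands of long terminal repeat (LTR) retrotransposon insertions. Each
insertion is a molecular fossil: its two LTRs were identical at insertion
time and have diverged neutrally since, so their distance clocks the
insertion age; its flanking sequence identifies the orthologous locus in the
other genome, so each insertion can be classified as shared, lineage
specific, or degraded in one lineage; and resequencing data from cultivar
panels reveal which reference insertions are still segregating within the
species. Put together, these three readouts describe how transposon activity
and loss have shaped the two genomes since their split.

`ltrdyn` implements this comparative analysis as a reusable, tested
pipeline: structural filtering and Copia/Gypsy classification of candidate
elements, LTR-pair dating, cross-species family clustering, orthologous-
locus classification, cohort fixed/polymorphic calls, and TE association of
between-genome structural variants — together with a genome-pair simulator
that provides ground truth for every stage.

## Insertion dating

For an element with LTR sequences $L_5$ and $L_3$, the package computes the
Kimura two-parameter (K2P) distance over the gap-free, unambiguous columns
of their global alignment. With transition proportion $P$ and transversion
proportion $Q$,

$$K \;=\; -\tfrac12\,\ln\!\big((1 - 2P - Q)\,\sqrt{1 - 2Q}\big).$$

Both LTRs accumulate substitutions independently after insertion, so the
expected divergence between them grows at twice the per-lineage rate and the
age estimate is

$$T \;=\; \frac{K}{2r}, \qquad r = 10^{-8}\ \text{substitutions site}^{-1}\,
\text{yr}^{-1}\ \text{by default}.$$

The substitution rate is expressed per year, so the generation time (10
years by default) is carried as metadata only; it does not enter the
formula. Because age is linear in $K$, halving $r$ doubles every age
exactly — a property the tests assert.

Two failure modes are flagged rather than silently propagated: *saturation*
(the logarithm's argument is non-positive, i.e. $1-2P-Q \le 0$ or
$1-2Q \le 0$) and *too-short* comparisons (fewer than 50 usable columns,
where the $\approx 1/\sqrt{n}$ binomial noise on $P$ and $Q$ makes the point
estimate meaningless). Both statuses are excluded from age histograms but
reported.

## Structural detection and filtering

The candidate detector looks for the structural signature directly: two
similar terminal repeats (100–3000 bp, identity $\ge 0.85$) bounding an
element of 1–15 kb. Exact 13-mer self-matches at a compatible spacing seed
candidate repeat pairs; each candidate is refined by local alignment of the
two repeat windows, whose noisy ends are trimmed back to a clean core under
a stricter per-column score. Because an LTR insertion duplicates its 4–6 bp
target site, the detector then scans a small window of boundary offsets for
an exact repeated 5-mer and, when found, anchors the element boundaries on
it; by default candidates without target-site-duplication (TSD) evidence are
dropped. This rule is what suppresses the classic failure mode of
k-mer-seeded detectors — pairing the repeats of two neighbouring copies of
the same family into one giant pseudo-element. Candidates are accepted
greedily (TSD first, then repeat identity, then score) without overlap.
Exact parity with any published detector is not claimed; on simulated
genomes the detector recovers $\ge 90\%$ of planted intact elements with
inter-LTR divergence $\le 10\%$, at $\ge 90\%$ precision against the truth
ledger.

Detected or imported elements then pass the coding-element filters: an
element is dropped if it has no internal protein-domain hit (domain tables
are consumed as input, not recomputed), more than 10% `N` content, more than
50% tandem repeats (period $\le 12$ autocorrelation runs of $\ge 24$ bp — a
dependency-free tandem finder), or exactly one 80/80 genomic match, i.e.
itself. The gap/tandem thresholds are applied to the whole element span, and
the single-hit check counts colinear seed-supported loci rather than full
alignments, which is reliable at these divergences and much cheaper.
Superfamily classification uses the internal domain order on the coding
strand: integrase before reverse transcriptase is Copia, the reverse is
Gypsy; elements missing any of GAG, PR, INT, RT, RH are tagged incomplete.

## Orthologous-locus classification

For each element, 500-bp flanks are mapped onto the other genome by exact
13-mer seeding plus affine-gap extension. A database-style E-value threshold
is deliberately replaced by a deterministic score floor (score $\ge 50$,
identity $\ge 0.75$): it depends on nothing but the two sequences. A flank
hit is *unambiguous* when its best hit out-scores the runner-up by a factor
of 1.2 and covers at least half the flank; flanks with more than five hits
are treated as repeat-dense and the element is left unmapped rather than
forced. A locus is *concordant* when both flanks map unambiguously to the
same sequence and strand, in preserved order, with an inner-edge distance
strictly below 25 kb.

The inter-flank region of a concordant locus is then aligned globally to
the element. Identity $\ge 0.8$ over $\ge 0.8$ coverage (of the longer
sequence — the conservative reading when lengths differ) calls the insertion
*conserved*. Otherwise a short inter-flank span reads as an empty site and
the insertion is *specific*; the cutoff is 100 bp, chosen because an empty
orthologous site should span little more than the TSD footprint, with slack
for small indels. Longer spans failing the alignment are
*partially deleted or rearranged*. The empty-site rule is our own decision
where the method description leaves the specific/partial distinction open;
it is recorded in the outputs.

## Family clustering

Elements of both genomes are pooled and connected whenever their full
sequences (LTRs plus internal region; the full-element choice is flagged in
the report metadata) align with identity strictly above 80% over strictly
more than 80% of the longer length. Clusters are the connected components —
single linkage, the standard 80/80 family practice, chosen because a
pairwise threshold with no linkage statement implies exactly this. The fast
driver exploits that single linkage needs only connectivity: pairs are
tested in decreasing shared-k-mer order and skipped once their members
already share a component, which leaves the partition provably unchanged.
Mixed clusters (members from both genomes) indicate families older than the
species split.

## Cohort polymorphism

Reference insertions are classified against per-cultivar deletion calls:
calls need $\ge 20$ supporting reads and must not fall within 1000 bp of an
assembly gap (`N` run). A deletion and a TE overlap when at least 80% of
*either* interval is covered by the other, and an insertion is polymorphic
as soon as one cultivar carries such an overlapping call. Presence is
inferred only from the absence of a deletion call — read-level evidence is
out of scope — and that asymmetry is stated in the output metadata.
Deduplicated deletion events are additionally summarised by size class
(1–50, 51–500, 501–10 000, 10 001–50 000 bp) with per-class TE-overlap
percentages.

## Structural variants

Between-genome variant tables (Assemblytics-style) are filtered to sizes of
20 bp–25 kb and flagged TE-associated when at least 50% of the variant span
is covered by the merged TE footprint of the appropriate genome: insertions
and repeat/tandem expansions against genome A, deletions and contractions
against genome B. The merged footprint (rather than any single element) is
the permissive, monotone reading of "spanned by a TE": adding annotation can
never unflag a variant.

## The simulator and what it does (not) emulate

`simulate_genome_pair()` builds an ancestral background sequence, plants
insertions of known family, age and fate, and evolves the two lineages
independently for 5.88 My under a per-site K2P substitution process with
total rate $r$ and transition/transversion ratio $\kappa = 2$, using exact
finite-time transition probabilities so successive epochs compose exactly.
Insertions older than the split share their pre-split mutations in both
genomes; each LTR of each copy mutates independently, so the expected
inter-LTR distance of a copy of age $T$ is $2rT$ — matching the estimator's
assumptions, which is precisely what makes dating recovery a fair test.
Every insertion plants a 5-bp TSD; partially-deleted fates remove a central
chunk (50–70%) of the copy in one lineage; `N` runs are planted for the
polymorphism filters; a cohort simulator assigns allele frequencies and
emits per-cultivar deletion calls with Poisson-distributed read support plus
spurious calls at a configurable rate. Everything is reproducible from one
seed, and a truth ledger records ages, fates, coordinates and per-cultivar
presence.

Deliberate idealisations, and hence limits on what passing tests show about
real data: background sequence is i.i.d. (no isochores, no genes, no nested
or fragmented elements other than the planted remnants); TSDs are planted
verbatim rather than diverging with age, which flatters the detector's TSD
gate on old elements; substitution rate is uniform (no rate variation,
no CpG effects); indels are off by default so every coordinate is exactly
mappable (a small-indel mode, default 1% per site in the background, exists
for stress tests); and deletion calls are simulated at the event level, not
from reads. Family copy number per genome is moderate; for genomes with
very-high-copy young families the detector's seed-occurrence cap
(`max_kmer_occurrences`) should be raised.

## Numerical choices and degenerate inputs

Alignment scoring defaults to match $+2$, mismatch $-3$, gap open 5, gap
extend 2 (Needle/BLASTn-like); `N` scores 0 against everything so assembly
gaps are neutral; ties in the DP are resolved deterministically by the
backend. $P$, $Q$ and identity denominators exclude gap and `N` columns.
Empty inputs return empty-but-valid tables throughout; empty cohorts,
out-of-bounds spans and unknown element ids raise classed errors
(`ltrdyn_input_error`, `ltrdyn_config_error`, `ltrdyn_saturation_error`,
`ltrdyn_flank_error`). Coordinates are 1-based inclusive everywhere in R,
matching GFF3/VCF conventions on disk and the IRanges/Biostrings ecosystem
in memory.

## Problem sizes used by the test-suite

The bundled checks run, by choice, at desk scale: the default simulated
genome pair is 2 Mb with 200 insertions across 6 families (the fate mix 50
conserved, 50 + 50 specific, 25 + 25 partially deleted); dating calibration
uses 200 LTR pairs of 1 kb and 200 of 5 kb; the cohort study uses 100
insertions across 10 cultivars with allele frequencies in {1.0, 0.9, 0.5}
and 5% spurious calls; oracle comparisons use 1000 random alignments and
exhaustive enumeration over two-letter sequences of length up to 7. These
sizes give stable statistics for every recovery check while a full run
of suite plus acceptance script stays comfortably under half an hour.

## A worked example

```{r example, eval = FALSE}
library(ltrdyn)

sim <- simulate_genome_pair(sim_config(seed = 1))
ages <- date_elements(sim$elements_a, sim$genome_a)
calls <- classify_orthologs(sim$elements_a, sim$genome_a, sim$genome_b)
tidy(age_by_category(calls, ages, speciation_mya = 5.88))

coh <- simulate_cohort(sim, "A", cohort_size = 10)
status <- classify_fixed_polymorphic(
  sim$elements_a, filter_deletions(coh$calls, sim$n_regions_a), coh$cohort)
plot_polymorphism_ages(status, ages)
```

File-based runs use `write_sim()` / `write_cohort()` and `run_pipeline()`,
which executes annotate → date → cluster → ortho → polymorph → report with
an idempotent manifest, or the thin command-line wrapper in
`inst/scripts/ltrdyn`.
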
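---
title: "Designing and evaluating an evenly spaced SNP array panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating an evenly spaced SNP array panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanel)
```

## The problem

High-density genotyping arrays for non-model species — the motivating case
is the large yellow croaker (*Larimichthys crocea*), a marine aquaculture
fish genotyped across wild and cultured populations — are built from
population resequencing call sets containing millions of candidate SNPs.
Only a few hundred thousand probes fit on an array, and the value of the
panel depends on three properties: each marker must be technically
genotypable (probe chemistry), informative (segregating at useful
frequency), and the set as a whole must cover the genome evenly so that
downstream linkage, association and genomic-selection analyses see no
blind spots. `snpanel` implements that reduction as a sequence of
auditable, individually testable stages, plus the statistics used to judge
the finished array.

## Pipeline stages and their parameters

### Site filtering

Per-population hard filters run in two passes, mirroring the two filtering
tools usually applied after variant calling. The primary pass keeps sites
with minor allele frequency ≥ 0.05 and at most 3 missing genotypes (plus
Phred-20 site/mapping/base-quality minima and 10× coverage whenever those
fields are present in the VCF — they are normally enforced inside the
caller, so they apply only if the input carries them). The secondary pass
requires a minor allele count of at least 2, at most 2 missing genotypes,
and no more than 3 observed alleles. MAF is computed over called alleles
only; the sources are silent on the denominator and excluding missing
alleles is the convention of the common genotype tools. All thresholds
live in `site_filter_config()` and can be overridden.

The per-population kept sets are pooled with `pool_unique()`, keyed by
(chromosome, position, ref, alt); sites present in exactly one population
are counted as population-specific. A reference-allele conflict between
populations aborts pooling, since it indicates inconsistent call sets.

### Probe screening

Each candidate's 35 bp flanks are screened (`filter_probes()`):

* no run of 4 or more contiguous G/C bases and no run of 6 or more
  contiguous A/T bases. "Contiguous G or C" is read as a run over the
  combined alphabet {G,C} — `GCGC` counts — because alternating G/C
  stretches cause the same duplex-stability problem as homopolymers and
  this is the stricter reading; a `combined_run_alphabet = FALSE` switch
  restores the homopolymer-only interpretation;
* GC content within [0.30, 0.70], inclusive at both ends. The window is
  the full 71-base probe context (both flanks plus the reference base) by
  default; `gc_window = "flanks"` restricts it to the flanks, since the
  original rule does not say which window it used;
* no other known variant within either flank (tested against the pooled
  candidate set — the only variant catalogue available at design time) and
  a biallelic SNP with no indel.

Every failing site records all violated rules, so the per-reason counts in
the screening report add up. Vendor "in silico" convertibility scoring is
proprietary; `filter_probes()` accepts an externally supplied score table
through the `scores`/`score_min` hook but implements no scorer.

### Three-stage even-spacing selection

The selection algorithm thins the surviving candidates to an evenly spaced
panel. All bins are 0-based half-open; partial bins at chromosome ends are
real bins; every tie breaks toward the lower coordinate so the output is
deterministic and independent of input record order.

* **Stage I** — split each chromosome into 1 kb bins. A bin with one SNP
  keeps it; a bin with two or more keeps the two SNPs nearest the two bin
  boundaries (for sorted positions, the first and last). This reading of
  the published rule maximises within-bin spread, which is the only
  interpretation consistent with the even-spacing goal. Everything else
  moves to a *dropped pool* — removed but recoverable.
* **Stage II** — merge 10 adjacent bins into 10 kb bins. Bins with more
  than 10 selected SNPs are thinned to exactly 10; bins with 7–9 are left
  alone; bins with fewer than 7 re-promote SNPs from their own dropped
  pool until they reach 7 or the pool runs out. The top-up target is 7,
  not 10, because recovery is triggered at "fewer than seven" and bins
  holding 7–9 are acceptable as they stand; recovery draws only from the
  same merged bin so that Stage II stays local and Stage III handles
  cross-bin repair. "Uniformly" is concretised as `uniform_pick()`:
  k equispaced targets at `start + (i − 0.5)·L/k` are each greedily
  matched to the nearest unassigned SNP.
* **Stage III** — scan each chromosome over the selected positions, with
  the chromosome start and end as virtual boundaries. While any adjacent
  gap exceeds 2 kb and an unused dropped SNP lies strictly inside it, the
  dropped SNP nearest the gap midpoint is promoted and both half-gaps are
  re-examined (left half first). Because the gaps partition the
  chromosome, the processing order cannot change the final set; it is
  fixed for determinism anyway. On termination, any residual oversized gap
  provably contains no usable dropped SNP.

Trait-associated and control markers join afterwards via
`add_fixed_markers()`; they are never displaced by the spacing stages, are
deduplicated by coordinate, and by default are screened by the probe rules
only advisorily (a failure warns rather than removes, since fixed markers
are typically non-negotiable).

The whole pipeline satisfies an exact conservation law — every candidate
ends as selected or dropped, none duplicated or lost — and the test suite
checks the full Stage I–III output site-for-site against an independently
coded brute-force reference on hundreds of random genomes and
configurations.

### Evaluation

`marker_qc()` keeps markers with call rate strictly above 0.90 and MAF
strictly above 0.02 (strict, as the published thresholds are phrased).
`conversion_classify()` assigns PolyHighResolution / NoMinorHom /
MonoHighResolution / OffRecommended / Other labels from genotype counts
and a 0.97 call-rate bound; these are a simplified, documented stand-in
for the vendor's cluster-geometry definitions, which depend on intensity
data that is out of scope. `polymorphic_accounting()` calls a marker
polymorphic within a group when at least two genotype classes are observed
among called samples — a threshold-free definition that matches how
"polymorphic sites" is used with small per-group sample sizes — and
specific when that happens in exactly one group. `feature_density()`
assigns each marker to the exon/intron/intergenic partition derived by
`derive_annotation()` (intron = gene minus exon, intergenic = genome minus
gene; the class lengths sum to the genome length exactly).
`spacing_scan()` reports adjacent-marker spacing and per-100 kb bin
occupancy. `concordance()` compares array and sequencing genotypes over
their shared grid; because the natural denominator of a "recovered
genotypes" percentage is ambiguous, all three plausible normalisations
(whole grid, sequencing-missing, array-called) are reported with explicit
denominators.

### Distances and trees

`allele_sharing_distance()` computes `1 − IBS/2` per pair over co-called
sites: with dosage coding the shared-allele count at one site is
`2 − |g1 − g2|`. The metric is a design choice — the original analysis
names only the tree method, not the distance — and is swappable.
`neighbor_joining()` is a standard Q-criterion NJ with the usual
branch-length formulas, deterministic lowest-pair tie-breaking, and
negative branch lengths reported as computed (an optional clamp exists for
display). Species-level trees average inter-group distances with
`group_mean_distance()` before joining; whether the original figure used
per-individual or per-species distances is unstated, so both routes are
provided.

## The synthetic-data generator

`simulate_genome()`, `simulate_populations()` and `simulate_array_run()`
exist so every stage is testable without external data. Sites are diploid,
autosomal and unlinked; per-population alternate-allele frequencies are
drawn independently from a uniform [0.05, 0.5] spectrum (a site either
segregates in all populations or in exactly one, controlled by
`shared_fraction`); missingness is missing-completely-at-random; genotype
errors replace a call with one of the other two classes uniformly.
Identical spec and seed give byte-identical outputs.

Defaults mirror the published study design where it is stated: six
populations, 14 samples each (82 fish across six sites, rounded), an SNP
density of 14 per kb (9.34 M SNPs over a 668.67 Mb genome), 41 % genome
GC, and `shared_fraction = 0.9955` (41,838 population-specific sites of
9.34 M pooled). The genome itself defaults to 3 chromosomes of 100 kb —
a deliberate desk-scale choice so that a full pipeline run takes seconds;
all rates are per-base or per-kb, so conclusions about the algorithms
transfer, but absolute counts (panel size, gap censuses) do not.

What the generator does **not** model: linkage disequilibrium (the
pipeline never uses LD), coalescent population structure, recombination
maps, sequencing reads, or base-composition heterogeneity along the
genome. The last point matters when interpreting probe-screen pass rates:
i.i.d. sequence at 41 % GC produces disqualifying G/C and A/T runs more
often than real genomes with isochore structure do, so synthetic pass
rates are conservative and should not be read as predictions for real
flank sequences. Passing tests demonstrate that the rules are applied
exactly as specified, not what fraction of real candidates survives them.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive in files (VCF convention) and 0-based
  half-open in bin arithmetic; converters are tested both ways.
* "Fewer than four contiguous G or C" is enforced as run ≥ 4 fails
  (likewise ≥ 6 for A/T); GC bounds are inclusive.
* MAF for multiallelic records is the frequency of the second most
  frequent allele among called alleles.
* Indels load from VCFs but are flagged excluded immediately, preserving
  the audit trail; multiallelic records survive until the site filter's
  allele-count rule and the probe filter's biallelic rule.
* Duplicate coordinates entering selection collapse to the first record
  (lowest alternate allele); a panel never holds two markers at one
  position.
* Pairs with zero co-called sites make the distance undefined: an error
  by default, `NA` plus an unreliability flag in permissive mode.
* An empty bin, an empty dropped pool, or a gap with no interior dropped
  SNP are all quietly legal states, not errors; the Stage III loop
  terminates because each promotion consumes one dropped SNP.

## Problem sizes used by the test suite

The suite exercises the selection oracle on 200 random genomes of up to
50 kb with up to 60 candidates and randomised configurations, the probe
oracle on 10,000 random 71-base contexts, gap-filling guarantees on a
1 Mb genome at one-plus candidates per kb, parameter recovery on a
five-population, 100-sample cohort of roughly 4,000 sites, and NJ
reconstruction on 100 random additive matrices of 4–12 leaves. These
sizes keep the whole suite under a minute while giving the property
checks enough randomisation to be informative.

## Known limitations

* The vendor conversion-type classes are a simplification; markers near
  the published class boundaries can be labelled differently than the
  vendor pipeline would label them.
* The probe screen knows only the pooled candidate set, so "no other
  variant in the flanks" is relative to that catalogue, as it is in any
  real design round.
* The evaluation statistics assume biallelic dosage coding; genuinely
  multiallelic markers must be resolved upstream.
* Published cohort-scale figures (panel size in the hundreds of
  thousands, genome-wide spacing averages, array-versus-sequencing
  percentages) depend on the original resequencing data and physical
  array runs and are not reproducible at desk scale; the package instead
  demonstrates, on synthetic truth, that the statistics which produced
  those figures measure what they claim to measure.
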
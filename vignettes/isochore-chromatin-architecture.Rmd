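---
title: "Isochores and chromatin domains: models, generators and design choices"
author: "isoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isochores and chromatin domains: models, generators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoarch)
```

## The scientific question

Mammalian genomes are compositional mosaics of **isochores**: long
(typically over 200 kb) segments of relatively homogeneous GC content,
classified by increasing GC into the families L1 and L2 (GC-poor, the
gene-poor "genome desert") and H1, H2 and H3 (GC-rich, the gene-rich
"genome core"). Chromatin, meanwhile, is organised into topologically
associating domains (TADs, 0.2–2 Mb self-interacting blocks on Hi-C
maps) and lamina-associated domains (LADs, GC-poor segments touching
the nuclear lamina, characterised by a contact frequency CF — the
proportion of cells in which the segment contacts the lamina).

`isoarch` implements the analytical machinery needed to ask whether
isochores are the genomic units underlying these chromatin domains:

1. **Isochore mapping** — sliding-window GC profiles and threshold
   segmentation into the five families.
2. **Region-set association** — permutation tests with z-scores and
   shifted *local z-score profiles* that distinguish boundary-level
   from merely regional co-location.
3. **Synteny and conservation** — order-conserved ortholog chaining
   into synteny blocks, projection of isochores across species, and GC
   correlation of orthologous regions.
4. **Contact stratification** — isochore-class annotation of binned
   Hi-C matrices: distance decay, long-range GC-poor interactions, the
   class composition of top inter-chromosomal contacts, boundary
   concordance and LAD CF summaries.
5. **A synthetic-genome generator** that plants all of these structures
   with recorded ground truth, so every statistic can be validated by
   recovering the parameter it was planted with.

All coordinates are 0-based half-open; interval files are BED, genomes
FASTA, matrices bin-table + triplet TSV.

## Isochore segmentation

The GC profile of a chromosome is computed in windows (default
non-overlapping 100 kb here; 300 kb is the classical display scale).
GC is computed over unambiguous bases only; windows with more than 50%
non-ACGT bases are masked and break segments. A trailing window is kept
if it covers at least half a window.

Family assignment is a total, monotone step function with half-open
intervals `[low, high)`. The "fixed" cutpoints default to 37/41/46/53%
GC; only the 46% H1 upper threshold is anchored in the primary
literature, so all four cutpoints are configuration values. An
"extended" mode relaxes each cutpoint by one GC% — its documented
purpose is to tolerate minimal trespassing of the 46% threshold, and
since the exact extended ranges are tabulated only in sources we do not
reproduce, the one-point relaxation is this package's own transcription
choice. With the half-open convention, a GC of exactly 46 falls in H2.

Threshold classification of noisy windows oversegments, so segments
shorter than `min_size` (default 200 kb, the lower edge of the domain
size range) are absorbed — smallest first — into the flanking neighbour
with the nearer mean GC (left neighbour on an exact tie), with the
merged segment's GC and family recomputed from the pooled windows until
stable. The absorption rule is an explicit design decision of this
package: the original isochore-mapping programs do not document their
smoothing. Segmentation uses non-overlapping windows because
overlapping windows would double-count sequence; overlapping steps
remain available for display profiles.

## The association test

`perm_test(A, B)` evaluates an overlap statistic — the count of A
intervals touching B, or the basepair intersection of the two unions —
and compares it with the statistic under `n_perm` randomizations of A.
The empirical p-value is `(1 + #[null >= observed])/(n_perm + 1)`; the
z-score is the observed value standardised by the null mean and SD.

Design choices, made where the underlying procedure was genuinely open:

* **Basepair mode for tiling sets.** Isochores tile the genome, so the
  count statistic saturates (every permutation ties the observed value)
  and the uniform randomization of a tiling set is even infeasible.
  Association tests involving isochores therefore run in basepair mode
  against a family subset (GC-rich isochores for TADs, GC-poor for
  LADs), mirroring the convention that "TADs" are the domains not
  overlapping LADs.
* **Uniform randomization** re-places each interval uniformly on its
  own chromosome, avoiding the mask and previously placed intervals.
  Placement samples directly from the remaining feasible start space
  (longest interval first) rather than looping on rejections: the
  contract — uniform, length-preserving, non-overlapping — is the same,
  but a single feasible slot is found deterministically and an
  infeasible chromosome is reported by name. Sequential placement is
  not exactly uniform over *joint* configurations; for the sparse sets
  used in testing the bias is negligible, and the type-I error of the
  test is verified by simulation to sit at or just below the nominal
  level.
* **Circular randomization** shifts all intervals of a chromosome by
  one uniform offset, wrapping at the ends. A wrapping interval is
  stored as two fragments sharing the parent interval's `id`; counts
  and length multisets are defined over ids, so both are conserved
  exactly.
* **One-sided enrichment** p-values by default; depletion by flag.

The **local z-score profile** recomputes z after translating A by each
offset in `±max_shift` (circular within chromosomes). The null
distribution is drawn once at shift 0 and reused — valid because
circular translation leaves the randomization law invariant — with a
`renull` flag to redraw per shift. A sharp central peak means the
association depends on the exact boundary coordinates; a flat profile
means it is regional. `peak_sharpness` is `|z(0)|` over the maximum
`|z|` at shifts of at least half the range, and profiles are called
sharp at a threshold of 2 (chosen so that a construct whose intervals
merely live inside the partner's territory, which retains most of its
overlap under moderate shifts, lands clearly below it, while a
boundary-matched construct loses its overlap within a few interval
lengths and lands clearly above).

## Synteny blocks and GC conservation

Ortholog pairs sorted along species A are chained while the next pair
stays on the same chromosome (and chromosome arm, when a centromere
table is supplied) in both species and keeps species-B positions
strictly monotonic in the chain's orientation; the orientation is fixed
by the first two members, any violation closes the chain and opens a
new one at the violating pair, and chains with at least 3 orthologs
become blocks. Descending B order counts as conserved (inverted) order
— inversions are ubiquitous in mammalian synteny and excluding them
would fragment blocks; `direct_only` restores the strict reading. No
maximum inter-gene gap is applied by default (an optional `max_gap`
exists). Micro-rearrangement tolerance (skipping single out-of-order
genes) is deliberately not implemented: the strict rule is
reproducible and is the one the planted-recovery tests certify.

Isochores covered at least 50% by a block (a threshold that avoids
sliver intersections) are projected into species B by linear
proportional mapping of the intersected interval onto the block's B
span, mirrored for inverted blocks. Cross-species GC agreement is
summarised by Pearson and Spearman correlations with a Fisher-z 95%
confidence interval.

## Contact-matrix stratification

Bins are annotated with the family of majority overlap (exact ties go
to the family containing the bin midpoint; bins less than half covered
stay unassigned), and classes group H1–H3 as GC-rich, L1/L2 as GC-poor.
Every unordered pair of distinct annotated bins contributes once to its
(class pair, distance stratum) cell; absent sparse entries count as
zeros (a `nonzero`-style restriction would bias Poisson means upward).
"Long range" defaults to bin distances above 5 Mb — the qualitative
"far away" of the underlying observation is not quantified anywhere, so
the threshold is a config value. Top inter-chromosomal interactions are
the N largest off-diagonal entries per chromosome pair (N defaulting to
100), ties broken lexicographically, and the class fractions are
computed over *distinct* participating bins (a bin in many top pairs
counts once) — the published ~75%/25% split speaks of the fraction of
mapped isochores *involved*, which is per-element, not per-pair
counting; a per-pair weighting is available behind the surface by
aggregating the top table directly.

## The synthetic-genome generator

The generator is first-class, tested code; its laws are the simplest
ones that reproduce the qualitative structures the analysis is meant to
detect, and each is a configuration knob:

* **Isochore mosaic.** Family succession is a Markov chain (zero
  diagonal, so adjacent isochores always differ; default uniform over
  the other four families, giving a uniform stationary distribution).
  Lengths are lognormal per family, truncated below at 250 kb, with
  default medians 1.2 Mb (L1) down to 0.4 Mb (H3): inside the 0.2–2 Mb
  domain range, GC-poor/LAD-forming isochores skewed larger (LADs have
  a median size around 500 kb). Sequence is drawn i.i.d. per base with
  the GC probability set per 100 kb window to the family target (35,
  39, 43.5, 49.5, 55% GC — the midpoints of the family ranges) plus
  Gaussian noise (SD 1 GC%). Only A/C/G/T are emitted; N-handling is
  tested with hand-built fixtures instead.
* **Domains.** Concordant TADs are isochores with endpoints jittered by
  N(0, 50 kb) — the jitter scale is calibrated only by the association
  mechanism being detectable, as no quantitative boundary-offset model
  exists in the source literature; a configurable fraction of TADs is
  placed uniformly at random instead ("discordant"). LADs are the L1
  and L2 isochores with CF drawn from per-family Beta laws (defaults
  Beta(8,2) for L1, Beta(4,4) for L2, making high CF > 0.8 an almost
  exclusively L1 property, as observed for the GC-poorest isochores).
* **Intra-chromosomal contacts.** Poisson counts around
  `base * d^-gamma` (bin distance d, default exponent 1), times a
  same-isochore domain boost (default 4) and a GC-poor pair boost
  (default 3) that produces the far-from-diagonal GC-poor signal. Bin
  classes in the generator use the same majority rule as the analysis,
  so planted class effects align exactly with measured classes.
* **Inter-chromosomal contacts.** Each chromosome owns a fixed set of
  24 "interactive" bins whose class composition equals the configured
  GC-rich preference (default 0.75); 150 hotspot pairs per chromosome
  pair link the two interactive sets with a high Poisson mean over a
  uniform background. Planting the preference in the *composition of
  interactive loci* (rather than routing intensity to rich-rich pairs,
  which would drive the top-interaction class fraction to 1) is what
  makes the published-style "fraction of involved loci" a recoverable
  parameter.
* **Orthologs.** Genes at regular spacing are grouped into blocks of 5;
  consecutive blocks alternate between two species-B chromosomes, are
  laid out in permuted order and independently inverted with
  probability 0.5. The alternation guarantees that chains break between
  planted blocks (two A-adjacent blocks on one B chromosome would
  remain chainable with probability about 1/4 per boundary, making
  exact planted recovery impossible); it is also realistic, since
  mammalian synteny scatters blocks across chromosomes. Species-B GC is
  species-A GC plus Gaussian noise per isochore piece; the unshuffled
  layout is a verbatim coordinate copy, useful for identity tests.
* **CTCF sites.** A homogeneous Poisson process per isochore at
  per-family rates, default 2/5/8/11/14 sites per Mb from L1 to H3 — a
  strictly increasing gradient mirroring the observed decrease of CTCF
  density towards GC-poor families.

Determinism: identical configurations (including the seed) give
bit-identical outputs. Every stage derives its seed from the global
seed and the stage name via a stable hash (`stage_seed`), so adding a
stage never perturbs another stage's stream.

### What the generator does and does not emulate

It reproduces the *mosaic structure* (family alternation, length
scales, GC levels), the *domain correspondence* (jittered boundaries,
CF laws), *contact organisation* (decay, domain blocks, class-dependent
long-range and inter-chromosomal signal) and *synteny with correlated
GC*. It does not attempt realistic k-mer composition, repeats,
centromeric gaps, CTCF motifs, read-level Hi-C, matrix balancing, or
assembly artefacts. Tests passing on this generator therefore certify
the *statistical machinery* — that each method recovers the structure
it targets at realistic scales and noise levels — not performance on
the idiosyncrasies of real genomes (mappability, normalization biases,
annotation error), which have no counterpart here.

## Numerical choices and degenerate inputs

* Empirical p-values use the add-one form, so p is never 0 and the
  minimum attainable value is `1/(n_perm + 1)`.
* A degenerate null (SD 0) still yields a p-value; the z-score is
  flagged undefined rather than infinite.
* Family assignment at exact cutpoints follows the half-open
  convention; segmentation absorption breaks exact GC ties to the left
  neighbour; top-interaction ties break lexicographically; annotation
  ties go to the midpoint's isochore — every tie-break is stated and
  deterministic.
* Fully masked profiles segment to an empty table with a warning;
  jitter that would collapse a TAD is re-drawn with a warning;
  infeasible randomization errors name the chromosome.
* Lognormal length draws are clamped to a 250 kb minimum so that
  planted isochores are never erased by the 200 kb segmentation
  `min_size`.

## Problem sizes used in the validation suite

The package's tests validate each mechanism at deliberately scaled-down
sizes chosen to give the estimators adequate power: isochore recovery
on 20 Mb genomes (10 seeds), association on 20 Mb single-chromosome
genomes with 999 permutations, calibration with 500 null replicates at
199 permutations, profile classification over 100 seeds (with a
long-isochore 60 Mb genome for the regional construct), synteny on 100
fuzzed tables plus a planted 50-block genome, GC correlation at roughly
300 orthologous regions per seed (noise calibrated to a planted Pearson
r of 0.9), inter-chromosomal fractions over 20 chromosome pairs of a
7 x 30 Mb genome, contact-law recovery on a 40 Mb chromosome with the
domain boost disabled (isolating the two laws being read off — the
decay exponent and the GC-poor boost), concordance against the Gaussian
closed form pooled over 10 seeds, and the CTCF gradient on 180 Mb
genomes where the per-family Poisson counts separate the planted rates
cleanly. Published figures tied to specific genome assemblies, Ensembl
versions and Hi-C depth (absolute block counts in the thousands,
p = 0.00093, 23,751 binding sites) depend on external data and are not
desk-scale reproducible; the suite instead certifies each mechanism by
planted-parameter recovery at stated tolerances.

## Known limitations

* Threshold segmentation is deliberately simple; no HMM or
  likelihood-based segmentation is provided, because classification of
  windowed GC *is* the method under study.
* Sequential uniform placement is exchangeable but not exactly uniform
  over joint non-overlapping configurations (a property shared by
  practical randomizers); the calibration test bounds the practical
  effect.
* The synteny chain is strict: one out-of-order gene closes a block.
* Inter-chromosomal generation plants hotspot structure at the bin
  level only; it does not model compartment checkerboards.
* LAD detection from DamID signal is out of scope: LADs enter as
  intervals with CF values.
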
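# isoarch

Isochore segmentation and chromatin-domain association analysis in R.

Mammalian genomes are mosaics of **isochores** — long (≳200 kb)
segments of fairly homogeneous GC content, classified by increasing GC
into the families L1, L2 (GC-poor) and H1, H2, H3 (GC-rich). Chromatin,
in turn, is organised into topologically associating domains (TADs) and
lamina-associated domains (LADs). `isoarch` provides the machinery to
test whether isochores are the genomic units underlying these chromatin
domains, for genomicists working with GC profiles, BED interval sets,
ortholog tables and binned Hi-C matrices:

* **Isochore maps** — sliding-window GC profiles
  (GC% = 100·(G+C)/(A+C+G+T) per window), threshold classification into
  the five families (half-open GC ranges with fixed cutpoints
  37/41/46/53), and merge/absorb segmentation with a 200 kb minimum
  isochore size.
* **Region-set association** — permutation tests: observed overlap
  statistic *s(A,B)* against `n_perm` randomizations of A, with
  z = (s − μ̂₀)/σ̂₀ and empirical p = (1 + #{s₀ ≥ s})/(n_perm + 1), plus
  the shifted **local z-score profile** z(δ) that distinguishes
  boundary-level association (sharp central peak) from regional
  co-location (flat profile).
* **Synteny & conservation** — chaining of order-conserved orthologs
  (≥3 genes, same chromosome/arm, strictly monotone positions, inverted
  blocks allowed) into synteny blocks, projection of isochores across
  species, and Pearson/Spearman GC correlation with Fisher-z intervals.
* **Hi-C stratification** — isochore-family annotation of matrix bins
  by majority overlap; class-stratified distance profiles (mean contact
  vs distance, GC-poor vs GC-rich pairs); top-N inter-chromosomal
  interactions and the class fractions of involved bins; TAD/isochore
  boundary concordance; LAD lamina-contact-frequency summaries per
  family.
* **A seeded synthetic-genome generator** planting all of the above
  with recorded ground truth, so that every statistic is validated by
  recovering its planted parameter.

## Worked example

Simulate a 20 Mb mosaic genome, recover its isochore map from sequence,
and test the TAD/isochore association:

```r
library(isoarch)

cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 2e7)
g   <- simulate_isochore_genome(cfg)

prof <- compute_gc_profile(g$sequences["chr1"], window = 1e5)
iso  <- segment_isochores(prof, family_boundaries("fixed"), min_size = 2e5)
head(iso[, c("chrom", "start", "end", "mean_gc", "family")], 4)
#>   chrom   start     end  mean_gc family
#> 1  chr1       0 1500000 34.96267     L1
#> 2  chr1 1500000 2400000 38.75589     L2
#> 3  chr1 2400000 3500000 35.01327     L1
#> 4  chr1 3500000 4000000 53.32180     H3

segmentation_accuracy(iso, g$truth$isochores, g$truth$genome,
                      tolerance = 1e5)
#> boundary_recall     bp_accuracy    n_boundaries
#>       1.0000000       0.9531527              24
```

Every planted isochore boundary is recovered within one window and 95%
of bases get the correct family label. Jittered TADs derived from the
GC-rich isochores then associate with the recovered GC-rich isochores
far beyond chance:

```r
dom  <- simulate_domains(g$truth, cfg)
rich <- c("H1", "H2", "H3")
A <- region_set(dom$tads[dom$tads$source_family %in% rich,
                         c("chrom", "start", "end")], g$truth$genome)
B <- region_set(iso[iso$family %in% rich,
                    c("chrom", "start", "end")], g$truth$genome)

perm_test(A, B, n_perm = 999, mode = "basepair", seed = 7)
#> <perm_result> basepair overlap, uniform randomization
#>   observed 7.472e+06 | null 3.252e+06 +- 6.032e+05 | z = 6.99 | p = 0.001 (999 perms)

lz <- local_z_profile(A, B, max_shift = 4e6, step = 2.5e5,
                      n_perm = 199, mode = "basepair", seed = 7)
lz
#> <local_z_profile> 33 shifts | z(0) = 7.17 | peak sharpness = 3.2
classify_profile(lz)
#> [1] "sharp"
```

The overlap (7.47 Mb of 8.0 Mb of TADs) sits 7 standard deviations
above the randomization null at the minimum attainable p-value, and the
z-score collapses as soon as the TADs are shifted off their positions —
the sharp profile says the association lives at the boundaries, not
merely in the same chromosomal neighbourhoods.

A command-line interface wrapping the same functions is installed at
`inst/scripts/isoarch` (subcommands `simulate`, `profile`, `segment`,
`assoc`, `localz`, `synteny`, `hic-top`, `concordance`, `run`), and
`run_pipeline()` executes the whole analysis end to end under one seed,
writing BED/TSV/JSON intermediates and a machine-readable report.

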
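Package: isoarch
Title: Isochore Segmentation and Chromatin Domain Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the compositional (GC) organisation of
    mammalian genomes and its relationship to chromatin architecture.
    Computes sliding-window GC profiles and segments them into isochores
    of the five Bernardi families (L1, L2, H1, H2, H3); tests the
    association between genomic region sets (isochores, topologically
    associating domains, lamina-associated domains) by interval
    permutation with z-scores and shifted local z-score profiles; builds
    synteny blocks from ortholog tables and correlates isochore GC across
    species; and stratifies binned Hi-C contact matrices by isochore
    class. A seeded synthetic-genome generator plants isochore mosaics,
    jittered domains, ortholog tables, CTCF sites and contact matrices
    with recorded ground truth so that every statistic can be validated
    by planted-parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
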
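Package: fiberfam
Title: Gene-Family Sequence Variation and Fiber-Trait Association Analysis in Cotton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for tracing a plant transcription-factor gene
    family from sequence to trait in allotetraploid cotton. Identifies
    MYB DNA-binding repeats in protein sequences by position-specific
    scoring and classifies genes into 1R/R2R3/3R/4R subfamilies; builds
    neighbor-joining trees and assigns subgroups by nearest annotated
    reference; classifies ortholog presence/absence patterns across two
    diploid progenitors and two tetraploid subgenome pairs into gene-loss
    scenarios and estimates pairwise dN/dS by Nei-Gojobori counting;
    detects same-trait QTL hotspots on genetic maps, anchors them to
    physical coordinates via flanking markers, and co-localizes genes
    with hotspot intervals; classifies interspecific versus
    parent-specific SNPs across multiple genome assemblies, runs
    marker-trait correlation analysis in a backcross inbred line
    population across environments, computes qPCR fold changes by the
    2^-ddCt method, and tests SNP/expression concordance. A seeded
    synthetic-data module generates inputs with known planted structure
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
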
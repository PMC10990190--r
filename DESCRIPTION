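Package: feralyeast
Title: Ancestry Painting, Introgression Scans and Aneuploidy Detection for
    Spontaneous-Ferment Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genomic analysis of Saccharomyces cerevisiae
    isolated from spontaneous grape ferments. Implements identity-by-state
    chromosome painting of query genomes against a clonal reference panel,
    windowed Nei's pi, d_XY and d_a, the fd ABBA-BABA introgression scan,
    local-tree subtree incongruence classification with fixed-admixture-block
    selection, a rank-based aneuploidy and genome-instability framework built
    on the Mann-Whitney rank-biserial effect size and the Hodges-Lehmann
    location shift of per-site read depth, and an exact canonical k-mer
    species classifier. Ships synthetic-data generators with truth tables so
    every analysis is exercisable end to end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
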
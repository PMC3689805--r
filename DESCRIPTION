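Package: rnaimap
Title: Quantitative Genetics of Germline RNAi Sensitivity Variation in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting heritable variation in germline RNA interference
    (RNAi) sensitivity between Caenorhabditis elegans strains, as assayed by induced
    embryonic lethality after feeding RNAi against an essential maternal-effect gene.
    Implements the background-corrected induced-lethality statistic and dominance
    estimation from plate-level embryo counts; exact expected F2 phenotype-class
    frequencies under multilocus models, including a linked paternal-effect
    toxin/rescue incompatibility (zeel-1/peel-1) with configurable penetrance, with
    chi-square goodness-of-fit tests against observed segregation; seeded forward
    simulation of meiosis, F2 panels under incompatibility viability selection,
    recombinant inbred advanced intercross line (RIAIL) genomes, and plate-level
    assay counts under preset genetic architectures; and interval mapping on inbred
    panels re-implemented from first principles: genotype posteriors on a cM grid,
    a nonparametric (extended Kruskal-Wallis) scan, a covariate-adjusted normal-model
    scan, permutation-based genome-wide thresholds, and lod-drop support intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
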
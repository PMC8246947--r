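Package: msgbs
Title: Quantifying Relative Species Abundance in Mixed Samples with
    Multispecies Genotyping-by-Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the relative abundance of plant species in
    mixed (e.g. root) DNA samples from reduced-representation
    genotyping-by-sequencing (GBS) reads. The pipeline demultiplexes and
    assembles paired-end reads carrying unique molecular identifiers (UMIs),
    builds a species-labelled de novo meta-reference from monoculture
    samples, maps all reads against it, removes PCR duplicates per cluster
    and sample, applies a monoculture-based cluster filter that enriches for
    species-diagnostic loci, and converts read counts into within-species
    and calibrated across-species abundance estimates. Includes false
    positive/negative signal evaluation, congener-group relative false
    positive signal (rFPS) statistics, and a full synthetic-data generator
    (genomes with controllable cross-species homology, in silico double
    restriction digest, library simulation with PCR duplicates and
    sequencing errors) so every stage is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
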
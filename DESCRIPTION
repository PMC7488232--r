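Package: spotmap
Title: Species-Diagnostic RFLP Markers and Backcross Linkage Statistics for
    Peromyscus Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for candidate-gene linkage mapping in interspecific
    rodent crosses. Discovers sequence variants that create or destroy
    restriction-enzyme recognition sites between two genomes, designs
    diagnostic CAPS/RFLP amplicon markers and calls genotypes from digest
    fragment patterns, computes genome-wide restriction-site statistics
    for RADseq enzyme selection, classifies variant consequences against
    gene models, and provides the backcross statistics layer
    (exclusion/linkage chi-square tests, segregation distortion,
    modifier-locus count inference, Welch comparison of spot-size
    phenotypes). A synthetic-data module simulates genome pairs, gene
    models, and backcross pedigrees with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
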
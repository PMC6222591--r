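Package: bsamap
Title: Bulked-Segregant Analysis Sequencing for Mutant Gene Cloning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps chemically induced mutations from pooled-segregant
    whole-genome sequencing (BSA-Seq and MutMap designs). Computes
    quality-adjusted pooled allele frequencies from samtools pileup
    evidence, filters variants by depth, quality, homozygosity and the
    canonical EMS mutation spectrum, subtracts background SNP panels,
    calls a mapping interval from per-megabase homozygous-variant counts,
    triages candidate lesions by predicted consequence against GFF3 gene
    models, designs indel PCR markers for fine mapping, and provides
    segregation chi-squared tests. Includes a pooled-F2 simulator
    (recombination via Haldane's map function, EMS mutation spectrum,
    binomial pooled read sampling) so the whole pipeline is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    methods,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
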
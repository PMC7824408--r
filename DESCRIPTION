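Package: dmcc
Title: In Silico DraI mtDNA COI-COII (DmCC) Genotyping of Honey Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the DraI mtDNA COI-COII (DmCC) honey bee genotyping
    test fully in silico. From a Sanger consensus of the extended COI-COII
    amplicon (or any template such as a complete mitogenome) the package
    locates primer sites with mismatch tolerance, amplifies in silico,
    trims sequences precisely to the classical H2-E2 window, digests with
    DraI (or any registry-defined CAPS enzyme), calls evolutionary lineage,
    haplotype and subspecies against a reference pattern registry, reports
    SNPs relative to reference haplotypes, and renders deterministic
    virtual gels (SVG and text). Ships a deterministic synthetic-fixture
    generator for COI-COII-like amplicons and registries, and a
    command-line entry point for batch genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
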
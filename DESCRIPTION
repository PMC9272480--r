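Package: varscape
Title: Variant Landscape Analysis for VEP-Annotated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the landscape of population variants in a
    gene, as catalogued in gnomAD and annotated with Ensembl's Variant Effect
    Predictor (VEP). Reads and cleans VEP tab-delimited output and VCF,
    classifies consequences into analysis categories, computes codon-position
    and amino-acid substitution spectra, quantifies nonsense accessibility of
    amino acids from the genetic code, maps variants onto protein domain
    architectures and exons, and summarizes likely-pathogenic subsets under
    configurable SIFT/PolyPhen rules. Includes a strand-aware internal
    consequence annotator and a synthetic gene-model/variant generator with
    known ground truth, so every pipeline stage is testable without external
    databases. Developed around the three myosin binding protein-C paralogs
    (MYBPC1, MYBPC2, MYBPC3) but applicable to any protein-coding gene.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
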
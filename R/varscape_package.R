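#' varscape: variant landscape analysis for VEP-annotated genes
#'
#' Characterizes the landscape of population variants in a protein-coding
#' gene: ingestion and cleaning of VEP-style annotation tables and VCF,
#' consequence classification, codon and amino-acid substitution spectra,
#' domain/exon mapping, likely-pathogenic filtering, and a synthetic
#' generator with known ground truth. See the package vignette for the
#' methods.
#'
#' @keywords internal
"_PACKAGE"
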
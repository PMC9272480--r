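---
title: "Methods: variant landscapes of protein-coding genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant landscapes of protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varscape)
```

## The problem

A population variant catalog annotated with VEP gives, for each variant and
each overlapping transcript, a set of Sequence-Ontology consequence terms,
the codon and amino-acid change where applicable, the exon ordinal, and
SIFT/PolyPhen predictions. varscape condenses such tables into a gene's
variant landscape: the category composition of coding variation, the
nucleotide- and codon-level substitution spectra, per-amino-acid mutation
prevalences, domain and exon hotspot profiles, and the distribution of a
likely-pathogenic subset. The package was built around the three MyBP-C
paralogs — slow-skeletal *MYBPC1*, fast-skeletal *MYBPC2*, cardiac *MYBPC3* —
whose landscapes differ in clinically relevant ways (truncating variation in
the cardiac paralog is a major cause of hypertrophic cardiomyopathy), but
every component is generic.

## Data model and cleaning

The working container is a flat table with one row per
(variant, transcript-annotation), exactly the shape of VEP `--tab` output.
Variant identity is `(chrom, pos, ref, alt)`: rsIDs are ignored for identity
because database rows can share an rsID across alternate alleles.
Multi-allelic VCF sites are decomposed at ingestion so every downstream
stage sees biallelic records. Genomic and protein coordinates are 1-based
inclusive externally (VCF/UniProt convention); interval arithmetic inside
the annotator converts at the boundary.

Cleaning reproduces three stages, each audited in a `cleaning_report` whose
distinct-variant counts are non-increasing:

1. **Dedup** — exactly duplicated rows are dropped; annotations of a
   duplicated variant that differ (e.g. other transcripts) are merged onto
   the one retained record. Merging (rather than keep-first-only) is the
   default because it is idempotent, order-insensitive, and loses nothing.
2. **Transcript selection** — annotations are kept only for the transcript
   under study. Version suffixes are stripped on both sides before matching,
   and a list of aliases is accepted; the shipped MYBPC3 entry carries both
   the 13-character ID printed in common usage and its padded 15-character
   Ensembl form (`mybpc_config()`).
3. **Overlapping-gene removal** — annotations on genes that overlap or flank
   the locus (configuration, not constants: overlap sets change with
   annotation releases) are removed, with per-symbol counts reported; a
   variant all of whose annotations are removed disappears.

Rows whose location or alleles cannot be parsed are counted and skipped,
never silently dropped, so `converted + skipped = total` always holds. The
report records both distinct-variant and row counts at every stage, so
either counting convention of a published total can be audited.

## Consequence classification

Each annotation's term set resolves to one of ten categories
(`consequence_categories()`), by the most severe recognized term under the
standard Ensembl-style severity order: start loss, stop gain ("truncation"),
frameshift, stop loss, canonical splice donor/acceptor, inframe indel,
missense, other protein-altering, synonymous, noncoding. Two deliberate
choices:

* **Truncation means stop gain only.** Frameshifts also truncate the
  protein, but they are tallied separately so either grouping can be
  recomposed downstream.
* **`splice_region_variant` is a modifier, not a category.** Only the ±1/±2
  intronic positions count as the splice bucket. A non-canonical
  splice-region term never decides the category: classification falls
  through to the next recognized term, so
  `missense_variant,splice_region_variant` is missense and
  `splice_region_variant,intron_variant` is noncoding. Placing the modifier
  in the severity ladder instead would either contaminate the splice bucket
  or misfile exonic synonymous variants, and the category map stays total.

Annotations with no recognized term classify as `protein_altering_other`
with a warning. When a variant carries several annotations (possible before
transcript selection), the most severe category represents it in tallies.

## The internal annotator and its oracle

`annotate_variant()` is a deliberately small stand-in for VEP that makes the
pipeline testable offline. It splices the CDS from the gene model
(reverse-complementing on the minus strand), substitutes, and translates:
coding SNVs/MNVs get codon change, protein position and amino-acid change;
indels overlapping the CDS are frameshift when the length difference is not
a multiple of 3, else inframe; SNVs in the two intronic bases adjacent to an
exon are splice donor/acceptor variants, strand-aware; remaining positions
get intron/UTR/upstream/downstream terms. Like VEP, it annotates each
variant independently; compound effects of neighboring variants on one codon
are not modeled. MNVs within a codon are classified by full-codon
replacement.

Its correctness is established against an independent oracle,
`annotate_by_retranslation()`: substitute the base into the genomic
sequence, re-splice, retranslate the *entire* protein, and diff against wild
type. The two routes share no codon-index arithmetic. The test suite checks
agreement of category, protein position, and amino-acid change on 1,000
seeded random SNVs over random multi-exon models on both strands, and exact
invariance under strand mirroring (a gene and its reverse-complemented,
coordinate-flipped twin must produce identical protein-level annotations).

## Genetic-code arithmetic

The standard nuclear code (NCBI table 1) is embedded as a literal table and
cross-checked against Biostrings in the tests. Exhaustive enumeration of all
64 × 9 = 576 single-base codon substitutions
(`enumerate_codon_substitutions()`) yields two mechanistic nulls used
throughout:

* synonymous substitutions concentrate at the third codon position (the
  enumeration itself computes the share; the suite asserts position 3
  strictly exceeds positions 1 and 2 combined), explaining why observed
  synonymous variants cluster there;
* per-codon nonsense accessibility (`stop_accessibility()`) is maximal for
  tryptophan (TGG) and tyrosine (TAT/TAC) at 2/9, with methionine at 0 —
  the null expectation behind Trp/Tyr dominating stop-gain source residues.

## Landscape statistics

Category proportions are reported over coding categories (summing to 1)
with the noncoding fraction of all variants alongside, mirroring how gene
landscapes are usually quoted ("~63% of coding variants are missense; ~75%
of all variants are intronic"). Nucleotide changes are tallied over the 12
ordered base pairs on the reference plus strand, SNVs only. Substitution
spectra count ordered (ref, alt) amino-acid pairs; top-k lists break ties by
descending count then lexicographically, since no published convention
exists. The frameshift tally counts the reference residue at the first
altered codon (VEP's protein-position convention). Domain distributions
always emit per-100-aa rates next to raw counts: a short domain can be a
hotspot by rate without leading raw counts, and the two views answer
different questions. Domain boundaries are inclusive on both ends; positions
in no named region are linker; the stop codon has no domain and is excluded
from domain tallies.

The likely-pathogenic screen is a label filter over SIFT and PolyPhen with
four modes. The default is the strictest sensible rule — `both`, with SIFT
`deleterious` and PolyPhen `probably_damaging` — because published analyses
rarely state their filter; all four mode counts are logged on every run so a
published profile can be bracketed. Annotations lacking both predictors
never pass, under any mode; since the predictors only score missense
variants, the screen implicitly restricts to missense, which the run log
states explicitly.

## The synthetic generator

`make_gene_model()` builds a random valid transcript (ATG start, single
terminal stop, no internal stops, random UTRs/introns/flanks; minus-strand
models are exact mirrors). `simulate_variants()` emits variants in two
modes:

* **Category-mix mode** (default) emulates a cleaned gnomAD/VEP export with
  known composition. The default mix is the reported MYBPC landscape: among
  coding variants 63% missense, 30% synonymous, 3% frameshift+truncation
  (split evenly between the two), 2% inframe indels, 2% canonical splice;
  75% of all variants noncoding — the middle of the 62–90% intronic range
  observed across the three paralogs. Category counts are apportioned by
  largest remainder (exact), sites are drawn *without replacement* within
  category from the exhaustive SNV-effect enumeration, and the
  transition/transversion indicator is Bernoulli `R/(R+1)` independent of
  category (default Ts/Tv R = 2, typical of human SNVs). Both the category
  proportions and the transition fraction are therefore recoverable from the
  output by construction — which is the point: the generator defines the
  conditions the pipeline must recover.
* **Mechanistic mode** draws sites with replacement (duplicates exercise the
  dedup stage), weighting each (site, alternate) by the Ts/Tv ratio and an
  optional CpG multiplier on C>T/G>A at CpG dinucleotides (off by default;
  8× is the documented stand-in for the hypermutability that makes arginine
  CGN codons mutable). Setting Ts/Tv to 0.5 makes every alternate equally
  likely, the uniform null used for the distribution calibrations.

Ground truth is recorded at generation time, before annotation: SNV truth
comes from the vectorized enumeration (a separate code path from
`annotate_variant()`), indel truth from the construction itself. SIFT and
PolyPhen labels are *generated*, not predicted — a per-category damaging
probability (default 0.35 for missense, labels drawn independently for the
two predictors with scores in the labels' published ranges) — because
re-implementing the predictors is out of scope.

What the simulator does not emulate: allele frequencies, coverage,
population structure, mutational signatures beyond Ts/Tv and CpG, real
hg19/hg38 sequence, and inter-variant linkage. Passing tests therefore
demonstrate that the pipeline measures what the data contain; they say
nothing about which landscape a particular database release contains.

## Numerical and design choices

* Tallies over simulated data are compared to configured values within 3
  binomial standard errors; distribution calibrations use chi-square
  goodness-of-fit at α = 0.01 with cells of expected count < 5 pooled. In
  category-mix mode the sampling is without replacement, so post-cleaning
  proportions match configuration to rounding; in mechanistic mode sampling
  is with replacement and properties are asserted on emitted records, since
  collapsing duplicates under heavy saturation biases spectra toward the
  pool composition.
* Problem sizes in the checks — 1,000 SNVs for the oracle comparison,
  10,000 variants for end-to-end recovery, 20,000 for the distribution
  nulls, gene models of 500–1,200 codons with intron lengths scaled so a
  75% noncoding mix is feasible — were chosen so every stochastic check has
  comfortable statistical headroom while the whole suite runs in about a
  minute and a half.
* Degenerate inputs: empty tables produce zero-count tallies with
  proportions absent rather than NaN; empty VEP files warn and return empty
  tables; an architecture position beyond the protein is a range error for
  `map_to_domain()` but silently out of scope for domain tallies (the stop
  codon); frameshifts without a protein position are tallied under
  `unknown` with a warning.
* Known limitations: no splice-strength scoring or NMD prediction; no
  liftover; no claim of reproducing any specific database snapshot's counts
  — real-mode results are only as current as the VEP export they ingest.

## Reproducibility

Every stochastic component takes an explicit integer seed
(`mutation_model(seed=)`, `make_gene_model(seed=)`, `run_config(seed=)`),
and identical seeds give identical outputs, including byte-identical written
files. `scripts/acceptance.R --seed S --out f.json` recomputes the headline
quantities from scratch under seed `S`.
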
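# Standard nuclear genetic code (NCBI translation table 1), embedded so that
# all codon arithmetic is self-contained and auditable.
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

DNA_BASES <- c("A", "C", "G", "T")

#' Translate codons under the standard genetic code
#'
#' Maps length-3 nucleotide strings to one-letter amino-acid codes, with `"*"`
#' for the three stop codons. Uses the standard nuclear code (NCBI table 1).
#'
#' @param codon Character vector of codons, each exactly 3 characters over
#'   `A/C/G/T` (case-insensitive).
#' @return Character vector of one-letter amino-acid codes (`"*"` = stop).
#' @examples
#' translate_codon(c("ATG", "TGG", "TAA"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (must be length 3 over A/C/G/T)")
  }
  unname(GENETIC_CODE_TABLE[codon])
}

#' Translate a coding sequence
#'
#' @param cds A single nucleotide string whose length is a multiple of 3.
#' @return Character vector of amino acids, one per codon (`"*"` = stop).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  translate_codon(substring(cds, starts, starts + 2L))
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings over `A/C/G/T` (case preserved
#'   per base).
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

is_transition <- function(ref, alt) {
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine) & ref != alt
}

#' Exhaustive enumeration of single-base codon substitutions
#'
#' Enumerates all 64 codons times 9 single-base substitutions (576 changes)
#' and classifies each at the protein level. This is the mechanistic null
#' behind two landscape observations: synonymous changes concentrate at the
#' third codon position, and tryptophan/tyrosine codons are the most
#' nonsense-accessible (their codons are one substitution away from a stop at
#' the highest per-codon rate).
#'
#' @return A data.frame with one row per (codon, position, alternate base):
#'   `codon`, `position` (1-3), `ref_base`, `alt_base`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, and `class` in
#'   `synonymous`/`missense`/`nonsense`/`stop_loss`. Stop-to-stop changes are
#'   classified synonymous, so the four classes partition all 576 rows.
#' @export
enumerate_codon_substitutions <- function() {
  codons <- names(GENETIC_CODE_TABLE)
  grid <- expand.grid(codon = codons, position = 1:3,
                      alt_base = DNA_BASES, stringsAsFactors = FALSE)
  grid$ref_base <- substr(grid$codon, grid$position, grid$position)
  grid <- grid[grid$ref_base != grid$alt_base, ]
  grid$alt_codon <- grid$codon
  substr(grid$alt_codon, grid$position, grid$position) <- grid$alt_base
  grid$ref_aa <- unname(GENETIC_CODE_TABLE[grid$codon])
  grid$alt_aa <- unname(GENETIC_CODE_TABLE[grid$alt_codon])
  grid$class <- ifelse(grid$ref_aa == grid$alt_aa, "synonymous",
                ifelse(grid$alt_aa == "*", "nonsense",
                ifelse(grid$ref_aa == "*", "stop_loss", "missense")))
  rownames(grid) <- NULL
  grid[, c("codon", "position", "ref_base", "alt_base", "alt_codon",
           "ref_aa", "alt_aa", "class")]
}

#' Nonsense accessibility of each amino acid
#'
#' For each amino acid, counts how many of the single-base substitutions of
#' its codons create a premature stop codon, aggregated over all codons of
#' that amino acid. Tryptophan (TGG) and tyrosine (TAT/TAC) top the
#' per-codon rate at 2/9, which is why they dominate stop-gain spectra.
#'
#' @return A data.frame with one row per amino acid: `aa`, `n_codons`,
#'   `n_nonsense` (substitutions creating a stop), `n_total` (all single
#'   substitutions, 9 per codon), and `rate_per_codon` = n_nonsense /
#'   n_codons / 9.
#' @export
stop_accessibility <- function() {
  en <- enumerate_codon_substitutions()
  en <- en[en$ref_aa != "*", ]
  aas <- sort(unique(en$ref_aa))
  out <- data.frame(
    aa = aas,
    n_codons = vapply(aas, function(a)
      sum(GENETIC_CODE_TABLE == a), integer(1)),
    n_nonsense = vapply(aas, function(a)
      sum(en$ref_aa == a & en$class == "nonsense"), integer(1)),
    n_total = vapply(aas, function(a) sum(en$ref_aa == a), integer(1)),
    row.names = NULL
  )
  out$rate_per_codon <- out$n_nonsense / out$n_total
  out
}
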
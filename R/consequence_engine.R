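# Ordered (most -> least severe) map from Sequence-Ontology-style consequence
# terms to analysis categories, modeled on the Ensembl severity ranking.
# splice_region_variant (non-canonical) is deliberately a modifier: it never
# decides the category, so [missense, splice_region] -> missense and
# [splice_region, intron] -> noncoding, and only +/-1,2 intronic positions
# land in the splice bucket.
CONSEQUENCE_CATEGORY_MAP <- c(
  start_lost = "start_loss",
  stop_gained = "truncation",
  frameshift_variant = "frameshift",
  stop_lost = "stop_loss",
  splice_donor_variant = "splice",
  splice_acceptor_variant = "splice",
  inframe_insertion = "inframe_indel",
  inframe_deletion = "inframe_indel",
  missense_variant = "missense",
  protein_altering_variant = "protein_altering_other",
  coding_sequence_variant = "protein_altering_other",
  incomplete_terminal_codon_variant = "protein_altering_other",
  synonymous_variant = "synonymous",
  stop_retained_variant = "synonymous",
  start_retained_variant = "synonymous",
  "5_prime_UTR_variant" = "noncoding",
  "3_prime_UTR_variant" = "noncoding",
  intron_variant = "noncoding",
  upstream_gene_variant = "noncoding",
  downstream_gene_variant = "noncoding",
  non_coding_transcript_exon_variant = "noncoding",
  non_coding_transcript_variant = "noncoding",
  intergenic_variant = "noncoding"
)

MODIFIER_TERMS <- c("splice_region_variant", "splice_polypyrimidine_tract_variant",
                    "splice_donor_region_variant", "splice_donor_5th_base_variant",
                    "NMD_transcript_variant")

#' Analysis categories, most to least severe
#'
#' The categories every classified annotation maps into: `start_loss`,
#' `truncation` (stop gain), `frameshift`, `stop_loss`, `splice` (canonical
#' donor/acceptor only), `inframe_indel`, `missense`,
#' `protein_altering_other`, `synonymous`, `noncoding`. `noncoding` covers
#' intronic, UTR, and up/downstream annotations; everything else counts as a
#' coding category.
#'
#' @return Character vector of category names in severity order.
#' @export
consequence_categories <- function() {
  unique(unname(CONSEQUENCE_CATEGORY_MAP))
}

#' Classify a set of consequence terms into one category
#'
#' Resolves a multi-term annotation (as VEP emits, e.g.
#' `missense_variant,splice_region_variant`) to a single analysis category by
#' picking the most severe recognized term. Non-canonical splice-region terms
#' are treated as modifiers and never decide the category. Annotations with
#' no recognized term classify as `protein_altering_other` with a warning.
#'
#' @param terms Character vector of consequence terms (one annotation).
#' @return A single category name (see [consequence_categories()]).
#' @examples
#' classify_terms(c("missense_variant", "splice_region_variant"))
#' classify_terms("stop_gained")
#' @export
classify_terms <- function(terms) {
  stopifnot(length(terms) >= 1L)
  terms <- trimws(terms)
  hit <- match(names(CONSEQUENCE_CATEGORY_MAP), terms)
  k <- which(!is.na(hit))
  if (length(k)) return(unname(CONSEQUENCE_CATEGORY_MAP[k[1L]]))
  unknown <- setdiff(terms, MODIFIER_TERMS)
  if (length(unknown))
    warning("unrecognized consequence term(s): ",
            paste(unknown, collapse = ", "),
            "; classifying as protein_altering_other")
  "protein_altering_other"
}

#' Classify comma/ampersand-joined consequence strings (vectorized)
#'
#' @param x Character vector; each element one annotation's terms joined by
#'   `,`, `&` or `;`.
#' @return Character vector of categories, same length as `x`.
#' @export
classify_consequences <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(x)
  out[ok] <- vapply(strsplit(x[ok], "[,&;]\\s*"), classify_terms, character(1))
  out
}

# Severity rank of a category (1 = most severe), for picking the dominant
# annotation of a multi-annotated variant.
category_severity <- function(category) {
  match(category, consequence_categories())
}

#' Parse VEP-style codon markup
#'
#' VEP writes codon changes with unchanged bases in lowercase and substituted
#' bases in uppercase, e.g. `gGg/gAg`. Parses the pair, verifies that the
#' uppercase positions are exactly the positions where the codons differ, and
#' returns normalized codons.
#'
#' @param field A string `refcodon/altcodon` in VEP case markup (plain
#'   uppercase codons are also accepted).
#' @return A list with `ref_codon`, `alt_codon` (uppercase) and
#'   `changed_positions` (integer subset of 1:3).
#' @export
parse_vep_codons <- function(field) {
  parts <- strsplit(field, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(nchar(parts) != 3L))
    stop("malformed codon field: ", field)
  ref <- toupper(parts[1L]); alt <- toupper(parts[2L])
  diff_pos <- which(strsplit(ref, "")[[1L]] != strsplit(alt, "")[[1L]])
  has_markup <- grepl("[a-z]", parts[1L]) || grepl("[a-z]", parts[2L])
  if (has_markup) {
    upper_pos <- sort(unique(c(which(strsplit(parts[1L], "")[[1L]] %in% LETTERS),
                               which(strsplit(parts[2L], "")[[1L]] %in% LETTERS))))
    if (!identical(as.integer(upper_pos), as.integer(diff_pos)))
      stop("codon markup inconsistent with base differences: ", field)
  }
  list(ref_codon = ref, alt_codon = alt,
       changed_positions = as.integer(diff_pos))
}

# Inverse of parse_vep_codons: emit VEP case markup for a codon pair.
markup_codons <- function(ref_codon, alt_codon) {
  mk <- function(codon, pos) {
    ch <- strsplit(tolower(codon), "")[[1L]]
    ch[pos] <- toupper(ch[pos])
    paste(ch, collapse = "")
  }
  mapply(function(r, a) {
    pos <- which(strsplit(r, "")[[1L]] != strsplit(a, "")[[1L]])
    paste0(mk(r, pos), "/", mk(a, pos))
  }, toupper(ref_codon), toupper(alt_codon), USE.NAMES = FALSE)
}

#' Codon position(s) of a substitution
#'
#' Returns which of the three codon positions changed. Accepts VEP case
#' markup (checked for consistency against the literal base differences) or
#' plain codons.
#'
#' @param ref_codon,alt_codon Length-3 codon strings; `ref_codon` may be the
#'   full VEP field `"gGg/gAg"`, in which case `alt_codon` is ignored.
#' @return Integer vector, subset of `1:3` (non-empty).
#' @examples
#' codon_position_of_change("gGg/gAg")
#' codon_position_of_change("GAA", "AAA")
#' @export
codon_position_of_change <- function(ref_codon, alt_codon = NULL) {
  field <- if (is.null(alt_codon)) ref_codon
           else paste0(ref_codon, "/", alt_codon)
  out <- parse_vep_codons(field)$changed_positions
  if (length(out) == 0L) stop("codons are identical: ", field)
  out
}

# --- internal annotator -----------------------------------------------------

empty_annotation <- function() {
  data.frame(transcript_id = NA_character_, gene_symbol = NA_character_,
             consequence = NA_character_, exon_index = NA_integer_,
             ref_codon = NA_character_, alt_codon = NA_character_,
             protein_pos = NA_integer_, ref_aa = NA_character_,
             alt_aa = NA_character_, sift_label = NA_character_,
             sift_score = NA_real_, polyphen_label = NA_character_,
             polyphen_score = NA_real_, stringsAsFactors = FALSE)
}

region_to_term <- function(region, strand_is_plus = TRUE) {
  switch(region,
         splice_donor = "splice_donor_variant",
         splice_acceptor = "splice_acceptor_variant",
         intron = "intron_variant",
         utr5 = "5_prime_UTR_variant",
         utr3 = "3_prime_UTR_variant",
         upstream = "upstream_gene_variant",
         downstream = "downstream_gene_variant",
         stop("unexpected region: ", region))
}

#' Annotate a variant against a gene model
#'
#' The package's internal stand-in for VEP: computes the consequence of one
#' normalized variant (VCF conventions; indels anchored) on a transcript.
#' Coding SNVs/MNVs get codon change, protein position and amino-acid change
#' by splicing the CDS (reverse-complementing on the minus strand),
#' substituting and translating. Indels overlapping the CDS are frameshift
#' when the length difference is not a multiple of 3, else inframe. SNVs in
#' the first/last two intronic bases are canonical splice donor/acceptor
#' variants (strand-aware); other intronic, UTR and flanking positions get
#' the corresponding noncoding terms.
#'
#' @param model A `gene_model`.
#' @param pos 1-based genomic position of the variant (anchor base for
#'   indels).
#' @param ref,alt Reference and alternate allele strings over `A/C/G/T`.
#' @return A one-row data.frame annotation: `transcript_id`, `gene_symbol`,
#'   `consequence` (comma-joined terms), `exon_index`, `ref_codon`,
#'   `alt_codon`, `protein_pos`, `ref_aa`, `alt_aa`, plus empty SIFT/PolyPhen
#'   columns.
#' @export
annotate_variant <- function(model, pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(nchar(ref) >= 1L, nchar(alt) >= 1L, ref != alt)
  span <- model_span(model)
  if (pos < span[1L] || pos + nchar(ref) - 1L > span[2L])
    stop("variant at ", pos, " lies outside the locus span ",
         span[1L], "-", span[2L])
  if (seq_base(model, pos, nchar(ref)) != ref)
    stop("reference allele mismatch at ", pos, ": expected ",
         seq_base(model, pos, nchar(ref)), ", got ", ref)

  ann <- empty_annotation()
  ann$transcript_id <- model$transcript_id
  ann$gene_symbol <- model$gene_symbol

  if (nchar(ref) == nchar(alt)) {
    ann <- annotate_substitution(model, pos, ref, alt, ann)
  } else {
    ann <- annotate_indel(model, pos, ref, alt, ann)
  }
  ann
}

# Substitutions (SNV or same-codon MNV). Works in spliced-CDS index space.
annotate_substitution <- function(model, pos, ref, alt, ann) {
  gpos <- pos + seq_len(nchar(ref)) - 1L
  refb <- strsplit(ref, "")[[1L]]
  altb <- strsplit(alt, "")[[1L]]
  changed <- which(refb != altb)
  gpos <- gpos[changed]; refb <- refb[changed]; altb <- altb[changed]

  cp <- coding_positions(model)
  idx <- match(gpos, cp)
  if (all(!is.na(idx))) {
    cds <- cds_sequence(model)
    tx_alt <- if (model$strand == "-") complement_base(altb) else altb
    mut <- strsplit(cds, "")[[1L]]
    mut[idx] <- tx_alt
    codons_hit <- sort(unique((idx - 1L) %/% 3L + 1L))
    cstart <- (codons_hit - 1L) * 3L + 1L
    ref_cod <- substring(cds, cstart, cstart + 2L)
    alt_cod <- vapply(cstart, function(s)
      paste(mut[s:(s + 2L)], collapse = ""), character(1))
    ref_aa <- translate_codon(ref_cod)
    alt_aa <- translate_codon(alt_cod)
    n_codons <- nchar(cds) %/% 3L
    # first codon where the protein actually changes, else first hit codon
    d <- which(ref_aa != alt_aa)
    j <- if (length(d)) d[1L] else 1L
    term <-
      if (codons_hit[j] == 1L && alt_aa[j] != "M") "start_lost"
      else if (length(d) && any(alt_aa[d] == "*" & ref_aa[d] != "*")) {
        j <- d[which(alt_aa[d] == "*" & ref_aa[d] != "*")[1L]]
        "stop_gained"
      } else if (length(d) && any(ref_aa[d] == "*")) {
        j <- d[which(ref_aa[d] == "*")[1L]]
        "stop_lost"
      } else if (length(d)) "missense_variant" else "synonymous_variant"
    ann$consequence <- term
    ann$exon_index <- exon_index_of(model, gpos[1L])
    ann$ref_codon <- ref_cod[j]
    ann$alt_codon <- alt_cod[j]
    ann$protein_pos <- codons_hit[j]
    ann$ref_aa <- ref_aa[j]
    ann$alt_aa <- alt_aa[j]
    return(ann)
  }
  if (any(!is.na(idx)))  # substitution straddling a coding boundary
    return(annotate_indel_region(model, gpos[!is.na(idx)][1L], ann,
                                 coding_term = "coding_sequence_variant"))
  region <- locus_region(model, gpos[1L])
  ann$consequence <- region_to_term(region)
  ann$exon_index <- exon_index_of(model, gpos[1L])
  ann
}

annotate_indel <- function(model, pos, ref, alt, ann) {
  if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L))
    stop("indel at ", pos, " is not anchored (ref and alt share no leading base)")
  is_del <- nchar(ref) > nchar(alt)
  len_diff <- abs(nchar(ref) - nchar(alt))
  cp <- coding_positions(model)
  if (is_del) {
    affected <- (pos + 1L):(pos + nchar(ref) - 1L)
    in_cds <- affected[affected %in% cp]
    coding <- length(in_cds) > 0L
  } else {
    affected <- c(pos, pos + 1L)
    coding <- all(affected %in% cp)
    in_cds <- affected[affected %in% cp]
  }
  if (coding) {
    term <- if (len_diff %% 3L != 0L) "frameshift_variant"
            else if (is_del) "inframe_deletion" else "inframe_insertion"
    idx <- min(match(in_cds, cp))
    codon_idx <- (idx - 1L) %/% 3L + 1L
    cds <- cds_sequence(model)
    cstart <- (codon_idx - 1L) * 3L + 1L
    ann$consequence <- term
    ann$exon_index <- exon_index_of(model, in_cds[1L])
    ann$protein_pos <- codon_idx
    ann$ref_aa <- translate_codon(substring(cds, cstart, cstart + 2L))
    return(ann)
  }
  annotate_indel_region(model, affected[1L], ann)
}

annotate_indel_region <- function(model, at, ann, coding_term = NULL) {
  region <- locus_region(model, at)
  ann$consequence <- if (region == "coding" && !is.null(coding_term))
    coding_term else region_to_term(region)
  ann$exon_index <- exon_index_of(model, at)
  ann
}

#' Annotate a variant by whole-protein retranslation (reference oracle)
#'
#' A deliberately naive reference annotator for single-nucleotide variants:
#' substitutes the base into the genomic sequence, re-splices and
#' re-translates the entire CDS, and diffs the mutant protein against the
#' wild type. Slower than [annotate_variant()] but with no codon-index
#' arithmetic, so the two serve as independent routes to the same answer.
#'
#' @param model A `gene_model`.
#' @param pos,ref,alt A single-nucleotide variant.
#' @return A list with `category`, `term`, `protein_pos`, `ref_aa`, `alt_aa`
#'   (the latter three `NA` for variants that leave the protein unchanged and
#'   sit outside the CDS).
#' @export
annotate_by_retranslation <- function(model, pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt)
  i <- pos - model$seq_offset + 1L
  if (substr(model$sequence, i, i) != ref)
    stop("reference allele mismatch at ", pos)

  splice_translate <- function(genome) {
    ex <- model$exons
    bases <- unlist(Map(function(s, e) {
      strsplit(substr(genome, s - model$seq_offset + 1L,
                      e - model$seq_offset + 1L), "")[[1L]]
    }, ex$start, ex$end), use.names = FALSE)
    gp <- unlist(Map(seq.int, ex$start, ex$end), use.names = FALSE)
    keep <- gp >= model$cds_start & gp <= model$cds_end
    cds <- paste(bases[keep], collapse = "")
    if (model$strand == "-")
      cds <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1L]]),
                   collapse = "")
    n <- nchar(cds)
    st <- seq.int(1L, n, by = 3L)
    unname(GENETIC_CODE_TABLE[substring(cds, st, st + 2L)])
  }

  mutant <- model$sequence
  substr(mutant, i, i) <- alt
  wt <- splice_translate(model$sequence)
  mt <- splice_translate(mutant)
  d <- which(wt != mt)

  if (length(d) == 0L) {
    ex <- model$exons
    exonic <- any(pos >= ex$start & pos <= ex$end)
    if (exonic && pos >= model$cds_start && pos <= model$cds_end)
      return(list(category = "synonymous", term = "synonymous_variant",
                  protein_pos = NA_integer_, ref_aa = NA_character_,
                  alt_aa = NA_character_))
    region <- locus_region(model, pos)
    term <- region_to_term(region)
    return(list(category = classify_terms(term), term = term,
                protein_pos = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_))
  }
  first <- d[1L]
  term <-
    if (first == 1L && wt[1L] == "M" && mt[1L] != "M") "start_lost"
    else if (mt[first] == "*") "stop_gained"
    else if (wt[first] == "*") "stop_lost"
    else "missense_variant"
  list(category = classify_terms(term), term = term,
       protein_pos = as.integer(first), ref_aa = wt[first], alt_aa = mt[first])
}

#' Exhaustively enumerate the effects of every possible SNV on a locus
#'
#' For every position in the gene model's span and each of its three
#' alternate bases, computes the consequence term, category, codon/protein
#' change and exon index, all vectorized. This is the generator's ground
#' truth and the expected-spectrum oracle: observed substitution spectra
#' under uniform SNV simulation converge to the per-cell counts of this
#' enumeration.
#'
#' @param model A `gene_model`.
#' @return A data.frame with one row per (position, alt base): `pos`, `ref`,
#'   `alt` (genomic strand), `term`, `category`, `exon_index`, `protein_pos`,
#'   `ref_codon`, `alt_codon`, `codon_position`, `ref_aa`, `alt_aa`,
#'   `transition` (logical), `cpg` (logical: C>T/G>A at a CpG dinucleotide).
#' @export
enumerate_snv_effects <- function(model) {
  span <- model_span(model)
  allpos <- seq.int(span[1L], span[2L])
  region <- locus_region(model, allpos)
  refb <- strsplit(model$sequence, "")[[1L]]

  # CpG context on the genomic strand
  nextb <- c(refb[-1L], "N")
  prevb <- c("N", refb[-length(refb)])
  cpg_site <- (refb == "C" & nextb == "G") | (refb == "G" & prevb == "C")

  per_alt <- function(k) {  # k = 1..3 -> k-th alternate base per site
    alt <- vapply(refb, function(b) setdiff(DNA_BASES, b)[k], character(1),
                  USE.NAMES = FALSE)
    data.frame(pos = allpos, ref = refb, alt = alt, region = region,
               cpg_site = cpg_site, stringsAsFactors = FALSE)
  }
  df <- rbind(per_alt(1L), per_alt(2L), per_alt(3L))
  df$transition <- is_transition(df$ref, df$alt)
  df$cpg <- df$cpg_site &
    ((df$ref == "C" & df$alt == "T") | (df$ref == "G" & df$alt == "A"))
  df$cpg_site <- NULL

  df$exon_index <- NA_integer_
  exonic <- df$region %in% c("coding", "utr5", "utr3")
  df$exon_index[exonic] <- exon_index_of(model, df$pos[exonic])

  df$term <- NA_character_
  df$protein_pos <- NA_integer_
  df$ref_codon <- NA_character_; df$alt_codon <- NA_character_
  df$codon_position <- NA_integer_
  df$ref_aa <- NA_character_; df$alt_aa <- NA_character_

  nc <- df$region != "coding"
  df$term[nc] <- vapply(df$region[nc], region_to_term, character(1))

  co <- which(!nc)
  if (length(co)) {
    cp <- coding_positions(model)
    cds <- cds_sequence(model)
    idx <- match(df$pos[co], cp)
    codon_idx <- (idx - 1L) %/% 3L + 1L
    pos_in_codon <- (idx - 1L) %% 3L + 1L
    cstart <- (codon_idx - 1L) * 3L + 1L
    ref_cod <- substring(cds, cstart, cstart + 2L)
    tx_alt <- if (model$strand == "-") complement_base(df$alt[co]) else df$alt[co]
    alt_cod <- ref_cod
    substr(alt_cod, pos_in_codon, pos_in_codon) <- tx_alt
    ref_aa <- unname(GENETIC_CODE_TABLE[ref_cod])
    alt_aa <- unname(GENETIC_CODE_TABLE[alt_cod])
    term <- ifelse(codon_idx == 1L & alt_aa != "M", "start_lost",
            ifelse(ref_aa == alt_aa, "synonymous_variant",
            ifelse(alt_aa == "*", "stop_gained",
            ifelse(ref_aa == "*", "stop_lost", "missense_variant"))))
    df$term[co] <- term
    df$protein_pos[co] <- codon_idx
    df$ref_codon[co] <- ref_cod
    df$alt_codon[co] <- alt_cod
    df$codon_position[co] <- pos_in_codon
    df$ref_aa[co] <- ref_aa
    df$alt_aa[co] <- alt_aa
  }
  df$category <- unname(CONSEQUENCE_CATEGORY_MAP[df$term])
  df$region <- NULL
  rownames(df) <- NULL
  df
}
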
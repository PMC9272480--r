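# All tallies operate on the flat variant table. Where a variant carries
# several annotation rows (possible before transcript selection), the most
# severe category represents the variant.

# One row per distinct variant, labeled with its (most severe) category.
variant_level <- function(tbl) {
  if (nrow(tbl) == 0L) {
    out <- empty_variant_table()
    out$category <- character(0)
    return(out)
  }
  tbl$category <- classify_consequences(tbl$consequence)
  o <- order(match(variant_key(tbl), unique(variant_key(tbl))),
             category_severity(tbl$category))
  tbl <- tbl[o, , drop = FALSE]
  out <- tbl[!duplicated(variant_key(tbl)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally variants by consequence category
#'
#' Counts distinct variants per analysis category. Proportions are computed
#' over the coding categories (everything except `noncoding`) and sum to 1;
#' the noncoding fraction of all variants is reported separately, matching
#' the convention of reporting "61-66% missense among coding variants" next
#' to "90% intronic overall".
#'
#' @param tbl A cleaned variant table.
#' @return A list of class `category_tally`: `table` (data.frame `category`,
#'   `count`, `proportion_coding`), `n_coding`, `n_noncoding`, `n_total`,
#'   `noncoding_fraction`.
#' @export
tally_categories <- function(tbl) {
  v <- variant_level(tbl)
  cats <- consequence_categories()
  count <- vapply(cats, function(k) sum(v$category %in% k), integer(1))
  coding <- cats != "noncoding"
  n_coding <- sum(count[coding])
  prop <- rep(NA_real_, length(cats))
  if (n_coding > 0L) prop[coding] <- count[coding] / n_coding
  structure(list(
    table = data.frame(category = cats, count = as.integer(count),
                       proportion_coding = prop, row.names = NULL),
    n_coding = n_coding,
    n_noncoding = as.integer(count[!coding]),
    n_total = nrow(v),
    noncoding_fraction = if (nrow(v)) unname(count["noncoding"] / nrow(v))
                         else NA_real_
  ), class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  print(x$table)
  cat(sprintf("coding: %d, noncoding: %d (%.1f%% of all)\n", x$n_coding,
              x$n_noncoding, 100 * x$noncoding_fraction))
  invisible(x)
}

#' Tally single-nucleotide changes
#'
#' Counts the 12 ordered reference-to-alternate base changes among SNVs
#' (indels do not contribute). The strand convention is the reference
#' genome's plus strand, as reported in the input.
#'
#' @param tbl A cleaned variant table.
#' @param per_category Split counts by consequence category.
#' @return A data.frame `ref`, `alt`, `change` (e.g. `"G>A"`), `count`
#'   (and `category` when `per_category`).
#' @export
tally_nucleotide_changes <- function(tbl, per_category = FALSE) {
  v <- variant_level(tbl)
  snv <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L, , drop = FALSE]
  cells <- expand.grid(alt = DNA_BASES, ref = DNA_BASES,
                       stringsAsFactors = FALSE)[, c("ref", "alt")]
  cells <- cells[cells$ref != cells$alt, ]
  rownames(cells) <- NULL
  one <- function(d) {
    cells$change <- paste0(cells$ref, ">", cells$alt)
    cells$count <- vapply(seq_len(nrow(cells)), function(i)
      sum(d$ref == cells$ref[i] & d$alt == cells$alt[i]), integer(1))
    cells
  }
  if (!per_category) return(one(snv))
  do.call(rbind, lapply(split(snv, snv$category), function(d) {
    out <- one(d)
    out$category <- d$category[1L]
    out
  }))
}

#' Transition fraction of an SNV tally
#'
#' @param changes Output of [tally_nucleotide_changes()].
#' @return Fraction of tallied SNVs that are transitions (A<->G, C<->T).
#' @export
transition_fraction <- function(changes) {
  ts <- changes$change %in% c("A>G", "G>A", "C>T", "T>C")
  sum(changes$count[ts]) / sum(changes$count)
}

#' Amino-acid substitution spectrum
#'
#' Counts ordered (reference amino acid, alternate amino acid) pairs over the
#' annotations passing the category filter; `"*"` denotes stop. The marginal
#' per reference amino acid is the per-amino-acid mutation prevalence.
#'
#' @param tbl A cleaned variant table.
#' @param categories Categories to include (default missense only).
#' @return Object of class `substitution_spectrum`: data.frame `ref_aa`,
#'   `alt_aa`, `count` (cells with count > 0), with attribute `n_total`.
#' @export
substitution_spectrum <- function(tbl, categories = "missense") {
  v <- variant_level(tbl)
  v <- v[v$category %in% categories & !is.na(v$ref_aa) & !is.na(v$alt_aa) &
           v$ref_aa != v$alt_aa, , drop = FALSE]
  if (nrow(v) == 0L) {
    out <- data.frame(ref_aa = character(0), alt_aa = character(0),
                      count = integer(0))
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(v))),
                            by = list(ref_aa = v$ref_aa, alt_aa = v$alt_aa),
                            FUN = sum)
    out <- agg[order(-agg$count, agg$ref_aa, agg$alt_aa), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("substitution_spectrum", "data.frame"),
            n_total = nrow(v))
}

#' Top-k substitutions of a spectrum
#'
#' Ties break by descending count, then lexicographically on
#' (ref_aa, alt_aa).
#'
#' @param spectrum A [substitution_spectrum()].
#' @param k Number of substitutions to return.
#' @return The first `k` rows (fewer if the spectrum is smaller).
#' @export
top_substitutions <- function(spectrum, k = 10L) {
  utils::head(as.data.frame(spectrum), k)
}

#' Per-reference-amino-acid marginal of a spectrum
#'
#' @param spectrum A [substitution_spectrum()].
#' @return data.frame `ref_aa`, `count`, sorted by descending count.
#' @export
spectrum_ref_marginal <- function(spectrum) {
  df <- as.data.frame(spectrum)
  if (nrow(df) == 0L) return(data.frame(ref_aa = character(0),
                                        count = integer(0)))
  agg <- stats::aggregate(count ~ ref_aa, data = df, FUN = sum)
  agg <- agg[order(-agg$count, agg$ref_aa), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Reference amino acids affected by frameshift variants
#'
#' Counts the reference residue at the first altered codon of each
#' frameshift-classified variant (VEP's `protein_pos` convention).
#' Frameshifts lacking a protein position are counted under `"unknown"` with
#' a warning.
#'
#' @param tbl A cleaned variant table.
#' @return data.frame `ref_aa`, `count`, descending.
#' @export
frameshift_aa_tally <- function(tbl) {
  v <- variant_level(tbl)
  v <- v[v$category %in% "frameshift", , drop = FALSE]
  aa <- v$ref_aa
  miss <- is.na(v$protein_pos) | is.na(aa)
  if (any(miss)) {
    warning(sum(miss), " frameshift variant(s) without a protein position; ",
            "counted as 'unknown'")
    aa[miss] <- "unknown"
  }
  if (length(aa) == 0L)
    return(data.frame(ref_aa = character(0), count = integer(0)))
  tab <- table(aa)
  out <- data.frame(ref_aa = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$ref_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Source amino acids of stop-gain (truncation) variants
#'
#' Counts the reference amino acid replaced by a premature stop. The
#' mechanistic expectation from [stop_accessibility()] is that tryptophan and
#' tyrosine lead the per-codon rate.
#'
#' @param tbl A cleaned variant table.
#' @return data.frame `ref_aa`, `count`, descending.
#' @export
stop_gain_sources <- function(tbl) {
  v <- variant_level(tbl)
  v <- v[v$category %in% "truncation" & !is.na(v$ref_aa) &
           !is.na(v$alt_aa) & v$alt_aa == "*", , drop = FALSE]
  if (nrow(v) == 0L)
    return(data.frame(ref_aa = character(0), count = integer(0)))
  tab <- table(v$ref_aa)
  out <- data.frame(ref_aa = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$ref_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Codon positions altered by coding substitutions
#'
#' Tallies which codon position(s) (1, 2, 3) changed among variants carrying
#' a codon change, by default missense and synonymous variants. A variant
#' altering several positions (MNV) contributes each altered position.
#'
#' @param tbl A cleaned variant table.
#' @param categories Categories to include.
#' @return data.frame `codon_position` (1:3), `count`.
#' @export
codon_position_tally <- function(tbl, categories = c("missense",
                                                     "synonymous")) {
  v <- variant_level(tbl)
  v <- v[v$category %in% categories & !is.na(v$ref_codon) &
           !is.na(v$alt_codon), , drop = FALSE]
  pos <- unlist(mapply(codon_position_of_change, v$ref_codon, v$alt_codon,
                       SIMPLIFY = FALSE), use.names = FALSE)
  data.frame(codon_position = 1:3,
             count = vapply(1:3, function(p) sum(pos == p), integer(1)))
}

#' Distribution of variants over protein domains
#'
#' Counts protein-positioned variants per region of the architecture;
#' positions in no named region count as `linker`. Counts partition the
#' positioned variants. Length-normalized rates (count per 100 aa) are
#' reported alongside raw counts: a short domain can be a hotspot by rate
#' without leading the raw counts.
#'
#' @param tbl A cleaned variant table.
#' @param arch A `domain_architecture`.
#' @param normalize Also report counts per 100 aa.
#' @return data.frame `region`, `class`, `length_aa`, `count` (and
#'   `per_100aa` when `normalize`).
#' @export
domain_distribution <- function(tbl, arch, normalize = TRUE) {
  v <- variant_level(tbl)
  v <- v[!is.na(v$protein_pos), , drop = FALSE]
  # positions beyond the mature protein (the stop codon) have no domain
  v <- v[v$protein_pos <= arch$length_aa, , drop = FALSE]
  region <- map_to_domain(v$protein_pos, arch)
  rg <- arch$regions
  linker_len <- arch$length_aa - sum(rg$end_aa - rg$start_aa + 1L)
  out <- data.frame(
    region = c(rg$name, "linker"),
    class = c(rg$class, "linker"),
    length_aa = c(rg$end_aa - rg$start_aa + 1L, linker_len))
  out$count <- vapply(out$region, function(r) sum(region == r), integer(1))
  if (normalize)
    out$per_100aa <- ifelse(out$length_aa > 0, out$count * 100 / out$length_aa,
                            NA_real_)
  rownames(out) <- NULL
  out
}

#' Distribution of variants over exons
#'
#' Counts variants per 1-based exon ordinal (transcription order). The exon
#' index is taken from the annotation when present, otherwise computed from
#' the gene model; variants in no exon (intronic/flanking) are excluded and
#' counted separately.
#'
#' @param tbl A cleaned variant table.
#' @param model Optional `gene_model` used to fill in missing exon indices.
#' @return A list: `table` (data.frame `exon_index`, `count`),
#'   `n_not_exonic`.
#' @export
exon_distribution <- function(tbl, model = NULL) {
  v <- variant_level(tbl)
  idx <- v$exon_index
  if (!is.null(model)) {
    fill <- is.na(idx)
    if (any(fill)) idx[fill] <- exon_index_of(model, v$pos[fill])
  }
  known <- sort(unique(idx[!is.na(idx)]))
  if (!is.null(model)) known <- seq_len(nrow(model$exons))
  tab <- data.frame(
    exon_index = as.integer(known),
    count = vapply(known, function(e)
      sum(!is.na(idx) & idx == e), integer(1)))
  list(table = tab, n_not_exonic = sum(is.na(idx)))
}

#' Define a likely-pathogenic filter rule
#'
#' Combines SIFT and PolyPhen predictions into a screening rule. This is a
#' computational screen, not an ACMG clinical classification.
#'
#' @param mode One of `sift_only`, `polyphen_only`, `either`, `both`.
#' @param sift_damaging Set of SIFT labels counted damaging (subset of
#'   deleterious / deleterious_low_confidence / tolerated /
#'   tolerated_low_confidence).
#' @param polyphen_damaging Set of PolyPhen labels counted damaging (subset
#'   of probably_damaging / possibly_damaging / benign / unknown).
#' @return Object of class `pathogenicity_rule`.
#' @export
pathogenicity_rule <- function(mode = c("both", "either", "sift_only",
                                        "polyphen_only"),
                               sift_damaging = "deleterious",
                               polyphen_damaging = "probably_damaging") {
  mode <- match.arg(mode)
  sift_vocab <- c("deleterious", "deleterious_low_confidence", "tolerated",
                  "tolerated_low_confidence")
  pp_vocab <- c("probably_damaging", "possibly_damaging", "benign", "unknown")
  stopifnot(all(sift_damaging %in% sift_vocab),
            all(polyphen_damaging %in% pp_vocab))
  structure(list(mode = mode, sift_damaging = sift_damaging,
                 polyphen_damaging = polyphen_damaging),
            class = "pathogenicity_rule")
}

#' Apply a likely-pathogenic rule
#'
#' An annotation lacking both predictors is never pathogenic, under every
#' mode. Under `both`, both predictors must be present and damaging; under
#' `either`, one damaging call suffices.
#'
#' @param tbl A variant table (any number of rows).
#' @param rule A [pathogenicity_rule()].
#' @return Logical vector, one element per row.
#' @export
is_likely_pathogenic <- function(tbl, rule = pathogenicity_rule()) {
  sift_hit <- !is.na(tbl$sift_label) & tbl$sift_label %in% rule$sift_damaging
  pp_hit <- !is.na(tbl$polyphen_label) &
    tbl$polyphen_label %in% rule$polyphen_damaging
  switch(rule$mode,
         both = sift_hit & pp_hit,
         either = sift_hit | pp_hit,
         sift_only = sift_hit,
         polyphen_only = pp_hit)
}

#' Exon and domain distributions of the likely-pathogenic subset
#'
#' Filters the table with [is_likely_pathogenic()], then computes
#' [exon_distribution()] and [domain_distribution()] on the surviving
#' variants.
#'
#' @param tbl A cleaned variant table.
#' @param rule A [pathogenicity_rule()].
#' @param arch A `domain_architecture` (or `NULL` to skip domains).
#' @param model A `gene_model` (or `NULL`).
#' @return A list: `n_pathogenic`, `exon` (as [exon_distribution()]), `domain`
#'   (as [domain_distribution()], or `NULL`).
#' @export
pathogenic_distribution <- function(tbl, rule = pathogenicity_rule(),
                                    arch = NULL, model = NULL) {
  v <- variant_level(tbl)
  keep <- is_likely_pathogenic(v, rule)
  sub <- v[keep, , drop = FALSE]
  list(n_pathogenic = nrow(sub),
       exon = exon_distribution(sub, model),
       domain = if (!is.null(arch)) domain_distribution(sub, arch) else NULL)
}
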
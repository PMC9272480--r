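#' Configure the variant simulator
#'
#' Defines the mutation model for [simulate_variants()]. Two modes:
#'
#' * **Category-mix mode** (`category_mix` non-NULL, the default): variants
#'   are drawn stratified by consequence category so the emitted set has
#'   known ground-truth proportions. The default mix is the landscape
#'   reported for the MYBPC paralogs: among coding variants 63% missense,
#'   30% synonymous, 3% frameshift+truncation (split evenly), 2% inframe
#'   indels and 2% canonical splice variants, with 75% of all variants
#'   noncoding (the middle of the reported 62-90% range across paralogs).
#'   Within each category, distinct (site, allele) combinations are sampled
#'   without replacement; the transition/transversion indicator is drawn
#'   Bernoulli with probability `ts_tv_ratio / (ts_tv_ratio + 1)`
#'   independently of category, so both the category proportions and the
#'   transition fraction are recoverable from the output.
#' * **Mechanistic mode** (`category_mix = NULL`): sites are drawn per
#'   `positional_model` with replacement; alternate alleles are weighted
#'   `ts_tv_ratio` for the transition and 1/2 for each transversion, times
#'   `cpg_multiplier` for C>T (G>A) at CpG dinucleotides. Category
#'   proportions then emerge from the gene structure.
#'
#' @param n_variants Number of variants to emit.
#' @param category_mix Named proportions over coding categories (must sum to
#'   1), or `NULL` for mechanistic mode.
#' @param noncoding_fraction Fraction of all variants that are noncoding
#'   (category-mix mode only).
#' @param snv_fraction Fraction of variants that are SNVs (mechanistic mode;
#'   the rest are indels).
#' @param ts_tv_ratio Transition:transversion ratio (default 2, typical of
#'   human SNVs).
#' @param cpg_multiplier Rate multiplier (>= 1) for C>T/G>A at CpG sites,
#'   mechanistic mode only. 1 disables; 8 is a documented stand-in for the
#'   hypermutability that makes arginine codons (CGN) mutable.
#' @param indel_length_distribution Named probabilities over indel lengths
#'   1-6 nt (must sum to 1).
#' @param positional_model `uniform_genomic` or `uniform_coding`.
#' @param damaging_prob Named per-category probability that a simulated
#'   annotation gets damaging SIFT and PolyPhen labels (independently);
#'   categories absent from this vector get no predictor labels, mirroring
#'   VEP, which scores only missense.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `mutation_model`.
#' @export
mutation_model <- function(n_variants = 1000L,
                           category_mix = c(missense = 0.63,
                                            synonymous = 0.30,
                                            truncation = 0.015,
                                            frameshift = 0.015,
                                            inframe_indel = 0.02,
                                            splice = 0.02),
                           noncoding_fraction = 0.75,
                           snv_fraction = 0.9,
                           ts_tv_ratio = 2,
                           cpg_multiplier = 1,
                           indel_length_distribution = c("1" = 0.4, "2" = 0.2,
                                                         "3" = 0.15, "4" = 0.1,
                                                         "5" = 0.05, "6" = 0.1),
                           positional_model = c("uniform_genomic",
                                                "uniform_coding"),
                           damaging_prob = c(missense = 0.35),
                           seed = 1L) {
  positional_model <- match.arg(positional_model)
  stopifnot(n_variants >= 0L, ts_tv_ratio > 0, cpg_multiplier >= 1,
            snv_fraction >= 0, snv_fraction <= 1,
            noncoding_fraction >= 0, noncoding_fraction < 1,
            abs(sum(indel_length_distribution) - 1) < 1e-9,
            all(names(indel_length_distribution) %in% as.character(1:6)))
  if (!is.null(category_mix)) {
    stopifnot(abs(sum(category_mix) - 1) < 1e-9, all(category_mix >= 0))
    bad <- setdiff(names(category_mix),
                   setdiff(consequence_categories(),
                           c("noncoding", "protein_altering_other")))
    if (length(bad))
      stop("category_mix names not simulable: ", paste(bad, collapse = ", "))
  }
  structure(list(n_variants = as.integer(n_variants),
                 category_mix = category_mix,
                 noncoding_fraction = noncoding_fraction,
                 snv_fraction = snv_fraction, ts_tv_ratio = ts_tv_ratio,
                 cpg_multiplier = cpg_multiplier,
                 indel_length_distribution = indel_length_distribution,
                 positional_model = positional_model,
                 damaging_prob = damaging_prob, seed = as.integer(seed)),
            class = "mutation_model")
}

#' Generate a random valid gene model
#'
#' Builds a multi-exon protein-coding transcript with random sequence: ATG
#' start, single terminal stop, no internal stops, random-length UTRs,
#' introns and flanks. Minus-strand models are the reverse complement of the
#' equivalent plus-strand arrangement, with mirrored coordinates.
#'
#' @param n_exons Number of exons (>= 1).
#' @param cds_length_codons CDS length in codons, counting the stop (>= 2).
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @param gene_symbol,transcript_id,chrom Identifiers for the model.
#' @param intron_range,utr_range,flank Length ranges (nt) for introns, UTRs
#'   and the up/downstream flanks included in the locus sequence.
#' @return A validated `gene_model`, deterministic given the seed.
#' @export
make_gene_model <- function(n_exons = 3L, cds_length_codons = 200L,
                            strand = "+", seed = 1L,
                            gene_symbol = "SYNGENE",
                            transcript_id = "ENST00000000001",
                            chrom = "1",
                            intron_range = c(60L, 300L),
                            utr_range = c(30L, 120L), flank = 150L) {
  n_exons <- as.integer(n_exons)
  cds_length_codons <- as.integer(cds_length_codons)
  stopifnot(n_exons >= 1L, cds_length_codons >= 2L, strand %in% c("+", "-"))
  cds_nt <- 3L * cds_length_codons
  if (cds_nt < n_exons)
    stop("cannot split a ", cds_nt, " nt CDS over ", n_exons, " exons")
  set.seed(seed)

  codons <- names(GENETIC_CODE_TABLE)
  stops <- c("TAA", "TAG", "TGA")
  body <- sample(setdiff(codons, stops), cds_length_codons - 2L,
                 replace = TRUE)
  cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")

  rand_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")
  utr5 <- rand_seq(sample(utr_range[1L]:utr_range[2L], 1L))
  utr3 <- rand_seq(sample(utr_range[1L]:utr_range[2L], 1L))

  # split the CDS into n_exons chunks of >= 1 nt
  if (n_exons > 1L) {
    cuts <- sort(sample(seq_len(cds_nt - 1L), n_exons - 1L))
    sizes <- diff(c(0L, cuts, cds_nt))
  } else sizes <- cds_nt
  cds_parts <- substring(cds, cumsum(c(1L, sizes[-n_exons])),
                         cumsum(sizes))
  introns <- if (n_exons > 1L)
    vapply(seq_len(n_exons - 1L), function(i)
      rand_seq(sample(intron_range[1L]:intron_range[2L], 1L)), character(1))
  else character(0)

  # assemble in transcription order on a local plus strand
  exon_seqs <- cds_parts
  exon_seqs[1L] <- paste0(utr5, exon_seqs[1L])
  exon_seqs[n_exons] <- paste0(exon_seqs[n_exons], utr3)
  pieces <- character(2L * n_exons - 1L)
  pieces[seq(1L, by = 2L, length.out = n_exons)] <- exon_seqs
  if (n_exons > 1L) pieces[seq(2L, by = 2L, length.out = n_exons - 1L)] <- introns
  locus <- paste0(rand_seq(flank), paste(pieces, collapse = ""),
                  rand_seq(flank))

  # local 1-based coordinates of exons and CDS
  exon_len <- nchar(exon_seqs)
  intron_len <- nchar(introns)
  starts <- integer(n_exons); ends <- integer(n_exons)
  at <- flank + 1L
  for (i in seq_len(n_exons)) {
    starts[i] <- at
    ends[i] <- at + exon_len[i] - 1L
    at <- ends[i] + (if (i < n_exons) intron_len[i] else 0L) + 1L
  }
  cds_start <- starts[1L] + nchar(utr5)
  cds_end <- ends[n_exons] - nchar(utr3)

  if (strand == "-") {
    L <- nchar(locus)
    locus <- reverse_complement(locus)
    flip <- function(s, e) c(L - e + 1L, L - s + 1L)
    new <- t(mapply(flip, starts, ends))
    o <- order(new[, 1L])
    starts <- new[o, 1L]; ends <- new[o, 2L]
    cd <- flip(cds_start, cds_end)
    cds_start <- cd[1L]; cds_end <- cd[2L]
  }
  offset <- 10001L
  gene_model(gene_symbol = gene_symbol, transcript_id = transcript_id,
             chrom = chrom, strand = strand,
             exons = data.frame(start = starts + offset - 1L,
                                end = ends + offset - 1L),
             cds_start = cds_start + offset - 1L,
             cds_end = cds_end + offset - 1L,
             sequence = locus, seq_offset = offset)
}

# Largest-remainder apportionment of n into round(n * probs) summing to n.
apportion <- function(n, probs) {
  x <- floor(n * probs)
  r <- n - sum(x)
  if (r > 0) {
    frac <- n * probs - x
    add <- order(frac, decreasing = TRUE)[seq_len(r)]
    x[add] <- x[add] + 1L
  }
  as.integer(x)
}

sample_n <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Simulate variants on a gene model with known ground truth
#'
#' Emits `mm$n_variants` variant records (VCF conventions, SNV reference
#' bases always matching the model sequence, indels anchored), annotated with
#' [annotate_variant()], plus a ground-truth table computed at generation
#' time from the exhaustive SNV-effect enumeration (for SNVs) and from the
#' construction itself (for indels) — i.e. before and independently of the
#' annotation step.
#'
#' @param model A `gene_model`.
#' @param mm A [mutation_model()].
#' @param arch Optional `domain_architecture`; when given, the ground truth
#'   includes the true domain of each protein-positioned variant.
#' @return A list: `variants` (flat annotated variant table) and `truth`
#'   (data.frame, one row per emitted variant, same order).
#' @export
simulate_variants <- function(model, mm, arch = NULL) {
  set.seed(mm$seed)
  en <- enumerate_snv_effects(model)
  p_ts <- mm$ts_tv_ratio / (mm$ts_tv_ratio + 1)

  if (!is.null(mm$category_mix)) {
    parts <- simulate_mix(model, mm, en, p_ts)
  } else {
    parts <- simulate_mechanistic(model, mm, en, p_ts)
  }
  snvs <- parts$snvs    # rows of en
  indels <- parts$indels # data.frame pos, ref, alt, category + truth fields

  truth_snv <- if (nrow(snvs)) data.frame(
    chrom = model$chrom, pos = snvs$pos, ref = snvs$ref, alt = snvs$alt,
    true_category = snvs$category, true_term = snvs$term,
    true_protein_pos = snvs$protein_pos, true_ref_aa = snvs$ref_aa,
    true_alt_aa = snvs$alt_aa, true_codon_position = snvs$codon_position,
    true_exon_index = snvs$exon_index, stringsAsFactors = FALSE) else NULL
  truth_ind <- if (nrow(indels)) data.frame(
    chrom = model$chrom, pos = indels$pos, ref = indels$ref,
    alt = indels$alt, true_category = indels$category,
    true_term = indels$term, true_protein_pos = indels$protein_pos,
    true_ref_aa = indels$ref_aa, true_alt_aa = NA_character_,
    true_codon_position = NA_integer_, true_exon_index = indels$exon_index,
    stringsAsFactors = FALSE) else NULL
  truth <- rbind(truth_snv, truth_ind)
  if (is.null(truth) || nrow(truth) == 0L)
    return(list(variants = empty_variant_table(), truth = truth))

  perm <- sample.int(nrow(truth))
  truth <- truth[perm, , drop = FALSE]
  rownames(truth) <- NULL
  if (!is.null(arch)) {
    truth$true_domain <- NA_character_
    hasp <- !is.na(truth$true_protein_pos) &
      truth$true_protein_pos <= arch$length_aa
    truth$true_domain[hasp] <- map_to_domain(truth$true_protein_pos[hasp],
                                             arch)
  }

  anns <- lapply(seq_len(nrow(truth)), function(i)
    annotate_variant(model, truth$pos[i], truth$ref[i], truth$alt[i]))
  grab_chr <- function(col) vapply(anns, function(a)
    as.character(a[[col]]), character(1))
  grab_int <- function(col) vapply(anns, function(a)
    as.integer(a[[col]]), integer(1))
  out <- data.frame(
    chrom = model$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    rs_id = NA_character_,
    transcript_id = grab_chr("transcript_id"),
    gene_symbol = grab_chr("gene_symbol"),
    consequence = grab_chr("consequence"),
    exon_index = grab_int("exon_index"),
    ref_codon = grab_chr("ref_codon"), alt_codon = grab_chr("alt_codon"),
    protein_pos = grab_int("protein_pos"),
    ref_aa = grab_chr("ref_aa"), alt_aa = grab_chr("alt_aa"),
    sift_label = NA_character_, sift_score = NA_real_,
    polyphen_label = NA_character_, polyphen_score = NA_real_,
    stringsAsFactors = FALSE)

  # synthetic SIFT/PolyPhen labels per configured damaging probability
  # (generated, not predicted); recorded in the ground truth
  for (cat in names(mm$damaging_prob)) {
    k <- which(truth$true_category == cat)
    if (!length(k)) next
    p <- mm$damaging_prob[[cat]]
    sd <- stats::runif(length(k)) < p
    pd <- stats::runif(length(k)) < p
    out$sift_label[k] <- ifelse(sd, "deleterious", "tolerated")
    out$sift_score[k] <- round(ifelse(sd, stats::runif(length(k), 0, 0.05),
                                      stats::runif(length(k), 0.05, 1)), 3)
    out$polyphen_label[k] <- ifelse(pd, "probably_damaging", "benign")
    out$polyphen_score[k] <- round(ifelse(pd,
                                          stats::runif(length(k), 0.909, 1),
                                          stats::runif(length(k), 0, 0.446)),
                                   3)
  }
  truth$true_sift_label <- out$sift_label
  truth$true_polyphen_label <- out$polyphen_label
  list(variants = out, truth = truth)
}

# Stratified (category x transition) sampling of distinct SNVs and indels.
simulate_mix <- function(model, mm, en, p_ts) {
  n <- mm$n_variants
  n_nc <- apportion(n, c(mm$noncoding_fraction, 1 - mm$noncoding_fraction))[1L]
  n_coding <- n - n_nc
  mix <- mm$category_mix
  counts <- apportion(n_coding, mix)
  names(counts) <- names(mix)
  want <- c(counts, noncoding = n_nc)

  snv_cats <- intersect(names(want),
                        c("missense", "synonymous", "truncation", "splice",
                          "start_loss", "stop_loss", "noncoding"))
  snv_rows <- list()
  for (cat in snv_cats) {
    n_k <- want[[cat]]
    if (n_k == 0L) next
    pool <- which(en$category == cat)
    if (length(pool) < n_k)
      stop("gene model offers only ", length(pool), " distinct ", cat,
           " SNVs; ", n_k, " requested")
    pool_ts <- pool[en$transition[pool]]
    pool_tv <- pool[!en$transition[pool]]
    n_ts <- stats::rbinom(1L, n_k, p_ts)
    n_ts <- min(n_ts, length(pool_ts))
    n_tv <- n_k - n_ts
    if (n_tv > length(pool_tv)) {
      n_tv <- length(pool_tv)
      n_ts <- n_k - n_tv
    }
    snv_rows[[cat]] <- c(sample_n(pool_ts, n_ts), sample_n(pool_tv, n_tv))
  }
  snvs <- en[unlist(snv_rows, use.names = FALSE), , drop = FALSE]

  indels <- make_indels(model, mm,
                        n_frameshift = if ("frameshift" %in% names(want))
                          want[["frameshift"]] else 0L,
                        n_inframe = if ("inframe_indel" %in% names(want))
                          want[["inframe_indel"]] else 0L,
                        distinct = TRUE)
  list(snvs = snvs, indels = indels)
}

# Site-weighted sampling with replacement (duplicates possible, as in raw
# database exports).
simulate_mechanistic <- function(model, mm, en, p_ts) {
  n <- mm$n_variants
  n_snv <- stats::rbinom(1L, n, mm$snv_fraction)
  n_indel <- n - n_snv
  pool <- if (mm$positional_model == "uniform_coding")
    which(!is.na(en$protein_pos)) else seq_len(nrow(en))
  w <- ifelse(en$transition[pool], mm$ts_tv_ratio, 0.5) *
    ifelse(en$cpg[pool], mm$cpg_multiplier, 1)
  rows <- sample_n(pool, n_snv, replace = TRUE, prob = w)
  snvs <- en[rows, , drop = FALSE]

  n_fs <- 0L; n_if <- 0L
  if (n_indel > 0L) {
    lens <- as.integer(names(mm$indel_length_distribution))
    ldraw <- sample_n(lens, n_indel, replace = TRUE,
                      prob = mm$indel_length_distribution)
    n_if <- sum(ldraw %% 3L == 0L)
    n_fs <- n_indel - n_if
  }
  indels <- make_indels(model, mm, n_frameshift = n_fs, n_inframe = n_if,
                        distinct = FALSE)
  list(snvs = snvs, indels = indels)
}

# Coding indels: anchors chosen so both the anchor and the next base are
# coding, guaranteeing the intended frameshift/inframe classification.
make_indels <- function(model, mm, n_frameshift, n_inframe, distinct) {
  n_total <- n_frameshift + n_inframe
  empty <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), category = character(0),
                      term = character(0), protein_pos = integer(0),
                      ref_aa = character(0), exon_index = integer(0),
                      stringsAsFactors = FALSE)
  if (n_total == 0L) return(empty)
  span <- model_span(model)
  cp <- sort(coding_positions(model))
  anchors_ok <- cp[(cp + 1L) %in% cp & cp + 7L <= span[2L]]
  if (length(anchors_ok) < n_total && distinct)
    stop("not enough coding anchor positions for ", n_total, " indels")
  lens <- as.integer(names(mm$indel_length_distribution))
  probs <- mm$indel_length_distribution
  draw_len <- function(n, frameshift) {
    keep <- if (frameshift) lens %% 3L != 0L else lens %% 3L == 0L
    if (!any(keep)) stop("indel length distribution offers no ",
                         if (frameshift) "frameshift" else "inframe",
                         " lengths")
    sample_n(lens[keep], n, replace = TRUE, prob = probs[keep])
  }
  anchors <- sample_n(anchors_ok, n_total, replace = !distinct)
  L <- c(draw_len(n_frameshift, TRUE), draw_len(n_inframe, FALSE))
  category <- rep(c("frameshift", "inframe_indel"),
                  c(n_frameshift, n_inframe))
  is_del <- stats::runif(n_total) < 0.5

  pos <- anchors
  ref <- character(n_total); alt <- character(n_total)
  term <- character(n_total)
  for (i in seq_len(n_total)) {
    anchor_base <- seq_base(model, pos[i])
    if (is_del[i]) {
      ref[i] <- seq_base(model, pos[i], L[i] + 1L)
      alt[i] <- anchor_base
      term[i] <- if (category[i] == "frameshift") "frameshift_variant"
                 else "inframe_deletion"
    } else {
      ref[i] <- anchor_base
      alt[i] <- paste0(anchor_base,
                       paste(sample(DNA_BASES, L[i], replace = TRUE),
                             collapse = ""))
      term[i] <- if (category[i] == "frameshift") "frameshift_variant"
                 else "inframe_insertion"
    }
  }
  # generation-time truth: first affected codon from the construction
  cp_tx <- coding_positions(model)  # transcription order
  cds <- cds_sequence(model)
  protein_pos <- integer(n_total); ref_aa <- character(n_total)
  exon_index <- integer(n_total)
  for (i in seq_len(n_total)) {
    affected <- if (is_del[i]) (pos[i] + 1L):(pos[i] + L[i])
                else c(pos[i], pos[i] + 1L)
    idx <- match(affected, cp_tx)
    idx <- idx[!is.na(idx)]
    ci <- (min(idx) - 1L) %/% 3L + 1L
    protein_pos[i] <- ci
    ref_aa[i] <- translate_codon(substring(cds, 3L * ci - 2L, 3L * ci))
    exon_index[i] <- exon_index_of(model, affected[1L])
  }
  data.frame(pos = pos, ref = ref, alt = alt, category = category,
             term = term, protein_pos = protein_pos, ref_aa = ref_aa,
             exon_index = exon_index, stringsAsFactors = FALSE)
}

#' Write a variant table in the VEP tab dialect
#'
#' Emits the `--tab`-style file [read_vep_table()] consumes: `##` metadata,
#' a `#`-prefixed header, one row per annotation, codons in VEP case markup
#' (`gGg/gAg`), SIFT/PolyPhen as `label(score)`. Round-trips losslessly
#' through [read_vep_table()].
#'
#' @param tbl A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vep_table <- function(tbl, path) {
  dash <- function(x) ifelse(is.na(x), "-", as.character(x))
  aa_field <- ifelse(is.na(tbl$ref_aa), "-",
              ifelse(is.na(tbl$alt_aa), paste0(tbl$ref_aa, "/-"),
              ifelse(tbl$ref_aa == tbl$alt_aa, tbl$ref_aa,
                     paste0(tbl$ref_aa, "/", tbl$alt_aa))))
  cod_field <- ifelse(is.na(tbl$ref_codon) | is.na(tbl$alt_codon), "-",
                      markup_codons_safe(tbl$ref_codon, tbl$alt_codon))
  pred_field <- function(label, score)
    ifelse(is.na(label), "-",
           ifelse(is.na(score), label,
                  sprintf("%s(%.6g)", label, score)))
  df <- data.frame(
    "#Uploaded_variation" = sprintf("%s_%d_%s/%s", tbl$chrom, tbl$pos,
                                    tbl$ref, tbl$alt),
    Location = sprintf("%s:%d", tbl$chrom, tbl$pos),
    Allele = tbl$alt,
    SYMBOL = dash(tbl$gene_symbol),
    Gene = dash(tbl$gene_symbol),
    Feature = dash(tbl$transcript_id),
    Consequence = dash(tbl$consequence),
    EXON = dash(tbl$exon_index),
    Protein_position = dash(tbl$protein_pos),
    Amino_acids = aa_field,
    Codons = cod_field,
    Existing_variation = dash(tbl$rs_id),
    SIFT = pred_field(tbl$sift_label, tbl$sift_score),
    PolyPhen = pred_field(tbl$polyphen_label, tbl$polyphen_score),
    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## varscape synthetic VEP-dialect output", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

markup_codons_safe <- function(ref_codon, alt_codon) {
  out <- rep(NA_character_, length(ref_codon))
  ok <- !is.na(ref_codon) & !is.na(alt_codon)
  if (any(ok)) out[ok] <- markup_codons(ref_codon[ok], alt_codon[ok])
  out
}

#' Write distinct variants as VCF v4.2
#'
#' One row per distinct (chrom, pos, ref, alt); annotations are not emitted
#' (the VEP-dialect table carries those). Readable by [read_vcf()].
#'
#' @param tbl A variant table.
#' @param path Output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tbl, path) {
  v <- tbl[!duplicated(variant_key(tbl)), , drop = FALSE]
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=varscape_simulator",
               paste0("##contig=<ID=", paste(unique(v$chrom)), ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", v$chrom, v$pos,
                       ifelse(is.na(v$rs_id), ".", v$rs_id), v$ref, v$alt),
               con)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param truth Ground-truth data.frame from [simulate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
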
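# The working container throughout the package is a flat data.frame with one
# row per (variant, transcript annotation), mirroring VEP --tab output:
# chrom, pos, ref, alt, rs_id, transcript_id, gene_symbol, consequence,
# exon_index, ref_codon, alt_codon, protein_pos, ref_aa, alt_aa,
# sift_label, sift_score, polyphen_label, polyphen_score.
# A "variant" is a distinct (chrom, pos, ref, alt) key; its annotations are
# its rows.

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "rs_id", "transcript_id",
                     "gene_symbol", "consequence", "exon_index", "ref_codon",
                     "alt_codon", "protein_pos", "ref_aa", "alt_aa",
                     "sift_label", "sift_score", "polyphen_label",
                     "polyphen_score")

#' Variant identity keys
#'
#' Variant identity is `(chrom, pos, ref, alt)`; rsIDs are ignored because
#' database rows can share rsIDs across alternate alleles.
#'
#' @param tbl A variant table.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(tbl) {
  paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, sep = ":")
}

#' Number of distinct variants in a table
#'
#' @param tbl A variant table.
#' @return Count of distinct `(chrom, pos, ref, alt)` keys.
#' @export
n_variants <- function(tbl) length(unique(variant_key(tbl)))

empty_variant_table <- function(n = 0L) {
  ann <- empty_annotation()[rep(1L, n), , drop = FALSE]
  rownames(ann) <- NULL
  out <- data.frame(chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
                    ref = rep(NA_character_, n), alt = rep(NA_character_, n),
                    rs_id = rep(NA_character_, n), ann,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[, VARIANT_COLUMNS]
}

#' Column dialect of a VEP-style table
#'
#' Names the input columns holding each logical field, defaulting to the
#' VEP `--tab` output run with `--symbol --sift b --polyphen b`. The
#' reference allele is recovered from the `Uploaded_variation` key
#' (`chrom_pos_ref/alt`) unless a dedicated `ref` column is named.
#'
#' @param ... Overrides, e.g. `consequence = "CSQ"`.
#' @return Named list of column names (class `vep_dialect`).
#' @export
vep_dialect <- function(...) {
  d <- list(uploaded_variation = "Uploaded_variation", location = "Location",
            allele = "Allele", gene_symbol = "SYMBOL", gene = "Gene",
            transcript = "Feature", consequence = "Consequence",
            exon = "EXON", protein_position = "Protein_position",
            amino_acids = "Amino_acids", codons = "Codons",
            rs_id = "Existing_variation", sift = "SIFT",
            polyphen = "PolyPhen", ref = NULL)
  over <- list(...)
  d[names(over)] <- over
  structure(d, class = "vep_dialect")
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "-", ".", "NA")] <- NA_character_
  x
}

parse_predictor <- function(x) {
  x <- blank_to_na(x)
  label <- sub("\\(.*\\)$", "", x)
  score <- suppressWarnings(as.numeric(sub("^.*\\(([^)]*)\\)$", "\\1", x)))
  score[!grepl("\\(", ifelse(is.na(x), "", x))] <- NA_real_
  list(label = label, score = score)
}

#' Read a VEP-style tab-delimited annotation table
#'
#' Reads the `--tab` dialect (`##` metadata lines, a `#`-prefixed header, one
#' row per variant-transcript consequence) into the package's flat variant
#' table. Rows whose location or alleles cannot be parsed are counted and
#' skipped, never silently dropped; the count is attached as attribute
#' `n_skipped` (and a warning is raised).
#'
#' @param path Path to the table.
#' @param dialect A [vep_dialect()] naming the columns.
#' @return A variant table (see [variant_key()]); attributes `n_skipped` and
#'   `n_rows` record parsing totality (`nrow + n_skipped = n_rows`).
#' @export
read_vep_table <- function(path, dialect = vep_dialect()) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0L || all(!nzchar(lines))) {
    warning("empty VEP table: ", path)
    out <- empty_variant_table()
    attr(out, "n_skipped") <- 0L; attr(out, "n_rows") <- 0L
    return(out)
  }
  lines[1L] <- sub("^#", "", lines[1L])
  raw <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("VEP table has a header but no rows: ", path)
    out <- empty_variant_table()
    attr(out, "n_skipped") <- 0L; attr(out, "n_rows") <- 0L
    return(out)
  }
  need <- c("location", "allele", "consequence", "transcript")
  for (f in need) {
    if (!dialect[[f]] %in% names(raw))
      stop("VEP table is missing the mandatory '", f, "' column '",
           dialect[[f]], "'")
  }
  col <- function(f) {
    nm <- dialect[[f]]
    if (is.null(nm) || !nm %in% names(raw)) rep(NA_character_, nrow(raw))
    else as.character(raw[[nm]])
  }

  loc <- col("location")
  chrom <- sub(":.*$", "", loc)
  pos <- suppressWarnings(as.integer(sub("-.*$", "", sub("^[^:]*:", "", loc))))
  alt <- toupper(blank_to_na(col("allele")))
  ref <- toupper(blank_to_na(col("ref")))
  up <- col("uploaded_variation")
  from_key <- grepl("^.+_\\d+_[ACGTacgt]+/[ACGTacgt]+$", ifelse(is.na(up), "", up))
  ref_key <- toupper(sub("/.*$", "", sub("^.+_\\d+_", "", up)))
  ref[is.na(ref) & from_key] <- ref_key[is.na(ref) & from_key]

  ok <- !is.na(chrom) & nzchar(chrom) & !is.na(pos) & pos >= 1L &
    !is.na(ref) & !is.na(alt) & !grepl("[^ACGT]", ref) &
    !grepl("[^ACGT]", alt) & ref != alt
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(n_skipped, " row(s) with unparseable location or alleles skipped")

  aa <- blank_to_na(col("amino_acids"))
  aa_parts <- strsplit(ifelse(is.na(aa), "", aa), "/", fixed = TRUE)
  ref_aa <- vapply(aa_parts, function(p)
    if (length(p) >= 1L && nzchar(p[1L])) p[1L] else NA_character_, character(1))
  alt_aa <- vapply(aa_parts, function(p) {
    if (length(p) >= 2L) {
      if (nzchar(p[2L]) && p[2L] != "-") p[2L] else NA_character_
    } else if (length(p) == 1L && nzchar(p[1L])) p[1L] else NA_character_
  }, character(1))

  cod <- blank_to_na(col("codons"))
  cod_parsed <- lapply(cod, function(x) {
    if (is.na(x)) return(list(ref_codon = NA_character_,
                              alt_codon = NA_character_))
    parse_vep_codons(x)
  })

  sift <- parse_predictor(col("sift"))
  pp <- parse_predictor(col("polyphen"))

  out <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    rs_id = blank_to_na(col("rs_id")),
    transcript_id = blank_to_na(col("transcript")),
    gene_symbol = blank_to_na(col("gene_symbol")),
    consequence = blank_to_na(col("consequence")),
    exon_index = suppressWarnings(
      as.integer(sub("/.*$", "", blank_to_na(col("exon"))))),
    ref_codon = vapply(cod_parsed, `[[`, character(1), "ref_codon"),
    alt_codon = vapply(cod_parsed, `[[`, character(1), "alt_codon"),
    protein_pos = suppressWarnings(
      as.integer(sub("-.*$", "", blank_to_na(col("protein_position"))))),
    ref_aa = ref_aa, alt_aa = alt_aa,
    sift_label = sift$label, sift_score = sift$score,
    polyphen_label = pp$label, polyphen_score = pp$score,
    stringsAsFactors = FALSE)
  out <- out[ok, VARIANT_COLUMNS]
  rownames(out) <- NULL
  # group annotations of the same variant together, preserving row order
  out <- out[order(match(variant_key(out), unique(variant_key(out)))), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_rows") <- nrow(raw)
  out
}

#' Remove duplicate variant entries
#'
#' Drops exactly duplicated annotation rows, keeping the first occurrence;
#' annotations of duplicated variants that differ (e.g. other transcripts)
#' are retained, i.e. duplicate records' annotations are merged. Idempotent,
#' and the retained key set does not depend on input order.
#'
#' @param tbl A variant table.
#' @return The deduplicated table, with attribute `n_removed` (rows dropped).
#' @export
dedup_variants <- function(tbl) {
  dup <- duplicated(tbl[, VARIANT_COLUMNS])
  out <- tbl[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(dup)
  out
}

strip_transcript_version <- function(x) sub("\\.\\d+$", "", x)

#' Keep only annotations on the transcript(s) of interest
#'
#' Retains annotation rows whose transcript matches any of `transcript_id`
#' (version suffixes such as `.5` are stripped on both sides before
#' comparing, so `ENST00000361466.5` matches `ENST00000361466`). Variants
#' left with no matching annotation are dropped and counted.
#'
#' @param tbl A variant table.
#' @param transcript_id Character vector of acceptable transcript IDs (a
#'   canonical ID plus any documented aliases).
#' @return The filtered table, with attribute `n_dropped_variants`.
#' @export
select_transcript <- function(tbl, transcript_id) {
  stopifnot(length(transcript_id) >= 1L, all(nzchar(transcript_id)))
  want <- strip_transcript_version(transcript_id)
  keep <- strip_transcript_version(ifelse(is.na(tbl$transcript_id), "",
                                          tbl$transcript_id)) %in% want
  before <- unique(variant_key(tbl))
  out <- tbl[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- setdiff(before, unique(variant_key(out)))
  if (nrow(tbl) > 0L && nrow(out) == 0L)
    warning("no annotations matched transcript(s) ",
            paste(transcript_id, collapse = ", "))
  attr(out, "n_dropped_variants") <- length(dropped)
  out
}

#' Remove annotations on overlapping or neighboring genes
#'
#' Drops annotation rows whose gene symbol is excluded (genes overlapping or
#' flanking the target locus, e.g. AC117505.1 inside MYBPC1, or SPI1/MADD
#' around MYBPC3). A variant whose every annotation is excluded disappears
#' from the table. Per-symbol removal counts are attached for the cleaning
#' report.
#'
#' @param tbl A variant table.
#' @param target_gene The gene under study (kept; used for reporting only).
#' @param excluded_genes Character vector of gene symbols to remove; empty
#'   vector means identity.
#' @return Filtered table with attributes `removed_gene_symbols` (named
#'   counts) and `n_dropped_variants`.
#' @export
filter_overlapping_genes <- function(tbl, target_gene, excluded_genes) {
  stopifnot(nzchar(target_gene))
  drop <- !is.na(tbl$gene_symbol) & tbl$gene_symbol %in% excluded_genes
  removed <- table(factor(tbl$gene_symbol[drop], levels = excluded_genes))
  before <- unique(variant_key(tbl))
  out <- tbl[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_gene_symbols") <-
    stats::setNames(as.integer(removed), excluded_genes)
  attr(out, "n_dropped_variants") <-
    length(setdiff(before, unique(variant_key(out))))
  out
}

#' Read variants from a VCF
#'
#' Parses VCF v4.x via `vcfR` into the flat variant table. Multi-allelic
#' sites are decomposed into one record per alternate allele, so every
#' downstream stage sees biallelic records. The records carry no annotations
#' (annotate internally or join with a VEP table).
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A variant table with annotation columns `NA`.
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_table())
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  i <- rep(seq_len(nrow(fix)), n_alt)
  out <- empty_variant_table(length(i))
  out$chrom <- fix$CHROM[i]
  out$pos <- as.integer(fix$POS[i])
  out$ref <- toupper(fix$REF[i])
  out$alt <- toupper(unlist(alts))
  out$rs_id <- blank_to_na(fix$ID[i])
  rownames(out) <- NULL
  out
}

#' Run the full cleaning sequence with an audit report
#'
#' Applies, in order, [dedup_variants()], [select_transcript()] and
#' [filter_overlapping_genes()], and assembles a `cleaning_report` whose
#' stage counts (distinct variants) are non-increasing:
#' `n_input >= n_after_dedup >= n_after_transcript_filter >=
#' n_after_gene_filter`.
#'
#' @param tbl A variant table as read by [read_vep_table()].
#' @param transcript_id Transcript ID(s) for [select_transcript()].
#' @param target_gene,excluded_genes Passed to [filter_overlapping_genes()].
#' @return A list with `records` (the cleaned table) and `report` (class
#'   `cleaning_report`).
#' @export
run_cleaning <- function(tbl, transcript_id, target_gene,
                         excluded_genes = character(0)) {
  n_in <- n_variants(tbl)
  rows_in <- nrow(tbl)
  dd <- dedup_variants(tbl)
  tf <- select_transcript(dd, transcript_id)
  gf <- filter_overlapping_genes(tf, target_gene, excluded_genes)
  report <- structure(list(
    n_input = n_in,
    n_after_dedup = n_variants(dd),
    n_after_transcript_filter = n_variants(tf),
    n_after_gene_filter = n_variants(gf),
    rows_input = rows_in,
    rows_after_dedup = nrow(dd),
    rows_after_transcript_filter = nrow(tf),
    rows_after_gene_filter = nrow(gf),
    n_duplicate_rows_removed = attr(dd, "n_removed"),
    n_skipped_rows = attr(tbl, "n_skipped") %||% 0L,
    removed_gene_symbols = as.list(attr(gf, "removed_gene_symbols"))
  ), class = "cleaning_report")
  list(records = gf, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning report (distinct variants):\n")
  cat(sprintf("  input: %d  dedup: %d  transcript: %d  gene filter: %d\n",
              x$n_input, x$n_after_dedup, x$n_after_transcript_filter,
              x$n_after_gene_filter))
  cat(sprintf("  duplicate rows removed: %d; unparseable rows skipped: %d\n",
              x$n_duplicate_rows_removed, x$n_skipped_rows))
  rem <- unlist(x$removed_gene_symbols)
  if (length(rem) && any(rem > 0))
    cat("  removed gene annotations:",
        paste(sprintf("%s=%d", names(rem)[rem > 0], rem[rem > 0]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write a cleaned variant table / cleaning report
#'
#' @param tbl A variant table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_variant_table
#' @param report A `cleaning_report`.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
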
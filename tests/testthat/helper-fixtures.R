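# Shared fixtures, built in code.

# Minimal single-exon model with CDS "ATG GAA TGG TAA" (M E W *), checkable
# by hand. Exon spans exactly the CDS; 5 nt of flank on each side.
toy_model <- function(strand = "+") {
  cds <- "ATGGAATGGTAA"
  seq <- paste0("TTTTT", cds, "GGGGG")
  if (strand == "+") {
    gene_model("TOY", "ENST00000000099", "1", "+",
               exons = data.frame(start = 106L, end = 117L),
               cds_start = 106L, cds_end = 117L,
               sequence = seq, seq_offset = 101L)
  } else {
    # same protein encoded on the minus strand: reverse-complemented locus,
    # mirrored coordinates (locus is 22 nt at offset 101, span 101..122)
    gene_model("TOY", "ENST00000000099", "1", "-",
               exons = data.frame(start = 106L, end = 117L),
               cds_start = 106L, cds_end = 117L,
               sequence = reverse_complement(seq), seq_offset = 101L)
  }
}

# Mirror a plus-strand model into the equivalent minus-strand gene, and map
# variants into its coordinates, for strand-symmetry checks.
mirror_model <- function(model) {
  span <- c(model$seq_offset,
            model$seq_offset + nchar(model$sequence) - 1L)
  flip <- function(s, e) c(span[1L] + span[2L] - e, span[1L] + span[2L] - s)
  ex <- t(mapply(flip, model$exons$start, model$exons$end))
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  cds <- flip(model$cds_start, model$cds_end)
  gene_model(model$gene_symbol, model$transcript_id, model$chrom,
             if (model$strand == "+") "-" else "+",
             exons = data.frame(start = ex[, 1L], end = ex[, 2L]),
             cds_start = cds[1L], cds_end = cds[2L],
             sequence = reverse_complement(model$sequence),
             seq_offset = span[1L])
}

mirror_snv <- function(model, pos, ref, alt) {
  span <- c(model$seq_offset,
            model$seq_offset + nchar(model$sequence) - 1L)
  list(pos = span[1L] + span[2L] - pos,
       ref = chartr("ACGT", "TGCA", ref),
       alt = chartr("ACGT", "TGCA", alt))
}

# drop bookkeeping attributes so tables compare on content
strip_attrs <- function(d) {
  for (nm in setdiff(names(attributes(d)), c("names", "row.names", "class")))
    attr(d, nm) <- NULL
  rownames(d) <- NULL
  d
}

# transition fraction over emitted SNV rows (no key collapsing)
raw_transition_fraction <- function(tbl) {
  snv <- nchar(tbl$ref) == 1 & nchar(tbl$alt) == 1
  ch <- paste0(tbl$ref[snv], ">", tbl$alt[snv])
  mean(ch %in% c("A>G", "G>A", "C>T", "T>C"))
}

# blank flat variant table with n rows, for constructing cases by hand
empty_variant_table_public <- function(n) {
  data.frame(chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
             ref = rep(NA_character_, n), alt = rep(NA_character_, n),
             rs_id = rep(NA_character_, n),
             transcript_id = rep(NA_character_, n),
             gene_symbol = rep(NA_character_, n),
             consequence = rep(NA_character_, n),
             exon_index = rep(NA_integer_, n),
             ref_codon = rep(NA_character_, n),
             alt_codon = rep(NA_character_, n),
             protein_pos = rep(NA_integer_, n),
             ref_aa = rep(NA_character_, n), alt_aa = rep(NA_character_, n),
             sift_label = rep(NA_character_, n),
             sift_score = rep(NA_real_, n),
             polyphen_label = rep(NA_character_, n),
             polyphen_score = rep(NA_real_, n), stringsAsFactors = FALSE)
}

seq_base_public <- function(model, pos) {
  i <- pos - model$seq_offset + 1L
  substr(model$sequence, i, i)
}

# some alternate base differing from the reference at pos
alt_of <- function(model, pos) {
  setdiff(c("A", "C", "G", "T"), seq_base_public(model, pos))[1L]
}

# Write a small VEP-dialect table from lines of fields (list of character
# vectors in header order), returning the path.
write_vep_fixture <- function(rows,
                              header = c("#Uploaded_variation", "Location",
                                         "Allele", "SYMBOL", "Gene",
                                         "Feature", "Consequence", "EXON",
                                         "Protein_position", "Amino_acids",
                                         "Codons", "Existing_variation",
                                         "SIFT", "PolyPhen")) {
  path <- tempfile(fileext = ".tsv")
  body <- vapply(rows, paste, character(1), collapse = "\t")
  writeLines(c("## test fixture", paste(header, collapse = "\t"), body), path)
  path
}

vep_row <- function(uploaded, location, allele, symbol = "MYBPC1",
                    feature = "ENST00000361466", consequence = "missense_variant",
                    exon = "2/34", protein_pos = "10", aa = "G/E",
                    codons = "gGg/gAg", rs = "-", sift = "-", polyphen = "-") {
  c(uploaded, location, allele, symbol, symbol, feature, consequence, exon,
    protein_pos, aa, codons, rs, sift, polyphen)
}
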
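#' Construct a gene model
#'
#' A gene model is the transcript structure the internal annotator works
#' against: exon intervals, the coding span, the strand, and the reference
#' sequence of the locus (exons plus introns plus flanks).
#'
#' Coordinates are 1-based inclusive genomic positions (VCF convention).
#' `sequence` covers `[seq_offset, seq_offset + nchar(sequence) - 1]` on the
#' plus strand of the reference; minus-strand transcripts are handled by
#' complementing at annotation time.
#'
#' @param gene_symbol,transcript_id,chrom Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (1-based
#'   inclusive), sorted ascending, non-overlapping.
#' @param cds_start,cds_end Genomic bounds of the coding span (inclusive);
#'   must lie within the exon union, and the spliced CDS must be a multiple
#'   of 3, at least 6 nt, begin with ATG and end with a stop codon in
#'   transcription order.
#' @param sequence Plus-strand reference sequence of the locus.
#' @param seq_offset Genomic coordinate of the first base of `sequence`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_symbol, transcript_id, chrom, strand, exons,
                       cds_start, cds_end, sequence, seq_offset) {
  model <- structure(
    list(gene_symbol = gene_symbol, transcript_id = transcript_id,
         chrom = as.character(chrom), strand = strand,
         exons = data.frame(start = as.integer(exons$start),
                            end = as.integer(exons$end)),
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         sequence = toupper(sequence), seq_offset = as.integer(seq_offset)),
    class = "gene_model")
  validate_gene_model(model)
  model
}

#' Validate a gene model
#'
#' Checks exon ordering, CDS placement within exons, spliced CDS length
#' (multiple of 3, >= 6), the ATG start and a terminal stop codon.
#'
#' @param model A `gene_model`.
#' @return The model, invisibly; errors describe the violated invariant.
#' @export
validate_gene_model <- function(model) {
  ex <- model$exons
  stopifnot(model$strand %in% c("+", "-"), nrow(ex) >= 1L)
  if (any(ex$end < ex$start)) stop("exon end before start")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex$start, strictly = TRUE))
      stop("exons must be sorted ascending by start")
    if (any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("exons overlap or abut out of order")
  }
  span <- model_span(model)
  if (ex$start[1L] < span[1L] || ex$end[nrow(ex)] > span[2L])
    stop("exons extend beyond the provided sequence span")
  if (grepl("[^ACGT]", model$sequence)) stop("sequence contains non-ACGT")
  in_exon <- function(p) any(p >= ex$start & p <= ex$end)
  if (!in_exon(model$cds_start) || !in_exon(model$cds_end))
    stop("CDS bounds must lie within exons")
  cds <- cds_sequence(model)
  if (nchar(cds) %% 3L != 0L || nchar(cds) < 6L)
    stop("spliced CDS length must be a multiple of 3 and >= 6, got ",
         nchar(cds))
  aa <- translate_cds(cds)
  if (aa[1L] != "M") stop("spliced CDS does not begin with ATG")
  if (aa[length(aa)] != "*") stop("spliced CDS does not end with a stop codon")
  invisible(model)
}

model_span <- function(model) {
  c(model$seq_offset, model$seq_offset + nchar(model$sequence) - 1L)
}

# Plus-strand reference base(s) at genomic position(s), vectorized.
seq_base <- function(model, pos, width = 1L) {
  i <- pos - model$seq_offset + 1L
  substring(model$sequence, i, i + width - 1L)
}

#' Coding positions and spliced CDS of a gene model
#'
#' `coding_positions()` returns the genomic positions of coding bases in
#' transcription order (5' to 3' of the mRNA: ascending for `+`, descending
#' for `-`); `cds_sequence()` returns the spliced CDS in reading-frame
#' orientation (reverse-complemented for minus-strand models).
#'
#' @param model A `gene_model`.
#' @return Integer vector of genomic positions / a single CDS string.
#' @export
coding_positions <- function(model) {
  ex <- model$exons
  pos <- unlist(Map(seq.int, ex$start, ex$end), use.names = FALSE)
  pos <- pos[pos >= model$cds_start & pos <= model$cds_end]
  if (model$strand == "-") rev(pos) else pos
}

#' @rdname coding_positions
#' @export
cds_sequence <- function(model) {
  cp <- coding_positions(model)
  bases <- seq_base(model, if (model$strand == "-") rev(cp) else cp)
  cds <- paste(bases, collapse = "")
  if (model$strand == "-") reverse_complement(cds) else cds
}

# 1-based exon ordinal in transcription order, NA if not exonic.
exon_index_of <- function(model, pos) {
  ex <- model$exons
  idx <- vapply(pos, function(p) {
    k <- which(p >= ex$start & p <= ex$end)
    if (length(k)) k else NA_integer_
  }, integer(1))
  if (model$strand == "-") nrow(ex) + 1L - idx else idx
}

# Classify a genomic position relative to the transcript:
# coding / splice_donor / splice_acceptor / intron / utr5 / utr3 /
# upstream / downstream.
locus_region <- function(model, pos) {
  ex <- model$exons
  n <- nrow(ex)
  vapply(pos, function(p) {
    if (p < ex$start[1L])
      return(if (model$strand == "+") "upstream" else "downstream")
    if (p > ex$end[n])
      return(if (model$strand == "+") "downstream" else "upstream")
    k <- which(p >= ex$start & p <= ex$end)
    if (length(k)) {
      if (p >= model$cds_start && p <= model$cds_end) return("coding")
      before_cds <- p < model$cds_start
      if (model$strand == "+") return(if (before_cds) "utr5" else "utr3")
      return(if (before_cds) "utr3" else "utr5")
    }
    # intronic: intron i lies between exon i and i+1 (genomic order)
    i <- max(which(ex$end < p))
    left <- ex$end[i]        # last base of genomic-left exon
    right <- ex$start[i + 1L] # first base of genomic-right exon
    off5 <- p - left          # 1,2 = first two intron bases, genomic left
    off3 <- right - p         # 1,2 = last two intron bases, genomic right
    if (model$strand == "+") {
      if (off5 <= 2L) return("splice_donor")
      if (off3 <= 2L) return("splice_acceptor")
    } else {
      if (off3 <= 2L) return("splice_donor")
      if (off5 <= 2L) return("splice_acceptor")
    }
    "intron"
  }, character(1))
}

#' Write a gene model to disk
#'
#' Serializes the transcript structure as a GFF3-like TSV (feature, start,
#' end, strand plus identifying attributes) and the locus sequence as FASTA
#' with the span encoded in the header.
#'
#' @param model A `gene_model`.
#' @param tsv_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gene_model <- function(model, tsv_path, fasta_path) {
  feats <- rbind(
    data.frame(feature = "exon", start = model$exons$start,
               end = model$exons$end),
    data.frame(feature = "CDS", start = model$cds_start,
               end = model$cds_end))
  feats$strand <- model$strand
  feats$attributes <- sprintf("gene=%s;transcript=%s;chrom=%s",
                              model$gene_symbol, model$transcript_id,
                              model$chrom)
  utils::write.table(feats, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  span <- model_span(model)
  seq <- Biostrings::DNAStringSet(model$sequence)
  names(seq) <- sprintf("%s:%d-%d", model$chrom, span[1L], span[2L])
  Biostrings::writeXStringSet(seq, fasta_path)
  invisible(c(tsv_path, fasta_path))
}

#' Read a gene model written by [write_gene_model()]
#'
#' @param tsv_path,fasta_path Paths produced by [write_gene_model()].
#' @return A validated `gene_model`.
#' @export
read_gene_model <- function(tsv_path, fasta_path) {
  feats <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  attrs <- strsplit(feats$attributes[1L], ";", fixed = TRUE)[[1L]]
  kv <- do.call(rbind, strsplit(attrs, "=", fixed = TRUE))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  hdr <- names(seqs)[1L]
  offset <- as.integer(sub("^.*:(\\d+)-\\d+$", "\\1", hdr))
  ex <- feats[feats$feature == "exon", c("start", "end")]
  ex <- ex[order(ex$start), , drop = FALSE]
  cds <- feats[feats$feature == "CDS", ]
  gene_model(gene_symbol = meta[["gene"]], transcript_id = meta[["transcript"]],
             chrom = meta[["chrom"]], strand = feats$strand[1L],
             exons = ex, cds_start = cds$start[1L], cds_end = cds$end[1L],
             sequence = as.character(seqs[[1L]]), seq_offset = offset)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %s (%s) %s strand %s\n", x$gene_symbol,
              x$transcript_id, x$chrom, x$strand))
  cat(sprintf("  %d exon(s), CDS %d-%d, locus %d nt\n", nrow(x$exons),
              x$cds_start, x$cds_end, nchar(x$sequence)))
  invisible(x)
}
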
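DOMAIN_CLASSES <- c("Ig", "Fn3", "PA_rich", "M_domain", "loop", "linker")

#' Construct a protein domain architecture
#'
#' An ordered set of non-overlapping amino-acid intervals (1-based,
#' inclusive), UniProt-style. Named regions need not tile the protein; gaps
#' are implicit linkers. For MyBP-C family proteins the regions are the
#' C0-C10 modules (immunoglobulin-like or fibronectin type III), the
#' proline/alanine-rich region and the phosphorylatable M-domain.
#'
#' @param protein_name Protein label.
#' @param length_aa Protein length in amino acids.
#' @param regions data.frame with columns `name`, `class` (one of
#'   `r paste(DOMAIN_CLASSES, collapse = ", ")`), `start_aa`, `end_aa`
#'   (1-based inclusive), sorted and non-overlapping, within
#'   `[1, length_aa]`.
#' @return Object of class `domain_architecture`.
#' @export
domain_architecture <- function(protein_name, length_aa, regions) {
  regions <- data.frame(name = as.character(regions$name),
                        class = as.character(regions$class),
                        start_aa = as.integer(regions$start_aa),
                        end_aa = as.integer(regions$end_aa),
                        stringsAsFactors = FALSE)
  length_aa <- as.integer(length_aa)
  stopifnot(length_aa >= 1L, nrow(regions) >= 1L)
  if (!all(regions$class %in% DOMAIN_CLASSES))
    stop("unknown domain class(es): ",
         paste(setdiff(regions$class, DOMAIN_CLASSES), collapse = ", "))
  if (any(regions$end_aa < regions$start_aa))
    stop("region end before start")
  if (any(regions$start_aa < 1L) || any(regions$end_aa > length_aa))
    stop("regions must lie within [1, length_aa]")
  o <- order(regions$start_aa)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$start_aa[-1L] <= regions$end_aa[-nrow(regions)]))
    stop("regions overlap")
  rownames(regions) <- NULL
  structure(list(protein_name = protein_name, length_aa = length_aa,
                 regions = regions),
            class = "domain_architecture")
}

#' Map protein positions to domains
#'
#' @param protein_pos Integer vector of 1-based amino-acid positions.
#' @param arch A `domain_architecture`.
#' @return Character vector of region names; positions in no named region map
#'   to `"linker"`. Boundaries are inclusive: `protein_pos == end_aa` maps to
#'   that region. Positions beyond the protein raise an error.
#' @examples
#' arch <- domain_architecture("toy", 200,
#'   data.frame(name = c("C1", "C2"), class = "Ig",
#'              start_aa = c(1, 101), end_aa = c(100, 200)))
#' map_to_domain(c(100, 101), arch)
#' @export
map_to_domain <- function(protein_pos, arch) {
  protein_pos <- as.integer(protein_pos)
  if (any(protein_pos < 1L | protein_pos > arch$length_aa, na.rm = TRUE))
    stop("protein position outside [1, ", arch$length_aa, "]")
  rg <- arch$regions
  vapply(protein_pos, function(p) {
    if (is.na(p)) return(NA_character_)
    k <- which(p >= rg$start_aa & p <= rg$end_aa)
    if (length(k)) rg$name[k] else "linker"
  }, character(1))
}

#' Read / write a domain-architecture TSV
#'
#' The file format is a TSV with columns `name`, `class`, `start_aa`,
#' `end_aa`; the protein name and length are carried in `##protein=` and
#' `##length_aa=` header lines. This is the hand-off point for real UniProt
#' boundaries (e.g. the Q14896/Q86TC9/Q14324 feature tables): transcribe the
#' domain rows into this format.
#'
#' @param path File path.
#' @return [read_domain_architecture()]: a `domain_architecture`.
#' @export
read_domain_architecture <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  kv <- sub("^##", "", meta)
  kvl <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kvl, `[`, character(1), 2L),
                          vapply(kvl, `[`, character(1), 1L))
  body <- lines[!startsWith(lines, "##")]
  regions <- utils::read.delim(text = paste(body, collapse = "\n"),
                               stringsAsFactors = FALSE)
  domain_architecture(protein_name = vals[["protein"]],
                      length_aa = as.integer(vals[["length_aa"]]),
                      regions = regions)
}

#' @rdname read_domain_architecture
#' @param arch A `domain_architecture`.
#' @export
write_domain_architecture <- function(arch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("##protein=%s", arch$protein_name),
               sprintf("##length_aa=%d", arch$length_aa)), con)
  utils::write.table(arch$regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("domain_architecture: %s (%d aa, %d regions)\n",
              x$protein_name, x$length_aa, nrow(x$regions)))
  print(x$regions)
  invisible(x)
}

#' Generate a MyBP-C-like domain architecture
#'
#' Lays out `n_domains` modules named C1..Cn (plus an N-terminal C0 when
#' `include_c0`, the cardiac layout) over a protein, with short linkers
#' between them. Domains C6, C7 and C9 are classed fibronectin type III and
#' the rest immunoglobulin-like, mirroring the family layout; a PA-rich
#' region precedes C1.
#'
#' @param protein_length Protein length (aa).
#' @param n_domains Number of C-domains after any C0.
#' @param include_c0 Add the cardiac-specific N-terminal C0 domain.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @return A `domain_architecture`.
#' @export
make_architecture <- function(protein_length, n_domains, include_c0 = FALSE,
                              seed = 1L) {
  protein_length <- as.integer(protein_length)
  n_domains <- as.integer(n_domains)
  stopifnot(n_domains >= 1L)
  names <- c(if (include_c0) "C0", "PA", paste0("C", seq_len(n_domains)))
  n_regions <- length(names)
  # minimum feasible: ~10 aa per region plus 1-aa linkers
  if (protein_length < n_regions * 12L)
    stop("protein_length ", protein_length, " too short for ", n_regions,
         " regions")
  set.seed(seed)
  # draw region lengths around 90 aa (PA shorter), then fit with linkers
  base_len <- ifelse(names == "PA", 30L, 90L)
  len <- pmax(10L, round(base_len * stats::runif(n_regions, 0.7, 1.3)))
  linker_budget <- protein_length - sum(len)
  while (linker_budget < n_regions + 1L) {
    len <- pmax(10L, len - 5L)
    linker_budget <- protein_length - sum(len)
  }
  # split the spare length into n_regions + 1 linker gaps
  cuts <- sort(sample.int(linker_budget, n_regions, replace = TRUE))
  gaps <- diff(c(0L, cuts))
  start <- cumsum(c(1L, len[-n_regions])) + cumsum(gaps)
  regions <- data.frame(name = names,
                        class = ifelse(names %in% c("C6", "C7", "C9"), "Fn3",
                                ifelse(names == "PA", "PA_rich", "Ig")),
                        start_aa = start, end_aa = start + len - 1L)
  domain_architecture(protein_name = sprintf("synthetic_MyBPC_like_%daa",
                                             protein_length),
                      length_aa = protein_length, regions = regions)
}
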
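#' Configure a pipeline run
#'
#' @param mode `"real"` (read an existing VEP table) or `"synthetic"`
#'   (generate a gene model and variants first).
#' @param vep_path VEP-dialect table to analyze (required in real mode;
#'   written in synthetic mode).
#' @param transcript_id Transcript ID(s) to select (aliases allowed; version
#'   suffixes ignored).
#' @param target_gene Gene symbol under study.
#' @param excluded_genes Overlapping/neighboring gene symbols whose
#'   annotations are removed. This is configuration, not a constant: overlap
#'   sets change with annotation releases. The shipped MYBPC defaults live in
#'   [mybpc_config()].
#' @param gene_model_tsv,gene_model_fasta Optional serialized gene model
#'   (see [write_gene_model()]); synthetic mode generates one when absent.
#' @param architecture_path Optional domain-architecture TSV; when absent,
#'   domain tables are skipped with a logged warning (real mode) or a
#'   synthetic architecture is generated (synthetic mode).
#' @param rule A [pathogenicity_rule()].
#' @param top_k Size of the top-substitution table.
#' @param mm A [mutation_model()] (synthetic mode).
#' @param outdir Output directory for tables; `NULL` writes nothing.
#' @param seed Integer seed used for all randomness in synthetic mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), vep_path = NULL,
                       transcript_id = "ENST00000000001",
                       target_gene = "SYNGENE",
                       excluded_genes = character(0),
                       gene_model_tsv = NULL, gene_model_fasta = NULL,
                       architecture_path = NULL,
                       rule = pathogenicity_rule(), top_k = 10L,
                       mm = NULL, outdir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(top_k >= 1L)
  if (mode == "real" && is.null(vep_path))
    stop("real mode requires vep_path")
  structure(list(mode = mode, vep_path = vep_path,
                 transcript_id = transcript_id, target_gene = target_gene,
                 excluded_genes = excluded_genes,
                 gene_model_tsv = gene_model_tsv,
                 gene_model_fasta = gene_model_fasta,
                 architecture_path = architecture_path, rule = rule,
                 top_k = as.integer(top_k), mm = mm, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file with the fields of [run_config()]; a nested
#' `mutation_model:` block is passed to [mutation_model()] and a nested
#' `rule:` block to [pathogenicity_rule()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mm <- if (!is.null(y$mutation_model)) {
    args <- y$mutation_model
    if (!is.null(args$category_mix)) args$category_mix <- unlist(args$category_mix)
    if (!is.null(args$indel_length_distribution))
      args$indel_length_distribution <- unlist(args$indel_length_distribution)
    if (!is.null(args$damaging_prob)) args$damaging_prob <- unlist(args$damaging_prob)
    do.call(mutation_model, args)
  }
  rule <- if (!is.null(y$rule)) do.call(pathogenicity_rule, y$rule)
          else pathogenicity_rule()
  run_config(mode = y$mode %||% "synthetic", vep_path = y$vep_path,
             transcript_id = y$transcript_id %||% "ENST00000000001",
             target_gene = y$target_gene %||% "SYNGENE",
             excluded_genes = unlist(y$excluded_genes) %||% character(0),
             gene_model_tsv = y$gene_model_tsv,
             gene_model_fasta = y$gene_model_fasta,
             architecture_path = y$architecture_path, rule = rule,
             top_k = y$top_k %||% 10L, mm = mm, outdir = y$outdir,
             seed = y$seed %||% 1L)
}

#' Shipped configuration for the MYBPC paralogs
#'
#' The per-paralog transcript IDs and overlapping-gene exclusion lists used
#' for the three myosin binding protein-C genes. The MYBPC3 transcript ID is
#' shipped verbatim as printed in the source material (`ENST0000545968`, a
#' 13-character ID) together with the standard 15-character Ensembl alias
#' `ENST00000545968`; transcript matching accepts either.
#'
#' @return Named list (MYBPC1/MYBPC2/MYBPC3) of lists with `transcript_id`
#'   (character vector: ID plus aliases) and `excluded_genes`.
#' @export
mybpc_config <- function() {
  list(
    MYBPC1 = list(transcript_id = "ENST00000361466",
                  excluded_genes = "AC117505.1"),
    MYBPC2 = list(transcript_id = "ENST00000357701",
                  excluded_genes = c("AC020909.1", "SPIB", "FAM71E1")),
    MYBPC3 = list(transcript_id = c("ENST0000545968", "ENST00000545968"),
                  excluded_genes = c("MADD", "SPI1"))
  )
}

#' Run the full variant-landscape pipeline
#'
#' Executes ingestion, cleaning (dedup, transcript selection, overlapping-
#' gene removal), consequence classification and every landscape summary in
#' order, logging input/output counts at each stage. Deterministic for fixed
#' inputs and seed.
#'
#' @param cfg A [run_config()].
#' @return A list of class `varscape_bundle`: `config`, `report`
#'   (`cleaning_report`), `categories`, `nucleotide_changes`,
#'   `codon_positions`, `spectrum`, `top_substitutions`,
#'   `missense_aa_marginal`, `frameshift_aa`, `stop_gain_sources`, `domain`,
#'   `exon`, `pathogenic`, `pathogenic_mode_counts`, `truth` (synthetic mode),
#'   `log` (character vector).
#' @export
run_pipeline <- function(cfg) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  model <- NULL
  arch <- NULL
  truth <- NULL

  if (!is.null(cfg$gene_model_tsv))
    model <- read_gene_model(cfg$gene_model_tsv, cfg$gene_model_fasta)
  if (!is.null(cfg$architecture_path))
    arch <- read_domain_architecture(cfg$architecture_path)

  if (cfg$mode == "synthetic") {
    mm <- cfg$mm %||% mutation_model(seed = cfg$seed)
    if (is.null(model)) {
      model <- make_gene_model(n_exons = 10L, cds_length_codons = 1200L,
                               strand = "+", seed = cfg$seed,
                               gene_symbol = cfg$target_gene,
                               transcript_id = cfg$transcript_id[1L],
                               intron_range = c(400L, 1200L), flank = 300L)
      say("generated gene model: %d exons, %d nt CDS",
          nrow(model$exons), nchar(cds_sequence(model)))
    }
    if (is.null(arch)) {
      n_aa <- nchar(cds_sequence(model)) %/% 3L - 1L
      arch <- make_architecture(n_aa, n_domains = 10L, include_c0 = TRUE,
                                seed = cfg$seed)
      say("generated domain architecture: %d regions over %d aa",
          nrow(arch$regions), arch$length_aa)
    }
    sim <- simulate_variants(model, mm, arch = arch)
    truth <- sim$truth
    say("simulated %d variants (%d rows)", n_variants(sim$variants),
        nrow(sim$variants))
    if (is.null(cfg$vep_path))
      cfg$vep_path <- file.path(outdir %||% tempdir(), "simulated_vep.tsv")
    write_vep_table(sim$variants, cfg$vep_path)
    if (!is.null(outdir)) {
      write_vcf(sim$variants, file.path(outdir, "simulated.vcf"))
      write_ground_truth(truth, file.path(outdir, "ground_truth.json"))
    }
  }

  raw <- read_vep_table(cfg$vep_path)
  say("read %d annotation rows (%d distinct variants, %d rows skipped)",
      nrow(raw), n_variants(raw), attr(raw, "n_skipped") %||% 0L)
  cleaned <- run_cleaning(raw, cfg$transcript_id, cfg$target_gene,
                          cfg$excluded_genes)
  rec <- cleaned$records
  rep <- cleaned$report
  say("cleaning: input %d -> dedup %d -> transcript %d -> gene filter %d",
      rep$n_input, rep$n_after_dedup, rep$n_after_transcript_filter,
      rep$n_after_gene_filter)

  categories <- tally_categories(rec)
  say("categories: %d coding, %d noncoding (%.1f%%)", categories$n_coding,
      categories$n_noncoding, 100 * categories$noncoding_fraction)
  nuc <- tally_nucleotide_changes(rec)
  codon_pos <- codon_position_tally(rec)
  spec <- substitution_spectrum(rec, categories = "missense")
  tops <- top_substitutions(spec, cfg$top_k)
  marginal <- spectrum_ref_marginal(spec)
  fs <- frameshift_aa_tally(rec)
  sg <- stop_gain_sources(rec)

  dom <- NULL
  if (!is.null(arch)) dom <- domain_distribution(rec, arch)
  else say("warning: no domain architecture supplied; domain tables skipped")
  ex <- exon_distribution(rec, model)

  mode_counts <- vapply(c("both", "either", "sift_only", "polyphen_only"),
                        function(m) {
                          r <- cfg$rule
                          r$mode <- m
                          sum(is_likely_pathogenic(variant_level(rec), r))
                        }, integer(1))
  say("likely-pathogenic counts by rule mode: %s",
      paste(sprintf("%s=%d", names(mode_counts), mode_counts),
            collapse = ", "))
  say(paste("note: only annotations carrying SIFT/PolyPhen labels",
            "(in practice, missense) can pass any pathogenicity mode"))
  patho <- pathogenic_distribution(rec, cfg$rule, arch, model)
  say("likely-pathogenic subset under mode=%s: %d variants", cfg$rule$mode,
      patho$n_pathogenic)

  bundle <- structure(list(
    config = cfg, report = rep, records = rec, categories = categories,
    nucleotide_changes = nuc, codon_positions = codon_pos, spectrum = spec,
    top_substitutions = tops, missense_aa_marginal = marginal,
    frameshift_aa = fs, stop_gain_sources = sg, domain = dom, exon = ex,
    pathogenic = patho, pathogenic_mode_counts = mode_counts,
    model = model, arch = arch, truth = truth, log = log),
    class = "varscape_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  w <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  write_variant_table(bundle$records, file.path(outdir, "cleaned_variants.tsv"))
  write_cleaning_report(bundle$report, file.path(outdir, "cleaning_report.json"))
  w(bundle$categories$table, "categories.tsv")
  w(bundle$nucleotide_changes, "nucleotide_changes.tsv")
  w(bundle$codon_positions, "codon_positions.tsv")
  w(bundle$top_substitutions, "top_substitutions.tsv")
  w(bundle$missense_aa_marginal, "missense_aa_prevalence.tsv")
  w(bundle$frameshift_aa, "frameshift_aa.tsv")
  w(bundle$stop_gain_sources, "stop_gain_sources.tsv")
  if (!is.null(bundle$domain)) w(bundle$domain, "domain_distribution.tsv")
  w(bundle$exon$table, "exon_distribution.tsv")
  w(bundle$pathogenic$exon$table, "pathogenic_exon.tsv")
  if (!is.null(bundle$pathogenic$domain))
    w(bundle$pathogenic$domain, "pathogenic_domain.tsv")
  writeLines(bundle$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Compare category tables across runs
#'
#' Joins the per-category counts of several bundles side by side (one column
#' per run) without pooling: the paralogs are compared, not combined.
#'
#' @param bundles Named list of `varscape_bundle`s.
#' @return data.frame `category` plus one count column per bundle.
#' @export
compare_bundles <- function(bundles) {
  stopifnot(length(bundles) >= 1L)
  out <- data.frame(category = consequence_categories())
  for (nm in names(bundles))
    out[[nm]] <- bundles[[nm]]$categories$table$count
  out
}

#' Render figure-equivalent charts from a result bundle
#'
#' Purely presentational bar charts of the bundle's tables: category
#' proportions, nucleotide changes, top substitutions, per-amino-acid
#' missense/frameshift/stop-gain tallies, domain and exon distributions and
#' their likely-pathogenic counterparts. No computation happens here.
#'
#' @param bundle A `varscape_bundle`.
#' @param outdir Directory for PNG files.
#' @return Character vector of written file paths, invisibly.
#' @export
render_figures <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  save_bar <- function(df, x, y, name, xlab = x, ylab = y) {
    df[[x]] <- factor(df[[x]], levels = unique(df[[x]]))
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data[[x]], y = .data[[y]])) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = xlab, y = ylab) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    f <- file.path(outdir, paste0(name, ".png"))
    ggplot2::ggsave(f, p, width = 7, height = 4, dpi = 120)
    paths <<- c(paths, f)
  }
  ct <- bundle$categories$table
  save_bar(ct[ct$count > 0, ], "category", "count", "categories")
  save_bar(bundle$nucleotide_changes, "change", "count", "nucleotide_changes")
  tops <- bundle$top_substitutions
  if (nrow(tops)) {
    tops$substitution <- paste0(tops$ref_aa, ">", tops$alt_aa)
    save_bar(tops, "substitution", "count", "top_substitutions")
  }
  if (nrow(bundle$missense_aa_marginal))
    save_bar(bundle$missense_aa_marginal, "ref_aa", "count",
             "missense_aa_prevalence")
  if (nrow(bundle$frameshift_aa))
    save_bar(bundle$frameshift_aa, "ref_aa", "count", "frameshift_aa")
  if (nrow(bundle$stop_gain_sources))
    save_bar(bundle$stop_gain_sources, "ref_aa", "count", "stop_gain_sources")
  if (!is.null(bundle$domain))
    save_bar(bundle$domain, "region", "count", "domain_distribution")
  save_bar(bundle$exon$table, "exon_index", "count", "exon_distribution")
  save_bar(bundle$pathogenic$exon$table, "exon_index", "count",
           "pathogenic_exon")
  if (!is.null(bundle$pathogenic$domain))
    save_bar(bundle$pathogenic$domain, "region", "count", "pathogenic_domain")
  invisible(paths)
}

#' @export
print.varscape_bundle <- function(x, ...) {
  cat("varscape result bundle\n")
  print(x$report)
  print(x$categories)
  invisible(x)
}
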
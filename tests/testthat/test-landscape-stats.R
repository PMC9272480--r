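make_cat_table <- function(categories, ...) {
  tbl <- empty_variant_table_public(length(categories))
  tbl$chrom <- "1"
  tbl$pos <- seq_along(categories)
  tbl$ref <- "A"; tbl$alt <- "G"
  term_of <- c(missense = "missense_variant", synonymous = "synonymous_variant",
               truncation = "stop_gained", frameshift = "frameshift_variant",
               inframe_indel = "inframe_deletion",
               splice = "splice_donor_variant", noncoding = "intron_variant",
               stop_loss = "stop_lost", start_loss = "start_lost",
               protein_altering_other = "protein_altering_variant")
  tbl$consequence <- unname(term_of[categories])
  extra <- list(...)
  for (nm in names(extra)) tbl[[nm]] <- extra[[nm]]
  tbl
}

test_that("category tally proportions are over coding, noncoding separate", {
  tbl <- make_cat_table(c(rep("missense", 63), rep("synonymous", 30),
                          rep("frameshift", 7), rep("noncoding", 100)))
  tc <- tally_categories(tbl)
  t <- tc$table
  expect_equal(t$proportion_coding[t$category == "missense"], 0.63)
  expect_equal(sum(t$proportion_coding, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(tc$n_coding, 100L)
  expect_equal(tc$noncoding_fraction, 0.5)
  # empty input: zero counts, proportions absent
  t0 <- tally_categories(empty_variant_table_public(0))
  expect_true(all(t0$table$count == 0L))
  expect_true(all(is.na(t0$table$proportion_coding)))
})

test_that("multi-annotated variants count once under the severest category", {
  tbl <- make_cat_table(c("missense", "noncoding"))
  tbl$pos <- c(5L, 5L)  # same variant, two annotations
  tc <- tally_categories(tbl)
  expect_equal(tc$n_total, 1L)
  expect_equal(tc$table$count[tc$table$category == "missense"], 1L)
})

test_that("nucleotide-change tally covers the 12 cells and skips indels", {
  tbl <- make_cat_table(c("missense", "frameshift"))
  tbl$ref <- c("G", "GA"); tbl$alt <- c("A", "G")
  nc <- tally_nucleotide_changes(tbl)
  expect_equal(nrow(nc), 12L)
  expect_equal(nc$count[nc$change == "G>A"], 1L)
  expect_equal(sum(nc$count), 1L)   # the indel does not contribute
  # indel-only input: all-zero map
  ind <- make_cat_table("frameshift"); ind$ref <- "GA"; ind$alt <- "G"
  expect_equal(sum(tally_nucleotide_changes(ind)$count), 0L)
  expect_equal(transition_fraction(nc), 1)
})

test_that("substitution spectrum counts pairs with marginals and top-k", {
  tbl <- make_cat_table(rep("missense", 5),
                        ref_aa = c("E", "E", "A", "R", "R"),
                        alt_aa = c("K", "K", "T", "C", "H"),
                        protein_pos = 1:5)
  sp <- substitution_spectrum(tbl)
  expect_equal(attr(sp, "n_total"), 5L)
  top1 <- top_substitutions(sp, 1)
  expect_equal(c(top1$ref_aa, top1$alt_aa), c("E", "K"))
  expect_equal(top1$count, 2L)
  marg <- spectrum_ref_marginal(sp)
  expect_equal(marg$count[marg$ref_aa == "R"], 2L)
  expect_equal(sum(marg$count), 5L)
  # ties break lexicographically after count
  tie <- substitution_spectrum(make_cat_table(
    rep("missense", 2), ref_aa = c("V", "A"), alt_aa = c("I", "T"),
    protein_pos = 1:2))
  expect_equal(top_substitutions(tie, 2)$ref_aa, c("A", "V"))
})

test_that("frameshift tally counts first affected residue; unknown warned", {
  tbl <- make_cat_table(rep("frameshift", 3),
                        ref_aa = c("T", "T", NA),
                        protein_pos = c(5L, 6L, NA))
  tbl$ref <- "GA"; tbl$alt <- "G"
  expect_warning(fs <- frameshift_aa_tally(tbl), "unknown")
  expect_equal(fs$count[fs$ref_aa == "T"], 2L)
  expect_equal(fs$count[fs$ref_aa == "unknown"], 1L)
  expect_equal(nrow(frameshift_aa_tally(make_cat_table("missense",
    ref_aa = "E", alt_aa = "K", protein_pos = 1L))), 0L)
})

test_that("stop-gain sources count the replaced amino acid", {
  tbl <- make_cat_table(c("truncation", "truncation", "missense"),
                        ref_aa = c("W", "Y", "E"),
                        alt_aa = c("*", "*", "K"), protein_pos = 1:3)
  sg <- stop_gain_sources(tbl)
  expect_equal(sum(sg$count), 2L)
  expect_setequal(sg$ref_aa, c("W", "Y"))
  expect_equal(nrow(stop_gain_sources(make_cat_table("missense",
    ref_aa = "E", alt_aa = "K", protein_pos = 1L))), 0L)
})

test_that("codon-position tally counts VEP-markup positions", {
  tbl <- make_cat_table(c("missense", "synonymous"),
                        ref_codon = c("GAA", "GGG"),
                        alt_codon = c("AAA", "GGA"),
                        ref_aa = c("E", "G"), alt_aa = c("K", "G"),
                        protein_pos = 1:2)
  cp <- codon_position_tally(tbl)
  expect_equal(cp$count, c(1L, 0L, 1L))
})

test_that("domain mapping respects inclusive 1-based boundaries", {
  arch <- domain_architecture("toy", 250, data.frame(
    name = c("C1", "C2"), class = c("Ig", "Fn3"),
    start_aa = c(1L, 101L), end_aa = c(100L, 200L)))
  expect_equal(map_to_domain(100, arch), "C1")   # position = end_aa
  expect_equal(map_to_domain(101, arch), "C2")
  expect_equal(map_to_domain(205, arch), "linker")
  expect_error(map_to_domain(251, arch), "outside")
  expect_error(domain_architecture("bad", 100, data.frame(
    name = c("A", "B"), class = "Ig", start_aa = c(1, 50),
    end_aa = c(60, 90))), "overlap")
})

test_that("the shipped synthetic architecture template reads and validates", {
  path <- system.file("extdata", "mybpc3_architecture_synthetic_template.tsv",
                      package = "varscape")
  arch <- read_domain_architecture(path)
  expect_s3_class(arch, "domain_architecture")
  expect_equal(arch$length_aa, 1270L)
  expect_equal(arch$regions$name[1], "C0")
  expect_setequal(arch$regions$class[arch$regions$name %in%
                                       c("C6", "C7", "C9")], "Fn3")
  expect_equal(map_to_domain(100, arch), "C0")
  expect_equal(map_to_domain(105, arch), "linker")
  # write/read round-trip
  tmp <- tempfile(fileext = ".tsv")
  write_domain_architecture(arch, tmp)
  back <- read_domain_architecture(tmp)
  expect_equal(back$regions, arch$regions)
})

test_that("domain distribution partitions positioned variants", {
  arch <- domain_architecture("toy", 250, data.frame(
    name = c("C1", "C2"), class = "Ig",
    start_aa = c(1L, 101L), end_aa = c(100L, 200L)))
  tbl <- make_cat_table(rep("missense", 3), ref_aa = "E", alt_aa = "K",
                        protein_pos = c(10L, 150L, 150L))
  dd <- domain_distribution(tbl, arch)
  expect_equal(dd$count[dd$region == "C1"], 1L)
  expect_equal(dd$count[dd$region == "C2"], 2L)
  expect_equal(sum(dd$count), 3L)   # conservation incl. linker
  expect_equal(dd$per_100aa[dd$region == "C2"], 2.0)
  expect_equal(dd$length_aa[dd$region == "linker"], 50L)
})

test_that("exon distribution uses annotation index, excludes intronic", {
  m <- toy_model("+")
  tbl <- make_cat_table(c("missense", "noncoding"),
                        exon_index = c(1L, NA))
  tbl$pos <- c(110L, 104L)  # 104 is outside the single exon
  ed <- exon_distribution(tbl, m)
  expect_equal(ed$table$count[ed$table$exon_index == 1], 1L)
  expect_equal(ed$n_not_exonic, 1L)
  # without a model, indices come from the annotation only
  ed2 <- exon_distribution(tbl, NULL)
  expect_equal(ed2$table$count, 1L)
})

test_that("pathogenicity rule semantics and monotonicity hold", {
  tbl <- empty_variant_table_public(4)
  tbl$chrom <- "1"; tbl$pos <- 1:4; tbl$ref <- "A"; tbl$alt <- "G"
  tbl$consequence <- "missense_variant"
  tbl$sift_label <- c("deleterious", "tolerated", "deleterious", NA)
  tbl$polyphen_label <- c("probably_damaging", "benign", NA, NA)
  expect_equal(is_likely_pathogenic(tbl, pathogenicity_rule("both")),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(is_likely_pathogenic(tbl, pathogenicity_rule("either")),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(is_likely_pathogenic(tbl, pathogenicity_rule("sift_only")),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(is_likely_pathogenic(tbl, pathogenicity_rule("polyphen_only")),
               c(TRUE, FALSE, FALSE, FALSE))
  # strengthening the rule never grows the subset
  both <- which(is_likely_pathogenic(tbl, pathogenicity_rule("both")))
  either <- which(is_likely_pathogenic(tbl, pathogenicity_rule("either")))
  expect_true(all(both %in% either))
  expect_error(pathogenicity_rule(sift_damaging = "nonsense_label"))
})

test_that("pathogenic distribution filters then distributes, idempotently", {
  arch <- domain_architecture("toy", 100, data.frame(
    name = "C1", class = "Ig", start_aa = 1L, end_aa = 100L))
  tbl <- make_cat_table(rep("missense", 10), ref_aa = "E", alt_aa = "K",
                        protein_pos = rep(c(10L, 20L), 5),
                        exon_index = rep(1:2, 5))
  tbl$sift_label <- rep(c("deleterious", "tolerated"), each = 5)
  tbl$polyphen_label <- rep(c("probably_damaging", "benign"), each = 5)
  pd <- pathogenic_distribution(tbl, pathogenicity_rule("both"), arch)
  expect_equal(pd$n_pathogenic, 5L)
  expect_equal(sum(pd$domain$count), 5L)
  expect_equal(sum(pd$exon$table$count), 5L)
  # applying the rule twice equals once
  keep <- is_likely_pathogenic(tbl, pathogenicity_rule("both"))
  sub <- tbl[keep, ]
  expect_equal(is_likely_pathogenic(sub, pathogenicity_rule("both")),
               rep(TRUE, nrow(sub)))
})
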
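test_that("VEP table rows map to records with optional fields honored", {
  path <- write_vep_fixture(list(
    vep_row("11_47353740_G/A", "11:47353740", "A", symbol = "MYBPC3",
            feature = "ENST00000545968", aa = "G/E", codons = "gGg/gAg"),
    vep_row("11_47353740_G/A", "11:47353740", "A", symbol = "MYBPC3",
            feature = "ENST00000999999", aa = "G/E", codons = "gGg/gAg"),
    vep_row("11_47360000_C/T", "11:47360000", "T", symbol = "MYBPC3",
            feature = "ENST00000545968", consequence = "intron_variant",
            exon = "-", protein_pos = "-", aa = "-", codons = "-")))
  tbl <- read_vep_table(path)
  expect_equal(nrow(tbl), 3L)
  expect_equal(n_variants(tbl), 2L)
  expect_equal(attr(tbl, "n_skipped"), 0L)
  # one variant, two transcript annotations, grouped together
  first <- tbl[variant_key(tbl) == "11:47353740:G:A", ]
  expect_equal(nrow(first), 2L)
  expect_setequal(first$transcript_id,
                  c("ENST00000545968", "ENST00000999999"))
  expect_equal(first$ref_aa, c("G", "G"))
  expect_equal(first$alt_aa, c("E", "E"))
  expect_equal(first$ref_codon, c("GGG", "GGG"))
  # intronic row: codon/protein fields absent
  intr <- tbl[tbl$consequence == "intron_variant", ]
  expect_true(is.na(intr$ref_codon) && is.na(intr$protein_pos))
  # SIFT/PolyPhen parsing
  path2 <- write_vep_fixture(list(
    vep_row("1_100_A/G", "1:100", "G", sift = "deleterious(0.01)",
            polyphen = "probably_damaging(0.97)")))
  t2 <- read_vep_table(path2)
  expect_equal(t2$sift_label, "deleterious")
  expect_equal(t2$sift_score, 0.01)
  expect_equal(t2$polyphen_label, "probably_damaging")
  expect_equal(t2$polyphen_score, 0.97)
})

test_that("unparseable rows are counted, never silently dropped", {
  path <- write_vep_fixture(list(
    vep_row("1_100_A/G", "1:100", "G"),
    vep_row("bad_id", "not_a_location", "G"),
    vep_row("1_200_?/G", "1:200", "G")))  # ref unrecoverable
  expect_warning(tbl <- read_vep_table(path), "skipped")
  expect_equal(nrow(tbl), 1L)
  expect_equal(attr(tbl, "n_skipped"), 2L)
  # totality: converted + skipped = rows
  expect_equal(nrow(tbl) + attr(tbl, "n_skipped"), attr(tbl, "n_rows"))
})

test_that("missing mandatory columns and empty files are reported", {
  path <- tempfile()
  writeLines(c("#Location\tAllele", "1:100\tG"), path)
  expect_error(read_vep_table(path), "Consequence")
  empty <- tempfile()
  writeLines("## meta only", empty)
  expect_warning(tbl <- read_vep_table(empty), "empty")
  expect_equal(nrow(tbl), 0L)
})

test_that("dedup removes duplicate entries, merges annotations, idempotent", {
  r1 <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                   rs_id = NA, transcript_id = "T1", gene_symbol = "G1",
                   consequence = "missense_variant", exon_index = 1L,
                   ref_codon = NA, alt_codon = NA, protein_pos = 5L,
                   ref_aa = "K", alt_aa = "E", sift_label = NA,
                   sift_score = NA, polyphen_label = NA, polyphen_score = NA,
                   stringsAsFactors = FALSE)
  r1b <- r1; r1b$transcript_id <- "T2"   # same variant, second transcript
  r2 <- r1; r2$pos <- 200L
  tbl <- rbind(r1, r1, r1b, r2)
  out <- dedup_variants(tbl)
  expect_equal(nrow(out), 3L)            # exact duplicate removed
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(n_variants(out), 2L)
  # annotations of the duplicate merged (both transcripts kept)
  expect_setequal(out$transcript_id[variant_key(out) == "1:100:A:G"],
                  c("T1", "T2"))
  expect_equal(strip_attrs(dedup_variants(out)), strip_attrs(out))  # idempotent
  # distinct records untouched
  expect_equal(attr(dedup_variants(rbind(r1, r2)), "n_removed"), 0L)
})

test_that("dedup is idempotent and order-insensitive on simulated tables", {
  m <- make_gene_model(n_exons = 4, cds_length_codons = 100, seed = 2)
  mm <- mutation_model(n_variants = 1000, category_mix = NULL,
                       snv_fraction = 0.95, seed = 3)
  v <- simulate_variants(m, mm)$variants
  expect_gt(nrow(v) - nrow(dedup_variants(v)), 0)  # sampling w/ replacement
  d1 <- dedup_variants(v)
  expect_equal(strip_attrs(dedup_variants(d1)), strip_attrs(d1))
  set.seed(1)
  perm <- sample.int(nrow(v))
  d2 <- dedup_variants(v[perm, ])
  expect_setequal(variant_key(d2), variant_key(d1))
})

test_that("transcript selection strips versions and drops non-matching", {
  base <- empty_variant_table_public(3)
  base$chrom <- "1"; base$pos <- c(1L, 1L, 2L)
  base$ref <- "A"; base$alt <- "G"
  base$transcript_id <- c("ENST00000361466.5", "ENST00000999999",
                          "ENST00000999999")
  base$consequence <- "missense_variant"
  out <- select_transcript(base, "ENST00000361466")
  expect_equal(nrow(out), 1L)
  expect_equal(out$transcript_id, "ENST00000361466.5")
  expect_equal(attr(out, "n_dropped_variants"), 1L)
  expect_warning(select_transcript(base, "ENST00000000000"), "no annotations")
  # alias list: the verbatim 13-character ID and the padded form both match
  cfgs <- mybpc_config()
  base$transcript_id <- "ENST00000545968.6"
  expect_equal(nrow(select_transcript(base, cfgs$MYBPC3$transcript_id)), 3L)
})

test_that("overlapping-gene filtering removes annotations then empty records", {
  tbl <- empty_variant_table_public(3)
  tbl$chrom <- "12"; tbl$pos <- c(10L, 10L, 20L)
  tbl$ref <- "C"; tbl$alt <- "T"
  tbl$gene_symbol <- c("MYBPC1", "AC117505.1", "SPI1")
  tbl$consequence <- "intron_variant"
  out <- filter_overlapping_genes(tbl, "MYBPC1", "AC117505.1")
  # variant kept, overlapping-gene annotation removed
  expect_equal(nrow(out), 2L)
  expect_false("AC117505.1" %in% out$gene_symbol)
  expect_equal(attr(out, "removed_gene_symbols")[["AC117505.1"]], 1L)
  # record annotated only to an excluded gene disappears
  out2 <- filter_overlapping_genes(tbl, "MYBPC3", c("SPI1"))
  expect_false("12:20:C:T" %in% variant_key(out2))
  expect_equal(attr(out2, "n_dropped_variants"), 1L)
  # empty exclusion list is the identity
  out3 <- filter_overlapping_genes(tbl, "MYBPC1", character(0))
  expect_equal(strip_attrs(out3), strip_attrs(tbl))
})

test_that("VCF reading decomposes multi-allelic sites and round-trips", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\trs1\tG\tA,T\t.\tPASS\t.",
               "1\t200\t.\tC\tT\t.\tPASS\t."), path)
  tbl <- read_vcf(path)
  expect_equal(nrow(tbl), 3L)                    # A,T decomposed
  expect_setequal(variant_key(tbl), c("1:100:G:A", "1:100:G:T", "1:200:C:T"))
  expect_equal(tbl$rs_id[tbl$pos == 200], NA_character_)
  expect_true(all(is.na(tbl$consequence)))
  out <- tempfile(fileext = ".vcf")
  write_vcf(tbl, out)
  back <- read_vcf(out)
  expect_setequal(variant_key(back), variant_key(tbl))
})

test_that("cleaning counts are monotone non-increasing with a full report", {
  m <- make_gene_model(n_exons = 3, cds_length_codons = 80, seed = 5)
  mm <- mutation_model(n_variants = 500, noncoding_fraction = 0.4, seed = 6)
  v <- simulate_variants(m, mm)$variants
  # add a decoy annotation on another transcript/gene
  decoy <- v[1:20, ]
  decoy$transcript_id <- "ENST00000222222"
  decoy$gene_symbol <- "DECOY1"
  cleaned <- run_cleaning(rbind(v, v[1:5, ], decoy),
                          transcript_id = m$transcript_id,
                          target_gene = m$gene_symbol,
                          excluded_genes = "DECOY1")
  rep <- cleaned$report
  expect_true(rep$n_input >= rep$n_after_dedup)
  expect_true(rep$n_after_dedup >= rep$n_after_transcript_filter)
  expect_true(rep$n_after_transcript_filter >= rep$n_after_gene_filter)
  expect_equal(rep$n_duplicate_rows_removed, 5L)
  expect_equal(n_variants(cleaned$records), rep$n_after_gene_filter)
  tmp <- tempfile(fileext = ".json")
  write_cleaning_report(rep, tmp)
  expect_equal(jsonlite::read_json(tmp)$n_input, rep$n_input)
})
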
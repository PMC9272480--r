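test_that("term classification follows the severity order", {
  expect_equal(classify_terms("stop_gained"), "truncation")
  expect_equal(classify_terms(c("missense_variant", "splice_region_variant")),
               "missense")
  expect_equal(classify_terms("intron_variant"), "noncoding")
  expect_equal(classify_terms(c("splice_region_variant", "synonymous_variant")),
               "synonymous")
  expect_equal(classify_terms(c("splice_region_variant", "intron_variant")),
               "noncoding")
  expect_equal(classify_terms(c("stop_gained", "missense_variant")),
               "truncation")
  expect_equal(classify_terms(c("inframe_deletion", "splice_donor_variant")),
               "splice")
  expect_equal(classify_terms("frameshift_variant"), "frameshift")
  expect_warning(out <- classify_terms("made_up_term"), "unrecognized")
  expect_equal(out, "protein_altering_other")
  expect_equal(classify_consequences(
    c("missense_variant,splice_region_variant", NA, "intron_variant")),
    c("missense", NA, "noncoding"))
})

test_that("codon position of change reads VEP markup and plain codons", {
  expect_equal(codon_position_of_change("gGg/gAg"), 2L)
  expect_equal(codon_position_of_change("GAA", "AAA"), 1L)
  expect_equal(codon_position_of_change("TAT", "TAA"), 3L)
  expect_equal(codon_position_of_change("GAA", "ATA"), c(1L, 2L))
  # markup claiming position 2 but bases differing at 3 is inconsistent
  expect_error(parse_vep_codons("gGg/gGa"), "inconsistent")
  expect_error(codon_position_of_change("AAA", "AAA"), "identical")
  expect_error(parse_vep_codons("GA/GAA"), "malformed")
})

test_that("markup round-trips through the parser", {
  pairs <- list(c("GGG", "GAG"), c("GAA", "AAA"), c("TAT", "TAA"),
                c("ATG", "GTA"))
  for (p in pairs) {
    field <- markup_codons(p[1], p[2])
    parsed <- parse_vep_codons(field)
    expect_equal(parsed$ref_codon, p[1])
    expect_equal(parsed$alt_codon, p[2])
  }
})

test_that("annotator reproduces hand-derived effects on the toy CDS", {
  # CDS is ATG GAA TGG TAA at 106..117 (plus strand)
  m <- toy_model("+")
  # codon 2 GAA -> AAA: E>K missense, first codon position
  a <- annotate_variant(m, 109, "G", "A")
  expect_equal(a$consequence, "missense_variant")
  expect_equal(a$protein_pos, 2L)
  expect_equal(c(a$ref_aa, a$alt_aa), c("E", "K"))
  expect_equal(codon_position_of_change(a$ref_codon, a$alt_codon), 1L)
  # codon 3 TGG -> TGA: W>* stop gain
  a <- annotate_variant(m, 114, "G", "A")
  expect_equal(a$consequence, "stop_gained")
  expect_equal(c(a$ref_aa, a$alt_aa), c("W", "*"))
  expect_equal(a$protein_pos, 3L)
  # codon 2 GAA -> GAG: synonymous (E)
  a <- annotate_variant(m, 111, "A", "G")
  expect_equal(a$consequence, "synonymous_variant")
  # start codon hit: ATG -> CTG
  a <- annotate_variant(m, 106, "A", "C")
  expect_equal(a$consequence, "start_lost")
  # stop codon TAA -> CAA: stop lost
  a <- annotate_variant(m, 115, "T", "C")
  expect_equal(a$consequence, "stop_lost")
  # TAA -> TGA: stop retained, synonymous
  a <- annotate_variant(m, 116, "A", "G")
  expect_equal(a$consequence, "synonymous_variant")
  # outside the exon: upstream on +
  a <- annotate_variant(m, 103, "T", "A")
  expect_equal(a$consequence, "upstream_gene_variant")
  expect_error(annotate_variant(m, 50, "A", "T"), "outside the locus")
  expect_error(annotate_variant(m, 109, "C", "A"), "mismatch")
})

test_that("minus-strand toy gene yields identical protein-level effects", {
  mp <- toy_model("+")
  mm_ <- mirror_model(mp)
  validate_gene_model(mm_)
  expect_equal(cds_sequence(mm_), cds_sequence(mp))
  for (v in list(c(109, "G", "A"), c(114, "G", "A"), c(106, "A", "C"),
                 c(111, "A", "G"))) {
    a <- annotate_variant(mp, as.integer(v[1]), v[2], v[3])
    mv <- mirror_snv(mp, as.integer(v[1]), v[2], v[3])
    b <- annotate_variant(mm_, mv$pos, mv$ref, mv$alt)
    expect_equal(b$consequence, a$consequence)
    expect_equal(b$protein_pos, a$protein_pos)
    expect_equal(b$ref_aa, a$ref_aa)
    expect_equal(b$alt_aa, a$alt_aa)
    expect_equal(b$ref_codon, a$ref_codon)
  }
})

test_that("intronic, splice and UTR positions are classified strand-aware", {
  m <- make_gene_model(n_exons = 3, cds_length_codons = 60, strand = "+",
                       seed = 21)
  ex <- m$exons
  # first two bases of intron 1 are the donor on the plus strand
  don <- ex$end[1] + 1L
  a <- annotate_variant(m, don, seq_base_public(m, don), alt_of(m, don))
  expect_equal(a$consequence, "splice_donor_variant")
  acc <- ex$start[2] - 1L
  a <- annotate_variant(m, acc, seq_base_public(m, acc), alt_of(m, acc))
  expect_equal(a$consequence, "splice_acceptor_variant")
  mid <- (ex$end[1] + ex$start[2]) %/% 2L
  a <- annotate_variant(m, mid, seq_base_public(m, mid), alt_of(m, mid))
  expect_equal(a$consequence, "intron_variant")
  # on the mirrored gene the same intron ends swap roles
  m2 <- mirror_model(m)
  don2 <- mirror_snv(m, don, seq_base_public(m, don), alt_of(m, don))
  a2 <- annotate_variant(m2, don2$pos, don2$ref, don2$alt)
  expect_equal(a2$consequence, "splice_donor_variant")
  # UTR terms: first exonic base before the CDS is 5' UTR on +
  u5 <- ex$start[1]
  if (u5 < m$cds_start) {
    a <- annotate_variant(m, u5, seq_base_public(m, u5), alt_of(m, u5))
    expect_equal(a$consequence, "5_prime_UTR_variant")
  }
})

test_that("indels classify by frame and anchor into codons", {
  m <- toy_model("+")
  # delete 1 base inside codon 2 (anchor 108, delete 109): frameshift at E
  a <- annotate_variant(m, 108, "GG", "G")
  expect_equal(a$consequence, "frameshift_variant")
  expect_equal(a$protein_pos, 2L)
  expect_equal(a$ref_aa, "E")
  # delete codon 2 entirely (anchor 108, delete 109-111): inframe deletion
  a <- annotate_variant(m, 108, "GGAA", "G")
  expect_equal(a$consequence, "inframe_deletion")
  expect_equal(a$protein_pos, 2L)
  # insertion of 2 bases after 109: frameshift
  a <- annotate_variant(m, 109, "G", "GTT")
  expect_equal(a$consequence, "frameshift_variant")
  # insertion of 3 bases: inframe insertion
  a <- annotate_variant(m, 109, "G", "GTTT")
  expect_equal(a$consequence, "inframe_insertion")
  expect_error(annotate_variant(m, 108, "GA", "G"), "mismatch")
  expect_error(annotate_variant(m, 108, "GG", "T"))
})

test_that("annotator agrees with the retranslation oracle on random models", {
  set.seed(404)
  for (s in c(3, 14)) {
    for (strand in c("+", "-")) {
      m <- make_gene_model(n_exons = sample(2:5, 1),
                           cds_length_codons = sample(40:90, 1),
                           strand = strand, seed = s)
      en <- enumerate_snv_effects(m)
      idx <- sample(nrow(en), 120)
      for (i in idx) {
        a <- annotate_variant(m, en$pos[i], en$ref[i], en$alt[i])
        o <- annotate_by_retranslation(m, en$pos[i], en$ref[i], en$alt[i])
        expect_equal(classify_consequences(a$consequence), o$category,
                     info = paste("pos", en$pos[i], en$ref[i], ">", en$alt[i]))
        if (!is.na(o$protein_pos)) {
          expect_equal(a$protein_pos, o$protein_pos)
          expect_equal(a$ref_aa, o$ref_aa)
          expect_equal(a$alt_aa, o$alt_aa)
        }
      }
    }
  }
})
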
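# feature set reconstructed from the packaged strain-A variant catalogue
table3_features <- function() {
  t3 <- load_table3_variants()
  f <- t3[t3$locus_tag != "", c("locus_tag", "product", "start", "end",
                                "strand", "feature")]
  f <- f[!duplicated(f$locus_tag), ]
  f$feature_kind <- ifelse(f$feature == "Pseudogene", "pseudogene",
                    ifelse(grepl("ribosomal RNA", f$product), "rrna", "cds"))
  f$feature <- NULL
  rownames(f) <- NULL
  f
}

test_that("variant positions are located in the published gene intervals", {
  feats <- table3_features()
  hit <- locate_variant(863781, feats)
  expect_equal(feats$locus_tag[hit], "X276_22865")
  expect_true(is.na(locate_variant(1190011, feats)))
  hit2 <- locate_variant(5443138, feats)
  expect_equal(feats$locus_tag[hit2], "X276_03000")
})

test_that("overlapping containing features are an error", {
  feats <- data.frame(locus_tag = c("a", "b"), product = "p",
                      start = c(10L, 50L), end = c(100L, 120L),
                      strand = "+", feature_kind = "cds")
  expect_error(locate_variant(60, feats), "overlapping")
})

test_that("codon coordinates follow the strand-aware arithmetic", {
  fplus <- data.frame(locus_tag = "f", product = "p", start = 101L,
                      end = 400L, strand = "+", feature_kind = "cds")
  expect_equal(codon_context(fplus, 101), list(codon_index = 0L, offset = 0L))
  expect_equal(codon_context(fplus, 106), list(codon_index = 1L, offset = 2L))
  fminus <- fplus
  fminus$strand <- "-"
  fminus$end <- 300L
  expect_equal(codon_context(fminus, 300), list(codon_index = 0L, offset = 0L))
  expect_error(codon_context(fplus, 50), "outside")
})

test_that("coding SNP effects follow the genetic code on both strands", {
  g <- genome_record("t", paste0(strrep("A", 100), "ATGGAATAA",
                                 strrep("C", 91)))
  ft <- data.frame(locus_tag = "L1", product = "p", start = 101L, end = 109L,
                   strand = "+", feature_kind = "cds")
  call <- function(pos, ref, alt)
    data.frame(position = pos, ref = ref, alt = alt, depth = 50L,
               alt_count = 50L, alt_fraction = 1, rel_coverage = 1,
               filter_status = "pass", stringsAsFactors = FALSE)
  # GAA -> AAA: E -> K (the recurrent substitution class of the catalogue)
  a <- annotate_variants(call(104, "G", "A"), ft, g)
  expect_equal(c(a$aa_ref, a$aa_alt, a$effect), c("E", "K", "missense"))
  # GAA -> GAG: silent
  b <- annotate_variants(call(106, "A", "G"), ft, g)
  expect_equal(c(b$aa_ref, b$aa_alt, b$effect), c("E", "E", "synonymous"))
  # GAA -> TAA: premature stop
  d <- annotate_variants(call(104, "G", "T"), ft, g)
  expect_equal(c(d$aa_alt, d$effect), c("*", "nonsense"))
  # disagreement with the reference allele is an error
  expect_error(annotate_variants(call(104, "T", "A"), ft, g), "disagrees")

  # the same gene encoded on the minus strand gives the same annotation
  g2 <- genome_record("t2", paste0(strrep("A", 100), revcomp("ATGGAATAA"),
                                   strrep("C", 91)))
  ft2 <- ft
  ft2$strand <- "-"
  a2 <- annotate_variants(call(109 - 3, "C", "T"), ft2, g2)  # rc of pos 104 G>A
  expect_equal(c(a2$aa_ref, a2$aa_alt, a2$effect), c("E", "K", "missense"))
})

test_that("indels and non-coding features are classed without amino acids", {
  g <- genome_record("t", paste0(strrep("A", 100), "ATGGAATAA",
                                 strrep("C", 91)))
  ft <- data.frame(locus_tag = c("L1", "R1"), product = c("p", "16S"),
                   start = c(101L, 150L), end = c(109L, 180L),
                   strand = "+", feature_kind = c("cds", "rrna"))
  call <- function(pos, ref, alt)
    data.frame(position = pos, ref = ref, alt = alt, depth = 50L,
               alt_count = 50L, alt_fraction = 1, rel_coverage = 1,
               filter_status = "pass", stringsAsFactors = FALSE)
  fs <- annotate_variants(call(103, "G", "GT"), ft, g)
  expect_equal(fs$effect, "frameshift")
  expect_equal(fs$aa_ref, "")
  inf <- annotate_variants(call(103, "GGAA", "G"), ft, g)
  expect_equal(inf$effect, "inframe_indel")
  nc <- annotate_variants(call(160, "C", "A"), ft, g)
  expect_equal(nc$effect, "non_coding_gene")
  ig <- annotate_variants(call(50, "A", "G"), ft, g)
  expect_equal(ig$effect, "intergenic")
  expect_equal(ig$locus_tag, "")
})

test_that("random coding SNPs agree with a full-translation oracle", {
  gen <- generate_genome(30000, 0.4, 12, 600, seed = 500)
  g <- gen$genome
  coding <- gen$features[gen$features$feature_kind %in%
                           c("cds", "pseudogene"), ]
  withr::with_seed(501, {
    effects <- character(0)
    for (i in 1:100) {
      ft <- coding[sample(nrow(coding), 1), ]
      pos <- sample(ft$start:ft$end, 1)
      ref <- substr(g$sequence, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- data.frame(position = pos, ref = ref, alt = alt, depth = 50L,
                      alt_count = 50L, alt_fraction = 1, rel_coverage = 1,
                      filter_status = "pass", stringsAsFactors = FALSE)
      got <- annotate_variants(v, gen$features, g)
      want <- oracle_snp_effect(g$sequence, ft, pos, alt)
      expect_equal(got$codon_index, want$codon_index)
      expect_equal(got$aa_ref, want$aa_ref)
      expect_equal(got$aa_alt, want$aa_alt)
      expect_equal(got$effect, want$effect)
      effects <- c(effects, got$effect)
    }
    # every variant got exactly one effect class
    expect_equal(length(effects), 100L)
    expect_true(all(effects %in% c("synonymous", "missense", "nonsense",
                                   "stop_lost")))
  })
})
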
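test_that("genome generation honours length, gene count and composition", {
  g0 <- generate_genome(1000, n_genes = 0L, seed = 1)
  expect_equal(g0$genome$length, 1000)
  expect_equal(nrow(g0$features), 0L)

  a <- generate_genome(20000, 0.4, 8, 600, seed = 42)
  b <- generate_genome(20000, 0.4, 8, 600, seed = 42)
  expect_identical(a, b)

  g <- generate_genome(50000, 0.30, n_genes = 0L, seed = 9)
  gc <- sum(strsplit(g$genome$sequence, "")[[1]] %in% c("G", "C")) / 50000
  expect_lt(abs(gc - 0.30), 0.02)
})

test_that("generated coding features are translatable ORFs", {
  g <- generate_genome(30000, 0.35, 12, 900, seed = 5)
  f <- g$features
  expect_true(all(f$start >= 1 & f$end <= 30000 & f$start <= f$end))
  # non-overlap
  o <- order(f$start)
  expect_true(all(f$start[o][-1] > f$end[o][-nrow(f)]))
  coding <- f[f$feature_kind %in% c("cds", "pseudogene"), ]
  for (i in seq_len(nrow(coding))) {
    len <- coding$end[i] - coding$start[i] + 1
    expect_equal(len %% 3, 0)
    cds <- substr(g$genome$sequence, coding$start[i], coding$end[i])
    if (coding$strand[i] == "-") cds <- revcomp(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, len - 3, 3), seq(3, len - 3, 3))
    expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("generate_genome rejects infeasible gene packing", {
  expect_error(generate_genome(1000, 0.4, 10, 900, seed = 1), "pack")
})

test_that("mutation injection edits the genome exactly as specified", {
  g <- generate_genome(5000, 0.4, 0, seed = 3)$genome
  # empty specs: identity
  expect_identical(inject_mutations(g, NULL)$genome$sequence, g$sequence)

  # one SNP: exactly one differing position
  base <- substr(g$sequence, 1234, 1234)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  specs <- data.frame(kind = "snp", position = 1234L, ref = NA, alt = alt,
                      size = NA)
  mut <- inject_mutations(g, specs)
  diffs <- which(strsplit(g$sequence, "")[[1]] !=
                 strsplit(mut$genome$sequence, "")[[1]])
  expect_equal(diffs, 1234L)
  expect_equal(substr(mut$genome$sequence, 1234, 1234), alt)
  expect_equal(mut$truth$ref, base)

  # conflicting declared ref allele is an error
  bad <- data.frame(kind = "snp", position = 1234L,
                    ref = setdiff(c("A", "C", "G", "T"), base)[2],
                    alt = alt, size = NA)
  expect_error(inject_mutations(g, bad), "disagrees")
})

test_that("a tandem duplication grows the genome by its printed size", {
  # interval [341278, 349235] spans 349235 - 341278 + 1 = 7958 bases
  size <- 349235 - 341278 + 1
  g <- genome_record("big", random_dna_str(360000, seed = 8))
  specs <- data.frame(kind = "duplication", position = 341278L, ref = NA,
                      alt = NA, size = size)
  mut <- inject_mutations(g, specs)
  expect_equal(mut$genome$length, g$length + 7958L)
  # the copy sits immediately after the segment
  seg <- substr(g$sequence, 341278, 349235)
  expect_equal(substr(mut$genome$sequence, 349236, 349236 + size - 1), seg)

  del <- inject_mutations(g, data.frame(kind = "segment_deletion",
                                        position = 1000L, ref = NA,
                                        alt = NA, size = 759L))
  expect_equal(del$genome$length, g$length - 759L)
})

test_that("overlapping mutation specs are rejected", {
  g <- generate_genome(5000, 0.4, 0, seed = 3)$genome
  specs <- data.frame(kind = c("duplication", "snp"),
                      position = c(1000L, 1500L), ref = NA, alt = c(NA, "A"),
                      size = c(800L, NA))
  expect_error(inject_mutations(g, specs), "overlap")
})

test_that("read simulation matches the coverage arithmetic and genome", {
  g <- genome_record("g", random_dna_str(10000, seed = 4))
  p <- simulate_reads(g, mean_coverage = 100, read_length = 100L,
                      insert_mean = 250L, error_rate = 0, seed = 6)
  expect_equal(nrow(p), 5000L)  # 100 * 10000 / (2 * 100)
  expect_identical(p, simulate_reads(g, 100, 100L, 250L, error_rate = 0,
                                     seed = 6))
  # with no errors every mate is an exact (possibly reverse-complemented)
  # substring at its recorded fragment coordinates
  for (i in seq_len(300)) {
    s <- p$true_origin[i]
    e <- s + p$frag_len[i] - 1L
    left <- substr(g$sequence, s, s + 99L)
    right <- revcomp(substr(g$sequence, e - 99L, e))
    if (p$true_strand[i] == "+") {
      expect_identical(p$mate1_seq[i], left)
      expect_identical(p$mate2_seq[i], right)
    } else {
      expect_identical(p$mate1_seq[i], right)
      expect_identical(p$mate2_seq[i], left)
    }
  }
  expect_error(simulate_reads(genome_record("s", random_dna_str(100, 1)),
                              10, 150L, 300L), "shorter")
})

test_that("injected substitution errors pool to the requested rate", {
  g <- genome_record("g", random_dna_str(20000, seed = 14))
  p <- simulate_reads(g, mean_coverage = 75, read_length = 150L,
                      error_rate = 0.005, seed = 15)
  n_mm <- 0L
  n_bases <- 0L
  for (i in seq_len(nrow(p))) {
    s <- p$true_origin[i]
    e <- s + p$frag_len[i] - 1L
    left <- substr(g$sequence, s, s + 149L)
    right <- revcomp(substr(g$sequence, e - 149L, e))
    exp1 <- if (p$true_strand[i] == "+") left else right
    exp2 <- if (p$true_strand[i] == "+") right else left
    n_mm <- n_mm + sum(charToRaw(p$mate1_seq[i]) != charToRaw(exp1)) +
      sum(charToRaw(p$mate2_seq[i]) != charToRaw(exp2))
    n_bases <- n_bases + 300L
  }
  rate <- n_mm / n_bases
  expect_lt(abs(rate - 0.005) / 0.005, 0.20)
})

test_that("quality strings follow the truncated Phred model", {
  g <- genome_record("g", random_dna_str(5000, seed = 20))
  p <- simulate_reads(g, 30, error_rate = 0, mean_quality = 35, seed = 21)
  q <- unlist(lapply(p$mate1_qual[1:200], phred_to_int))
  expect_true(all(q >= 2 & q <= 41))
  expect_lt(abs(mean(q) - 35), 1)
})

test_that("the truth table is conserved in the mutant sequence", {
  g <- generate_genome(20000, 0.35, 0, seed = 30)$genome
  specs <- random_truth_specs(g, n_snp = 8, n_ins = 0, n_del = 0,
                              dup_size = 0, del_size = 0, seed = 31)
  mut <- inject_mutations(g, specs)
  snps <- mut$truth[mut$truth$kind == "snp", ]
  for (i in seq_len(nrow(snps)))
    expect_equal(substr(mut$genome$sequence, snps$position[i],
                        snps$position[i]), snps$alt[i])
})
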
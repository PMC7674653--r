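test_that("pileup tallies equal a brute-force per-position recount", {
  for (seed in c(101, 102, 103)) {
    g <- generate_genome(4000, 0.4, 0, seed = seed)$genome
    specs <- random_truth_specs(g, n_snp = 3, n_ins = 1, n_del = 1,
                                dup_size = 0, del_size = 0, min_gap = 200,
                                margin = 500, seed = seed + 1)
    mut <- inject_mutations(g, specs)
    pairs <- simulate_reads(mut$genome, mean_coverage = 3,
                            error_rate = 0.01, seed = seed + 2)
    aln <- mark_duplicates(map_reads(pairs, g))
    pile <- build_pileup(aln, g)
    want <- oracle_pileup(aln, g$sequence)
    expect_equal(unname(pile$base_counts), unname(want$base_counts))
    expect_equal(pile$deletion_count, want$deletion_count)
    expect_equal(pile$depth, want$depth)
    # spec invariant: depth = base counts + deletions, everywhere
    expect_equal(pile$depth,
                 as.integer(rowSums(pile$base_counts)) + pile$deletion_count)
  }
})

test_that("single-column calling arithmetic is exact", {
  ref <- paste0(strrep("A", 49), "C", strrep("A", 50))
  bc <- matrix(0L, 100, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  bc[, "A"] <- 100L
  bc[50, ] <- c(0L, 60L, 40L, 0L)
  pile <- structure(list(
    depth = as.integer(rowSums(bc)),
    base_counts = bc, deletion_count = integer(100),
    insertion_events = data.frame(anchor = integer(0), seq = character(0)),
    deletion_events = data.frame(anchor = integer(0), len = integer(0)),
    ref_length = 100L), class = "pileup")
  calls <- call_variants(pile, ref, mean_depth = 100)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 50L)
  expect_equal(calls$alt, "G")
  expect_equal(calls$alt_fraction, 0.40)

  # below min_alt_count: silence
  bc[50, ] <- c(0L, 98L, 2L, 0L)
  pile$base_counts <- bc
  pile$depth <- as.integer(rowSums(bc))
  expect_equal(nrow(call_variants(pile, ref, mean_depth = 100,
                                  min_alt_count = 3)), 0L)
})

test_that("the caller equals an exhaustive per-site oracle on random pileups", {
  ref <- random_dna_str(120, seed = 200)
  for (seed in 201:220) {
    pile <- random_pileup(ref, seed)
    got <- call_variants(pile, ref, mean_depth = 30, min_depth = 10,
                         min_alt_count = 3, min_alt_fraction = 0.10)
    ev_ins <- pile$insertion_events
    ev_del <- pile$deletion_events
    key_i <- paste(ev_ins$anchor, ev_ins$seq)
    key_d <- paste(ev_del$anchor, ev_del$len)
    oracle_pile <- pile
    oracle_pile$insertion_events <- cbind(ev_ins[!duplicated(key_i), ,
                                                 drop = FALSE],
                                          count = as.vector(table(key_i)[
                                            unique(key_i)]))
    oracle_pile$deletion_events <- cbind(ev_del[!duplicated(key_d), ,
                                                drop = FALSE],
                                         count = as.vector(table(key_d)[
                                           unique(key_d)]))
    want <- oracle_calls(oracle_pile, ref, min_depth = 10, min_alt_count = 3,
                         min_alt_fraction = 0.10)
    expect_equal(got$position, want$position, info = paste("seed", seed))
    expect_equal(got$ref, want$ref, info = paste("seed", seed))
    expect_equal(got$alt, want$alt, info = paste("seed", seed))
    expect_equal(got$alt_count, want$alt_count, info = paste("seed", seed))
  }
})

test_that("self-calling clean wild-type reads yields zero variants", {
  g <- generate_genome(8000, 0.35, 3, 600, seed = 111)$genome
  pairs <- simulate_reads(g, mean_coverage = 25, error_rate = 0, seed = 112)
  aln <- mark_duplicates(map_reads(trim_pairs(pairs), g))
  calls <- call_variants(build_pileup(aln, g), g)
  expect_equal(nrow(calls), 0L)
})

test_that("indel normalisation produces the canonical leftmost encoding", {
  #        123456789
  seq <- "GCAAATTCG"
  # deleting one A of the A-run, anchored at the last A, shifts left
  nv <- normalize_variant(4L, "AA", "A", seq)
  expect_equal(nv$position, 2L)
  expect_equal(nv$ref, "CA")
  expect_equal(nv$alt, "C")
  # inserting T before the T-run is the same as inserting after it
  nv2 <- normalize_variant(6L, "T", "TT", seq)
  nv3 <- normalize_variant(5L, "A", "AT", seq)
  expect_equal(nv2[c("position", "ref", "alt")],
               nv3[c("position", "ref", "alt")])
  # SNPs are untouched
  expect_equal(normalize_variant(3L, "A", "G", seq),
               list(position = 3L, ref = "A", alt = "G"))
})
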
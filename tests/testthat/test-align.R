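make_pairs <- function(m1, m2, q = 38L) {
  data.frame(pair_id = sprintf("p%03d", seq_along(m1)),
             mate1_seq = m1, mate1_qual = int_to_phred(rep(q, nchar(m1[1]))),
             mate2_seq = m2, mate2_qual = int_to_phred(rep(q, nchar(m2[1]))),
             stringsAsFactors = FALSE)
}

test_that("error-free simulated reads map back to their true origins", {
  g <- genome_record("g", random_dna_str(20000, seed = 50))
  p <- simulate_reads(g, mean_coverage = 20, error_rate = 0, seed = 51)
  aln <- map_reads(p, g)
  expect_equal(attr(aln, "n_unmapped"), 0L)
  expect_true(all(aln$n_mismatches == 0L))
  expect_true(all(aln$ref_start >= 1 &
                  aln$ref_start + cigar_query_span(aln$cigar) - 1 <= 20000))
  # expected mate placements from the recorded fragment coordinates
  i1 <- match(paste(p$pair_id, 1), paste(aln$read_id, aln$mate))
  i2 <- match(paste(p$pair_id, 2), paste(aln$read_id, aln$mate))
  left_start <- p$true_origin
  right_start <- p$true_origin + p$frag_len - 150L
  exp1 <- ifelse(p$true_strand == "+", left_start, right_start)
  exp2 <- ifelse(p$true_strand == "+", right_start, left_start)
  ok <- mean(aln$ref_start[i1] == exp1 & aln$ref_start[i2] == exp2,
             na.rm = TRUE)
  expect_gte(ok, 0.99)
  # minus-strand mates are reported on the minus strand
  j <- which(p$true_strand == "-")[1]
  expect_equal(aln$strand[i1[j]], "-")
  expect_equal(aln$ref_start[i1[j]], right_start[j])
})

test_that("substitutions are counted and short indels recovered in cigars", {
  g <- genome_record("g", random_dna_str(5000, seed = 52))
  read <- substr(g$sequence, 2001, 2150)
  substr(read, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, 40, 40))[1]
  substr(read, 90, 90) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, 90, 90))[1]
  mate2 <- revcomp(substr(g$sequence, 2201, 2350))
  aln <- map_reads(make_pairs(read, mate2), g)
  a1 <- aln[aln$mate == 1L, ]
  expect_equal(a1$ref_start, 2001L)
  expect_equal(a1$n_mismatches, 2L)
  expect_equal(a1$cigar, "150M")

  # 4-base deletion relative to the reference
  del_read <- paste0(substr(g$sequence, 3001, 3070),
                     substr(g$sequence, 3075, 3154))
  aln2 <- map_reads(make_pairs(del_read, mate2), g)
  a2 <- aln2[aln2$mate == 1L, ]
  expect_equal(a2$ref_start, 3001L)
  expect_equal(a2$cigar, "70M4D80M")
  expect_equal(a2$n_mismatches, 0L)

  # 3-base insertion
  ins_read <- paste0(substr(g$sequence, 3501, 3575), "ACG",
                     substr(g$sequence, 3576, 3647))
  aln3 <- map_reads(make_pairs(ins_read, mate2), g)
  a3 <- aln3[aln3$mate == 1L, ]
  expect_equal(a3$ref_start, 3501L)
  expect_equal(a3$cigar, "75M3I72M")
})

test_that("reads with tied best placements are flagged ambiguous", {
  unit <- random_dna_str(400, seed = 53)
  g <- genome_record("rep", paste0(unit, unit, random_dna_str(400, seed = 54)))
  read <- substr(unit, 101, 250)
  aln <- map_reads(make_pairs(read, revcomp(substr(g$sequence, 900, 1049))), g)
  a1 <- aln[aln$mate == 1L, ]
  expect_true(a1$is_ambiguous)
})

test_that("duplicate marking keeps the best pair of each signature", {
  base <- data.frame(
    mate = c(1L, 2L), ref_start = c(100L, 300L), cigar = "50M",
    strand = c("+", "-"), n_mismatches = 0L, is_ambiguous = FALSE,
    is_duplicate = FALSE, seq = strrep("A", 50), stringsAsFactors = FALSE)
  mk <- function(id, sq) {
    x <- rbind(base, base)[1:2, ]
    x$read_id <- id
    x$sum_qual <- sq
    x
  }
  # distinct signatures: no duplicates
  two <- rbind(mk("a", 450L), mk("b", 450L))
  two$ref_start[3:4] <- c(150L, 350L)
  expect_false(any(mark_duplicates(two)$is_duplicate))

  # identical signatures: exactly one pair survives, the highest-quality one
  three <- rbind(mk("a", 450L), mk("b", 455L), mk("c", 452L))
  md <- mark_duplicates(three)
  expect_equal(sum(md$is_duplicate), 4L)
  expect_false(any(md$is_duplicate[md$read_id == "b"]))
})

test_that("coverage profiles follow the counting arithmetic", {
  one <- data.frame(read_id = "r", mate = 1L, ref_start = 1L, cigar = "100M",
                    strand = "+", n_mismatches = 0L, is_ambiguous = FALSE,
                    is_duplicate = FALSE, seq = strrep("A", 100),
                    sum_qual = 0L, stringsAsFactors = FALSE)
  prof <- coverage_profile(one, 100L, window = 100L)
  expect_equal(prof$mean_depth, 1.0)
  expect_equal(prof$window_depth, 1.0)

  none <- coverage_profile(one[0, ], 100L, window = 10L)
  expect_true(all(none$depth == 0))

  # genome mean equals the length-weighted mean of window depths
  g <- genome_record("g", random_dna_str(9950, seed = 55))
  p <- simulate_reads(g, 25, error_rate = 0, seed = 56)
  aln <- map_reads(p, g)
  prof <- coverage_profile(aln, 9950L, window = 100L)
  wlen <- c(rep(100L, 99), 50L)
  expect_equal(prof$mean_depth,
               sum(prof$window_depth * wlen) / sum(wlen))
})

test_that("a simulated run's mean depth tracks the requested coverage", {
  g <- genome_record("g", random_dna_str(20000, seed = 57))
  p <- simulate_reads(g, 50, error_rate = 0.005, seed = 58)
  aln <- mark_duplicates(map_reads(trim_pairs(p), g))
  prof <- coverage_profile(aln, 20000L, 100L)
  expect_lt(abs(prof$mean_depth - 50) / 50, 0.10)
})

test_that("SAM round-trip preserves placement fields", {
  g <- genome_record("g", random_dna_str(5000, seed = 59))
  p <- simulate_reads(g, 8, error_rate = 0.002, seed = 60)
  aln <- mark_duplicates(map_reads(p, g))
  path <- tempfile(fileext = ".sam")
  write_sam(aln, path, seqid = "g", ref_length = 5000L)
  back <- read_sam(path)
  expect_equal(back$ref_start, aln$ref_start)
  expect_equal(back$cigar, aln$cigar)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$is_duplicate, aln$is_duplicate)
  expect_equal(back$n_mismatches, aln$n_mismatches)
})
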
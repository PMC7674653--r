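#' Construct a genome record
#'
#' A genome record holds a single (linearised) bacterial chromosome as a
#' plain DNA string plus an identifier. Sequences are restricted to the
#' unambiguous alphabet A/C/G/T.
#'
#' @param id sequence identifier.
#' @param sequence DNA string over A/C/G/T.
#' @return an object of class `genome_record` with fields `id`, `sequence`
#'   and `length`.
#' @export
genome_record <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop_fmt("genome '%s' contains characters outside A/C/G/T", id)
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp\n", x$id, x$length))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# a CDS body: ATG + non-stop codons + one stop codon, base composition
# following gc_fraction, length a multiple of 3
random_cds <- function(len, gc_fraction) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_mid <- len / 3 - 2L
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  draw <- function(n) {
    m <- matrix(sample(BASES, 3L * n, replace = TRUE, prob = p), ncol = 3L)
    paste0(m[, 1], m[, 2], m[, 3])
  }
  codons <- draw(n_mid)
  bad <- codons %in% STOP_CODONS
  while (any(bad)) {            # rejection sampling keeps composition honest
    codons[bad] <- draw(sum(bad))
    bad <- codons %in% STOP_CODONS
  }
  paste0("ATG", paste0(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

PRODUCT_VOCAB <- c(
  "hypothetical protein", "ABC transporter permease",
  "MarR family transcriptional regulator", "S-layer family protein",
  "methyl-accepting chemotaxis protein", "peptidase S8",
  "cytochrome b5", "glycoside hydrolase", "AAA family ATPase",
  "response regulator")

#' Generate a random annotated reference genome
#'
#' Emulates a sized-down bacterial chromosome (treated as linear) carrying
#' non-overlapping stranded gene features. Coding features (CDS and
#' pseudogene) start with ATG on their coding strand, end with a stop
#' codon, contain no internal in-frame stop, and have lengths that are
#' multiples of three. A small fraction of features is emitted as
#' pseudogene, rRNA and tRNA records so downstream annotation exercises
#' every feature kind.
#'
#' @param length genome length in bases.
#' @param gc_fraction target GC fraction, strictly between 0 and 1.
#' @param n_genes number of gene features to place.
#' @param mean_gene_length mean feature length in bases.
#' @param seed integer seed; the result is byte-identical for a fixed seed.
#' @return a list with elements `genome` (a [genome_record()]) and
#'   `features` (a data frame with columns `locus_tag`, `product`, `start`,
#'   `end`, `strand`, `feature_kind`; 1-based inclusive coordinates).
#' @export
generate_genome <- function(length, gc_fraction = 0.35, n_genes = 0L,
                            mean_gene_length = 900L, seed = 1L) {
  stopifnot(length >= 1, gc_fraction > 0, gc_fraction < 1, n_genes >= 0)
  if (n_genes > 0 && length < n_genes * mean_gene_length)
    stop_fmt("cannot pack %d genes of mean length %d into %d bases",
             n_genes, mean_gene_length, length)
  withr::with_seed(seed, {
    if (n_genes == 0L) {
      genome <- genome_record("synthetic_ref", random_dna(length, gc_fraction))
      feats <- data.frame(locus_tag = character(0), product = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), feature_kind = character(0),
                          stringsAsFactors = FALSE)
      return(list(genome = genome, features = feats))
    }
    lens <- round(stats::rnorm(n_genes, mean_gene_length,
                               mean_gene_length / 6) / 3) * 3L
    lens <- pmax(90L, as.integer(lens))
    if (sum(lens) + n_genes + 1L > length) {
      scale <- (length - n_genes - 1L) / sum(lens)
      lens <- pmax(90L, (as.integer(lens * scale) %/% 3L) * 3L)
      if (sum(lens) + n_genes + 1L > length)
        stop_fmt("infeasible gene packing: %d genes do not fit in %d bases",
                 n_genes, length)
    }
    kinds <- sample(c("cds", "pseudogene", "rrna", "trna"), n_genes,
                    replace = TRUE, prob = c(0.85, 0.05, 0.05, 0.05))
    # rRNA/tRNA features need no codon structure; keep their lengths too
    gaps <- as.vector(stats::rmultinom(1, length - sum(lens), rep(1, n_genes + 1L)))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    pieces <- character(2L * n_genes + 1L)
    feats <- vector("list", n_genes)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      pieces[2L * i - 1L] <- if (gaps[i] > 0)
        random_dna(gaps[i], gc_fraction) else ""
      pos <- pos + gaps[i]
      body <- if (kinds[i] %in% c("cds", "pseudogene"))
        random_cds(lens[i], gc_fraction) else random_dna(lens[i], gc_fraction)
      pieces[2L * i] <- if (strands[i] == "+") body else revcomp(body)
      feats[[i]] <- data.frame(
        locus_tag = sprintf("SYN_%05d", 5L * i),
        product = sample(PRODUCT_VOCAB, 1L),
        start = pos + 1L, end = pos + lens[i],
        strand = strands[i], feature_kind = kinds[i],
        stringsAsFactors = FALSE)
      pos <- pos + lens[i]
    }
    pieces[2L * n_genes + 1L] <- if (gaps[n_genes + 1L] > 0)
      random_dna(gaps[n_genes + 1L], gc_fraction) else ""
    genome <- genome_record("synthetic_ref", paste0(pieces, collapse = ""))
    stopifnot(genome$length == length)
    list(genome = genome, features = do.call(rbind, feats))
  })
}

truth_interval <- function(kind, position, ref, size) {
  end <- switch(kind,
    snp = position,
    insertion = position,
    deletion = position + (if (is.na(size)) nchar(ref) - 1L else size),
    duplication = position + size - 1L,
    segment_deletion = position + size - 1L)
  c(position, end)
}

#' Derive a mutant genome from explicit mutation specifications
#'
#' Applies SNPs, short indels, a tandem duplication and/or a segment
#' deletion to a reference genome and returns the mutant sequence together
#' with a finalised truth table whose `ref`/`alt` columns use the anchored
#' VCF encoding (insertions as `A -> AT`, deletions as `CA -> C`). A
#' duplication of size s inserts a tandem copy immediately after the
#' segment and grows the genome by s bases; a segment deletion shrinks it
#' by s.
#'
#' @param genome a [genome_record()].
#' @param specs data frame with columns `kind` (one of `snp`, `insertion`,
#'   `deletion`, `duplication`, `segment_deletion`), `position` (1-based,
#'   on the reference), and, per kind, `alt` (SNP alternate base or
#'   inserted bases) and `size` (bases deleted/duplicated). Specs must be
#'   mutually non-overlapping.
#' @return a list with `genome` (mutant [genome_record()]) and `truth`
#'   (data frame: `kind`, `position`, `ref`, `alt`, `size`).
#' @export
inject_mutations <- function(genome, specs) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(specs) || nrow(specs) == 0L) {
    truth <- data.frame(kind = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        size = integer(0), stringsAsFactors = FALSE)
    return(list(genome = genome, truth = truth))
  }
  specs$size <- if ("size" %in% names(specs)) as.integer(specs$size) else NA_integer_
  specs$alt <- if ("alt" %in% names(specs)) specs$alt else NA_character_
  specs$ref <- if ("ref" %in% names(specs)) specs$ref else NA_character_
  seqc <- genome$sequence
  L <- genome$length
  # finalise ref/alt from the reference, validate, and check overlap
  iv <- t(mapply(function(k, p, r, s) truth_interval(k, p, r, s),
                 specs$kind, specs$position, specs$ref, specs$size))
  if (any(iv[, 1] < 1) || any(iv[, 2] > L))
    stop_fmt("mutation specification outside genome bounds")
  o <- order(iv[, 1])
  if (nrow(specs) > 1 && any(iv[o, 1][-1] <= iv[o, 2][-nrow(specs)]))
    stop_fmt("mutation specifications overlap")
  truth <- specs[o, , drop = FALSE]
  iv <- iv[o, , drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    p <- truth$position[i]
    base <- substr(seqc, p, p)
    truth$ref[i] <- switch(truth$kind[i],
      snp = {
        if (!is.na(truth$ref[i]) && truth$ref[i] != base)
          stop_fmt("spec ref '%s' at %d disagrees with reference base '%s'",
                   truth$ref[i], p, base)
        base
      },
      insertion = base,
      deletion = substr(seqc, p, p + truth$size[i]),
      duplication = base,
      segment_deletion = base)
    truth$alt[i] <- switch(truth$kind[i],
      snp = {
        if (is.na(truth$alt[i]) || !truth$alt[i] %in% setdiff(BASES, base))
          stop_fmt("snp at %d needs an alt base different from '%s'", p, base)
        truth$alt[i]
      },
      insertion = paste0(base, truth$alt[i]),
      deletion = base,
      duplication = NA_character_,
      segment_deletion = NA_character_)
  }
  # apply highest-position first so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(truth)))) {
    p <- truth$position[i]
    s <- truth$size[i]
    seqc <- switch(truth$kind[i],
      snp = paste0(substr(seqc, 1L, p - 1L), truth$alt[i],
                   substr(seqc, p + 1L, nchar(seqc))),
      insertion = paste0(substr(seqc, 1L, p), substr(truth$alt[i], 2L, nchar(truth$alt[i])),
                         substr(seqc, p + 1L, nchar(seqc))),
      deletion = paste0(substr(seqc, 1L, p),
                        substr(seqc, p + s + 1L, nchar(seqc))),
      duplication = paste0(substr(seqc, 1L, p + s - 1L),
                           substr(seqc, p, p + s - 1L),
                           substr(seqc, p + s, nchar(seqc))),
      segment_deletion = paste0(substr(seqc, 1L, p - 1L),
                                substr(seqc, p + s, nchar(seqc))))
  }
  # canonical leftmost encoding for short indels, matching the caller
  for (i in seq_len(nrow(truth))) {
    if (truth$kind[i] %in% c("insertion", "deletion")) {
      nv <- normalize_variant(truth$position[i], truth$ref[i], truth$alt[i],
                              genome$sequence)
      truth$position[i] <- nv$position
      truth$ref[i] <- nv$ref
      truth$alt[i] <- nv$alt
    }
  }
  rownames(truth) <- NULL
  list(genome = genome_record(paste0(genome$id, "_mut"), seqc),
       truth = truth[, c("kind", "position", "ref", "alt", "size")])
}

#' Simulate Illumina-like paired-end reads
#'
#' Draws fragments uniformly from the genome, emits both mates (mate 2
#' reverse-complemented), injects independent per-base substitution errors
#' and assigns per-base Phred qualities from a truncated normal
#' distribution. Defaults target the sequencing depths and base qualities
#' typical of a bacterial NextSeq resequencing run (~150x, Q~35, 150 bp
#' paired ends). The number of pairs is
#' `round(mean_coverage * genome_length / (2 * read_length))`.
#'
#' @param genome a [genome_record()].
#' @param mean_coverage target mean fold coverage.
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd fragment length distribution (bases).
#' @param error_rate per-base substitution error probability in `[0, 0.5)`.
#' @param mean_quality,quality_sd Phred quality model, truncated to `[2, 41]`.
#' @param seed integer seed.
#' @return a data frame of read pairs: `pair_id`, `mate1_seq`, `mate1_qual`,
#'   `mate2_seq`, `mate2_qual` (qualities Phred+33 encoded), `true_origin`
#'   (1-based fragment start), `true_strand` and `frag_len`.
#' @export
simulate_reads <- function(genome, mean_coverage = 150, read_length = 150L,
                           insert_mean = 300L, insert_sd = 50,
                           error_rate = 0.005, mean_quality = 35,
                           quality_sd = 3, seed = 1L) {
  stopifnot(inherits(genome, "genome_record"),
            read_length <= insert_mean, error_rate >= 0, error_rate < 0.5)
  if (genome$length < insert_mean)
    stop_fmt("genome (%d bp) shorter than mean insert size (%d bp)",
             genome$length, insert_mean)
  L <- genome$length
  n_pairs <- as.integer(round(mean_coverage * L / (2 * read_length)))
  withr::with_seed(seed, {
    fl <- pmin(L, pmax(read_length, as.integer(round(
      stats::rnorm(n_pairs, insert_mean, insert_sd)))))
    start <- 1L + as.integer(floor(stats::runif(n_pairs) * (L - fl + 1L)))
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    left <- substring(genome$sequence, start, start + read_length - 1L)
    right <- revcomp(substring(genome$sequence, start + fl - read_length,
                               start + fl - 1L))
    # FR layout: one mate per fragment end, reading inward; true_strand
    # records which end mate 1 was sequenced from
    m1 <- ifelse(strand == "+", left, right)
    m2 <- ifelse(strand == "+", right, left)
    m1 <- add_substitution_errors(m1, error_rate, read_length)
    m2 <- add_substitution_errors(m2, error_rate, read_length)
    data.frame(
      pair_id = sprintf("rp%07d", seq_len(n_pairs)),
      mate1_seq = m1,
      mate1_qual = draw_qualities(n_pairs, read_length, mean_quality, quality_sd),
      mate2_seq = m2,
      mate2_qual = draw_qualities(n_pairs, read_length, mean_quality, quality_sd),
      true_origin = start,
      true_strand = strand,
      frag_len = fl,
      stringsAsFactors = FALSE)
  })
}

# substitution errors injected in one pass over the concatenated reads
add_substitution_errors <- function(seqs, rate, read_length) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  x <- charToRaw(paste0(seqs, collapse = ""))
  idx <- which(stats::runif(length(x)) < rate)
  if (length(idx)) {
    bases <- charToRaw(paste0(BASES, collapse = ""))
    cur <- match(x[idx], bases)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    x[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  big <- rawToChar(x)
  substring(big, seq(1L, by = read_length, length.out = length(seqs)),
            seq(read_length, by = read_length, length.out = length(seqs)))
}

draw_qualities <- function(n_reads, read_length, mean_quality, quality_sd) {
  q <- as.integer(round(stats::rnorm(n_reads * read_length, mean_quality,
                                     quality_sd)))
  q <- pmin(41L, pmax(2L, q))
  big <- intToUtf8(q + 33L)
  substring(big, seq(1L, by = read_length, length.out = n_reads),
            seq(read_length, by = read_length, length.out = n_reads))
}
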
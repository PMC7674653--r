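#' Write a genome to FASTA
#'
#' @param genome a [genome_record()] (or list of them).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  x <- Biostrings::DNAStringSet(vapply(genome, `[[`, "", "sequence"))
  names(x) <- vapply(genome, `[[`, "", "id")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genome records from FASTA
#'
#' @param path FASTA file.
#' @return a list of [genome_record()]s.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(x), function(i)
    genome_record(sub("\\s.*$", "", names(x)[i]), as.character(x[[i]])))
}

#' Write read pairs as paired FASTQ files (Phred+33)
#'
#' @param pairs read-pair data frame.
#' @param path1,path2 output files for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$mate1_seq, pairs$mate1_qual, paste0(pairs$pair_id, "/1"), path1)
  wr(pairs$mate2_seq, pairs$mate2_qual, paste0(pairs$pair_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files (Phred+33)
#'
#' Mate files must list the same pairs in the same order; a trailing
#' `/1` / `/2` on the identifiers is stripped.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return a read-pair data frame as produced by [simulate_reads()]
#'   (without truth columns).
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("/[12]$", "", sub("\\s.*$", "", names(x))),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(path1)
  b <- rd(path2)
  if (length(a$id) != length(b$id) || any(a$id != b$id))
    stop_fmt("paired FASTQ files '%s' and '%s' disagree in pair ids",
             path1, path2)
  data.frame(pair_id = a$id, mate1_seq = unname(a$seq),
             mate1_qual = unname(a$qual), mate2_seq = unname(b$seq),
             mate2_qual = unname(b$qual), stringsAsFactors = FALSE)
}

GFF_TYPE <- c(cds = "CDS", pseudogene = "pseudogene", rrna = "rRNA",
              trna = "tRNA")

#' Write gene features as GFF3
#'
#' Coordinates are written 1-based inclusive with `locus_tag` and
#' `product` attributes; pseudogenes additionally carry `pseudo=true`.
#'
#' @param features feature data frame.
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- unname(GFF_TYPE[features$feature_kind])
  S4Vectors::mcols(gr)$source <- "clonevar"
  S4Vectors::mcols(gr)$phase <- ifelse(features$feature_kind == "cds", 0L,
                                       NA_integer_)
  S4Vectors::mcols(gr)$locus_tag <- features$locus_tag
  S4Vectors::mcols(gr)$product <- features$product
  S4Vectors::mcols(gr)$pseudo <- ifelse(features$feature_kind == "pseudogene",
                                        "true", NA_character_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene features from GFF3
#'
#' @param path GFF3 file.
#' @return a feature data frame (`locus_tag`, `product`, `start`, `end`,
#'   `strand`, `feature_kind`); 1-based inclusive coordinates.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  kind <- names(GFF_TYPE)[match(as.character(S4Vectors::mcols(gr)$type),
                                GFF_TYPE)]
  if (anyNA(kind))
    stop_fmt("%s: unsupported feature type '%s'", path,
             as.character(S4Vectors::mcols(gr)$type)[which(is.na(kind))[1]])
  mc <- S4Vectors::mcols(gr)
  data.frame(
    locus_tag = as.character(mc$locus_tag),
    product = as.character(mc$product),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_kind = kind,
    stringsAsFactors = FALSE)
}

FILTER_CODE <- c(raw = ".", pass = "PASS", shared_with_wt = "SharedWithWT",
                 low_relcov = "LowRelCov", low_fraction = "LowFraction")

#' Write variant calls as VCF 4.2
#'
#' INFO carries DP (depth), AC (alternate count), AF (alternate fraction)
#' and RC (relative coverage); the FILTER column encodes the pipeline
#' filter status and the calibrated thresholds are echoed in the header.
#'
#' @param calls variant-call data frame.
#' @param path output file.
#' @param seqid chromosome name.
#' @param thresholds optional [calibrated_thresholds()] echoed in the
#'   header.
#' @param ref_length optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, seqid = "chr", thresholds = NULL,
                      ref_length = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonevar",
           if (!is.null(ref_length))
             sprintf("##contig=<ID=%s,length=%d>", seqid, ref_length)
           else sprintf("##contig=<ID=%s>", seqid),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele read count\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele read fraction\">",
           "##INFO=<ID=RC,Number=1,Type=Float,Description=\"Depth relative to genome mean\">",
           "##FILTER=<ID=SharedWithWT,Description=\"Called in wild-type and mutant\">",
           "##FILTER=<ID=LowRelCov,Description=\"Relative coverage at or below threshold\">",
           "##FILTER=<ID=LowFraction,Description=\"Alternate fraction below threshold\">",
           if (!is.null(thresholds)) c(
             sprintf("##clonevar_rel_cov_min=%g", thresholds$rel_cov_min),
             sprintf("##clonevar_pop_fraction_min=%g",
                     thresholds$pop_fraction_min)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AC=%d;AF=%.6g;RC=%.6g",
    seqid, calls$position, calls$ref, calls$alt,
    unname(FILTER_CODE[calls$filter_status]),
    calls$depth, calls$alt_count, calls$alt_fraction, calls$rel_coverage)
  else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read variant calls from a clonevar VCF
#'
#' @param path VCF file.
#' @return a variant-call data frame.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0L)
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      alt_count = integer(0), alt_fraction = numeric(0),
                      rel_coverage = numeric(0), filter_status = character(0),
                      stringsAsFactors = FALSE))
  info_field <- function(key) {
    m <- regmatches(v@fix[, "INFO"],
                    regexec(paste0("(?:^|;)", key, "=([^;]+)"),
                            v@fix[, "INFO"]))
    as.numeric(vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                      character(1)))
  }
  status <- names(FILTER_CODE)[match(fx$FILTER, FILTER_CODE)]
  status[is.na(status)] <- "raw"
  data.frame(
    position = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
    depth = as.integer(info_field("DP")),
    alt_count = as.integer(info_field("AC")),
    alt_fraction = info_field("AF"),
    rel_coverage = info_field("RC"),
    filter_status = status,
    stringsAsFactors = FALSE)
}

#' Write alignments as a minimal SAM file
#'
#' Emits an @SQ header and one record per alignment with POS, CIGAR and
#' FLAG bits for strand (0x10) and duplicate (0x400); ambiguous
#' alignments carry mapping quality 0, unique ones 60. SEQ is stored in
#' reference orientation, as in SAM.
#'
#' @param alignments alignment data frame from [map_reads()].
#' @param path output file.
#' @param seqid reference name.
#' @param ref_length reference length for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, seqid = "chr", ref_length) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", seqid, ref_length))
  flag <- ifelse(alignments$strand == "-", 16L, 0L) +
    ifelse(alignments$is_duplicate, 1024L, 0L) +
    ifelse(alignments$mate == 1L, 64L, 128L) + 1L
  rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  alignments$read_id, flag, seqid, alignments$ref_start,
                  ifelse(alignments$is_ambiguous, 0L, 60L),
                  alignments$cigar, alignments$seq,
                  alignments$n_mismatches)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a SAM file into an alignment data frame
#'
#' Accepts minimal SAM as written by [write_sam()] or by external
#' mappers; only single-segment records with M/I/D cigars are supported.
#'
#' @param path SAM file.
#' @return an alignment data frame usable by [build_pileup()] and
#'   [coverage_profile()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(0), mate = integer(0),
                      ref_start = integer(0), cigar = character(0),
                      strand = character(0), n_mismatches = integer(0),
                      is_ambiguous = logical(0), is_duplicate = logical(0),
                      seq = character(0), sum_qual = integer(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  bad <- grepl("[^0-9MID]", cigar)
  if (any(bad))
    stop_fmt("%s: unsupported CIGAR '%s' (line %d)", path,
             cigar[bad][1], which(bad)[1])
  nm <- rep(NA_integer_, length(f))
  for (i in seq_along(f)) {
    tag <- grep("^NM:i:", f[[i]], value = TRUE)
    if (length(tag)) nm[i] <- as.integer(sub("^NM:i:", "", tag[1]))
  }
  data.frame(
    read_id = get(1), mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    ref_start = as.integer(get(4)), cigar = cigar,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    n_mismatches = nm,
    is_ambiguous = as.integer(get(5)) == 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    seq = get(10),
    sum_qual = 0L,
    stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param intervals data frame with `start`, `end` and optionally `kind`
#'   (used as the name column).
#' @param path output file.
#' @param seqid chromosome name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, seqid = "chr") {
  name <- if ("kind" %in% names(intervals)) intervals$kind else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", seqid, intervals$start - 1L,
                     intervals$end, name), path)
  invisible(path)
}

#' Write a truth table as TSV
#'
#' @param truth truth data frame from [inject_mutations()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "clonevar")
  if (p == "") stop_fmt("packaged fixture '%s' not found", name)
  p
}

#' Load the packaged mutant-strain SNP/indel catalogue
#'
#' A transcription of the published per-strain variant table of nine
#' butanol-tolerant *C. beijerinckii* NRRL B-598 mutant strains: one row
#' per variant with strain, position, alleles, containing locus (empty
#' for non-coding records) and amino-acid change.
#'
#' @return a data frame with columns `strain`, `position`, `ref`, `alt`,
#'   `locus_tag`, `product`, `start`, `end`, `strand`, `feature`,
#'   `aa_ref`, `aa_alt`.
#' @export
load_table3_variants <- function() {
  x <- utils::read.delim(fixture_path("table3_variants.tsv"),
                         stringsAsFactors = FALSE, na.strings = NULL,
                         colClasses = "character")
  x$position <- as.integer(x$position)
  x$start <- suppressWarnings(as.integer(x$start))
  x$end <- suppressWarnings(as.integer(x$end))
  x
}

parse_interval <- function(s) {
  p <- strsplit(s, "[-–]")[[1]]
  if (length(p) != 2L) stop_fmt("malformed interval '%s'", s)
  as.integer(p)
}

#' Load the packaged longer-change catalogue
#'
#' Longer genomic losses of the published mutant strains, with 1-based
#' inclusive intervals parsed from the printed "start-end" positions.
#'
#' @return a data frame with `strain`, `start`, `end`, `size`, `note`.
#' @export
load_table4_changes <- function() {
  x <- utils::read.delim(fixture_path("table4_long_changes.tsv"),
                         stringsAsFactors = FALSE)
  iv <- t(vapply(x$position, parse_interval, integer(2)))
  data.frame(strain = x$strain, start = iv[, 1], end = iv[, 2],
             size = as.integer(x$size_bp), note = x$note,
             stringsAsFactors = FALSE)
}

#' Load the packaged copy-number-variation catalogue
#'
#' Copy-number variations of the published mutant strains; one row per
#' (strain, locus) with the CNV interval repeated across its loci.
#'
#' @return a data frame with `strain`, `start`, `end`, `size_kb` (as
#'   printed), `locus_tag`, `product`.
#' @export
load_table5_cnv <- function() {
  x <- utils::read.delim(fixture_path("table5_cnv.tsv"),
                         stringsAsFactors = FALSE)
  iv <- t(vapply(x$position, parse_interval, integer(2)))
  data.frame(strain = x$strain, start = iv[, 1], end = iv[, 2],
             size = x$size, locus_tag = x$locus_tag, product = x$product,
             stringsAsFactors = FALSE)
}
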
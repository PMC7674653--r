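#' Build an exact k-mer index of a reference sequence
#'
#' Hashes every overlapping k-mer of the forward strand to its 1-based
#' start positions. Reverse-strand placements are found by looking up
#' seeds of the reverse-complemented read, so only one strand is indexed.
#'
#' @param reference a [genome_record()] or DNA string.
#' @param k seed length in bases.
#' @return an environment mapping k-mer strings to integer position vectors.
#' @export
kmer_index <- function(reference, k = 21L) {
  ref <- if (inherits(reference, "genome_record")) reference$sequence else reference
  n <- nchar(ref) - k + 1L
  stopifnot(n >= 1)
  kmers <- substring(ref, seq_len(n), seq_len(n) + k - 1L)
  e <- new.env(hash = TRUE, size = n)
  list2env(split(seq_len(n), kmers), envir = e)
  e
}

parse_cigar <- function(cig) {
  list(len = as.integer(regmatches(cig, gregexpr("\\d+", cig))[[1]]),
       op = regmatches(cig, gregexpr("[MID]", cig))[[1]])
}

# reference bases consumed by each cigar (M and D operations)
cigar_ref_span <- function(cigs) {
  out <- integer(length(cigs))
  simple <- grepl("^[0-9]+M$", cigs)
  out[simple] <- as.integer(sub("M$", "", cigs[simple]))
  out[!simple] <- vapply(cigs[!simple], function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op != "I"])
  }, integer(1))
  out
}

# query bases consumed by each cigar (M and I operations)
cigar_query_span <- function(cigs) {
  out <- integer(length(cigs))
  simple <- grepl("^[0-9]+M$", cigs)
  out[simple] <- as.integer(sub("M$", "", cigs[simple]))
  out[!simple] <- vapply(cigs[!simple], function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op != "D"])
  }, integer(1))
  out
}

# ungapped mismatch counts for many reads at fixed placements, chunked so
# the concatenated comparison never materialises more than ~6 Mb at once
bulk_mismatch <- function(seqs, starts, ref_raw, chunk = 20000L) {
  m <- length(seqs)
  out <- integer(m)
  if (m == 0L) return(out)
  w <- nchar(seqs)
  for (ch in split(seq_len(m), (seq_len(m) - 1L) %/% chunk)) {
    big <- charToRaw(paste0(seqs[ch], collapse = ""))
    ridx <- sequence(w[ch], from = starts[ch])
    neq <- big != ref_raw[ridx]
    idx <- rep.int(seq_along(ch), w[ch])
    out[ch] <- as.integer(rowsum(as.integer(neq), idx)[, 1])
  }
  out
}

# banded single-indel alignment: read anchored at `start` (its prefix
# diagonal), one insertion or deletion of <= band bases, anchors of at
# least min_anchor matched-or-mismatched bases on both sides
try_indel <- function(read_raw, ref_raw, start, band = 10L, min_anchor = 6L) {
  w <- length(read_raw)
  L <- length(ref_raw)
  cmp <- function(shift) {
    pos <- start + seq_len(w) - 1L + shift
    ok <- pos >= 1L & pos <= L
    mm <- rep(TRUE, w)
    mm[ok] <- read_raw[ok] != ref_raw[pos[ok]]
    mm
  }
  if (w < 2L * min_anchor + 1L) return(list(mm = Inf, cigar = NULL))
  cum0 <- cumsum(cmp(0L))
  best <- list(mm = Inf, cigar = NULL)
  for (d in seq_len(band)) {
    cumd <- cumsum(cmp(d))
    i <- min_anchor:(w - min_anchor)
    tot <- cum0[i] + (cumd[w] - cumd[i])
    j <- which.min(tot)
    if (tot[j] < best$mm)
      best <- list(mm = tot[j],
                   cigar = sprintf("%dM%dD%dM", i[j], d, w - i[j]))
    if (w - d - min_anchor >= min_anchor) {
      cumi <- cumsum(cmp(-d))
      i2 <- min_anchor:(w - d - min_anchor)
      tot2 <- cum0[i2] + (cumi[w] - cumi[i2 + d])
      j2 <- which.min(tot2)
      if (tot2[j2] < best$mm)
        best <- list(mm = tot2[j2],
                     cigar = sprintf("%dM%dI%dM", i2[j2], d, w - i2[j2] - d))
    }
  }
  best
}

#' Map read pairs to a reference with a k-mer seed-and-extend aligner
#'
#' Exact k-mer seeds (read start, middle and end) vote by diagonal on both
#' strands; the candidate placements are extended ungapped and, when the
#' mismatch count exceeds `max_mismatches`, a banded single-indel
#' alignment (band 10) is attempted to recover short indels. Reads whose
#' two best placements tie in score are marked ambiguous and excluded from
#' pileups; reads with no seed hit are omitted and counted in the
#' `n_unmapped` attribute.
#'
#' @param pairs read pairs (see [simulate_reads()]), normally after
#'   [trim_pairs()].
#' @param reference a [genome_record()] or DNA string.
#' @param k seed length (>= 11).
#' @param max_mismatches maximum accepted mismatches per mate.
#' @param index optional precomputed [kmer_index()] of `reference`.
#' @return a data frame of alignments: `read_id`, `mate`, `ref_start`,
#'   `cigar`, `strand`, `n_mismatches`, `is_ambiguous`, `is_duplicate`,
#'   `seq` (reference-orientation sequence, as in SAM) and `sum_qual`
#'   (summed Phred scores of the mate). Attribute `n_unmapped` counts
#'   unplaced mates.
#' @export
map_reads <- function(pairs, reference, k = 21L, max_mismatches = 6L,
                      index = NULL) {
  stopifnot(k >= 11L)
  ref <- if (inherits(reference, "genome_record")) reference$sequence else reference
  L <- nchar(ref)
  stopifnot(L > 0L)
  ref_raw <- charToRaw(ref)
  if (is.null(index)) index <- kmer_index(ref, k)

  n <- nrow(pairs)
  ids <- rep(pairs$pair_id, 2L)
  mate <- rep(c(1L, 2L), each = n)
  seqs <- c(pairs$mate1_seq, pairs$mate2_seq)
  quals <- c(pairs$mate1_qual, pairs$mate2_qual)
  m <- length(seqs)
  w <- nchar(seqs)
  rc <- revcomp(seqs)
  sumq <- sum_phred(quals)

  offs <- list(rep(1L, m),
               pmax(1L, (w - k) %/% 2L + 1L),
               pmax(1L, w - k + 1L))
  look <- function(sq, off) {
    keys <- substring(sq, off, off + k - 1L)
    keys[nchar(keys) < k] <- "__short__"
    mget(keys, envir = index, ifnotfound = list(NULL))
  }
  res_f <- lapply(offs, function(o) look(seqs, o))
  res_r <- lapply(offs, function(o) look(rc, o))

  seed_summary <- function(res, o) {
    len <- lengths(res)
    val <- rep(NA_integer_, m)
    sing <- len == 1L
    val[sing] <- unlist(res[sing], use.names = FALSE) - o[sing] + 1L
    list(val = val, multi = len > 1L)
  }
  sf <- mapply(seed_summary, res_f, offs, SIMPLIFY = FALSE)
  sr <- mapply(seed_summary, res_r, offs, SIMPLIFY = FALSE)
  fmin <- pmin(sf[[1]]$val, sf[[2]]$val, sf[[3]]$val, na.rm = TRUE)
  fmax <- pmax(sf[[1]]$val, sf[[2]]$val, sf[[3]]$val, na.rm = TRUE)
  rmin <- pmin(sr[[1]]$val, sr[[2]]$val, sr[[3]]$val, na.rm = TRUE)
  rmax <- pmax(sr[[1]]$val, sr[[2]]$val, sr[[3]]$val, na.rm = TRUE)
  fmulti <- sf[[1]]$multi | sf[[2]]$multi | sf[[3]]$multi
  rmulti <- sr[[1]]$multi | sr[[2]]$multi | sr[[3]]$multi

  in_bounds <- function(st) !is.na(st) & st >= 1L & st + w - 1L <= L
  fast_f <- !fmulti & !rmulti & !is.na(fmin) & fmin == fmax & is.na(rmin) &
    in_bounds(fmin)
  fast_r <- !fmulti & !rmulti & !is.na(rmin) & rmin == rmax & is.na(fmin) &
    in_bounds(rmin)
  has_any <- !is.na(fmin) | !is.na(rmin) | fmulti | rmulti
  slow <- which(has_any & !(fast_f | fast_r))

  ref_start <- rep(NA_integer_, m)
  strand <- rep(NA_character_, m)
  cigar <- rep(NA_character_, m)
  n_mm <- rep(NA_integer_, m)
  ambiguous <- rep(FALSE, m)
  aligned <- rep(NA_character_, m)

  fi <- which(fast_f)
  ri <- which(fast_r)
  mm_f <- bulk_mismatch(seqs[fi], fmin[fi], ref_raw)
  mm_r <- bulk_mismatch(rc[ri], rmin[ri], ref_raw)
  acc_f <- fi[mm_f <= max_mismatches]
  acc_r <- ri[mm_r <= max_mismatches]
  ref_start[acc_f] <- fmin[acc_f]
  ref_start[acc_r] <- rmin[acc_r]
  strand[acc_f] <- "+"
  strand[acc_r] <- "-"
  n_mm[acc_f] <- mm_f[mm_f <= max_mismatches]
  n_mm[acc_r] <- mm_r[mm_r <= max_mismatches]
  cigar[c(acc_f, acc_r)] <- paste0(w[c(acc_f, acc_r)], "M")
  aligned[acc_f] <- seqs[acc_f]
  aligned[acc_r] <- rc[acc_r]
  slow <- sort(c(slow, fi[mm_f > max_mismatches], ri[mm_r > max_mismatches]))

  for (i in slow) {
    cand <- unique(rbind(
      do.call(rbind, lapply(seq_len(3L), function(j) {
        p <- res_f[[j]][[i]]
        if (is.null(p)) NULL else cbind(p - offs[[j]][i] + 1L, 1L)
      })),
      do.call(rbind, lapply(seq_len(3L), function(j) {
        p <- res_r[[j]][[i]]
        if (is.null(p)) NULL else cbind(p - offs[[j]][i] + 1L, 2L)
      }))))
    if (is.null(cand)) next
    cand <- cand[cand[, 1] >= 1L & cand[, 1] + w[i] - 1L <= L, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
    fwd_raw <- charToRaw(seqs[i])
    rev_raw <- charToRaw(rc[i])
    scores <- vapply(seq_len(nrow(cand)), function(j) {
      rr <- if (cand[j, 2] == 1L) fwd_raw else rev_raw
      pos <- cand[j, 1] + seq_len(w[i]) - 1L
      sum(rr != ref_raw[pos])
    }, numeric(1))
    b <- which.min(scores)
    if (scores[b] <= max_mismatches) {
      ref_start[i] <- cand[b, 1]
      strand[i] <- c("+", "-")[cand[b, 2]]
      cigar[i] <- paste0(w[i], "M")
      n_mm[i] <- as.integer(scores[b])
      ambiguous[i] <- sum(scores == scores[b]) > 1L
      aligned[i] <- if (cand[b, 2] == 1L) seqs[i] else rc[i]
      next
    }
    # ungapped placement failed everywhere: banded single-indel recovery
    gaps <- lapply(seq_len(nrow(cand)), function(j) {
      rr <- if (cand[j, 2] == 1L) fwd_raw else rev_raw
      try_indel(rr, ref_raw, cand[j, 1])
    })
    gmm <- vapply(gaps, function(g) g$mm, numeric(1))
    b <- which.min(gmm)
    if (is.finite(gmm[b]) && gmm[b] <= max_mismatches &&
        min(scores) - gmm[b] >= 3) {
      ref_start[i] <- cand[b, 1]
      strand[i] <- c("+", "-")[cand[b, 2]]
      cigar[i] <- gaps[[b]]$cigar
      n_mm[i] <- as.integer(gmm[b])
      ambiguous[i] <- sum(gmm == gmm[b]) > 1L
      aligned[i] <- if (cand[b, 2] == 1L) seqs[i] else rc[i]
    }
  }

  mapped <- which(!is.na(ref_start))
  out <- data.frame(
    read_id = ids[mapped], mate = mate[mapped],
    ref_start = ref_start[mapped], cigar = cigar[mapped],
    strand = strand[mapped], n_mismatches = n_mm[mapped],
    is_ambiguous = ambiguous[mapped], is_duplicate = FALSE,
    seq = aligned[mapped], sum_qual = sumq[mapped],
    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- m - length(mapped)
  out
}

#' Mark duplicate read pairs
#'
#' Pairs sharing both mates' 5'-most reference coordinates and orientation
#' form a duplicate group; within a group the pair with the highest summed
#' base quality survives (ties broken by pair identifier) and every other
#' pair is flagged `is_duplicate` on both mates. Only pairs with both
#' mates mapped unambiguously are considered.
#'
#' @param alignments alignment data frame from [map_reads()].
#' @return the alignments with `is_duplicate` set.
#' @export
mark_duplicates <- function(alignments) {
  a <- alignments
  a$is_duplicate <- FALSE
  if (nrow(a) == 0L) return(a)
  span <- cigar_ref_span(a$cigar)
  p5 <- ifelse(a$strand == "+", a$ref_start, a$ref_start + span - 1L)
  ok <- !a$is_ambiguous
  i1 <- which(a$mate == 1L & ok)
  i2 <- which(a$mate == 2L & ok)
  j <- match(a$read_id[i1], a$read_id[i2])
  paired <- !is.na(j)
  i1 <- i1[paired]
  i2 <- i2[j[paired]]
  if (length(i1) == 0L) return(a)
  sig <- paste(p5[i1], p5[i2], a$strand[i1], a$strand[i2], sep = "|")
  totq <- a$sum_qual[i1] + a$sum_qual[i2]
  ord <- order(sig, -totq, a$read_id[i1], method = "radix")
  losers <- a$read_id[i1][ord][duplicated(sig[ord])]
  a$is_duplicate[a$read_id %in% losers] <- TRUE
  a
}

#' Per-window coverage profile
#'
#' Per-position depth counts reference-consuming bases of non-duplicate,
#' unambiguous alignments; window depth is the mean depth over the
#' window's positions and the genome mean is the mean over all positions
#' (so it equals the length-weighted mean of the window depths).
#'
#' @param alignments alignment data frame from [map_reads()] (after
#'   [mark_duplicates()]).
#' @param ref_length reference length in bases.
#' @param window window width in bases.
#' @return an object of class `coverage_profile` with fields `window`,
#'   `window_start`, `window_depth`, `mean_depth`, `depth` (per-position)
#'   and `ref_length`.
#' @export
coverage_profile <- function(alignments, ref_length, window = 100L) {
  stopifnot(window >= 1L)
  use <- !alignments$is_duplicate & !alignments$is_ambiguous
  s <- alignments$ref_start[use]
  e <- s + cigar_ref_span(alignments$cigar[use]) - 1L
  if (any(e > ref_length)) stop_fmt("alignment extends past reference end")
  inc <- tabulate(s, ref_length)
  dec <- tabulate(pmin(e + 1L, ref_length + 1L), ref_length + 1L)
  depth <- cumsum(inc - dec[seq_len(ref_length)])
  pos <- seq_len(ref_length)
  win_id <- ((pos - 1L) %/% window) + 1L
  wd <- as.vector(rowsum(depth, win_id)) / tabulate(win_id)
  structure(list(window = as.integer(window),
                 window_start = (seq_along(wd) - 1L) * window + 1L,
                 window_depth = wd,
                 mean_depth = mean(depth),
                 depth = depth,
                 ref_length = as.integer(ref_length)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d bp, window %d, mean depth %.1fx\n",
              x$ref_length, x$window, x$mean_depth))
  invisible(x)
}
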
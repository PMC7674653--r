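#' Build a per-position pileup from alignments
#'
#' Tallies aligned read bases, deletions and insertion events over every
#' reference position. Duplicate and ambiguous alignments are excluded.
#' CIGAR deletions increment `deletion_count` on each deleted position and
#' are also recorded as events at their anchor (the reference base before
#' the deleted run); insertions are recorded at their anchor only, since
#' they consume no reference.
#'
#' @param alignments alignment data frame from [map_reads()] (after
#'   [mark_duplicates()]); `seq` must hold the reference-orientation read.
#' @param reference a [genome_record()] or DNA string.
#' @return an object of class `pileup`: `depth` (per-position, equal to
#'   base counts plus deletions), `base_counts` (length x 4 matrix, columns
#'   A/C/G/T), `deletion_count`, `insertion_events` (data frame `anchor`,
#'   `seq`, one row per supporting read), `deletion_events` (`anchor`,
#'   `len`) and `ref_length`.
#' @export
build_pileup <- function(alignments, reference) {
  ref <- if (inherits(reference, "genome_record")) reference$sequence else reference
  L <- nchar(ref)
  ref_raw <- charToRaw(ref)
  a <- alignments[!alignments$is_duplicate & !alignments$is_ambiguous, ,
                  drop = FALSE]
  match_cov <- integer(L)
  del_cov <- integer(L)
  mm_pos <- integer(0)
  mm_base <- raw(0)
  ins_anchor <- integer(0)
  ins_seq <- character(0)
  del_anchor <- integer(0)
  del_len <- integer(0)

  simple <- grepl("^[0-9]+M$", a$cigar)
  s <- a$ref_start[simple]
  sq <- a$seq[simple]
  w <- nchar(sq)
  if (any(s + w - 1L > L)) stop_fmt("alignment walks past reference end")
  if (length(s)) {
    inc <- tabulate(s, L)
    dec <- tabulate(pmin(s + w, L + 1L), L + 1L)
    match_cov <- match_cov + cumsum(inc - dec[seq_len(L)])
    chunk <- 20000L
    for (ch in split(seq_along(s), (seq_along(s) - 1L) %/% chunk)) {
      big <- charToRaw(paste0(sq[ch], collapse = ""))
      ridx <- sequence(w[ch], from = s[ch])
      neq <- which(big != ref_raw[ridx])
      mm_pos <- c(mm_pos, ridx[neq])
      mm_base <- c(mm_base, big[neq])
    }
  }

  for (i in which(!simple)) {
    cg <- parse_cigar(a$cigar[i])
    rp <- a$ref_start[i]
    qp <- 1L
    rraw <- charToRaw(a$seq[i])
    for (j in seq_along(cg$op)) {
      len <- cg$len[j]
      op <- cg$op[j]
      if (op == "M") {
        if (rp + len - 1L > L) stop_fmt("alignment walks past reference end")
        seg <- rp:(rp + len - 1L)
        match_cov[seg] <- match_cov[seg] + 1L
        neq <- which(rraw[qp:(qp + len - 1L)] != ref_raw[seg])
        mm_pos <- c(mm_pos, seg[neq])
        mm_base <- c(mm_base, rraw[qp + neq - 1L])
        rp <- rp + len
        qp <- qp + len
      } else if (op == "D") {
        if (rp + len - 1L > L) stop_fmt("alignment walks past reference end")
        seg <- rp:(rp + len - 1L)
        del_cov[seg] <- del_cov[seg] + 1L
        del_anchor <- c(del_anchor, rp - 1L)
        del_len <- c(del_len, len)
        rp <- rp + len
      } else {
        ins_anchor <- c(ins_anchor, rp - 1L)
        ins_seq <- c(ins_seq, substr(a$seq[i], qp, qp + len - 1L))
        qp <- qp + len
      }
    }
  }

  base_raw <- charToRaw(paste0(BASES, collapse = ""))
  bc <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  if (length(mm_pos)) {
    code <- (mm_pos - 1L) * 4L + match(mm_base, base_raw)
    bc <- matrix(tabulate(code, 4L * L), nrow = L, ncol = 4L, byrow = TRUE,
                 dimnames = list(NULL, BASES))
  }
  mm_tot <- as.integer(rowSums(bc))
  ref_idx <- match(ref_raw, base_raw)
  bc[cbind(seq_len(L), ref_idx)] <- match_cov - mm_tot
  structure(list(
    depth = match_cov + del_cov,
    base_counts = bc,
    deletion_count = del_cov,
    insertion_events = data.frame(anchor = ins_anchor, seq = ins_seq,
                                  stringsAsFactors = FALSE),
    deletion_events = data.frame(anchor = del_anchor, len = del_len),
    ref_length = L), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d bp, %d covered positions, max depth %d\n",
              x$ref_length, sum(x$depth > 0), max(x$depth)))
  invisible(x)
}

#' Left-normalise a variant record
#'
#' Indels in repetitive context admit several equivalent anchored
#' encodings; this produces the canonical leftmost one (shared trailing
#' bases truncated, the record extended leftwards when an allele empties,
#' then shared leading bases beyond the anchor stripped). SNPs are
#' returned unchanged. Both the caller and the mutation injector
#' normalise through this function, so truth tables and call sets use
#' identical coordinates.
#'
#' @param position 1-based position of the record.
#' @param ref,alt anchored reference and alternate alleles.
#' @param sequence the reference sequence the record lies on.
#' @return list with normalised `position`, `ref` and `alt`.
#' @export
normalize_variant <- function(position, ref, alt, sequence) {
  if (nchar(ref) == nchar(alt)) return(list(position = position, ref = ref,
                                            alt = alt))
  repeat {
    nr <- nchar(ref)
    na <- nchar(alt)
    if (nr >= 1L && na >= 1L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (position == 1L) {
        # cannot extend further left; re-anchor on the first base
        base <- substr(sequence, 1L, 1L)
        return(list(position = 1L, ref = paste0(base, ref),
                    alt = paste0(base, alt)))
      }
      position <- position - 1L
      base <- substr(sequence, position, position)
      ref <- paste0(base, ref)
      alt <- paste0(base, alt)
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }
  list(position = position, ref = ref, alt = alt)
}

#' Call raw SNVs and short indels from a pileup
#'
#' At every position with depth at least `min_depth`, each non-reference
#' allele (substituted base, insertion or deletion) whose supporting read
#' count reaches `min_alt_count` and whose read fraction reaches
#' `min_alt_fraction` is a candidate; per site only the highest-count
#' allele is reported, ties broken by the lexicographically smallest
#' alternate allele. Indels use the anchored VCF encoding (`A -> AT`,
#' `CA -> C`). Defaults are deliberately permissive: noise removal is the
#' job of the wild-type-calibrated filter stage, not the caller.
#'
#' @param pileup a [build_pileup()] result.
#' @param reference a [genome_record()] or DNA string.
#' @param mean_depth genome mean depth used for relative coverage; defaults
#'   to the mean of the pileup depth vector.
#' @param min_depth,min_alt_count,min_alt_fraction raw-call thresholds.
#' @return a data frame of variant calls: `position`, `ref`, `alt`,
#'   `depth`, `alt_count`, `alt_fraction`, `rel_coverage` and
#'   `filter_status` (all `"raw"`).
#' @export
call_variants <- function(pileup, reference, mean_depth = NULL,
                          min_depth = 10L, min_alt_count = 3L,
                          min_alt_fraction = 0.10) {
  stopifnot(inherits(pileup, "pileup"), min_depth >= 1L)
  ref <- if (inherits(reference, "genome_record")) reference$sequence else reference
  L <- pileup$ref_length
  stopifnot(nchar(ref) == L)
  if (is.null(mean_depth)) mean_depth <- mean(pileup$depth)
  depth <- pileup$depth

  ref_idx <- match(charToRaw(ref), charToRaw(paste0(BASES, collapse = "")))
  alt_bc <- pileup$base_counts
  alt_bc[cbind(seq_len(L), ref_idx)] <- 0L
  best_col <- max.col(alt_bc, ties.method = "first")  # A<C<G<T tie order
  best_cnt <- alt_bc[cbind(seq_len(L), best_col)]
  snv_pos <- which(best_cnt > 0L)
  cand <- if (length(snv_pos)) data.frame(
    position = snv_pos,
    ref = substring(ref, snv_pos, snv_pos),
    alt = BASES[best_col[snv_pos]],
    alt_count = best_cnt[snv_pos],
    stringsAsFactors = FALSE)
  else data.frame(position = integer(0), ref = character(0),
                  alt = character(0), alt_count = integer(0),
                  stringsAsFactors = FALSE)

  indels <- data.frame(position = integer(0), ref = character(0),
                       alt = character(0), alt_count = integer(0),
                       stringsAsFactors = FALSE)
  ie <- pileup$insertion_events
  if (nrow(ie)) {
    key <- paste(ie$anchor, ie$seq)
    agg <- ie[!duplicated(key), , drop = FALSE]
    agg$alt_count <- as.integer(table(key)[paste(agg$anchor, agg$seq)])
    agg <- agg[agg$anchor >= 1L, , drop = FALSE]
    if (nrow(agg)) {
      anchor_base <- substring(ref, agg$anchor, agg$anchor)
      indels <- rbind(indels, data.frame(
        position = agg$anchor, ref = anchor_base,
        alt = paste0(anchor_base, agg$seq), alt_count = agg$alt_count,
        stringsAsFactors = FALSE))
    }
  }
  de <- pileup$deletion_events
  if (nrow(de)) {
    key <- paste(de$anchor, de$len)
    agg <- de[!duplicated(key), , drop = FALSE]
    agg$alt_count <- as.integer(table(key)[paste(agg$anchor, agg$len)])
    agg <- agg[agg$anchor >= 1L & agg$anchor + agg$len <= L, , drop = FALSE]
    if (nrow(agg)) {
      indels <- rbind(indels, data.frame(
        position = agg$anchor,
        ref = substring(ref, agg$anchor, agg$anchor + agg$len),
        alt = substring(ref, agg$anchor, agg$anchor),
        alt_count = agg$alt_count,
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(indels)) {
    # equivalent encodings collapse onto the canonical leftmost record
    for (i in seq_len(nrow(indels))) {
      nv <- normalize_variant(indels$position[i], indels$ref[i],
                              indels$alt[i], ref)
      indels$position[i] <- nv$position
      indels$ref[i] <- nv$ref
      indels$alt[i] <- nv$alt
    }
    key <- paste(indels$position, indels$ref, indels$alt)
    counts <- tapply(indels$alt_count, key, sum)
    indels <- indels[!duplicated(key), , drop = FALSE]
    indels$alt_count <- as.integer(counts[paste(indels$position, indels$ref,
                                                indels$alt)])
    cand <- rbind(cand, indels)
  }

  cand$depth <- depth[cand$position]
  keep <- cand$depth >= min_depth & cand$alt_count >= min_alt_count &
    cand$alt_count / cand$depth >= min_alt_fraction
  cand <- cand[keep, , drop = FALSE]
  # one allele per site: highest count, then lexicographically smallest alt
  cand <- cand[order(cand$position, -cand$alt_count, cand$alt), , drop = FALSE]
  cand <- cand[!duplicated(cand$position), , drop = FALSE]
  out <- data.frame(
    position = cand$position, ref = cand$ref, alt = cand$alt,
    depth = cand$depth, alt_count = cand$alt_count,
    alt_fraction = cand$alt_count / cand$depth,
    rel_coverage = cand$depth / mean_depth,
    filter_status = rep("raw", nrow(cand)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}
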
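#' Quality trimming policy
#'
#' Sliding-window quality trimming parameters. Defaults follow the common
#' documented defaults of window-based read trimmers (window 4, mean
#' quality 15, minimum surviving length 36).
#'
#' @param window window width in bases.
#' @param min_window_quality minimum mean Phred quality of a window.
#' @param min_length minimum read length after trimming; shorter reads are
#'   dropped.
#' @return a list of class `trim_policy`.
#' @export
trim_policy <- function(window = 4L, min_window_quality = 15,
                        min_length = 36L) {
  stopifnot(window >= 1, min_length >= 1)
  structure(list(window = as.integer(window),
                 min_window_quality = min_window_quality,
                 min_length = as.integer(min_length)),
            class = "trim_policy")
}

# crop point for one quality vector: leading bases below Phred 3 are
# removed, then the read is cropped at the end of the last window whose
# mean quality reaches the threshold; returns c(from, to) or NULL (drop)
trim_bounds <- function(q, policy) {
  n <- length(q)
  from <- which(q >= 3L)[1]
  if (is.na(from)) return(NULL)
  q <- q[from:n]
  n <- length(q)
  w <- policy$window
  if (n < w) return(NULL)
  cs <- cumsum(c(0, q))
  win_mean <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
  ok <- which(win_mean >= policy$min_window_quality)
  if (length(ok) == 0L) return(NULL)
  to <- ok[length(ok)] + w - 1L
  if (to < policy$min_length) return(NULL)
  c(from, from + to - 1L)
}

#' Quality-trim a single read
#'
#' Removes leading bases below Phred 3, then scans sliding windows and
#' crops the read at the end of the last window whose mean quality reaches
#' `min_window_quality`. Reads shorter than `min_length` after cropping are
#' dropped.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string of the same length.
#' @param policy a [trim_policy()].
#' @return a list `(seq, qual)` with the trimmed read, or `NULL` if the
#'   read is dropped.
#' @export
quality_trim <- function(seq, qual, policy = trim_policy()) {
  stopifnot(nchar(seq) == nchar(qual))
  b <- trim_bounds(phred_to_int(qual), policy)
  if (is.null(b)) return(NULL)
  list(seq = substr(seq, b[1], b[2]), qual = substr(qual, b[1], b[2]))
}

#' Trim read pairs and drop singletons
#'
#' Applies [quality_trim()] to both mates of every pair and keeps only
#' pairs in which both mates survive, so the output contains no unpaired
#' mate.
#'
#' @param pairs a read-pair data frame from [simulate_reads()] or
#'   [read_fastq_pairs()].
#' @param policy a [trim_policy()].
#' @return the surviving pairs with trimmed sequences and qualities; the
#'   number of dropped pairs is attached as attribute `n_dropped`.
#' @export
trim_pairs <- function(pairs, policy = trim_policy()) {
  n <- nrow(pairs)
  if (n == 0L) {
    attr(pairs, "n_dropped") <- 0L
    return(pairs)
  }
  bounds <- function(quals) lapply(quals, function(s)
    trim_bounds(phred_to_int(s), policy))
  b1 <- bounds(pairs$mate1_qual)
  b2 <- bounds(pairs$mate2_qual)
  keep <- !vapply(b1, is.null, logical(1)) & !vapply(b2, is.null, logical(1))
  out <- pairs[keep, , drop = FALSE]
  crop <- function(x, b) substr(x, vapply(b, `[`, integer(1), 1L),
                                vapply(b, `[`, integer(1), 2L))
  if (nrow(out)) {
    bk1 <- b1[keep]; bk2 <- b2[keep]
    out$mate1_seq <- crop(out$mate1_seq, bk1)
    out$mate1_qual <- crop(out$mate1_qual, bk1)
    out$mate2_seq <- crop(out$mate2_seq, bk2)
    out$mate2_qual <- crop(out$mate2_qual, bk2)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n - nrow(out)
  out
}
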
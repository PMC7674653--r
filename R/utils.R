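BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; delegates to Biostrings.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param s a single quality string.
#' @return integer vector of Phred scores.
#' @export
phred_to_int <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  utf8ToInt(s) - 33L
}

#' Convert integer Phred scores to a Phred+33 quality string
#'
#' @param q integer vector of Phred scores.
#' @return a single quality string.
#' @export
int_to_phred <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(as.integer(q) + 33L)
}

# random DNA string with a given GC fraction
random_dna <- function(n, gc_fraction) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste0(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# sum of per-read Phred scores for a vector of quality strings
sum_phred <- function(quals) {
  w <- nchar(quals)
  if (sum(w) == 0L) return(integer(length(quals)))
  big <- utf8ToInt(paste0(quals, collapse = "")) - 33L
  idx <- rep.int(seq_along(quals), w)
  out <- integer(length(quals))
  s <- rowsum(big, idx)
  out[as.integer(rownames(s))] <- as.integer(s[, 1])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
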
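#' Detect copy-number gains and longer losses from comparative coverage
#'
#' Each window's copy ratio is the mutant window depth over the mutant
#' genome mean, divided by the same quantity for the wild-type profile.
#' Segmentation uses two thresholds: a call needs a seed run of at least
#' `min_windows` consecutive windows at the full threshold (`gain_min`
#' for gains, `loss_max` for losses; seed runs separated by at most one
#' window merge), and the seed is then extended across windows beyond the
#' midpoint between the threshold and 1, so edge-window sampling noise
#' does not fragment an event. Windows with zero wild-type depth are
#' masked. Call boundaries are refined to base resolution by scanning the
#' per-position copy ratio outwards from the run edges until it crosses
#' the same midpoint. The reported copy ratio is the median window ratio
#' over the call.
#'
#' @param mutant_profile,wts_profile [coverage_profile()]s sharing window
#'   size and genome length.
#' @param gain_min minimum window ratio of a gain.
#' @param loss_max maximum window ratio of a loss.
#' @param min_windows minimum run length in windows.
#' @param features optional feature data frame; overlapped locus tags are
#'   then reported per call.
#' @return a data frame of CNV calls: `start`, `end`, `size`
#'   (`end - start + 1`), `kind` (`gain`/`loss`), `copy_ratio` and,
#'   when `features` is given, a comma-separated `loci` column.
#' @export
detect_cnv <- function(mutant_profile, wts_profile, gain_min = 1.75,
                       loss_max = 0.25, min_windows = 5L, features = NULL) {
  stopifnot(inherits(mutant_profile, "coverage_profile"),
            inherits(wts_profile, "coverage_profile"))
  if (mutant_profile$window != wts_profile$window ||
      mutant_profile$ref_length != wts_profile$ref_length)
    stop_fmt("coverage profiles disagree in window size or genome length")
  w <- mutant_profile$window
  L <- mutant_profile$ref_length
  mw <- mutant_profile$window_depth / mutant_profile$mean_depth
  ww <- wts_profile$window_depth / wts_profile$mean_depth
  masked <- wts_profile$window_depth <= 0
  ratio <- ifelse(masked, NA_real_, mw / ww)

  # two-threshold segmentation: seed runs must hold the full threshold,
  # extension tolerates windows beyond the midpoint between threshold and
  # 1, so sampling noise at the event edges does not fragment a call
  segment_kind <- function(kind) {
    if (kind == "gain") {
      core <- !is.na(ratio) & ratio >= gain_min
      ext <- !is.na(ratio) & ratio >= (gain_min + 1) / 2
    } else {
      core <- !is.na(ratio) & ratio <= loss_max
      ext <- !is.na(ratio) & ratio <= (loss_max + 1) / 2
    }
    r <- rle(core)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- data.frame(from = starts[r$values], to = ends[r$values])
    # merge core runs separated by at most one window
    if (nrow(seg) > 1L) {
      i <- 1L
      while (i < nrow(seg)) {
        if (seg$from[i + 1L] - seg$to[i] <= 2L) {
          seg$to[i] <- seg$to[i + 1L]
          seg <- seg[-(i + 1L), , drop = FALSE]
        } else i <- i + 1L
      }
    }
    seg <- seg[seg$to - seg$from + 1L >= min_windows, , drop = FALSE]
    if (nrow(seg)) {
      for (i in seq_len(nrow(seg))) {
        while (seg$from[i] > 1L && ext[seg$from[i] - 1L])
          seg$from[i] <- seg$from[i] - 1L
        while (seg$to[i] < length(ext) && ext[seg$to[i] + 1L])
          seg$to[i] <- seg$to[i] + 1L
      }
      # extension can make neighbouring calls touch; take their union
      i <- 1L
      while (i < nrow(seg)) {
        if (seg$from[i + 1L] - seg$to[i] <= 1L) {
          seg$to[i] <- max(seg$to[i], seg$to[i + 1L])
          seg <- seg[-(i + 1L), , drop = FALSE]
        } else i <- i + 1L
      }
      seg$kind <- kind
    } else {
      seg <- data.frame(from = integer(0), to = integer(0),
                        kind = character(0), stringsAsFactors = FALSE)
    }
    seg
  }
  seg <- rbind(segment_kind("gain"), segment_kind("loss"))
  if (is.null(seg) || nrow(seg) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0), size = integer(0),
                      kind = character(0), copy_ratio = numeric(0),
                      stringsAsFactors = FALSE)
    if (!is.null(features)) out$loci <- character(0)
    return(out)
  }

  # per-position ratio for boundary refinement
  pr_m <- mutant_profile$depth / mutant_profile$mean_depth
  pr_w <- wts_profile$depth / wts_profile$mean_depth
  pos_ratio <- ifelse(pr_w > 0, pr_m / pr_w, NA_real_)
  refine <- function(p, mid, is_gain, step) {
    inside <- function(r) !is.na(r) && (if (is_gain) r >= mid else r <= mid)
    if (inside(pos_ratio[p])) {
      while (p + step >= 1L && p + step <= L && inside(pos_ratio[p + step]))
        p <- p + step
    } else {
      while (p - step >= 1L && p - step <= L && !inside(pos_ratio[p]))
        p <- p - step
    }
    p
  }

  out <- lapply(seq_len(nrow(seg)), function(i) {
    is_gain <- seg$kind[i] == "gain"
    mid <- if (is_gain) (gain_min + 1) / 2 else (loss_max + 1) / 2
    p1 <- (seg$from[i] - 1L) * w + 1L
    p2 <- min(L, seg$to[i] * w)
    p1 <- refine(p1, mid, is_gain, -1L)
    p2 <- refine(p2, mid, is_gain, +1L)
    data.frame(start = p1, end = p2, size = p2 - p1 + 1L,
               kind = seg$kind[i],
               copy_ratio = stats::median(ratio[seg$from[i]:seg$to[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(features))
    out$loci <- vapply(seq_len(nrow(out)), function(i)
      paste(overlap_loci(out$start[i], out$end[i], features), collapse = ","),
      character(1))
  rownames(out) <- NULL
  out
}

#' Locus tags overlapped by an interval
#'
#' Returns, in genomic order, the locus tags of features whose 1-based
#' inclusive interval intersects `[start, end]`. Touching intervals
#' (`end + 1 == feature start`) do not overlap.
#'
#' @param start,end 1-based inclusive interval bounds.
#' @param features feature data frame with `locus_tag`, `start`, `end`.
#' @return character vector of locus tags.
#' @export
overlap_loci <- function(start, end, features) {
  hit <- features$start <= end & features$end >= start
  f <- features[hit, , drop = FALSE]
  f$locus_tag[order(f$start)]
}
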
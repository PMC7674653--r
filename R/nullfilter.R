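#' Calibrated empirical-null filter thresholds
#'
#' Holds the two filter parameters of the wild-type-calibrated variant
#' filter: the minimum relative coverage (site depth as a proportion of
#' the strain's genome mean depth) and the minimum population fraction
#' (alternate-allele read fraction). The defaults 0.259 and 0.308 are the
#' published values calibrated from wild-type self-resequencing false
#' positives of a *C. beijerinckii* NRRL B-598 run.
#'
#' @param rel_cov_min minimum relative coverage, in `[0, 1)`; a call must
#'   exceed it strictly ("more than").
#' @param pop_fraction_min minimum alternate-allele fraction, in `(0, 1]`;
#'   a call must reach it ("at least").
#' @return a list of class `calibrated_thresholds`.
#' @export
calibrated_thresholds <- function(rel_cov_min = 0.259,
                                  pop_fraction_min = 0.308) {
  stopifnot(rel_cov_min >= 0, rel_cov_min < 1,
            pop_fraction_min > 0, pop_fraction_min <= 1)
  structure(list(rel_cov_min = rel_cov_min,
                 pop_fraction_min = pop_fraction_min),
            class = "calibrated_thresholds")
}

#' @export
print.calibrated_thresholds <- function(x, ...) {
  cat(sprintf("<calibrated_thresholds> rel_cov_min > %.3f, pop_fraction_min >= %.3f\n",
              x$rel_cov_min, x$pop_fraction_min))
  invisible(x)
}

#' Calibrate filter thresholds from wild-type self-resequencing calls
#'
#' Calls obtained by running the caller on wild-type reads against the
#' wild-type's own reference are false positives by construction. The
#' relative-coverage threshold is set to the highest relative coverage
#' observed among those false calls, and the population-fraction threshold
#' to their highest alternate-allele fraction, so that every calibration
#' false positive itself fails the filter. With no false calls the
#' fallback (by default the published 0.259 / 0.308 pair) is returned
#' unchanged.
#'
#' @param wts_self_calls variant-call data frame from [call_variants()]
#'   run on wild-type reads versus the wild-type reference.
#' @param fallback a [calibrated_thresholds()] used when no false calls
#'   are available.
#' @return a [calibrated_thresholds()].
#' @export
calibrate_thresholds <- function(wts_self_calls,
                                 fallback = calibrated_thresholds()) {
  stopifnot(inherits(fallback, "calibrated_thresholds"))
  if (is.null(wts_self_calls) || nrow(wts_self_calls) == 0L) return(fallback)
  calibrated_thresholds(
    rel_cov_min = max(wts_self_calls$rel_coverage),
    pop_fraction_min = max(wts_self_calls$alt_fraction))
}

#' Subtract variants shared with the wild-type strain
#'
#' A mutant call is marked `shared_with_wt` when the wild-type call set
#' (made against the same reference) contains a call with the identical
#' position, reference allele and alternate allele. Matching is
#' allele-exact: a different alternate allele at the same position is not
#' shared.
#'
#' @param mutant_calls,wts_calls variant-call data frames against the same
#'   reference.
#' @return `mutant_calls` with `filter_status` set to `shared_with_wt`
#'   where matched.
#' @export
subtract_shared <- function(mutant_calls, wts_calls) {
  if (nrow(mutant_calls) == 0L) return(mutant_calls)
  key <- function(x) paste(x$position, x$ref, x$alt)
  shared <- key(mutant_calls) %in% if (nrow(wts_calls)) key(wts_calls) else character(0)
  mutant_calls$filter_status[shared] <- "shared_with_wt"
  mutant_calls
}

#' Apply calibrated thresholds to variant calls
#'
#' For every call not already marked `shared_with_wt`: the call fails as
#' `low_relcov` unless its relative coverage strictly exceeds
#' `rel_cov_min` ("covered by more than ..."), then fails as
#' `low_fraction` unless its alternate-allele fraction reaches
#' `pop_fraction_min` ("called in at least ..."); otherwise it passes.
#' SNVs and short indels are filtered identically.
#'
#' @param calls variant-call data frame carrying `rel_coverage` and
#'   `alt_fraction` (shared calls already marked by [subtract_shared()]).
#' @param thresholds a [calibrated_thresholds()].
#' @return the calls with final `filter_status` in
#'   `pass`/`shared_with_wt`/`low_relcov`/`low_fraction`.
#' @export
apply_thresholds <- function(calls, thresholds = calibrated_thresholds()) {
  stopifnot(inherits(thresholds, "calibrated_thresholds"))
  if (nrow(calls) == 0L) return(calls)
  todo <- calls$filter_status != "shared_with_wt"
  status <- ifelse(calls$rel_coverage <= thresholds$rel_cov_min, "low_relcov",
            ifelse(calls$alt_fraction < thresholds$pop_fraction_min,
                   "low_fraction", "pass"))
  calls$filter_status[todo] <- status[todo]
  calls
}
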
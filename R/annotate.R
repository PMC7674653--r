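#' Locate a variant position among non-overlapping features
#'
#' @param position 1-based reference position.
#' @param features feature data frame (non-overlapping intervals).
#' @return the row index of the containing feature, or `NA` for
#'   intergenic positions.
#' @export
locate_variant <- function(position, features) {
  hit <- which(features$start <= position & features$end >= position)
  if (length(hit) > 1L)
    stop_fmt("position %d is contained in %d overlapping features",
             position, length(hit))
  if (length(hit) == 0L) NA_integer_ else hit
}

#' Codon coordinates of a position inside a coding feature
#'
#' For a plus-strand feature the codon index is
#' `floor((position - start) / 3)` with offset `(position - start) %% 3`;
#' for a minus-strand feature the frame runs from the feature end:
#' `floor((end - position) / 3)` and `(end - position) %% 3`.
#'
#' @param feature one row of a feature data frame (`cds` or `pseudogene`).
#' @param position 1-based reference position inside the feature.
#' @return list with `codon_index` (0-based) and `offset` (0-2 within the
#'   codon, in coding orientation).
#' @export
codon_context <- function(feature, position) {
  if (position < feature$start || position > feature$end)
    stop_fmt("position %d outside feature %s [%d, %d]", position,
             feature$locus_tag, feature$start, feature$end)
  if (feature$strand == "+") {
    d <- position - feature$start
  } else {
    d <- feature$end - position
  }
  list(codon_index = d %/% 3L, offset = d %% 3L)
}

translate_codon <- function(codon) {
  code <- Biostrings::getGeneticCode("11")
  unname(code[codon])
}

#' Classify the coding effect of a single variant
#'
#' Intergenic variants and variants in rRNA/tRNA features receive no amino
#' acids. SNPs inside CDS or pseudogene features are translated with the
#' bacterial/archaeal genetic code (table 11, stop written `*`): the
#' affected codon is extracted in coding orientation (reverse-complemented
#' for minus-strand features), the alternate base substituted, and both
#' codons translated. Indels are `frameshift` when the length difference
#' is not a multiple of three, otherwise `inframe_indel`; their amino-acid
#' fields stay empty. Pseudogenes are annotated as if coding, with the
#' frame taken from the annotated interval.
#'
#' @param variant one row of a variant-call data frame.
#' @param feature_row containing feature row index from [locate_variant()]
#'   (`NA` for intergenic).
#' @param features feature data frame.
#' @param genome a [genome_record()] (must match the variant coordinates).
#' @return a one-row data frame with `locus_tag`, `product`,
#'   `feature_kind`, `feature_start`, `feature_end`, `feature_strand`,
#'   `codon_index`, `aa_ref`, `aa_alt` and `effect`.
#' @export
classify_effect <- function(variant, feature_row, features, genome) {
  blank <- data.frame(locus_tag = "", product = "", feature_kind = "intergenic",
                      feature_start = NA_integer_, feature_end = NA_integer_,
                      feature_strand = "", codon_index = NA_integer_,
                      aa_ref = "", aa_alt = "", effect = "intergenic",
                      stringsAsFactors = FALSE)
  p <- variant$position
  ref_here <- substr(genome$sequence, p, p + nchar(variant$ref) - 1L)
  if (ref_here != variant$ref)
    stop_fmt("variant ref '%s' at %d disagrees with reference '%s'",
             variant$ref, p, ref_here)
  if (is.na(feature_row)) return(blank)
  ft <- features[feature_row, , drop = FALSE]
  out <- blank
  out$locus_tag <- ft$locus_tag
  out$product <- ft$product
  out$feature_kind <- ft$feature_kind
  out$feature_start <- ft$start
  out$feature_end <- ft$end
  out$feature_strand <- ft$strand
  is_indel <- nchar(variant$ref) != nchar(variant$alt)
  if (ft$feature_kind %in% c("rrna", "trna")) {
    out$effect <- "non_coding_gene"
    return(out)
  }
  if (is_indel) {
    out$effect <- if ((nchar(variant$ref) - nchar(variant$alt)) %% 3L != 0L)
      "frameshift" else "inframe_indel"
    return(out)
  }
  cc <- codon_context(ft, p)
  out$codon_index <- cc$codon_index
  if (ft$strand == "+") {
    c_start <- ft$start + 3L * cc$codon_index
    codon <- substr(genome$sequence, c_start, c_start + 2L)
    alt_codon <- codon
    substr(alt_codon, cc$offset + 1L, cc$offset + 1L) <- variant$alt
  } else {
    c_end <- ft$end - 3L * cc$codon_index
    codon <- revcomp(substr(genome$sequence, c_end - 2L, c_end))
    alt_codon <- codon
    substr(alt_codon, cc$offset + 1L, cc$offset + 1L) <- revcomp(variant$alt)
  }
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  out$aa_ref <- aa_ref
  out$aa_alt <- aa_alt
  out$effect <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  out
}

#' Annotate a set of variant calls against gene features
#'
#' Assigns each call to its containing feature (or intergenic space) and
#' classifies its coding effect with [classify_effect()].
#'
#' @param calls variant-call data frame.
#' @param features feature data frame (non-overlapping).
#' @param genome a [genome_record()].
#' @return the calls with annotation columns appended.
#' @export
annotate_variants <- function(calls, features, genome) {
  if (nrow(calls) == 0L) {
    ann0 <- data.frame(
      locus_tag = character(0), product = character(0),
      feature_kind = character(0), feature_start = integer(0),
      feature_end = integer(0), feature_strand = character(0),
      codon_index = integer(0), aa_ref = character(0),
      aa_alt = character(0), effect = character(0),
      stringsAsFactors = FALSE)
    return(cbind(calls, ann0))
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, , drop = FALSE]
    classify_effect(v, locate_variant(v$position, features), features, genome)
  }))
  out <- cbind(calls, ann)
  rownames(out) <- NULL
  out
}
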
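#' Default pipeline configuration
#'
#' All module parameters with their documented defaults, serialisable to
#' YAML with [write_config()] / [read_config()].
#'
#' @param ... named overrides of nested defaults, e.g.
#'   `reads = list(mean_coverage = 120)`.
#' @return a nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(length = 100000L, gc_fraction = 0.35, n_genes = 30L,
                  mean_gene_length = 900L),
    reads = list(mean_coverage = 150, read_length = 150L,
                 insert_mean = 300L, insert_sd = 50, error_rate = 0.005,
                 mean_quality = 35, quality_sd = 3),
    trim = list(window = 4L, min_window_quality = 15, min_length = 36L),
    map = list(k = 21L, max_mismatches = 6L),
    call = list(min_depth = 10L, min_alt_count = 3L, min_alt_fraction = 0.10),
    filter = list(rel_cov_min = 0.259, pop_fraction_min = 0.308),
    cnv = list(window = 100L, gain_min = 1.75, loss_max = 0.25,
               min_windows = 5L, fine_window = 25L, fine_min_windows = 4L),
    distance = "binary",
    mutants = list())
  over <- list(...)
  groups <- c("genome", "reads", "trim", "map", "call", "filter", "cnv")
  for (nm in names(over)) {
    if (nm %in% groups && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `path` invisibly (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Draw non-overlapping mutation specifications for a simulated strain
#'
#' Places SNPs, short (1-3 base) indels and optionally one tandem
#' duplication and one segment deletion at positions separated by at
#' least `min_gap` bases and away from the genome ends, so the events do
#' not interact during read mapping.
#'
#' @param genome a [genome_record()].
#' @param n_snp,n_ins,n_del counts of SNPs, insertions, deletions.
#' @param dup_size,del_size sizes of the tandem duplication and segment
#'   deletion (0 = none).
#' @param min_gap minimum distance between events.
#' @param margin distance kept free at both genome ends.
#' @param seed integer seed.
#' @return a specification data frame for [inject_mutations()].
#' @export
random_truth_specs <- function(genome, n_snp = 15L, n_ins = 1L, n_del = 1L,
                               dup_size = 8000L, del_size = 759L,
                               min_gap = 500L, margin = 2000L, seed = 1L) {
  L <- genome$length
  withr::with_seed(seed, {
    sizes <- c(if (dup_size > 0) dup_size, if (del_size > 0) del_size,
               rep(4L, n_ins + n_del), rep(1L, n_snp))
    kinds <- c(if (dup_size > 0) "duplication", if (del_size > 0) "segment_deletion",
               rep("insertion", n_ins), rep("deletion", n_del),
               rep("snp", n_snp))
    pos <- integer(0)
    taken_start <- integer(0)
    taken_end <- integer(0)
    out <- vector("list", length(kinds))
    for (i in seq_along(kinds)) {
      ok <- FALSE
      for (try in 1:1000) {
        p <- sample.int(L - 2L * margin - sizes[i], 1L) + margin
        if (all(p + sizes[i] + min_gap < taken_start |
                p > taken_end + min_gap)) { ok <- TRUE; break }
      }
      if (!ok) stop_fmt("could not place %s after 1000 draws", kinds[i])
      taken_start <- c(taken_start, p)
      taken_end <- c(taken_end, p + sizes[i] - 1L)
      base <- substr(genome$sequence, p, p)
      out[[i]] <- switch(kinds[i],
        snp = data.frame(kind = "snp", position = p, ref = base,
                         alt = sample(setdiff(BASES, base), 1L),
                         size = NA_integer_, stringsAsFactors = FALSE),
        insertion = data.frame(kind = "insertion", position = p,
                               ref = NA_character_,
                               alt = paste0(sample(BASES, sample(1:3, 1L),
                                                   replace = TRUE),
                                            collapse = ""),
                               size = NA_integer_, stringsAsFactors = FALSE),
        deletion = data.frame(kind = "deletion", position = p,
                              ref = NA_character_, alt = NA_character_,
                              size = sample(1:3, 1L), stringsAsFactors = FALSE),
        duplication = data.frame(kind = "duplication", position = p,
                                 ref = NA_character_, alt = NA_character_,
                                 size = sizes[i], stringsAsFactors = FALSE),
        segment_deletion = data.frame(kind = "segment_deletion", position = p,
                                      ref = NA_character_, alt = NA_character_,
                                      size = sizes[i], stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  })
}

process_sample <- function(pairs, reference, index, cfg) {
  trimmed <- trim_pairs(pairs, trim_policy(cfg$trim$window,
                                           cfg$trim$min_window_quality,
                                           cfg$trim$min_length))
  aln <- map_reads(trimmed, reference, k = cfg$map$k,
                   max_mismatches = cfg$map$max_mismatches, index = index)
  aln <- mark_duplicates(aln)
  profile <- coverage_profile(aln, reference$length, cfg$cnv$window)
  fine_profile <- coverage_profile(aln, reference$length, cfg$cnv$fine_window)
  pile <- build_pileup(aln, reference)
  calls <- call_variants(pile, reference, mean_depth = profile$mean_depth,
                         min_depth = cfg$call$min_depth,
                         min_alt_count = cfg$call$min_alt_count,
                         min_alt_fraction = cfg$call$min_alt_fraction)
  list(pairs_in = nrow(pairs), pairs_trimmed = nrow(trimmed),
       n_unmapped = attr(aln, "n_unmapped"),
       n_duplicates = sum(aln$is_duplicate & aln$mate == 1L),
       alignments = aln, profile = profile, fine_profile = fine_profile,
       calls = calls)
}

#' Run the full mutant-versus-wild-type pipeline on simulated strains
#'
#' Generates an annotated wild-type genome, simulates a wild-type
#' resequencing run and one run per configured mutant, then executes the
#' stage chain: trim, map, deduplicate, pileup, raw calling, threshold
#' calibration from the wild-type self-run, shared-variant subtraction,
#' threshold filtering, comparative-coverage CNV detection (default and
#' fine windows) and codon-level annotation of passing calls. Each mutant
#' entry of `config$mutants` is a list with a `name` and either explicit
#' `specs` (see [inject_mutations()]) or a `truth` drawn by
#' [random_truth_specs()].
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, FASTA/GFF3/FASTQ, VCFs,
#'   BED/TSV CNV tables and the summary are written there.
#' @return a list: `genome`, `features`, `thresholds`, `wts` (self-run
#'   results), per-mutant results (truth table, calls with final filter
#'   status, CNV calls, annotated passing calls) and a `summary` data
#'   frame of per-stage counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  gen <- generate_genome(cfg$genome$length, cfg$genome$gc_fraction,
                         cfg$genome$n_genes, cfg$genome$mean_gene_length,
                         seed = cfg$seed)
  reference <- gen$genome
  features <- gen$features
  index <- kmer_index(reference, cfg$map$k)
  sim <- function(genome, seed_offset) {
    simulate_reads(genome, mean_coverage = cfg$reads$mean_coverage,
                   read_length = cfg$reads$read_length,
                   insert_mean = cfg$reads$insert_mean,
                   insert_sd = cfg$reads$insert_sd,
                   error_rate = cfg$reads$error_rate,
                   mean_quality = cfg$reads$mean_quality,
                   quality_sd = cfg$reads$quality_sd,
                   seed = cfg$seed + seed_offset)
  }
  wts <- process_sample(sim(reference, 1000L), reference, index, cfg)
  thresholds <- calibrate_thresholds(
    wts$calls, calibrated_thresholds(cfg$filter$rel_cov_min,
                                     cfg$filter$pop_fraction_min))

  mutants <- list()
  for (i in seq_along(cfg$mutants)) {
    mspec <- cfg$mutants[[i]]
    name <- mspec$name %||% sprintf("mutant%d", i)
    specs <- if (!is.null(mspec$specs)) as.data.frame(mspec$specs)
      else do.call(random_truth_specs,
                   c(list(genome = reference), mspec$truth %||% list(),
                     list(seed = cfg$seed + i)))
    inj <- inject_mutations(reference, specs)
    res <- process_sample(sim(inj$genome, 2000L + i), reference, index, cfg)
    calls <- subtract_shared(res$calls, wts$calls)
    calls <- apply_thresholds(calls, thresholds)
    cnv <- detect_cnv(res$profile, wts$profile,
                      gain_min = cfg$cnv$gain_min, loss_max = cfg$cnv$loss_max,
                      min_windows = cfg$cnv$min_windows, features = features)
    cnv_fine <- detect_cnv(res$fine_profile, wts$fine_profile,
                           gain_min = cfg$cnv$gain_min,
                           loss_max = cfg$cnv$loss_max,
                           min_windows = cfg$cnv$fine_min_windows,
                           features = features)
    passing <- calls[calls$filter_status == "pass", , drop = FALSE]
    annotated <- annotate_variants(passing, features, reference)
    annotated$strain <- rep(name, nrow(annotated))
    mutants[[name]] <- c(res["pairs_in"], res["pairs_trimmed"],
                         res["n_unmapped"], res["n_duplicates"],
                         list(truth = inj$truth, calls = calls,
                              passing = passing, annotated = annotated,
                              cnv = cnv, cnv_fine = cnv_fine,
                              profile = res$profile,
                              mean_depth = res$profile$mean_depth))
  }

  num <- function(f) vapply(mutants, function(m) as.numeric(f(m)), numeric(1))
  summary <- data.frame(
    strain = c("WTS", names(mutants)),
    pairs_in = c(wts$pairs_in, num(function(m) m$pairs_in)),
    pairs_trimmed = c(wts$pairs_trimmed, num(function(m) m$pairs_trimmed)),
    mean_depth = round(c(wts$profile$mean_depth,
                         num(function(m) m$mean_depth)), 2),
    raw_calls = c(nrow(wts$calls), num(function(m) nrow(m$calls))),
    shared_with_wt = c(NA, num(function(m)
      sum(m$calls$filter_status == "shared_with_wt"))),
    low_relcov = c(NA, num(function(m)
      sum(m$calls$filter_status == "low_relcov"))),
    low_fraction = c(NA, num(function(m)
      sum(m$calls$filter_status == "low_fraction"))),
    passing = c(NA, num(function(m) nrow(m$passing))),
    cnv_calls = c(NA, num(function(m) nrow(m$cnv))),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL

  out <- list(genome = reference, features = features,
              thresholds = thresholds,
              wts = wts[c("calls", "profile", "pairs_in", "pairs_trimmed")],
              mutants = mutants, summary = summary, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(res$genome, file.path(out_dir, "reference.fasta"))
  if (nrow(res$features))
    write_gff3(res$features, file.path(out_dir, "reference.gff3"),
               seqid = res$genome$id)
  write_vcf(res$wts$calls, file.path(out_dir, "wts_self.vcf"),
            seqid = res$genome$id, thresholds = res$thresholds,
            ref_length = res$genome$length)
  for (name in names(res$mutants)) {
    m <- res$mutants[[name]]
    write_vcf(m$calls, file.path(out_dir, paste0(name, ".vcf")),
              seqid = res$genome$id, thresholds = res$thresholds,
              ref_length = res$genome$length)
    write_truth_tsv(m$truth, file.path(out_dir, paste0(name, "_truth.tsv")))
    if (nrow(m$cnv))
      write_bed(m$cnv, file.path(out_dir, paste0(name, "_cnv.bed")),
                seqid = res$genome$id)
    utils::write.table(m$cnv, file.path(out_dir, paste0(name, "_cnv.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
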
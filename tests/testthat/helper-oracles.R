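# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: each re-derives the expected result from first
# principles rather than sharing code with the implementation.

# direct sliding-window scan over a quality vector; returns c(from, to)
# of the surviving slice or NULL
oracle_trim <- function(q, policy) {
  n <- length(q)
  from <- 0L
  for (i in seq_len(n)) if (q[i] >= 3L) { from <- i; break }
  if (from == 0L) return(NULL)
  qs <- q[from:n]
  w <- policy$window
  if (length(qs) < w) return(NULL)
  last_ok <- 0L
  for (i in seq_len(length(qs) - w + 1L))
    if (mean(qs[i:(i + w - 1L)]) >= policy$min_window_quality) last_ok <- i
  if (last_ok == 0L) return(NULL)
  to <- last_ok + w - 1L
  if (to < policy$min_length) return(NULL)
  c(from, from + to - 1L)
}

# per-position recount of a pileup by walking every alignment base by base
oracle_pileup <- function(alignments, ref_seq) {
  L <- nchar(ref_seq)
  bases <- c("A", "C", "G", "T")
  bc <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
  del <- integer(L)
  ins <- list()
  a <- alignments[!alignments$is_duplicate & !alignments$is_ambiguous, ,
                  drop = FALSE]
  for (i in seq_len(nrow(a))) {
    ops <- regmatches(a$cigar[i], gregexpr("[MID]", a$cigar[i]))[[1]]
    lens <- as.integer(regmatches(a$cigar[i],
                                  gregexpr("[0-9]+", a$cigar[i]))[[1]])
    rp <- a$ref_start[i]
    qp <- 1L
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        for (z in seq_len(lens[k])) {
          b <- substr(a$seq[i], qp, qp)
          bc[rp, b] <- bc[rp, b] + 1L
          rp <- rp + 1L
          qp <- qp + 1L
        }
      } else if (ops[k] == "D") {
        for (z in seq_len(lens[k])) {
          del[rp] <- del[rp] + 1L
          rp <- rp + 1L
        }
      } else {
        ins[[length(ins) + 1L]] <- list(anchor = rp - 1L,
                                        seq = substr(a$seq[i], qp,
                                                     qp + lens[k] - 1L))
        qp <- qp + lens[k]
      }
    }
  }
  list(base_counts = bc, deletion_count = del,
       depth = as.integer(rowSums(bc)) + del, insertions = ins)
}

# exhaustive per-site caller: enumerates every allele at every position
# and applies the depth / count / fraction rules
oracle_calls <- function(pileup, ref_seq, min_depth, min_alt_count,
                         min_alt_fraction) {
  bases <- c("A", "C", "G", "T")
  L <- pileup$ref_length
  out <- list()
  ins <- pileup$insertion_events
  dele <- pileup$deletion_events
  for (p in seq_len(L)) {
    depth <- pileup$depth[p]
    if (depth < min_depth) next
    alleles <- list()
    refb <- substr(ref_seq, p, p)
    for (b in bases) if (b != refb && pileup$base_counts[p, b] > 0L)
      alleles[[length(alleles) + 1L]] <-
        list(ref = refb, alt = b, n = pileup$base_counts[p, b])
    if (nrow(ins)) for (k in which(ins$anchor == p))
      alleles[[length(alleles) + 1L]] <-
        list(ref = refb, alt = paste0(refb, ins$seq[k]), n = ins$count[k])
    if (nrow(dele)) for (k in which(dele$anchor == p))
      alleles[[length(alleles) + 1L]] <-
        list(ref = substr(ref_seq, p, p + dele$len[k]), alt = refb,
             n = dele$count[k])
    ok <- Filter(function(al) al$n >= min_alt_count &&
                   al$n / depth >= min_alt_fraction, alleles)
    if (length(ok) == 0L) next
    ns <- vapply(ok, function(al) al$n, 0)
    top <- ok[ns == max(ns)]
    alts <- vapply(top, function(al) al$alt, "")
    pick <- top[[order(alts)[1]]]
    out[[length(out) + 1L]] <- data.frame(
      position = p, ref = pick$ref, alt = pick$alt, alt_count = pick$n,
      depth = depth, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(0), ref = character(0), alt = character(0),
               alt_count = integer(0), depth = integer(0))
}

# full-protein translation oracle for coding SNPs: rebuild the mutant
# genome, translate reference and mutant CDS completely, and diff
oracle_snp_effect <- function(genome_seq, feature, position, alt) {
  mut <- genome_seq
  substr(mut, position, position) <- alt
  prot <- function(s) {
    cds <- substr(s, feature$start, feature$end)
    if (feature$strand == "-") cds <- clonevar::revcomp(cds)
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE)), "")[[1]]
  }
  p1 <- prot(genome_seq)
  p2 <- prot(mut)
  ci <- if (feature$strand == "+") (position - feature$start) %/% 3L
        else (feature$end - position) %/% 3L
  aa_ref <- p1[ci + 1L]
  aa_alt <- p2[ci + 1L]
  effect <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  list(codon_index = ci, aa_ref = aa_ref, aa_alt = aa_alt, effect = effect)
}

# exhaustive complete-linkage agglomeration: recompute every
# inter-cluster maximum at every step
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# random pileup object with insertion/deletion events, for caller tests
random_pileup <- function(ref_seq, seed) {
  withr::with_seed(seed, {
    L <- nchar(ref_seq)
    bases <- c("A", "C", "G", "T")
    ref_idx <- match(strsplit(ref_seq, "")[[1]], bases)
    depth_target <- sample(0:60, L, replace = TRUE)
    bc <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
    for (p in seq_len(L)) {
      alt_n <- sample(0:min(20, depth_target[p]), 1L)
      bc[p, ref_idx[p]] <- depth_target[p] - alt_n
      if (alt_n > 0) {
        b <- sample(setdiff(seq_len(4L), ref_idx[p]), 1L)
        bc[p, b] <- alt_n
      }
    }
    ref_chr <- strsplit(ref_seq, "")[[1]]
    # indel records are drawn already left-normalised (the inserted string
    # must not end with the anchor base; a deletion must not be followable
    # by an equal base), so the naive per-site oracle and the caller see
    # the same canonical encodings
    n_ins <- sample(0:3, 1L)
    ins_anchor <- sample(seq_len(L), n_ins)
    ins_seq <- vapply(ins_anchor, function(a) {
      repeat {
        s <- paste0(sample(bases, sample(1:3, 1L), replace = TRUE),
                    collapse = "")
        if (substr(s, nchar(s), nchar(s)) != ref_chr[a]) return(s)
      }
    }, "")
    ins <- data.frame(anchor = ins_anchor, seq = ins_seq,
                      count = sample(1:15, n_ins, replace = TRUE),
                      stringsAsFactors = FALSE)
    n_del <- sample(0:3, 1L)
    del_anchor <- vapply(seq_len(n_del), function(i) {
      repeat {
        a <- sample(seq_len(L - 5L), 1L)
        if (all(ref_chr[a + 1:3] != ref_chr[a])) return(a)
      }
    }, 0L)
    del <- data.frame(anchor = del_anchor,
                      len = sample(1:3, n_del, replace = TRUE),
                      count = sample(1:15, n_del, replace = TRUE))
    del_cov <- integer(L)
    for (k in seq_len(n_del)) {
      span <- (del$anchor[k] + 1L):(del$anchor[k] + del$len[k])
      del_cov[span] <- del_cov[span] + del$count[k]
    }
    structure(list(
      depth = as.integer(rowSums(bc)) + del_cov,
      base_counts = bc,
      deletion_count = del_cov,
      insertion_events = ins[rep(seq_len(nrow(ins)), ins$count),
                             c("anchor", "seq"), drop = FALSE],
      deletion_events = del[rep(seq_len(nrow(del)), del$count),
                            c("anchor", "len"), drop = FALSE],
      ref_length = L), class = "pileup")
  })
}

random_dna_str <- function(n, seed) {
  withr::with_seed(seed,
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# minimal coverage_profile object from a raw depth vector
make_profile <- function(depth, window) {
  L <- length(depth)
  win_id <- ((seq_len(L) - 1L) %/% window) + 1L
  wd <- as.vector(rowsum(depth, win_id)) / tabulate(win_id)
  structure(list(window = as.integer(window),
                 window_start = (seq_along(wd) - 1L) * window + 1L,
                 window_depth = wd, mean_depth = mean(depth),
                 depth = depth, ref_length = L),
            class = "coverage_profile")
}
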
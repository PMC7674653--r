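#' Build the gene x strain binary mutation matrix
#'
#' Cell (g, s) is 1 when strain s carries at least one passing variant in
#' locus g. Variants without a locus (intergenic / non-coding records) are
#' excluded; rows and columns are ordered by first appearance. Because the
#' matrix is built from locus-bearing variants, every row and column has
#' at least one 1.
#'
#' @param variants data frame with columns `strain` and `locus_tag`
#'   (empty/NA locus rows are dropped); e.g. the Table 3 fixture from
#'   [load_table3_variants()] or stacked [annotate_variants()] output.
#' @return an integer 0/1 matrix, genes in rows, strains in columns.
#' @export
build_binary_matrix <- function(variants) {
  v <- variants[!is.na(variants$locus_tag) & variants$locus_tag != "", ,
                drop = FALSE]
  genes <- unique(v$locus_tag)
  strains <- unique(v$strain)
  m <- matrix(0L, nrow = length(genes), ncol = length(strains),
              dimnames = list(genes, strains))
  m[cbind(match(v$locus_tag, genes), match(v$strain, strains))] <- 1L
  m
}

#' Per-gene recurrence counts
#'
#' @param m binary mutation matrix from [build_binary_matrix()].
#' @return named integer vector: for each gene, the number of strains
#'   carrying a mutation in it.
#' @export
recurrence_counts <- function(m) {
  counts <- rowSums(m)
  storage.mode(counts) <- "integer"
  counts
}

#' Number of genes mutated in at least k strains
#'
#' @param m binary mutation matrix.
#' @param k minimum number of strains.
#' @return integer count of genes.
#' @export
genes_at_least <- function(m, k) {
  sum(rowSums(m) >= k)
}

#' Binary (asymmetric binary) distance between two 0/1 vectors
#'
#' With a = both 1, b = first only, c = second only:
#' `(b + c) / (a + b + c)` — the complement of the Jaccard index. Two
#' all-zero vectors have no informative positions; their distance is
#' defined as 0 with a warning.
#'
#' @param x,y 0/1 vectors of equal length.
#' @return a proportion in `[0, 1]`.
#' @export
binary_distance <- function(x, y) {
  if (length(x) != length(y))
    stop_fmt("vectors differ in length (%d vs %d)", length(x), length(y))
  x <- x != 0
  y <- y != 0
  denom <- sum(x | y)
  if (denom == 0L) {
    warning("both vectors all-zero; binary distance defined as 0")
    return(0)
  }
  sum(xor(x, y)) / denom
}

#' Pairwise binary distance matrix over matrix rows
#'
#' @param m 0/1 matrix; distances are computed between rows.
#' @param method `"binary"` (asymmetric binary, the default) or
#'   `"matching"` (simple matching distance, the proportion of
#'   disagreeing positions).
#' @return a symmetric distance matrix with zero diagonal.
#' @export
binary_distance_matrix <- function(m, method = c("binary", "matching")) {
  method <- match.arg(method)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <- if (method == "binary")
      binary_distance(m[i, ], m[j, ])
    else mean(m[i, ] != m[j, ])
  }
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomeration with the complete-linkage update
#' `D(A U B, C) = max(D(A, C), D(B, C))`. Ties in the minimal pair are
#' broken by the lexicographically smallest pair of cluster labels (the
#' smallest member label represents a cluster), making the result fully
#' deterministic. Merge heights are non-decreasing.
#'
#' @param d symmetric distance matrix (zero diagonal) or `dist` object.
#' @return an object of class `linkage_result`: `merge` (hclust-style
#'   merge matrix), `height`, `order` (leaf ordering for heatmap
#'   rendering) and `labels`. Convert with [as.hclust.linkage_result()]
#'   for plotting.
#' @export
complete_linkage <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12))
    stop_fmt("distance matrix must be symmetric")
  n <- nrow(m)
  labels <- rownames(m) %||% as.character(seq_len(n))
  stopifnot(n >= 2L)
  # active clusters: id (hclust convention), members, representative label
  id <- -seq_len(n)
  members <- as.list(seq_len(n))
  rep_lab <- labels
  ord_list <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)
  dm <- m
  diag(dm) <- Inf
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- dm[act, act, drop = FALSE]
    best <- min(sub)
    idx <- which(sub == best, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # lexicographically smallest (label_a, label_b) among tied pairs
    la <- rep_lab[act[idx[, 1]]]
    lb <- rep_lab[act[idx[, 2]]]
    swap <- la > lb
    tmp <- la[swap]; la[swap] <- lb[swap]; lb[swap] <- tmp
    pick <- order(la, lb)[1]
    i <- act[min(idx[pick, ])]
    j <- act[max(idx[pick, ])]
    a <- id[i]; b <- id[j]
    merge[step, ] <- if (a < b) c(a, b) else c(b, a)
    height[step] <- best
    # complete-linkage update into slot i
    newd <- pmax(dm[i, ], dm[j, ])
    dm[i, ] <- newd
    dm[, i] <- newd
    dm[i, i] <- Inf
    active[j] <- FALSE
    id[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    ord_list[[i]] <- c(ord_list[[i]], ord_list[[j]])
  }
  structure(list(merge = merge, height = height,
                 order = ord_list[[which(active)]], labels = labels),
            class = "linkage_result")
}

#' Convert a linkage result to an hclust object
#'
#' @param x a [complete_linkage()] result.
#' @param ... ignored.
#' @return an object of class `hclust`.
#' @export
as.hclust.linkage_result <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 call = match.call(), dist.method = "binary"),
            class = "hclust")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> %d leaves, %d merges, max height %.3f\n",
              length(x$labels), nrow(x$merge), max(x$height)))
  invisible(x)
}

#' Bi-cluster a binary mutation matrix
#'
#' Clusters genes (rows) and strains (columns) independently by
#' binary-distance complete linkage and returns the reordered matrix with
#' both dendrograms — the ingredients of a bi-clustered mutation heatmap.
#'
#' @param m binary mutation matrix from [build_binary_matrix()].
#' @param method distance variant, see [binary_distance_matrix()].
#' @return list with `matrix` (reordered), `genes` and `strains`
#'   ([complete_linkage()] results).
#' @export
cluster_mutations <- function(m, method = "binary") {
  g <- complete_linkage(binary_distance_matrix(m, method))
  s <- complete_linkage(binary_distance_matrix(t(m), method))
  list(matrix = m[g$order, s$order, drop = FALSE], genes = g, strains = s)
}
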
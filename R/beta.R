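## Depth normalization and the beta-diversity distances: Bray-Curtis,
## Jaccard (membership), Yue-Clayton theta, Morisita-Horn, and weighted /
## unweighted UniFrac over a supplied phylogeny.

#' Rarefy a count table to equal depth
#'
#' Each sample is subsampled once, without replacement, to exactly `depth`
#' reads (seeded). Samples with fewer reads than `depth` are dropped with a
#' warning.
#'
#' @param table taxa x samples integer matrix.
#' @param depth target depth; default is the minimum column sum.
#' @param seed integer seed.
#' @return rarefied count matrix (all column sums equal `depth`).
#' @export
rarefy_counts <- function(table, depth = NULL, seed = 1L) {
  table <- check_count_table(table)
  totals <- colSums(table)
  if (is.null(depth)) depth <- min(totals)
  if (depth < 1) stop_gutenv("depth must be >= 1")
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped",
            call. = FALSE)
    table <- table[, keep, drop = FALSE]
    totals <- totals[keep]
  }
  with_seed(child_seed(seed, "rarefy"), {
    out <- table
    for (j in seq_len(ncol(table))) {
      n <- totals[j]
      if (n == depth) next
      picked <- sample.int(n, depth)  # which of the n reads survive
      cuts <- cumsum(table[, j])
      out[, j] <- tabulate(findInterval(picked - 1L, c(0, cuts),
                                        left.open = FALSE),
                           nbins = nrow(table))
    }
    storage.mode(out) <- "integer"
    out
  })
}

dm_from_fun <- function(table, f) {
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- f(table[, i], table[, j])
  }
  d
}

#' Pairwise community dissimilarity matrix
#'
#' * `braycurtis`: `sum(|x-y|) / sum(x+y)` on counts.
#' * `jaccard`: `1 - shared / union` of observed taxa (membership only).
#' * `thetayc`: `1 - sum(p q) / (sum((p-q)^2) + sum(p q))` on relative
#'   abundances (Yue & Clayton theta dissimilarity).
#' * `morisitahorn`: `1 - 2 sum(p q) / (sum(p^2) + sum(q^2))` on relative
#'   abundances.
#'
#' @param table taxa x samples matrix (>= 2 samples, positive column sums).
#' @param metric one of `"braycurtis"`, `"jaccard"`, `"thetayc"`,
#'   `"morisitahorn"`.
#' @return labelled symmetric matrix with zero diagonal.
#' @export
pairwise_distance <- function(table,
                              metric = c("braycurtis", "jaccard", "thetayc",
                                         "morisitahorn")) {
  metric <- match.arg(metric)
  table <- check_count_table(table)
  if (ncol(table) < 2) stop_gutenv("need at least 2 samples")
  if (any(colSums(table) == 0)) stop_gutenv("sample with zero total")
  P <- sweep(table, 2, colSums(table), "/")
  f <- switch(metric,
    braycurtis = function(x, y) sum(abs(x - y)) / sum(x + y),
    jaccard = function(x, y) {
      shared <- sum(x > 0 & y > 0)
      union <- sum(x > 0 | y > 0)
      1 - shared / union
    },
    thetayc = NULL, morisitahorn = NULL)
  if (metric %in% c("thetayc", "morisitahorn")) {
    f <- switch(metric,
      thetayc = function(p, q) {
        cross <- sum(p * q)
        1 - cross / (sum((p - q)^2) + cross)
      },
      morisitahorn = function(p, q) {
        1 - 2 * sum(p * q) / (sum(p^2) + sum(q^2))
      })
    return(dm_from_fun(P, f))
  }
  dm_from_fun(table, f)
}

#' UniFrac distances over a phylogenetic tree
#'
#' Unweighted: unique (symmetric-difference) branch length divided by the
#' branch length observed in either sample. Weighted (normalized variant):
#' `sum(b |p - q|) / sum(b (p + q))` over branches, where `p`, `q` are the
#' relative abundances descending from each branch.
#'
#' @param table taxa x samples matrix; every taxon must be a tip of `tree`.
#' @param tree an [ape] `phylo` object with branch lengths.
#' @param weighted logical.
#' @return labelled symmetric distance matrix.
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  table <- check_count_table(table)
  if (!inherits(tree, "phylo")) stop_gutenv("tree must be a 'phylo' object")
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing))
    stop_gutenv("taxa missing from tree: ", paste(missing, collapse = ", "))
  tree <- ape::keep.tip(tree, rownames(table))
  P <- sweep(table, 2, colSums(table), "/")
  ## Per-edge relative abundance of descendant tips, by postorder accumulation.
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  acc <- matrix(0, nrow = n_tip + n_node, ncol = ncol(P))
  acc[seq_len(n_tip), ] <- P[tree$tip.label, , drop = FALSE]
  for (e in ape::postorder(tree)) {
    acc[edge[e, 1], ] <- acc[edge[e, 1], ] + acc[edge[e, 2], ]
  }
  E <- acc[edge[, 2], , drop = FALSE]  # branch x sample descendant mass
  b <- tree$edge.length
  n <- ncol(P)
  d <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi <- E[, i]; pj <- E[, j]
    if (weighted) {
      denom <- sum(b * (pi + pj))
      d[i, j] <- d[j, i] <- if (denom > 0) sum(b * abs(pi - pj)) / denom else 0
    } else {
      oi <- pi > 0; oj <- pj > 0
      denom <- sum(b[oi | oj])
      d[i, j] <- d[j, i] <- if (denom > 0) sum(b[xor(oi, oj)]) / denom else 0
    }
  }
  d
}

#' Hellinger transform of a count table
#'
#' Square root of relative abundances, oriented samples x taxa for use as a
#' response matrix in redundancy analysis.
#'
#' @param table taxa x samples count matrix.
#' @return samples x taxa matrix of square-rooted relative abundances.
#' @export
hellinger_transform <- function(table) {
  table <- check_count_table(table)
  if (any(colSums(table) == 0)) stop_gutenv("sample with zero total")
  t(sqrt(sweep(table, 2, colSums(table), "/")))
}
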
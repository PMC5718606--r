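## Distance-based permutation tests: PERMANOVA (pseudo-F / NP-MANOVA), AMOVA
## (molecular-variance components, mothur convention), HOMOVA (Bartlett-style
## homogeneity of molecular variance) and the Mantel test, all with the
## (1 + count) / (1 + n_perm) permutation p-value estimator so p is never 0.
## Group labels are permuted freely (the crossover study design gives no
## restricted scheme); a within-participant-constrained mode is available
## through the `strata` argument.

## Sums of squares from squared distances for a label vector.
ss_components <- function(D2, groups) {
  N <- nrow(D2)
  lev <- unique(groups)
  sst <- sum(D2[upper.tri(D2)]) / N
  ssw <- 0
  ssw_g <- numeric(length(lev))
  n_g <- numeric(length(lev))
  for (k in seq_along(lev)) {
    idx <- which(groups == lev[k])
    n_g[k] <- length(idx)
    ssw_g[k] <- sum(D2[idx, idx][upper.tri(diag(n_g[k]))]) / n_g[k]
  }
  ssw <- sum(ssw_g)
  list(sst = sst, ssw = ssw, ssa = sst - ssw, ssw_g = ssw_g, n_g = n_g,
       K = length(lev), N = N)
}

check_groups <- function(d, groups, min_size = 2) {
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop_gutenv("groups length must match samples")
  tab <- table(groups)
  if (length(tab) < 2) stop_gutenv("need at least 2 groups")
  if (any(tab < min_size))
    stop_gutenv("every group needs at least ", min_size, " samples")
  groups
}

## Permutation matrix of group labels, optionally within strata.
perm_labels <- function(groups, n_perm, strata = NULL) {
  N <- length(groups)
  out <- matrix("", N, n_perm)
  if (is.null(strata)) {
    for (b in seq_len(n_perm)) out[, b] <- groups[sample.int(N)]
  } else {
    for (b in seq_len(n_perm)) {
      idx <- seq_len(N)
      for (s in unique(strata)) {
        w <- which(strata == s)
        idx[w] <- w[sample.int(length(w))]
      }
      out[, b] <- groups[idx]
    }
  }
  out
}

## Vectorized within-group SS over B permutation columns.
ssw_perms <- function(D2, perms, lev, sizes) {
  ssw <- numeric(ncol(perms))
  for (k in seq_along(lev)) {
    U <- perms == lev[k]
    storage.mode(U) <- "double"
    q <- colSums(U * (D2 %*% U))          # u' D2 u, includes diagonal (0)
    ssw <- ssw + q / (2 * sizes[k])
  }
  ssw
}

#' PERMANOVA (one-way NP-MANOVA) on a distance matrix
#'
#' Pseudo-F from among- and within-group sums of squared distances;
#' significance by free permutation of group labels.
#'
#' @param d distance matrix (square labelled matrix or `dist`).
#' @param groups group label per sample (>= 2 groups of >= 2).
#' @param n_perm number of permutations (study convention: 10000).
#' @param seed integer seed.
#' @param strata optional blocking factor restricting permutations within
#'   blocks (e.g. participant).
#' @return a `gutenv_test` with the pseudo-F statistic.
#' @export
permanova <- function(d, groups, n_perm = 10000, seed = 1L, strata = NULL) {
  d <- as_dm(d)
  groups <- check_groups(d, groups)
  D2 <- d^2
  cmp <- ss_components(D2, groups)
  fstat <- function(ssw) {
    ssa <- cmp$sst - ssw
    (ssa / (cmp$K - 1)) / (ssw / (cmp$N - cmp$K))
  }
  f_obs <- fstat(cmp$ssw)
  lev <- unique(groups)
  sizes <- vapply(lev, function(g) sum(groups == g), 0)
  with_seed(child_seed(seed, "permanova"), {
    perms <- perm_labels(groups, n_perm, strata)
    f_perm <- fstat(ssw_perms(D2, perms, lev, sizes))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    new_test_result("PERMANOVA", f_obs, p, n_perm,
                    list(ss.among = cmp$ssa, ss.within = cmp$ssw,
                         df = c(cmp$K - 1, cmp$N - cmp$K)))
  })
}

#' AMOVA (analysis of molecular variance) on a distance matrix
#'
#' Distance-based molecular-variance decomposition following the mothur
#' convention (squared distances): among- and within-group variance
#' components, the among fraction (phi statistic) and the Fs ratio, with a
#' free label-permutation p-value.
#'
#' @inheritParams permanova
#' @return a `gutenv_test`; statistic is Fs, extras carry `sigma2.among`,
#'   `sigma2.within`, `phi`.
#' @export
amova <- function(d, groups, n_perm = 10000, seed = 1L, strata = NULL) {
  d <- as_dm(d)
  groups <- check_groups(d, groups)
  D2 <- d^2
  cmp <- ss_components(D2, groups)
  N <- cmp$N; K <- cmp$K
  n_bar <- (N - sum(cmp$n_g^2) / N) / (K - 1)  # unequal-size correction
  fstat <- function(ssw) {
    ssa <- cmp$sst - ssw
    (ssa / (K - 1)) / (ssw / (N - K))
  }
  f_obs <- fstat(cmp$ssw)
  s2_within <- cmp$ssw / (N - K)
  s2_among <- (cmp$ssa / (K - 1) - s2_within) / n_bar
  phi <- s2_among / (s2_among + s2_within)
  lev <- unique(groups)
  sizes <- vapply(lev, function(g) sum(groups == g), 0)
  with_seed(child_seed(seed, "amova"), {
    perms <- perm_labels(groups, n_perm, strata)
    f_perm <- fstat(ssw_perms(D2, perms, lev, sizes))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    new_test_result("AMOVA", f_obs, p, n_perm,
                    list(sigma2.among = s2_among, sigma2.within = s2_within,
                         phi = phi))
  })
}

#' HOMOVA (homogeneity of molecular variance) on a distance matrix
#'
#' Bartlett-style statistic
#' `B = (N-K) ln(pooled within dispersion) - sum (n_g - 1) ln(group dispersion)`
#' with dispersions from mean squared within-group distances; permutation
#' p-value by free label permutation. `B >= 0` always.
#'
#' @inheritParams permanova
#' @return a `gutenv_test` with the B statistic and per-group dispersions.
#' @export
homova <- function(d, groups, n_perm = 10000, seed = 1L, strata = NULL) {
  d <- as_dm(d)
  groups <- check_groups(d, groups)
  D2 <- d^2
  lev <- unique(groups)
  sizes <- vapply(lev, function(g) sum(groups == g), 0)
  bstat_from_ssw_g <- function(ssw_g) {
    s2 <- ssw_g / (sizes - 1)
    pooled <- sum(ssw_g) / sum(sizes - 1)
    sum(sizes - 1) * log(pooled) - sum((sizes - 1) * log(s2))
  }
  ssw_g_for <- function(g) {
    vapply(seq_along(lev), function(k) {
      idx <- which(g == lev[k])
      sum(D2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }, 0)
  }
  obs_ssw_g <- ssw_g_for(groups)
  if (any(obs_ssw_g == 0)) stop_gutenv("a group has zero within-group dispersion")
  b_obs <- bstat_from_ssw_g(obs_ssw_g)
  with_seed(child_seed(seed, "homova"), {
    perms <- perm_labels(groups, n_perm, strata)
    b_perm <- apply(perms, 2, function(g) {
      sg <- ssw_g_for(g)
      if (any(sg == 0)) return(Inf)
      bstat_from_ssw_g(sg)
    })
    p <- (1 + sum(b_perm >= b_obs)) / (1 + n_perm)
    new_test_result("HOMOVA", b_obs, p, n_perm,
                    list(dispersion = obs_ssw_g / (sizes - 1),
                         group.sizes = sizes))
  })
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over strictly-upper-triangle entries, one-sided
#' (positive association) p-value by joint row/column permutation of the
#' second matrix.
#'
#' @param d1,d2 distance matrices with identical labels in identical order.
#' @param n_perm number of permutations (study convention: 9999).
#' @param seed integer seed.
#' @return a `gutenv_test` with statistic r; extras carry `r.squared`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  d1 <- as_dm(d1); d2 <- as_dm(d2)
  if (!identical(dim(d1), dim(d2))) stop_gutenv("matrix dimensions differ")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop_gutenv("distance matrices have mismatched labels")
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  r_obs <- cor(v1, d2[ut])
  N <- nrow(d1)
  with_seed(child_seed(seed, "mantel"), {
    r_perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N)
      cor(v1, d2[idx, idx][ut])
    }, 0)
    p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
    new_test_result("Mantel", r_obs, p, n_perm, list(r.squared = r_obs^2))
  })
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (delegates to [stats::p.adjust()]); validates
#' the input range. Adjusted values are always >= the raw values and
#' order-preserving.
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_gutenv("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}
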
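## Four-test differential battery: metastats-style permutation t-test with a
## Fisher-exact branch for sparse taxa, indicator-value analysis, a
## Kruskal-Wallis + log-effect screen (one-dimensional surrogate for an LDA
## score: a taxon votes "significant" only when the rank test passes AND the
## between-group log10 mean difference clears a threshold), and the AWKS
## core-shift test; plus the congruency conjunction and the
## Firmicutes:Bacteroidetes ratio series.

#' Column-wise relative abundances
#'
#' @param table taxa x samples matrix with positive column sums.
#' @return matrix whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  table <- check_count_table(table)
  tot <- colSums(table)
  if (any(tot == 0)) stop_gutenv("sample with zero total")
  sweep(table, 2, tot, "/")
}

welch_t <- function(P, inA, inB) {
  nA <- sum(inA); nB <- sum(inB)
  mA <- rowMeans(P[, inA, drop = FALSE])
  mB <- rowMeans(P[, inB, drop = FALSE])
  vA <- rowSums((P[, inA, drop = FALSE] - mA)^2) / (nA - 1)
  vB <- rowSums((P[, inB, drop = FALSE] - mB)^2) / (nB - 1)
  se <- sqrt(vA / nA + vB / nB)
  t <- (mA - mB) / se
  t[se == 0] <- 0
  t
}

#' Metastats-style differential-abundance test (two cohorts)
#'
#' Per taxon: unequal-variance (Welch) t statistic on relative abundances
#' with a two-sided label-permutation null. Taxa whose pooled count across
#' both cohorts is below `sparse_threshold` are instead tested by Fisher's
#' exact test on the pooled 2x2 table (taxon reads vs all other reads, cohort
#' A vs B). Benjamini-Hochberg q-values are computed across all taxa.
#'
#' @param counts taxa x samples count matrix.
#' @param groups two-level label per sample; both cohorts need >= 3 samples.
#' @param n_perm permutations for the t-branch.
#' @param sparse_threshold pooled-count cutoff routing a taxon to the Fisher
#'   branch (original metastats convention: 8).
#' @param seed integer seed.
#' @return data.frame: taxon, branch, statistic, p, q.
#' @export
metastats_test <- function(counts, groups, n_perm = 1000, sparse_threshold = 8,
                           seed = 1L) {
  counts <- check_count_table(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop_gutenv("metastats_test needs exactly 2 cohorts")
  if (any(table(groups) < 3)) stop_gutenv("both cohorts need >= 3 samples")
  P <- relative_abundance(counts)
  inA <- groups == lev[1]; inB <- groups == lev[2]
  totals <- rowSums(counts)
  sparse <- totals < sparse_threshold
  t_obs <- welch_t(P, inA, inB)
  n <- ncol(P)
  nA <- sum(inA)
  p <- rep(NA_real_, nrow(P))
  if (any(!sparse)) {
    cnt <- integer(nrow(P))
    with_seed(child_seed(seed, "metastats"), {
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        pa <- logical(n); pa[idx[seq_len(nA)]] <- TRUE
        t_b <- welch_t(P, pa, !pa)
        cnt <- cnt + (abs(t_b) >= abs(t_obs) - 1e-12)
      }
    })
    p[!sparse] <- ((1 + cnt) / (1 + n_perm))[!sparse]
  }
  if (any(sparse)) {
    sumA <- rowSums(counts[, inA, drop = FALSE])
    sumB <- rowSums(counts[, inB, drop = FALSE])
    totA <- sum(sumA); totB <- sum(sumB)
    for (i in which(sparse)) {
      tab <- matrix(c(sumA[i], totA - sumA[i], sumB[i], totB - sumB[i]), 2)
      p[i] <- fisher.test(tab)$p.value
    }
  }
  data.frame(taxon = rownames(P),
             branch = ifelse(sparse, "fisher", "t"),
             statistic = t_obs, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

indval_values <- function(P, groups, lev) {
  gm <- matrix(vapply(lev, function(g)
    rowMeans(P[, groups == g, drop = FALSE]), numeric(nrow(P))), nrow = nrow(P))
  occ <- matrix(vapply(lev, function(g)
    rowMeans(P[, groups == g, drop = FALSE] > 0), numeric(nrow(P))),
    nrow = nrow(P))
  A <- gm / pmax(rowSums(gm), .Machine$double.eps)
  100 * apply(A * occ, 1, max)
}

#' Indicator species (IndVal) analysis
#'
#' `IndVal = 100 * max_g (specificity A_ig * fidelity B_ig)` where `A_ig` is
#' the group mean relative abundance divided by the sum of group means and
#' `B_ig` is the within-group occupancy. One-sided permutation p-value.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param groups label per sample (>= 2 non-empty groups).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame: taxon, indval, p.
#' @export
indval_test <- function(profiles, groups, n_perm = 999, seed = 1L) {
  profiles <- as.matrix(profiles)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) stop_gutenv("need >= 2 groups")
  if (any(table(groups) == 0)) stop_gutenv("empty group")
  iv_obs <- indval_values(profiles, groups, lev)
  cnt <- integer(nrow(profiles))
  with_seed(child_seed(seed, "indval"), {
    for (b in seq_len(n_perm)) {
      iv_b <- indval_values(profiles, groups[sample.int(length(groups))], lev)
      cnt <- cnt + (iv_b >= iv_obs - 1e-12)
    }
  })
  data.frame(taxon = rownames(profiles), indval = iv_obs,
             p = (1 + cnt) / (1 + n_perm), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Kruskal-Wallis + log-effect differential screen
#'
#' Per taxon: Kruskal-Wallis H across groups (ties-corrected chi-square
#' p-value); taxa passing `alpha` are scored by the effect size
#' `max over group pairs of |log10(mean_1 + eps) - log10(mean_2 + eps)|`
#' with `eps` = half the minimum nonzero relative abundance. A taxon is
#' significant when `p < alpha` AND `effect >= effect_threshold`. Constant
#' taxa get `p = 1` by convention.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param groups label per sample.
#' @param alpha significance level for the rank test.
#' @param effect_threshold minimum log10 effect (default 0.25, about a
#'   1.8-fold mean difference).
#' @return data.frame: taxon, H, p, effect, significant.
#' @export
kw_effect_test <- function(profiles, groups, alpha = 0.05,
                           effect_threshold = 0.25) {
  profiles <- as.matrix(profiles)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop_gutenv("need >= 2 groups")
  nz <- profiles[profiles > 0]
  eps <- if (length(nz)) min(nz) / 2 else .Machine$double.eps
  lev <- levels(groups)
  res <- t(apply(profiles, 1, function(x) {
    if (length(unique(x)) == 1) return(c(H = 0, p = 1))
    kt <- kruskal.test(x, groups)
    c(H = unname(kt$statistic), p = kt$p.value)
  }))
  gm <- vapply(lev, function(g)
    rowMeans(profiles[, groups == g, drop = FALSE]), numeric(nrow(profiles)))
  gm <- matrix(gm, nrow = nrow(profiles))
  lg <- log10(gm + eps)
  pairs <- utils::combn(seq_along(lev), 2)
  effect <- apply(abs(lg[, pairs[1, ], drop = FALSE] -
                        lg[, pairs[2, ], drop = FALSE]), 1, max)
  data.frame(taxon = rownames(profiles), H = res[, "H"], p = res[, "p"],
             effect = effect,
             significant = res[, "p"] < alpha & effect >= effect_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Congruency report over the four differential tests
#'
#' A taxon is flagged congruent iff the metastats q, the IndVal p, the
#' KW-effect verdict and the AWKS (core-shift) p are all individually
#' significant at their thresholds. Tightening any threshold can only remove
#' congruent taxa.
#'
#' @param metastats output of [metastats_test()].
#' @param indval output of [indval_test()].
#' @param kw output of [kw_effect_test()].
#' @param awks output of [awks_test()] over the same taxa.
#' @param thresholds list with `q`, `indval_p`, `awks_p` (defaults 0.05).
#' @return data.frame of class `gutenv_congruency`: taxon, the four verdicts
#'   and `congruent`.
#' @export
congruency_report <- function(metastats, indval, kw, awks,
                              thresholds = list(q = 0.05, indval_p = 0.05,
                                                awks_p = 0.05)) {
  taxa <- metastats$taxon
  if (!identical(sort(taxa), sort(indval$taxon)) ||
      !identical(sort(taxa), sort(kw$taxon)) ||
      !identical(sort(taxa), sort(awks$taxon)))
    stop_gutenv("the four tests were not run on the same taxon set")
  m <- metastats[match(taxa, metastats$taxon), ]
  iv <- indval[match(taxa, indval$taxon), ]
  k <- kw[match(taxa, kw$taxon), ]
  a <- awks[match(taxa, awks$taxon), ]
  out <- data.frame(
    taxon = taxa,
    metastats_q = m$q, metastats_sig = m$q < thresholds$q,
    indval_p = iv$p, indval_sig = iv$p < thresholds$indval_p,
    kw_effect = k$effect, kw_sig = k$significant,
    awks_p = a$p, awks_sig = a$p < thresholds$awks_p,
    stringsAsFactors = FALSE, row.names = NULL)
  out$congruent <- out$metastats_sig & out$indval_sig & out$kw_sig & out$awks_sig
  class(out) <- c("gutenv_congruency", "data.frame")
  out
}

#' @export
print.gutenv_congruency <- function(x, ...) {
  hits <- x$taxon[x$congruent]
  cat(sprintf("Four-test congruency over %d taxa: %d congruent\n",
              nrow(x), length(hits)))
  if (length(hits)) cat("  ", paste(hits, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full four-test differential battery on two cohorts
#'
#' Convenience wrapper: relative abundances, [metastats_test()],
#' [indval_test()], [kw_effect_test()], [awks_test()] and
#' [congruency_report()].
#'
#' @param counts taxa x samples count matrix.
#' @param cohortA,cohortB disjoint character vectors of sample ids.
#' @param n_perm permutations for the permutation-based members.
#' @param seed integer seed.
#' @param effect_threshold passed to [kw_effect_test()].
#' @param thresholds passed to [congruency_report()].
#' @return list with the four per-test tables and the congruency report.
#' @export
differential_battery <- function(counts, cohortA, cohortB, n_perm = 1999,
                                 seed = 1L, effect_threshold = 0.25,
                                 thresholds = list(q = 0.05, indval_p = 0.05,
                                                   awks_p = 0.05)) {
  if (length(intersect(cohortA, cohortB))) stop_gutenv("cohorts overlap")
  sub <- counts[, c(cohortA, cohortB), drop = FALSE]
  groups <- rep(c("A", "B"), c(length(cohortA), length(cohortB)))
  P <- relative_abundance(sub)
  ms <- metastats_test(sub, groups, n_perm = n_perm, seed = seed)
  iv <- indval_test(P, groups, n_perm = n_perm, seed = seed)
  kw <- kw_effect_test(P, groups, effect_threshold = effect_threshold)
  aw <- awks_test(P, cohortA, cohortB, n_perm = n_perm, seed = seed)
  rep <- congruency_report(ms, iv, kw, aw, thresholds = thresholds)
  list(metastats = ms, indval = iv, kw = kw, awks = aw, congruency = rep)
}

#' Firmicutes:Bacteroidetes ratio series and per-participant rate of change
#'
#' Per sample: ratio of summed Firmicutes counts to summed Bacteroidetes
#' counts (`NA` when the Bacteroidetes sum is zero). Per (participant, arm):
#' the least-squares slope of `ln(ratio)` against day.
#'
#' @param counts taxa x samples count matrix.
#' @param taxonomy data.frame with `taxon` and `phylum` covering every taxon.
#' @param design design table with `sample_id`, `participant_id`, `arm`,
#'   `day`.
#' @return list with `per_sample` (sample_id, ratio, log_ratio) and `rates`
#'   (participant_id, arm, slope, n_points).
#' @export
fb_ratio_series <- function(counts, taxonomy, design) {
  counts <- check_count_table(counts)
  phy <- taxonomy$phylum[match(rownames(counts), taxonomy$taxon)]
  if (any(is.na(phy))) stop_gutenv("taxonomy does not cover every taxon")
  f <- colSums(counts[phy == "Firmicutes", , drop = FALSE])
  b <- colSums(counts[phy == "Bacteroidetes", , drop = FALSE])
  ratio <- ifelse(b > 0, f / b, NA_real_)
  per_sample <- data.frame(sample_id = colnames(counts), ratio = ratio,
                           log_ratio = log(ratio), stringsAsFactors = FALSE,
                           row.names = NULL)
  d <- merge(design, per_sample, by = "sample_id")
  groups <- split(d, list(d$participant_id, d$arm), drop = TRUE)
  rates <- do.call(rbind, lapply(groups, function(g) {
    g <- g[is.finite(g$log_ratio), ]
    slope <- if (nrow(g) >= 2 && length(unique(g$day)) >= 2)
      unname(coef(lm(log_ratio ~ day, data = g))[2]) else NA_real_
    data.frame(participant_id = g$participant_id[1], arm = g$arm[1],
               slope = slope, n_points = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  list(per_sample = per_sample, rates = rates)
}
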
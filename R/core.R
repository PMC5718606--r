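## Core-microbiome analysis: ubiquity curves over abundance thresholds,
## core-fraction surfaces, major/minor core classification, the
## abundance-variability plot data, and the abundance-weighted
## Kolmogorov-Smirnov (AWKS) two-cohort statistic.

#' Default abundance-threshold grid
#'
#' 30 log-spaced points spanning `1e-5` to the maximum observed relative
#' abundance.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param n number of grid points.
#' @return descending-free (ascending) numeric grid.
#' @export
abundance_grid <- function(profiles, n = 30) {
  top <- max(profiles)
  if (top <= 1e-5) top <- 1
  exp(seq(log(1e-5), log(top), length.out = n))
}

## Ubiquity of every taxon at every grid point for one cohort:
## U[taxon, k] = fraction of cohort samples with relabund >= grid[k].
ubiquity_matrix <- function(profiles, samples, grid) {
  sub <- profiles[, samples, drop = FALSE]
  u <- vapply(grid, function(a) rowMeans(sub >= a), numeric(nrow(profiles)))
  matrix(u, nrow = nrow(profiles), ncol = length(grid),
         dimnames = list(rownames(profiles), NULL))
}

#' Ubiquity curve of one taxon in one cohort
#'
#' `U(a)` = fraction of the cohort's samples in which the taxon occurs at
#' relative abundance `>= a`; non-increasing in `a`.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param samples cohort sample ids (>= 1).
#' @param taxon taxon label.
#' @param grid abundance thresholds; defaults to [abundance_grid()].
#' @return data.frame: threshold, ubiquity.
#' @export
ubiquity_curve <- function(profiles, samples, taxon, grid = NULL) {
  if (length(samples) < 1) stop_gutenv("cohort needs >= 1 sample")
  if (is.null(grid)) grid <- abundance_grid(profiles)
  if (length(grid) == 0) stop_gutenv("empty threshold grid")
  p <- profiles[taxon, samples]
  data.frame(threshold = grid,
             ubiquity = vapply(grid, function(a) mean(p >= a), 0))
}

#' Core-fraction surface
#'
#' Entry `(a, u)` is the fraction of taxa whose ubiquity at abundance
#' threshold `a` is at least `u`; non-increasing along both axes.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param samples cohort sample ids.
#' @param abundance_grid,ubiquity_grid numeric grids (non-empty).
#' @return matrix (abundance thresholds x ubiquity thresholds).
#' @export
core_fraction_surface <- function(profiles, samples,
                                  abundance_grid, ubiquity_grid) {
  if (!length(abundance_grid) || !length(ubiquity_grid))
    stop_gutenv("grids must be non-empty")
  U <- ubiquity_matrix(profiles, samples, abundance_grid)
  out <- vapply(ubiquity_grid,
                function(u) colMeans(U >= u),
                numeric(length(abundance_grid)))
  out <- matrix(out, nrow = length(abundance_grid),
                ncol = length(ubiquity_grid))
  dimnames(out) <- list(signif(abundance_grid, 4), signif(ubiquity_grid, 4))
  out
}

#' Classify taxa into major / minor cores and build plot data
#'
#' Major core: ubiquity at the major reference abundance (default `0.001`)
#' at least `0.75`. Minor core: not major, and ubiquity at the minor
#' reference abundance (default `1e-4`) at least `0.5`. The returned table
#' is the abundance-variability plot datum per taxon: cohort mean relative
#' abundance, coefficient of variation, ubiquity at the major reference
#' threshold, and the core class.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param samples cohort sample ids.
#' @param major list(a = abundance threshold, u = ubiquity cutoff).
#' @param minor list(a =, u =) for the minor core.
#' @return data.frame: taxon, mean_abundance, variability, ubiquity,
#'   core_class in {major, minor, none}.
#' @export
classify_cores <- function(profiles, samples,
                           major = list(a = 0.001, u = 0.75),
                           minor = list(a = 1e-4, u = 0.5)) {
  sub <- profiles[, samples, drop = FALSE]
  m <- rowMeans(sub)
  s <- apply(sub, 1, sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  u_major <- rowMeans(sub >= major$a)
  u_minor <- rowMeans(sub >= minor$a)
  cls <- ifelse(u_major >= major$u, "major",
                ifelse(u_minor >= minor$u, "minor", "none"))
  data.frame(taxon = rownames(profiles), mean_abundance = m, variability = cv,
             ubiquity = u_major, core_class = cls, stringsAsFactors = FALSE,
             row.names = NULL)
}

awks_stat <- function(profiles, inA, inB, grid, weights) {
  UA <- ubiquity_matrix(profiles, which(inA), grid)
  UB <- ubiquity_matrix(profiles, which(inB), grid)
  diff <- abs(UA - UB)
  if (is.null(weights)) apply(diff, 1, max)             # sup-norm variant
  else as.numeric(diff %*% weights) / sum(weights)
}

#' Abundance-weighted Kolmogorov-Smirnov (AWKS) test
#'
#' Compares the two cohorts' ubiquity curves across the abundance-threshold
#' grid, per taxon:
#' `D = sum_k w_k |U_A(a_k) - U_B(a_k)| / sum_k w_k` with weights
#' `w_k = a_k`, so differences at higher abundance weigh more. `D` lies in
#' `[0, 1]` and is 0 iff the curves coincide on the grid. The sup-norm
#' (unweighted KS-style) statistic is available via `weighting = "sup"`.
#' Significance by cohort-label permutation.
#'
#' @param profiles taxa x samples relative-abundance matrix.
#' @param cohortA,cohortB disjoint sample-id vectors (>= 3 each).
#' @param n_perm number of permutations.
#' @param grid abundance thresholds; defaults to [abundance_grid()] of the
#'   two cohorts.
#' @param weighting `"abundance"` (default) or `"sup"`.
#' @param seed integer seed.
#' @return data.frame: taxon, D, p.
#' @export
awks_test <- function(profiles, cohortA, cohortB, n_perm = 999, grid = NULL,
                      weighting = c("abundance", "sup"), seed = 1L) {
  weighting <- match.arg(weighting)
  if (length(intersect(cohortA, cohortB))) stop_gutenv("cohorts overlap")
  if (length(cohortA) < 3 || length(cohortB) < 3)
    stop_gutenv("both cohorts need >= 3 samples")
  pool <- c(cohortA, cohortB)
  sub <- profiles[, pool, drop = FALSE]
  if (is.null(grid)) grid <- abundance_grid(sub)
  w <- if (weighting == "abundance") grid else NULL
  nA <- length(cohortA)
  inA <- seq_along(pool) <= nA
  d_obs <- awks_stat(sub, inA, !inA, grid, w)
  cnt <- integer(nrow(sub))
  with_seed(child_seed(seed, "awks"), {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool))
      pa <- logical(length(pool)); pa[idx[seq_len(nA)]] <- TRUE
      d_b <- awks_stat(sub, pa, !pa, grid, w)
      cnt <- cnt + (d_b >= d_obs - 1e-12)
    }
  })
  data.frame(taxon = rownames(sub), D = d_obs, p = (1 + cnt) / (1 + n_perm),
             stringsAsFactors = FALSE, row.names = NULL)
}
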
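test_that("PERMANOVA pseudo-F matches vegan::adonis2 and separates clear clusters", {
  m <- rand_counts(n_taxa = 12, n_samples = 10, depth = 400, seed = 21)
  d <- pairwise_distance(m, "braycurtis")
  grp <- rep(c("a", "b"), each = 5)
  ours <- permanova(d, grp, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ grp, permutations = 99)
  expect_equal(ours$statistic, ad$F[1], tolerance = 1e-10)

  # two tight, well-separated clusters (10 + 10): p hits the permutation
  # floor, since re-drawing the separating split by chance is negligible
  set.seed(3)
  x <- cbind(matrix(rnorm(5 * 10, 0, 0.01), 5),
             matrix(rnorm(5 * 10, 10, 0.01), 5))
  dd <- as.matrix(dist(t(x)))
  dimnames(dd) <- list(paste0("s", 1:20), paste0("s", 1:20))
  sep <- permanova(dd, rep(c("a", "b"), each = 10), n_perm = 199, seed = 2)
  expect_equal(sep$p.value, 1 / 200)
  expect_error(permanova(dd[1:6, 1:6], c("a", "a", "a", "a", "a", "b")),
               "at least 2")
})

test_that("permutation p agrees with exhaustive enumeration on a 6-sample case", {
  set.seed(33)
  x <- matrix(rnorm(6 * 4), ncol = 6)
  x[, 1:3] <- x[, 1:3] + 0.8
  d <- as.matrix(dist(t(x)))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  grp <- rep(c("a", "b"), each = 3)
  p_exact <- enumerate_permanova_p(d, grp)
  B <- 2000
  p_hat <- permanova(d, grp, n_perm = B, seed = 5)$p.value
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_hat - p_exact), 2 * se + 2 / B)
})

test_that("AMOVA reports variance components and is invariant to within-group relabelling", {
  m <- rand_counts(n_taxa = 10, n_samples = 12, depth = 300, seed = 8)
  d <- pairwise_distance(m, "braycurtis")
  grp <- rep(c("a", "b"), each = 6)
  r1 <- amova(d, grp, n_perm = 99, seed = 3)
  # permute sample order within groups: statistic unchanged
  ord <- c(sample(1:6), sample(7:12))
  r2 <- amova(d[ord, ord], grp, n_perm = 99, seed = 3)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_true(is.finite(r1$sigma2.among) && is.finite(r1$sigma2.within))
  expect_lte(r1$phi, 1)
})

test_that("AMOVA p-values are uniform under an exchangeable null", {
  set.seed(99)
  ps <- replicate(120, {
    x <- matrix(rnorm(10 * 4), ncol = 10)
    d <- as.matrix(dist(t(x)))
    dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
    amova(d, rep(c("a", "b"), each = 5), n_perm = 99,
          seed = sample.int(1e6, 1))$p.value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("HOMOVA is non-negative, null-calibrated and detects inflated dispersion", {
  # analytic property: B >= 0 on any data (Jensen)
  for (s in 1:5) {
    m <- rand_counts(n_taxa = 8, n_samples = 10, depth = 200, seed = 40 + s)
    d <- pairwise_distance(m, "braycurtis")
    r <- homova(d, rep(c("a", "b"), each = 5), n_perm = 49, seed = s)
    expect_gte(r$statistic, -1e-10)
  }
  # one group with 4x dispersion is flagged at n = 18 per group
  set.seed(7)
  x <- cbind(matrix(rnorm(18 * 5, sd = 1), 5), matrix(rnorm(18 * 5, sd = 4), 5))
  d <- as.matrix(dist(t(x)))
  dimnames(d) <- list(paste0("s", 1:36), paste0("s", 1:36))
  r <- homova(d, rep(c("a", "b"), each = 18), n_perm = 199, seed = 2)
  expect_lt(r$p.value, 0.05)
})

test_that("Mantel reaches r = 1 on identical and affine matrices and matches vegan", {
  m <- rand_counts(n_taxa = 10, n_samples = 8, depth = 300, seed = 3)
  d1 <- pairwise_distance(m, "braycurtis")
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$statistic, 1)
  d_aff <- 0.2 + 3 * d1
  diag(d_aff) <- 0
  expect_equal(mantel_test(d1, d_aff, n_perm = 99, seed = 1)$statistic, 1,
               tolerance = 1e-12)
  d2 <- pairwise_distance(m, "morisitahorn")
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  vg <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                      permutations = 99)
  expect_equal(ours$statistic, vg$statistic, tolerance = 1e-10)
  expect_equal(ours$r.squared, ours$statistic^2)
  d3 <- d2[c(2, 1, 3:8), c(2, 1, 3:8)]
  expect_error(mantel_test(d1, d3), "labels")
})

test_that("BH adjustment is the step-up procedure with monotonicity", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), 1:50)  # order-preserving
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("stratified permutation mode runs and respects blocks", {
  m <- rand_counts(n_taxa = 10, n_samples = 12, depth = 300, seed = 12)
  d <- pairwise_distance(m, "braycurtis")
  grp <- rep(c("a", "b"), 6)
  strata <- rep(paste0("p", 1:6), each = 2)
  r <- permanova(d, grp, n_perm = 99, seed = 4, strata = strata)
  expect_true(r$p.value >= 1 / 100 && r$p.value <= 1)
})
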
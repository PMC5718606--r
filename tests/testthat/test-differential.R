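test_that("relative abundances normalize each column", {
  P <- relative_abundance(tiny_counts())
  expect_equal(unname(colSums(P)), rep(1, 3), tolerance = 1e-12)
  expect_equal(P[, 1], tiny_counts()[, 1] / sum(tiny_counts()[, 1]))
  z <- tiny_counts(); z[, 2] <- 0L
  expect_error(relative_abundance(z), "zero total")
})

test_that("metastats routes sparse taxa to the Fisher branch and flags a strong shift", {
  m <- rand_counts(n_taxa = 10, n_samples = 12, depth = 400, seed = 50)
  m["t3", ] <- 0L
  m["t3", c(1, 5, 9)] <- 1L  # 3 reads in total: below the sparse threshold
  grp <- rep(c("A", "B"), each = 6)
  res <- metastats_test(m, grp, n_perm = 99, seed = 1)
  expect_equal(res$branch[res$taxon == "t3"], "fisher")
  expect_true(all(res$branch[res$taxon != "t3"] == "t"))
  expect_true(all(res$q >= res$p, na.rm = TRUE))

  m2 <- m
  m2["t1", grp == "A"] <- m2["t1", grp == "A"] + 500L
  res2 <- metastats_test(m2, grp, n_perm = 1999, seed = 1)
  expect_lt(res2$q[res2$taxon == "t1"], 0.05)
  expect_error(metastats_test(m, rep(c("A", "B", "C"), each = 4)), "2 cohorts")
  expect_error(metastats_test(m[, 1:4], rep(c("A", "B"), each = 2)), ">= 3")
})

test_that("IndVal closed forms: perfect indicator scores 100, uniform taxon 100/K", {
  P <- matrix(0, nrow = 2, ncol = 9,
              dimnames = list(c("ind", "unif"), paste0("s", 1:9)))
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  P["ind", grp == "g2"] <- 0.4       # present in every g2 sample only
  P["unif", ] <- 0.2                 # identical everywhere
  res <- indval_test(P, grp, n_perm = 99, seed = 2)
  expect_equal(res$indval[res$taxon == "ind"], 100)
  expect_equal(res$indval[res$taxon == "unif"], 100 / 3, tolerance = 1e-10)
  expect_lt(res$p[res$taxon == "ind"], 0.05)
  expect_error(indval_test(P, rep("g1", 9)), ">= 2 groups")
})

test_that("Kruskal-Wallis H matches the hand rank formula and effects use log10 means", {
  # no ties: ranks are 1..6; H = 12/(N(N+1)) * sum n (Rbar - (N+1)/2)^2
  x <- c(1, 3, 5, 2, 4, 6)
  grp <- rep(c("a", "b"), each = 3)
  P <- matrix(x / sum(x), nrow = 1, dimnames = list("t1", paste0("s", 1:6)))
  res <- kw_effect_test(P, grp, effect_threshold = 0)
  rbar <- tapply(rank(x), grp, mean)
  H_hand <- 12 / (6 * 7) * sum(3 * (rbar - 3.5)^2)
  expect_equal(res$H, H_hand, tolerance = 1e-10)

  # ten-fold mean difference gives effect ~ 1.0 (a trace taxon keeps the
  # pseudocount far below the tested means)
  P2 <- rbind(t1 = c(rep(0.010, 6), rep(0.100, 6)),
              t2 = c(rep(0.495, 6), rep(0.450, 6)),
              t3 = rep(1e-6, 12))
  colnames(P2) <- paste0("s", 1:12)
  res2 <- kw_effect_test(P2, rep(c("a", "b"), each = 6))
  expect_equal(res2$effect[res2$taxon == "t1"], 1.0, tolerance = 0.01)
  # constant taxon: p = 1 by convention
  P3 <- rbind(t1 = rep(0.5, 6))
  colnames(P3) <- paste0("s", 1:6)
  expect_equal(kw_effect_test(P3, rep(c("a", "b"), each = 3))$p, 1)
})

test_that("congruency is a strict conjunction and monotone in thresholds", {
  mk <- function(taxa, p) data.frame(taxon = taxa, p = p)
  taxa <- c("x", "y")
  ms <- data.frame(taxon = taxa, q = c(0.01, 0.01))
  iv <- data.frame(taxon = taxa, p = c(0.01, 0.01))
  kw <- data.frame(taxon = taxa, effect = c(2, 2), significant = c(TRUE, TRUE))
  aw <- data.frame(taxon = taxa, p = c(0.01, 0.2))  # y fails one of four
  rep1 <- congruency_report(ms, iv, kw, aw)
  expect_true(rep1$congruent[rep1$taxon == "x"])
  expect_false(rep1$congruent[rep1$taxon == "y"])
  # tightening a threshold never adds a congruent taxon
  rep2 <- congruency_report(ms, iv, kw, aw,
                            thresholds = list(q = 0.005, indval_p = 0.05,
                                              awks_p = 0.05))
  expect_true(all(rep2$congruent <= rep1$congruent))
  aw_bad <- data.frame(taxon = c("x", "z"), p = c(0.01, 0.2))
  expect_error(congruency_report(ms, iv, kw, aw_bad), "same taxon set")
})

test_that("the four-test battery flags a planted enrichment end to end", {
  cfg <- generator_config(scale = 0.05, bacteroides_fold = 3, seed = 77)
  ds <- generate_dataset(cfg)
  d <- ds$design
  eff <- d$sample_id[d$arm == "HBR" & d$day %in% c(18, 21)]
  ref <- d$sample_id[d$arm == "HAmb" & d$day %in% c(18, 21)]
  bat <- differential_battery(ds$counts, eff, ref, n_perm = 1999, seed = 3)
  con <- bat$congruency
  expect_true(con$congruent[con$taxon == "Bacteroides"])
  expect_error(differential_battery(ds$counts, eff, c(ref, eff[1])),
               "overlap")
})

test_that("F:B ratio and its rate of change follow the log-linear closed form", {
  tax <- data.frame(taxon = c("f1", "f2", "b1"),
                    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"))
  design <- data.frame(sample_id = paste0("s", 1:4),
                       participant_id = "P01", arm = "HBR",
                       day = c(0, 1, 2, 3))
  # ratio doubles each day: slope of ln(ratio) vs day is ln 2
  counts <- rbind(f1 = c(10, 20, 40, 80), f2 = c(10, 20, 40, 80),
                  b1 = c(20, 20, 20, 20))
  colnames(counts) <- design$sample_id
  fb <- fb_ratio_series(counts, tax, design)
  expect_equal(fb$per_sample$ratio, c(1, 2, 4, 8))
  expect_equal(fb$rates$slope, log(2), tolerance = 1e-10)
  # zero Bacteroidetes: ratio missing, not infinite
  counts2 <- counts; counts2["b1", 2] <- 0
  fb2 <- fb_ratio_series(counts2, tax, design)
  expect_true(is.na(fb2$per_sample$ratio[2]))
  expect_error(fb_ratio_series(rbind(counts, u = 1), tax, design),
               "taxonomy")
})

test_that("F:B rate of change is centred on zero under the null generator", {
  cfg <- generator_config(scale = 0.02, bacteroides_fold = 1, seed = 31)
  ds <- generate_dataset(cfg)
  fb <- fb_ratio_series(ds$counts, ds$taxonomy, ds$design)
  expect_lt(abs(mean(fb$rates$slope, na.rm = TRUE)), 0.02)
})
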
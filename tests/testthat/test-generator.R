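test_that("crossover design has the full participant x arm x day layout", {
  d <- generate_design(generator_config(seed = 3))
  expect_equal(nrow(d), 9 * 3 * 6)
  expect_false(anyDuplicated(d[, c("participant_id", "arm", "day")]) > 0)
  expect_setequal(unique(d$arm), c("NBR", "HBR", "HAmb"))
  # week derivation
  expect_true(all(d$week[d$day < 0] == 0))
  expect_equal(unique(d$week[d$day == 3]), 1)
  expect_equal(unique(d$week[d$day == 10]), 2)
  expect_equal(unique(d$week[d$day == 18]), 3)
  expect_equal(unique(d$week[d$day == 21]), 4)

  d2 <- generate_design(generator_config(n_participants = 2, seed = 3))
  expect_equal(nrow(d2), 36)
  for (p in unique(d2$participant_id))
    expect_setequal(unique(d2$arm[d2$participant_id == p]),
                    c("NBR", "HBR", "HAmb"))
  expect_error(generator_config(n_participants = 0), "n_participants")
})

test_that("generator outputs are bit-reproducible under a fixed seed", {
  cfg <- generator_config(scale = 0.02, seed = 17)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$meta$chem, b$meta$chem)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("count tables have positive drawn depths and a truthful effect ledger", {
  cfg <- generator_config(scale = 0.02, seed = 5)
  d <- generate_design(cfg)
  cts <- generate_counts(d, cfg)
  expect_true(all(colSums(cts$counts) > 0))
  expect_equal(cts$ledger$effect_taxa, "Bacteroides")
  expect_setequal(cts$ledger$effect_samples,
                  d$sample_id[d$arm == "HBR" & d$day %in% c(18, 21)])
  expect_error(generator_config(bacteroides_fold = -1), "bacteroides_fold")
})

test_that("planted fold-2 enrichment doubles effect-taxon relabund; null fold leaves arms equal", {
  ratios <- sapply(1:15, function(s) {
    cfg <- generator_config(scale = 0.02, seed = 300 + s)
    d <- generate_design(cfg)
    cts <- generate_counts(d, cfg)
    P <- relative_abundance(cts$counts)
    eff <- d$sample_id[d$arm == "HBR" & d$day == 21]
    ctl <- d$sample_id[d$arm == "HAmb" & d$day == 21]
    mean(P["Bacteroides", eff]) / mean(P["Bacteroides", ctl])
  })
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)

  null_ratios <- sapply(1:15, function(s) {
    cfg <- generator_config(scale = 0.02, bacteroides_fold = 1, seed = 600 + s)
    d <- generate_design(cfg)
    cts <- generate_counts(d, cfg)
    P <- relative_abundance(cts$counts)
    eff <- d$sample_id[d$arm == "HBR" & d$day == 21]
    ctl <- d$sample_id[d$arm == "HAmb" & d$day == 21]
    mean(P["Bacteroides", eff]) / mean(P["Bacteroides", ctl])
  })
  expect_gt(mean(null_ratios), 0.85)
  expect_lt(mean(null_ratios), 1.15)
})

test_that("baseline community is Firmicutes/Bacteroidetes dominated", {
  tax <- baseline_taxonomy()
  expect_equal(nrow(tax), 60)
  expect_equal(length(unique(tax$phylum)), 5)
  expect_gte(sum(tax$baseline[tax$phylum %in% c("Firmicutes", "Bacteroidetes")]),
             0.8)
  expect_equal(sum(tax$baseline), 1)
})

test_that("random trees cover the taxa and reject duplicates", {
  tr <- generate_tree(c("a", "b"), seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(tr$Nnode, 1)
  taxa <- paste0("g", 1:12)
  tr2 <- generate_tree(taxa, seed = 2)
  expect_setequal(tr2$tip.label, taxa)
  expect_true(all(tr2$edge.length > 0))
  expect_identical(ape::write.tree(generate_tree(taxa, seed = 9)),
                   ape::write.tree(generate_tree(taxa, seed = 9)))
  expect_error(generate_tree(c("a", "a")), "duplicate")
})

test_that("spectra sit on the 121-point grid and scale linearly across dilutions", {
  cfg <- generator_config(n_participants = 2, seed = 4)
  d <- generate_design(cfg)[1:2, ]
  sp <- generate_spectra(d, cfg, noise_sd = 0)
  one <- sp$spectra[sp$spectra$sample_id == d$sample_id[1], ]
  expect_equal(sum(one$dilution == 10), (800 - 200) / 5 + 1)
  a10 <- one$absorbance[one$dilution == 10]
  a100 <- one$absorbance[one$dilution == 100]
  expect_equal(a100, a10 / 10, tolerance = 1e-12)
  expect_true(all(sp$tsoc > 0))
})

test_that("peak tables share a registry and support a planted shift", {
  cfg <- generator_config(n_participants = 2, seed = 8)
  d <- generate_design(cfg)
  pk <- generate_peak_tables(d, cfg)
  by_sample <- split(pk$sterol$peak_id, pk$sterol$sample_id)
  expect_true(all(vapply(by_sample, function(x) identical(x, by_sample[[1]]),
                         TRUE)))
  tot <- tapply(pk$sterol$area, pk$sterol$sample_id, sum)
  expect_true(all(tot > 0))

  pk2 <- generate_peak_tables(d, cfg, effect = list(class = "sterol",
                                                    factor = 50))
  eff <- d$sample_id[d$arm == "HBR" & d$day %in% c(18, 21)]
  first_pk <- pk2$sterol[pk2$sterol$peak_id == "sterol_pk01", ]
  expect_gt(mean(first_pk$area[first_pk$sample_id %in% eff]),
            5 * mean(first_pk$area[!first_pk$sample_id %in% eff]))
})

test_that("metadata matrices have the study widths and an honest coupling ledger", {
  cfg <- generator_config(n_participants = 3, seed = 6)
  d <- generate_design(cfg)
  m <- generate_metadata_matrices(d, cfg)
  expect_equal(ncol(m$chem), 109)
  expect_equal(ncol(m$design), 12)
  expect_equal(ncol(m$diet), 110)
  expect_equal(length(m$ledger$chem$coupled), 8)
  cfg0 <- generator_config(n_participants = 3,
                           meta_coupling = c(chem = 0, design = 0, diet = 0),
                           seed = 6)
  m0 <- generate_metadata_matrices(d, cfg0)
  expect_equal(length(m0$ledger$chem$coupled), 0)
  expect_identical(generate_metadata_matrices(d, cfg)$chem, m$chem)
})

test_that("conductivity generator plants the per-arm week-1 increases", {
  cfg <- generator_config(seed = 21)
  d <- generate_design(cfg)
  run <- generate_conductivity(d, cfg, noise_sd = 0)
  iec <- run$ledger$true_iec
  rel <- function(arm) {
    base <- mean(iec[d$sample_id[d$arm == arm & d$week == 0]])
    post <- mean(iec[d$sample_id[d$arm == arm & d$week >= 1]])
    post / base
  }
  expect_equal(rel("HBR"), 1.67, tolerance = 0.1)
  expect_equal(rel("NBR"), 1.32, tolerance = 0.1)
  expect_equal(rel("HAmb"), 1.0, tolerance = 0.1)
})

test_that("optional dropout removes design slots at roughly the configured rate", {
  cfg <- generator_config(dropout = 0.4, seed = 12)
  d <- generate_design(cfg)
  expect_lt(nrow(d), 162)
  expect_gt(nrow(d), 162 * 0.3)
})

test_that("dataset files round-trip through the plain-text writers", {
  dir <- tempfile("gutenv_ds_")
  cfg <- generator_config(n_participants = 2, scale = 0.01, seed = 2)
  ds <- generate_dataset(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "counts.tsv", "design.tsv", "tree.nwk", "spectra.tsv", "tsoc.tsv",
    "peaks_sterol.tsv", "peaks_polyphenol.tsv", "iec_run.tsv",
    "iec_standards.tsv", "meta_chem.tsv", "meta_design.tsv", "meta_diet.tsv",
    "ledger.json")))))
  rt <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(unname(rt$counts), unname(ds$counts))
  expect_equal(rt$taxonomy$phylum, ds$taxonomy$phylum)
  unlink(dir, recursive = TRUE)
})
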
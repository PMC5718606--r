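test_that("Napierian conversion follows a = 2.303 A / l", {
  lam <- seq(200, 800, by = 5)
  zero <- napierian_spectrum(lam, rep(0, length(lam)))
  expect_true(all(zero$a == 0))
  one <- napierian_spectrum(lam, rep(1, length(lam)), path_length = 2 / 3,
                            dilution = 1)
  expect_equal(unique(one$a), 2.303 * 1 / (2 / 3), tolerance = 1e-12)
  # a * l / A is the fixed conversion constant at every point
  A <- runif(length(lam), 0.01, 2)
  nap <- napierian_spectrum(lam, A, path_length = 0.5, dilution = 1)
  expect_equal(nap$a * 0.5 / A, rep(2.303, length(lam)), tolerance = 1e-12)
  expect_error(napierian_spectrum(lam, A, path_length = 0), "path_length")
})

test_that("dilution selection picks the least-diluted in-range spectrum", {
  lam <- seq(200, 800, by = 5)
  mk <- function(d, peak) data.frame(
    dilution = d, wavelength_nm = lam,
    absorbance = peak * exp(-(lam - 300)^2 / (2 * 40^2)))
  sp <- rbind(mk(10, 2.1), mk(50, 0.6), mk(100, 0.2))
  expect_equal(attr(select_dilution(sp), "dilution"), 50)
  expect_equal(attr(select_dilution(mk(50, 0.6)), "dilution"), 50)
  sp_bad <- rbind(mk(10, 8), mk(50, 4), mk(100, 2))
  expect_warning(ch <- select_dilution(sp_bad), "nearest")
  expect_equal(attr(ch, "dilution"), 100)
  expect_error(select_dilution(sp[0, ]), "no spectra")
})

test_that("TDLP9 model returns its intercept at unit coefficients and is monotone", {
  expect_equal(log(tdlp9_model(1, 1, 1)), 2.909, tolerance = 1e-12)
  base <- tdlp9_model(2, 3, 4)
  expect_gt(tdlp9_model(2, 3, 4.5), base)  # positive a(295) coefficient
  expect_lt(tdlp9_model(2.5, 3, 4), base)  # negative a(350) coefficient
  expect_lt(tdlp9_model(2, 3.5, 4), base)  # negative a(275) coefficient
  expect_true(is.na(tdlp9_model(0, 1, 1)))
})

test_that("flat spectra give unit indole ratios and TSOC homogeneity holds", {
  fs <- flat_spectrum(a_level = 1)
  di <- dom_indices(fs$wavelength_nm, fs$absorbance, tsoc = 10)
  expect_equal(di$indole_217_365, 1, tolerance = 1e-12)
  expect_equal(di$indole_287_365, 1, tolerance = 1e-12)
  expect_equal(log(di$tdlp9), 2.909, tolerance = 1e-9)
  di2 <- dom_indices(fs$wavelength_nm, fs$absorbance, tsoc = 20)
  expect_equal(di2$suva, di$suva / 2)
  expect_equal(di2$svia, di$svia / 2)
  expect_equal(di2$cdom, di$cdom / 2)
  expect_equal(di2$indole_217_365, di$indole_217_365)
  expect_equal(di2$tdlp9, di$tdlp9)
})

test_that("index computation commutes with dilution correction", {
  lam <- seq(200, 800, by = 5)
  A_undiluted <- 0.8 * exp(-0.01 * (lam - 200)) + 0.05
  diluted <- dom_indices(lam, A_undiluted / 50, tsoc = 5, dilution = 50)
  direct <- dom_indices(lam, A_undiluted, tsoc = 5, dilution = 1)
  expect_equal(diluted, direct, tolerance = 1e-10)
})

test_that("undefined indices propagate as NA, not zero", {
  lam <- seq(200, 800, by = 5)
  A <- rep(1, length(lam))
  A[lam >= 350] <- -0.01  # non-positive absorption at 350/365
  di <- dom_indices(lam, A, tsoc = 10)
  expect_true(is.na(di$indole_217_365))
  expect_true(is.na(di$cdom))
  expect_true(is.na(di$tdlp9))
  expect_false(is.na(di$suva))
})

test_that("ground-truth DOM parameters are recovered from noise-free spectra", {
  cfg <- generator_config(n_participants = 2, seed = 31)
  d <- generate_design(cfg)[1:3, ]
  sp <- generate_spectra(d, cfg, noise_sd = 0)
  tab <- dom_indices_table(sp$spectra, sp$tsoc, path_length = sp$path_length)
  for (i in seq_len(nrow(tab))) {
    tru <- sp$ledger[[tab$sample_id[i]]]
    lam <- seq(200, 800, by = 5)
    a_true <- tru$a0 * exp(-tru$S * (lam - 275)) +
      tru$band * exp(-(lam - 280)^2 / (2 * 15^2))
    a_at <- function(w) approx(lam, a_true, w)$y
    expect_equal(tab$cdom[i], a_at(350) / tru$tsoc, tolerance = 1e-6)
    expect_equal(tab$indole_217_365[i], a_at(217) / a_at(365),
                 tolerance = 1e-6)
    expect_equal(tab$tdlp9[i],
                 tdlp9_model(a_at(350), a_at(275), a_at(295)),
                 tolerance = 1e-6)
  }
})

test_that("conductivity calibration inverts the instrument line and flags drift", {
  std <- expand.grid(level = c("a", "b", "c"), replicate = 1:3, batch = 1:2)
  std$nominal <- c(a = 100, b = 10, c = 1)[std$level]
  # perfect instrument
  std$measured <- std$nominal
  smp <- data.frame(sample_id = paste0("s", 1:4), reading = c(2, 4, 6, 8),
                    batch = c(1, 1, 2, 2))
  cal <- calibrate_conductivity(smp, std)
  expect_equal(cal$iec$iec, smp$reading, tolerance = 1e-10)
  expect_false(cal$drift_flag)
  expect_equal(cal$fit$r.squared, 1)
  # gain-2 instrument: calibrated values are readings / 2
  std2 <- std
  std2$measured <- 2 * std2$nominal
  cal2 <- calibrate_conductivity(smp, std2)
  expect_equal(cal2$iec$iec, smp$reading / 2, tolerance = 1e-10)
  # 10% high standards in the last batch raise the drift flag
  std3 <- std
  std3$measured <- std3$nominal * ifelse(std3$batch == 2, 1.1, 1)
  cal3 <- calibrate_conductivity(smp, std3)
  expect_true(cal3$drift_flag)
  expect_true(all(cal3$drift$flagged))
  # a sloppy standard curve triggers the goodness-of-fit warning
  std4 <- std
  set.seed(1)
  std4$measured <- std4$nominal * exp(rnorm(nrow(std4), 0, 0.6))
  expect_warning(calibrate_conductivity(smp, std4), "R\\^2")
  expect_error(calibrate_conductivity(smp, std[std$level == "a", ]),
               "standard levels")
})

test_that("fingerprint profiles normalize areas and preserve totals", {
  fp <- fingerprint_profile(c(1, 1, 2))
  expect_equal(fp$total, 4)
  expect_equal(fp$profile, c(0.25, 0.25, 0.5))
  expect_equal(fingerprint_profile(5)$profile, 1)
  fp10 <- fingerprint_profile(c(10, 10, 20))
  expect_equal(fp10$profile, fp$profile)
  expect_equal(fp10$total, 10 * fp$total)
  expect_error(fingerprint_profile(c(0, 0)), "all-zero")
  expect_error(fingerprint_profile(c(-1, 2)), "non-negative")
})
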
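## Intestinal-environment chemistry: Napierian conversion of microtiter
## absorbance spectra, the five chromophoric-DOM indices, electrical
## conductivity calibration against KCl standards, and chemical fingerprint
## profiles from HPLC peak tables.

#' Convert an absorbance spectrum to Napierian absorption coefficients
#'
#' `a(lambda) = 2.303 * A(lambda) / l`, with `l` the optical path length in
#' cm, optionally corrected back to the undiluted supernatant by multiplying
#' with the dilution factor.
#'
#' @param wavelength_nm,absorbance numeric vectors of equal length.
#' @param path_length optical path in cm (default 2/3, a 200 uL well).
#' @param dilution dilution factor of the measured aliquot.
#' @param dilution_correct multiply by `dilution` to recover the undiluted
#'   coefficient.
#' @return data.frame with `wavelength_nm` and `a` (per cm).
#' @export
napierian_spectrum <- function(wavelength_nm, absorbance, path_length = 2 / 3,
                               dilution = 1, dilution_correct = TRUE) {
  if (path_length <= 0) stop_gutenv("path_length must be positive")
  if (length(wavelength_nm) != length(absorbance))
    stop_gutenv("wavelength and absorbance lengths differ")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop_gutenv("wavelengths must be strictly increasing")
  a <- 2.303 * absorbance / path_length
  if (dilution_correct) a <- a * dilution
  data.frame(wavelength_nm = wavelength_nm, a = a)
}

#' Select the working dilution for a sample's spectra
#'
#' Returns the least-diluted spectrum whose maximum absorbance over the
#' 217-420 nm index window lies within `[lo, hi]` (photometrically reliable
#' range); if none qualifies, the spectrum closest to the range boundary is
#' returned with a warning.
#'
#' @param spectra data.frame with columns `dilution`, `wavelength_nm`,
#'   `absorbance` for one sample (one or more dilutions).
#' @param lo,hi acceptance window for the maximum absorbance.
#' @return the chosen subset of `spectra` (single dilution), with the chosen
#'   factor in attribute `"dilution"`.
#' @export
select_dilution <- function(spectra, lo = 0.05, hi = 1.0) {
  if (nrow(spectra) == 0) stop_gutenv("no spectra supplied")
  dils <- sort(unique(spectra$dilution))
  peak <- vapply(dils, function(d) {
    s <- spectra[spectra$dilution == d, ]
    max(s$absorbance[s$wavelength_nm >= 217 & s$wavelength_nm <= 420])
  }, 0)
  ok <- peak >= lo & peak <= hi
  if (any(ok)) {
    chosen <- dils[ok][1]  # dils ascending: least-diluted qualifying first
  } else {
    dist <- pmax(lo - peak, peak - hi, 0)
    chosen <- dils[which.min(dist)]
    warning("no dilution inside absorbance range [", lo, ", ", hi,
            "]; using nearest (1:", chosen, ")", call. = FALSE)
  }
  out <- spectra[spectra$dilution == chosen, ]
  attr(out, "dilution") <- chosen
  out
}

#' TDLP9 lignin-phenol spectral model
#'
#' Estimated sum of nine p-hydroxy, vanillyl and syringyl lignin phenols from
#' Napierian absorption coefficients:
#' `ln(TDLP9) = -2.282 ln a(350) - 8.209 ln a(275) + 11.365 ln a(295) + 2.909`.
#'
#' @param a350,a275,a295 absorption coefficients (per cm basis as produced by
#'   [napierian_spectrum()]); must be positive.
#' @return TDLP9 on the model's natural scale (`NA` if any input is
#'   non-positive).
#' @export
tdlp9_model <- function(a350, a275, a295) {
  bad <- !is.finite(a350) | !is.finite(a275) | !is.finite(a295) |
    a350 <= 0 | a275 <= 0 | a295 <= 0
  out <- rep(NA_real_, max(length(a350), length(a275), length(a295)))
  if (any(!bad))
    out[!bad] <- exp(-2.282 * log(a350[!bad]) - 8.209 * log(a275[!bad]) +
                       11.365 * log(a295[!bad]) + 2.909)
  out
}

interp_at <- function(x, y, x0) approx(x, y, xout = x0, rule = 1)$y

#' Compute the five DOM spectral indices for one spectrum
#'
#' Indices: indole ratios `a(217)/a(365)` and `a(287)/a(365)`; SUVA254
#' `A(254)/TSOC` (aromaticity); SViA420 `A(420)/TSOC` (non-aromatic DOM);
#' cDOM `a(350)/TSOC` (colored DOM); and the TDLP9 lignin-phenol model.
#' Off-grid wavelengths (217, 254, 287 nm on a 5-nm grid) are linearly
#' interpolated. Undefined indices (non-positive denominators or model
#' inputs) propagate as `NA`, never as zero.
#'
#' @param wavelength_nm,absorbance one spectrum (typically the output of
#'   [select_dilution()], already on the measured scale).
#' @param tsoc total soluble organic carbon per g dry matter (> 0).
#' @param path_length optical path in cm.
#' @param dilution dilution factor; absorbances and coefficients are
#'   corrected to the undiluted supernatant before index computation.
#' @return one-row data.frame: `indole_217_365`, `indole_287_365`, `suva`,
#'   `svia`, `cdom`, `tdlp9`.
#' @export
dom_indices <- function(wavelength_nm, absorbance, tsoc, path_length = 2 / 3,
                        dilution = 1) {
  if (tsoc <= 0) stop_gutenv("tsoc must be positive")
  A <- absorbance * dilution
  nap <- napierian_spectrum(wavelength_nm, absorbance, path_length,
                            dilution = dilution, dilution_correct = TRUE)
  aat <- function(w) interp_at(nap$wavelength_nm, nap$a, w)
  Aat <- function(w) interp_at(wavelength_nm, A, w)
  a365 <- aat(365); a350 <- aat(350); a275 <- aat(275); a295 <- aat(295)
  ## non-positive absorption at a required wavelength: undefined, never zero
  ratio <- function(num, den) if (is.na(den) || den <= 0 || is.na(num) ||
                                  num <= 0) NA_real_ else num / den
  data.frame(
    indole_217_365 = ratio(aat(217), a365),
    indole_287_365 = ratio(aat(287), a365),
    suva = ratio(Aat(254), tsoc),
    svia = ratio(Aat(420), tsoc),
    cdom = ratio(a350, tsoc),
    tdlp9 = tdlp9_model(a350, a275, a295))
}

#' DOM indices for every sample of a long-format spectra table
#'
#' Applies [select_dilution()] per sample, then [dom_indices()].
#'
#' @param spectra long data.frame: `sample_id`, `dilution`, `wavelength_nm`,
#'   `absorbance`.
#' @param tsoc named vector of TSOC values (per sample).
#' @param path_length optical path in cm.
#' @return data.frame with one row per sample (column `sample_id` plus the
#'   six indices).
#' @export
dom_indices_table <- function(spectra, tsoc, path_length = 2 / 3) {
  ids <- unique(spectra$sample_id)
  rows <- lapply(ids, function(id) {
    s <- select_dilution(spectra[spectra$sample_id == id, ])
    cbind(sample_id = id,
          dom_indices(s$wavelength_nm, s$absorbance, tsoc[[id]],
                      path_length = path_length,
                      dilution = attr(s, "dilution")))
  })
  do.call(rbind, rows)
}

#' Calibrate fecal conductivity readings against KCl standards
#'
#' Fits measured-versus-nominal conductivity of the external standard series
#' (1 M KCl and its 10-fold dilutions, triplicates, re-measured after every
#' five samples), maps sample readings through the inverted fit, reports the
#' goodness of fit (warning below R^2 = 0.99) and per-level electrode drift
#' (relative change of repeated-standard means across batches; flagged above
#' 5%).
#'
#' @param samples data.frame `sample_id`, `reading`, `batch`.
#' @param standards data.frame `level`, `nominal`, `measured`, `batch`.
#' @param drift_tolerance relative drift that raises a flag.
#' @return list of class `gutenv_iec`: `iec` (data.frame sample_id, iec),
#'   `fit` (slope, intercept, r.squared), `drift` (per level: max relative
#'   change, flag), `drift_flag`.
#' @export
calibrate_conductivity <- function(samples, standards, drift_tolerance = 0.05) {
  if (length(unique(standards$nominal)) < 2)
    stop_gutenv("need at least 2 standard levels")
  fit <- lm(measured ~ nominal, data = standards)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((standards$measured - mean(standards$measured))^2)
  if (r2 < 0.99)
    warning(sprintf("standard-curve R^2 = %.4f below 0.99", r2), call. = FALSE)
  b <- coef(fit)
  iec <- (samples$reading - b[[1]]) / b[[2]]
  per_level <- lapply(split(standards, standards$level), function(s) {
    m <- tapply(s$measured, s$batch, mean)
    ref <- m[[1]]
    max_rel <- max(abs(m - ref) / ref)
    data.frame(level = s$level[1], max_relative_drift = max_rel,
               flagged = max_rel > drift_tolerance, stringsAsFactors = FALSE)
  })
  drift <- do.call(rbind, per_level)
  rownames(drift) <- NULL
  structure(list(
    iec = data.frame(sample_id = samples$sample_id, iec = iec,
                     stringsAsFactors = FALSE),
    fit = list(slope = b[[2]], intercept = b[[1]], r.squared = r2),
    drift = drift, drift_flag = any(drift$flagged)),
    class = "gutenv_iec")
}

#' @export
print.gutenv_iec <- function(x, ...) {
  cat(sprintf("IEC calibration: slope %.4g, intercept %.4g, R^2 = %.4f\n",
              x$fit$slope, x$fit$intercept, x$fit$r.squared))
  cat(sprintf("  %d samples calibrated; electrode drift flag: %s\n",
              nrow(x$iec), x$drift_flag))
  invisible(x)
}

#' Chemical fingerprint profile of a peak table
#'
#' Total content (sum of peak areas) and the relative peak-abundance vector,
#' usable downstream exactly like a community relative-abundance vector
#' (chemical diversity).
#'
#' @param areas non-negative peak areas (named or not).
#' @return list with `total` and `profile` (sums to 1).
#' @export
fingerprint_profile <- function(areas) {
  if (any(areas < 0)) stop_gutenv("peak areas must be non-negative")
  total <- sum(areas)
  if (total == 0) stop_gutenv("all-zero peak table")
  list(total = total, profile = areas / total)
}
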
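## Thirteen-index alpha-diversity suite. Shannon uses the natural logarithm
## (mothur convention); Chao-1 is the bias-corrected form; Brillouin is
## computed through log-gamma so large counts never overflow.

ALPHA_INDEX_NAMES <- c("Taxa_S", "Individuals", "Dominance_D", "Simpson_1-D",
                       "Shannon_H", "Evenness", "Brillouin", "Menhinick",
                       "Margalef", "Equitability_J", "Fisher_alpha",
                       "Berger-Parker", "Chao-1")

#' Solve for Fisher's alpha
#'
#' Unique positive root of `S = alpha * ln(1 + N / alpha)`, found by
#' bracketed bisection and polished by Newton iterations to a residual below
#' `1e-10`.
#'
#' @param S number of observed taxa (0 < S < N).
#' @param N number of individuals.
#' @return Fisher's alpha.
#' @export
fisher_alpha_solve <- function(S, N) {
  if (S <= 0) stop_gutenv("S must be positive")
  if (S >= N) stop_gutenv("Fisher's alpha requires S < N (no finite root)")
  f <- function(a) a * log(1 + N / a) - S
  ## f is increasing in alpha; bracket the root.
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, hi)) break
  }
  a <- (lo + hi) / 2
  for (i in 1:50) {
    ## f'(a) = ln(1 + N/a) - N/(a + N)
    step <- f(a) / (log(1 + N / a) - N / (a + N))
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) break
    a <- a_new
    if (abs(f(a)) < 1e-12) break
  }
  if (abs(f(a)) > 1e-10) stop_gutenv("Fisher's alpha root did not converge")
  a
}

#' Alpha-diversity profile of one abundance vector
#'
#' Computes the thirteen ecological indices `Taxa_S`, `Individuals`,
#' `Dominance_D`, `Simpson_1-D`, `Shannon_H` (natural log), `Evenness`
#' (`exp(H)/S`), `Brillouin`, `Menhinick`, `Margalef`, `Equitability_J`,
#' `Fisher_alpha`, `Berger-Parker` and bias-corrected `Chao-1`.
#'
#' In `mode = "profile"` the vector is a relative-abundance (or chemical
#' fingerprint) profile: the count-only indices Brillouin, Chao-1 and
#' Fisher's alpha are not defined and are returned as `NA`. `Margalef` and
#' `Equitability_J` are `NA` for the degenerate cases `S = 1` or `N = 1`
#' rather than infinities.
#'
#' @param x non-negative abundance vector with positive sum.
#' @param mode `"counts"` (integers) or `"profile"` (relative abundances).
#' @return named numeric vector of the 13 indices.
#' @export
alpha_profile <- function(x, mode = c("counts", "profile")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || sum(x) <= 0) stop_gutenv("empty abundance vector")
  if (any(x < 0)) stop_gutenv("negative abundances")
  if (mode == "counts" && any(abs(x - round(x)) > 1e-8))
    stop_gutenv("counts mode requires integer abundances")
  n <- x[x > 0]
  N <- sum(n)
  S <- length(n)
  p <- n / N
  D <- sum(p^2)
  H <- -sum(p * log(p))
  out <- c(
    "Taxa_S" = S,
    "Individuals" = N,
    "Dominance_D" = D,
    "Simpson_1-D" = 1 - D,
    "Shannon_H" = H,
    "Evenness" = exp(H) / S,
    "Brillouin" = NA_real_,
    "Menhinick" = S / sqrt(N),
    "Margalef" = if (N > 1) (S - 1) / log(N) else NA_real_,
    "Equitability_J" = if (S > 1) H / log(S) else NA_real_,
    "Fisher_alpha" = NA_real_,
    "Berger-Parker" = max(n) / N,
    "Chao-1" = NA_real_)
  if (mode == "counts") {
    out["Brillouin"] <- (lgamma(N + 1) - sum(lgamma(n + 1))) / N
    F1 <- sum(n == 1)
    F2 <- sum(n == 2)
    out["Chao-1"] <- S + F1 * (F1 - 1) / (2 * (F2 + 1))
    out["Fisher_alpha"] <- if (S < N) fisher_alpha_solve(S, N) else NA_real_
  }
  out[ALPHA_INDEX_NAMES]
}

#' Alpha-diversity table for a count (or profile) matrix
#'
#' @param table taxa x samples matrix.
#' @param mode passed to [alpha_profile()].
#' @return data.frame: `sample_id` plus the 13 indices, one row per sample.
#' @export
alpha_table <- function(table, mode = c("counts", "profile")) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  res <- t(apply(table, 2, alpha_profile, mode = mode))
  data.frame(sample_id = colnames(table), res, check.names = FALSE,
             stringsAsFactors = FALSE)
}
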
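# Fixtures are built in code; nothing is read from disk.

tiny_counts <- function() {
  m <- matrix(c(
    10, 0, 4,
    5, 5, 5,
    0, 8, 1,
    2, 2, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  m
}

rand_counts <- function(n_taxa = 12, n_samples = 8, depth = 500, seed = 1) {
  set.seed(seed)
  base <- rgamma(n_taxa, 2)
  m <- sapply(seq_len(n_samples), function(j)
    rmultinom(1, depth, base * rlnorm(n_taxa, 0, 0.3))[, 1])
  dimnames(m) <- list(paste0("t", seq_len(n_taxa)),
                      paste0("s", seq_len(n_samples)))
  m
}

flat_spectrum <- function(a_level = 1, path_length = 2 / 3) {
  lambda <- seq(200, 800, by = 5)
  list(wavelength_nm = lambda,
       absorbance = rep(a_level * path_length / 2.303, length(lambda)))
}

# Exact permutation p-value for the pseudo-F of a two-group design by full
# enumeration of all group-label assignments (independent oracle).
enumerate_permanova_p <- function(d, groups) {
  d <- as.matrix(d)
  D2 <- d^2
  N <- nrow(D2)
  lev <- unique(groups)
  nA <- sum(groups == lev[1])
  fstat <- function(g) {
    sst <- sum(D2[upper.tri(D2)]) / N
    ssw <- 0
    for (l in lev) {
      idx <- which(g == l)
      ssw <- ssw + sum(D2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ((sst - ssw) / (length(lev) - 1)) / (ssw / (N - length(lev)))
  }
  f_obs <- fstat(groups)
  combos <- utils::combn(N, nA)
  f_all <- apply(combos, 2, function(ix) {
    g <- rep(lev[2], N)
    g[ix] <- lev[1]
    fstat(g)
  })
  mean(f_all >= f_obs - 1e-12)
}
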
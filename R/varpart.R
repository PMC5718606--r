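## Step-down univariate screening of explanatory metadata matrices against a
## Hellinger-transformed community, and three-matrix variation partitioning
## by redundancy analysis with Ezekiel-adjusted R^2.

## Redundancy-analysis R^2 of a (samples x taxa) response on a predictor
## matrix: proportion of total centered variance captured by the fitted
## values of the multivariate linear regression.
rda_r2 <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  fit <- qr.fitted(qx, Yc)
  list(r2 = sum(fit^2) / sum(Yc^2), rank = qx$rank)
}

adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

#' Step-down univariate screening of one metadata matrix
#'
#' Each variable is tested marginally by single-predictor redundancy
#' analysis on the (Hellinger-transformed) community matrix with a
#' row-permutation p-value; variables with `p >= alpha` are dropped. Among
#' the retained variables, while any pair correlates beyond `r_max`, the
#' member with the larger mean absolute correlation to the remaining
#' variables is removed (co-correlation pruning). Constant variables are
#' dropped with a warning.
#'
#' The alternative `mode = "probe"` implements a random-probe (shadow
#' variable) criterion: a variable is retained only when its marginal R^2
#' exceeds the association threshold of a completely random test variable,
#' estimated as the maximum marginal R^2 over `n_probes` independent
#' standard-normal probes. This removes chance-level associations that a
#' fixed per-variable level would keep (about `alpha` of a pure-noise
#' matrix).
#'
#' @param community samples x taxa response matrix (e.g.
#'   [hellinger_transform()] output), rows aligned to `x` rows.
#' @param x samples x variables metadata matrix.
#' @param n_perm marginal-test permutations (study convention: 5000).
#' @param alpha marginal significance level.
#' @param r_max co-correlation cutoff.
#' @param mode `"alpha"` (fixed level) or `"probe"`.
#' @param n_probes number of random probe variables in probe mode.
#' @param seed integer seed.
#' @return list: `retained` (column names), `table` (variable, r2, p,
#'   dropped_by).
#' @export
stepdown_screen <- function(community, x, n_perm = 5000, alpha = 0.05,
                            r_max = 0.8, mode = c("alpha", "probe"),
                            n_probes = 100, seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) != nrow(community)) stop_gutenv("matrix not aligned to community samples")
  n <- nrow(x)
  Yc <- scale(community, center = TRUE, scale = FALSE)
  sstot <- sum(Yc^2)
  const <- apply(x, 2, function(v) sd(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant variable(s) dropped", call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) == 0) return(list(retained = character(),
                                table = data.frame()))
  Xc <- scale(x, center = TRUE, scale = FALSE)
  ## Marginal R^2 of a single centered predictor: ||Y'x||^2 / (x'x * sstot).
  marg_r2 <- function(v) sum(crossprod(Yc, v)^2) / (sum(v^2) * sstot)
  r2_obs <- apply(Xc, 2, marg_r2)
  with_seed(child_seed(seed, "screen"), {
    if (mode == "alpha") {
      perm_idx <- replicate(n_perm, sample.int(n))
      p <- vapply(seq_len(ncol(Xc)), function(j) {
        Xp <- matrix(Xc[perm_idx, j], nrow = n)
        M <- crossprod(Yc, Xp)                       # taxa x n_perm
        r2_b <- colSums(M^2) / (colSums(Xp^2) * sstot)
        (1 + sum(r2_b >= r2_obs[j] - 1e-15)) / (1 + n_perm)
      }, 0)
      keep <- p < alpha
    } else {
      probes <- matrix(rnorm(n * n_probes), nrow = n)
      probes <- scale(probes, center = TRUE, scale = FALSE)
      M <- crossprod(Yc, probes)
      r2_probe <- colSums(M^2) / (colSums(probes^2) * sstot)
      thr <- max(r2_probe)
      p <- rep(NA_real_, ncol(Xc))
      keep <- r2_obs > thr
    }
  })
  tab <- data.frame(variable = colnames(x), r2 = r2_obs, p = p,
                    dropped_by = ifelse(keep, "", "marginal"),
                    stringsAsFactors = FALSE, row.names = NULL)
  retained <- colnames(x)[keep]
  ## Co-correlation pruning among survivors.
  while (length(retained) > 1) {
    cm <- abs(cor(x[, retained, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    mean_abs <- rowMeans(cm[pair, , drop = FALSE])
    drop <- pair[which.max(mean_abs)]
    tab$dropped_by[tab$variable == drop] <- "co-correlation"
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, table = tab)
}

varpart_subsets <- function(Y, mats) {
  n <- nrow(Y)
  idx <- seq_along(mats)
  subsets <- unlist(lapply(idx, function(k) utils::combn(idx, k, simplify = FALSE)),
                    recursive = FALSE)
  out <- list()
  for (s in subsets) {
    X <- do.call(cbind, mats[s])
    r <- rda_r2(Y, X)
    out[[paste(s, collapse = "")]] <- adj_r2(r$r2, n, r$rank)
  }
  out
}

#' Three-matrix variation partitioning of community variance
#'
#' Adjusted R^2 (Ezekiel correction) from redundancy analysis of the
#' (Hellinger-transformed) community on all non-empty subsets of the three
#' explanatory matrices; the seven exclusive fractions are recovered by
#' inclusion-exclusion, and the unexplained fraction is
#' `1 - adjR2(X1 u X2 u X3)`. Fractions plus the unexplained fraction sum to
#' one by construction; negative adjusted fractions are reported as-is.
#' Marginal matrix significance is assessed by row permutation of each
#' matrix alone.
#'
#' @param community samples x taxa response matrix.
#' @param x1,x2,x3 screened explanatory matrices (x3 may be `NULL` for
#'   two-way partitioning).
#' @param n_perm permutations for marginal significance.
#' @param seed integer seed.
#' @return object of class `gutenv_varpart`: `fractions` (named numeric:
#'   pure and shared fractions plus `unexplained`), `adj_r2` per subset,
#'   `marginal` (matrix, adjR2, p).
#' @export
partition_variation <- function(community, x1, x2, x3 = NULL, n_perm = 999,
                                seed = 1L) {
  Y <- as.matrix(community)
  mats <- Filter(Negate(is.null), list(x1 = x1, x2 = x2, x3 = x3))
  mats <- lapply(mats, as.matrix)
  if (any(vapply(mats, ncol, 0L) == 0)) stop_gutenv("an explanatory matrix is empty")
  if (!all(vapply(mats, nrow, 0L) == nrow(Y)))
    stop_gutenv("explanatory matrices not aligned to community samples")
  n <- nrow(Y)
  m_tot <- sum(vapply(mats, ncol, 0L))
  if (m_tot >= n - 1)
    stop_gutenv("more retained variables (", m_tot, ") than samples - 1 (",
                n - 1, "); screen more strongly")
  ar <- varpart_subsets(Y, mats)
  k <- length(mats)
  fr <- c()
  if (k == 3) {
    R123 <- ar[["123"]]
    g <- ar[["1"]] + ar[["2"]] + ar[["3"]] - ar[["12"]] - ar[["13"]] -
      ar[["23"]] + R123
    a <- R123 - ar[["23"]]
    b <- R123 - ar[["13"]]
    c3 <- R123 - ar[["12"]]
    d <- ar[["1"]] + ar[["2"]] - ar[["12"]] - g
    e <- ar[["2"]] + ar[["3"]] - ar[["23"]] - g
    f <- ar[["1"]] + ar[["3"]] - ar[["13"]] - g
    fr <- c(pure_x1 = a, pure_x2 = b, pure_x3 = c3, shared_x1x2 = d,
            shared_x2x3 = e, shared_x1x3 = f, shared_all = g,
            unexplained = 1 - R123)
  } else if (k == 2) {
    R12 <- ar[["12"]]
    d <- ar[["1"]] + ar[["2"]] - R12
    fr <- c(pure_x1 = R12 - ar[["2"]], pure_x2 = R12 - ar[["1"]],
            shared_x1x2 = d, unexplained = 1 - R12)
  } else {
    fr <- c(pure_x1 = ar[["1"]], unexplained = 1 - ar[["1"]])
  }
  marginal <- with_seed(child_seed(seed, "varpart"), {
    do.call(rbind, lapply(seq_along(mats), function(i) {
      X <- mats[[i]]
      r_obs <- rda_r2(Y, X)
      r_perm <- vapply(seq_len(n_perm), function(b)
        rda_r2(Y, X[sample.int(n), , drop = FALSE])$r2, 0)
      data.frame(matrix = names(mats)[i],
                 adj_r2 = adj_r2(r_obs$r2, n, r_obs$rank),
                 p = (1 + sum(r_perm >= r_obs$r2 - 1e-15)) / (1 + n_perm),
                 stringsAsFactors = FALSE)
    }))
  })
  structure(list(fractions = fr, adj_r2 = ar, marginal = marginal,
                 n = n, n_vars = vapply(mats, ncol, 0L)),
            class = "gutenv_varpart")
}

#' @export
print.gutenv_varpart <- function(x, ...) {
  cat("Variation partitioning (RDA, adjusted R^2):\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-12s %8.4f\n", nm, x$fractions[[nm]]))
  cat("Marginal matrix tests:\n")
  print(x$marginal, row.names = FALSE)
  invisible(x)
}
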
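## Shared internal helpers: argument checks, seed fan-out, matrix coercions.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gutenv <- function(...) stop(..., call. = FALSE)

check_count_table <- function(table) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (!is.numeric(table)) stop_gutenv("count table must be numeric")
  if (any(!is.finite(table))) stop_gutenv("count table contains non-finite values")
  if (any(table < 0)) stop_gutenv("count table contains negative values")
  if (is.null(rownames(table))) stop_gutenv("count table must have taxon rownames")
  if (is.null(colnames(table))) stop_gutenv("count table must have sample colnames")
  table
}

## Deterministic 32-bit child seed from a parent seed and a stage name, so that
## toggling one pipeline stage never shifts another stage's random stream.
child_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647L
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Coerce a square labelled matrix or a 'dist' into a validated distance matrix.
as_dm <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_gutenv("distance matrix must be square")
  if (any(!is.finite(d))) stop_gutenv("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop_gutenv("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_gutenv("distance matrix must have zero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  d
}

new_test_result <- function(method, statistic, p_value, n_perm, extra = list()) {
  stopifnot(p_value >= 1 / (n_perm + 1) - 1e-12)
  structure(
    c(list(method = method, statistic = statistic, p.value = p_value,
           n.perm = as.integer(n_perm), adjusted.p = NA_real_), extra),
    class = "gutenv_test")
}

#' @export
print.gutenv_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p.value, x$n.perm))
  if (!is.na(x$adjusted.p)) cat(sprintf("  BH-adjusted p = %.4g\n", x$adjusted.p))
  invisible(x)
}
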
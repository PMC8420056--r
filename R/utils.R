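# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
stop_param <- function(...) stop(..., call. = FALSE)

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop_param(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

#' @noRd
check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stop_param(sprintf("`%s` must lie in %s%g, %g%s", name,
                              if (open_lo) "(" else "[", lo, hi,
                              if (open_hi) ")" else "]"))
  as.numeric(x)
}

# Two-sided p from a t statistic
#' @noRd
p_from_t <- function(t, df) 2 * stats::pt(-abs(t), df = df)

# Pearson correlation p via the t transform, two-sided (df = n - 2)
#' @noRd
p_from_r <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  ifelse(abs(r) >= 1, .Machine$double.xmin, p_from_t(t, n - 2))
}

# Union-find over 1..n; returns component id per element
#' @noRd
connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}
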
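# Gene-metabolite and gene-gene networks, permutation-calibrated hub genes,
# pathway enrichment, and the printed-ratio summaries.

#' Gene-metabolite association edges (simple OLS)
#'
#' For every (metabolite, gene) pair, simple linear regression of metabolite
#' abundance on log2(x+1) gene expression over the shared lines; an edge is
#' kept iff the two-sided slope p (df = n - 2, identical to the correlation
#' test) is <= `threshold`.
#'
#' @param expression an [expr_matrix()].
#' @param metabolites a [metab_matrix()] (log scale).
#' @param threshold edge p-value threshold.
#' @return An object of class `bipartite_network`: list with `edges`
#'   (data.frame gene, metabolite, beta, p, condition), `genes` (universe of
#'   tested genes), `metabolites`, `condition`, `n_lines`.
#' @export
gene_metabolite_edges <- function(expression, metabolites, threshold = 1e-5) {
  lines <- intersect(expression$line_ids, rownames(metabolites$values))
  if (length(lines) < 4L) stop_param("fewer than 4 shared lines")
  ex <- t(log2(expression$values[, lines, drop = FALSE] + 1))
  keep <- apply(ex, 2L, stats::sd) > 0
  if (!all(keep)) warning("excluding ", sum(!keep), " constant gene(s)")
  ex <- ex[, keep, drop = FALSE]
  mt <- metabolites$values[lines, , drop = FALSE]
  n <- length(lines)
  r <- stats::cor(mt, ex)
  p <- p_from_r(r, n)
  hit <- which(p <= threshold, arr.ind = TRUE)
  beta <- r[hit] * (apply(mt, 2L, stats::sd)[hit[, 1L]] /
                      apply(ex, 2L, stats::sd)[hit[, 2L]])
  edges <- data.frame(gene = colnames(ex)[hit[, 2L]],
                      metabolite = rownames(r)[hit[, 1L]],
                      beta = as.numeric(beta), p = p[hit],
                      condition = rep(expression$condition, nrow(hit)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$p), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, genes = colnames(ex),
                 metabolites = colnames(mt),
                 condition = expression$condition, n_lines = n),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d edges (%d genes x %d metabolites tested), condition %s, n = %d\n",
              nrow(x$edges), length(x$genes), length(x$metabolites),
              x$condition, x$n_lines))
  invisible(x)
}

#' Gene-gene co-expression edges (Pearson correlation)
#'
#' Per gene pair, the two-sided p from the t transform of the correlation,
#' t = r sqrt(n-2)/sqrt(1-r^2); symmetric, no self-edges; constant genes are
#' excluded with a warning.
#'
#' @param expression an [expr_matrix()].
#' @param threshold edge p-value threshold.
#' @return data.frame with columns gene_a, gene_b, r, p, condition
#'   (gene_a < gene_b).
#' @export
coexpression_edges <- function(expression, threshold = 4.67e-9) {
  ex <- t(log2(expression$values + 1))
  keep <- apply(ex, 2L, stats::sd) > 0
  if (!all(keep)) warning("excluding ", sum(!keep), " constant gene(s)")
  ex <- ex[, keep, drop = FALSE]
  n <- nrow(ex)
  r <- stats::cor(ex)
  p <- p_from_r(r, n)
  p[!upper.tri(p)] <- Inf # self and duplicate pairs out
  hit <- which(p <= threshold, arr.ind = TRUE)
  out <- data.frame(gene_a = colnames(ex)[hit[, 1L]],
                    gene_b = colnames(ex)[hit[, 2L]],
                    r = r[hit], p = p[hit],
                    condition = rep(expression$condition, nrow(hit)),
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Permutation-derived hub-gene degree threshold
#'
#' The null keeps every edge's metabolite endpoint and reassigns its gene
#' endpoint uniformly at random over the gene universe, `n_perm` times
#' (alternatively, whole metabolites are reassigned). Per-gene degrees from
#' all permutations x genes are pooled; the threshold is the smallest degree
#' k with empirical P(degree >= k) < `alpha`, capped at the edge count.
#'
#' @param network a [gene_metabolite_edges()] result.
#' @param n_perm number of permutations.
#' @param alpha tail probability defining significance.
#' @param seed integer RNG seed.
#' @param mode `"edge"` (default; per-edge gene reassignment) or
#'   `"metabolite"` (each metabolite with all its edges moves together).
#' @return integer threshold, with the pooled null tail probabilities in
#'   `attr(, "tail")`; `NA` for an empty network.
#' @export
hub_threshold <- function(network, n_perm = 1000L, alpha = 0.01, seed = 1L,
                          mode = c("edge", "metabolite")) {
  mode <- match.arg(mode)
  n_perm <- check_count(n_perm, "n_perm")
  check_fraction(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  e <- nrow(network$edges)
  if (e == 0L) {
    message("empty network: hub threshold undefined")
    return(NA_integer_)
  }
  g <- length(network$genes)
  n_balls <- if (mode == "edge") e else length(unique(network$edges$metabolite))
  with_seed(seed, {
    deg_freq <- numeric(n_balls + 1L) # counts of degree 0..n_balls
    for (i in seq_len(n_perm)) {
      tab <- tabulate(sample.int(g, n_balls, replace = TRUE), nbins = g)
      deg_freq <- deg_freq + tabulate(tab + 1L, nbins = n_balls + 1L)
    }
    tail_p <- rev(cumsum(rev(deg_freq))) / (g * n_perm) # P(degree >= k-1)
    names(tail_p) <- 0:n_balls
    below <- which(tail_p < alpha)
    k <- if (length(below)) as.integer(names(tail_p)[below[1L]]) else n_balls + 1L
    k <- min(k, n_balls)
    attr(k, "tail") <- tail_p
    k
  })
}

#' Hub-gene calls at a degree threshold
#'
#' @param network a [gene_metabolite_edges()] result.
#' @param threshold degree threshold (from [hub_threshold()] or an externally
#'   chosen count).
#' @return data.frame with gene_id, degree (distinct connected metabolites),
#'   threshold_used, condition, is_hub.
#' @export
hub_calls <- function(network, threshold) {
  if (nrow(network$edges) == 0L || is.na(threshold)) {
    return(data.frame(gene_id = character(), degree = integer(),
                      threshold_used = integer(), condition = character(),
                      is_hub = logical(), stringsAsFactors = FALSE))
  }
  deg <- tapply(network$edges$metabolite, network$edges$gene,
                function(m) length(unique(m)))
  data.frame(gene_id = names(deg), degree = as.integer(deg),
             threshold_used = as.integer(threshold),
             condition = network$condition,
             is_hub = as.integer(deg) >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pathway over-representation by the hypergeometric (Fisher) test
#'
#' One-sided p per pathway from the 2x2 table of gene-set membership against
#' pathway membership within the universe, BH-adjusted across pathways.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @param pathways named list of gene-id vectors (e.g. [read_gmt()]).
#' @return data.frame with pathway, overlap, pathway_size, odds_ratio, p, fdr.
#' @export
fisher_enrichment <- function(gene_set, universe, pathways) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    stop_param("`gene_set` must be a subset of `universe`")
  }
  n_univ <- length(universe)
  n_set <- length(gene_set)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], universe)
    if (!length(members)) return(NULL) # pathway absent from universe
    k <- length(members)
    a <- length(intersect(gene_set, members))
    p <- stats::phyper(a - 1L, k, n_univ - k, n_set, lower.tail = FALSE)
    or <- (a * (n_univ - k - n_set + a)) / ((k - a) * (n_set - a))
    data.frame(pathway = pw, overlap = a, pathway_size = k,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric(), stringsAsFactors = FALSE))
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Percentage summaries of labeled count ratios
#'
#' 100 * numerator / denominator, rounded half-to-even to `digits` decimals
#' (0 when an integer percent is requested).
#'
#' @param num,den numeric vectors of numerators and positive denominators.
#' @param digits decimals per ratio (recycled).
#' @return Named numeric vector of percentages (names taken from `num`).
#' @export
summarize_ratios <- function(num, den, digits = 1L) {
  if (any(den <= 0)) stop_param("denominators must be positive")
  stopifnot(length(num) == length(den))
  digits <- rep_len(digits, length(num))
  out <- vapply(seq_along(num), function(i) {
    round(100 * num[i] / den[i], digits[i])
  }, numeric(1L))
  names(out) <- names(num)
  out
}
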
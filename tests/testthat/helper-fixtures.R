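# Shared fixtures and independent oracle helpers, built in code.

# Small deterministic genotype panel
small_geno <- function(n_lines = 60, n_snps = 200, seed = 101, ...) {
  generate_genotypes(n_lines, n_snps, seed = seed, ...)
}

# Hand-built genotype matrix from explicit dosages/positions
manual_geno <- function(dosages, chrom, pos) {
  rownames(dosages) <- sprintf("L%02d", seq_len(nrow(dosages)))
  info <- data.frame(snp_id = sprintf("s%03d", seq_along(pos)),
                     chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  geno_matrix(dosages, info)
}

# Feature-table pair from explicit intensity matrices (features x lines)
manual_features <- function(ww_int, ds_int, rt = NULL, mode = NULL, mz = NULL) {
  p <- nrow(ww_int)
  meta <- data.frame(
    feature_id = sprintf("f%03d", seq_len(p)),
    mz = if (is.null(mz)) seq(100, 200, length.out = p) else mz,
    rt = if (is.null(rt)) seq(1, 15, length.out = p) else rt,
    mode = if (is.null(mode)) rep("positive", p) else mode,
    stringsAsFactors = FALSE)
  ln <- sprintf("L%02d", seq_len(ncol(ww_int)))
  colnames(ww_int) <- colnames(ds_int) <- ln
  list(ww = feature_table(meta, ww_int, "WW"),
       ds = feature_table(meta, ds_int, "DS"))
}

# Brute-force step-up BH oracle (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# O(n^2) transitive closure of the "< gap apart on the same chromosome"
# relation; returns a component label per row
closure_oracle <- function(chrom, pos, gap) {
  n <- length(pos)
  adj <- outer(chrom, chrom, "==") & abs(outer(pos, pos, "-")) < gap
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- apply(reach, 1L, function(r) min(which(r)))
  match(labels, unique(labels))
}

# Brute-force connected components of an explicit pairwise predicate
components_oracle <- function(n, is_edge) {
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (is_edge(i, j) && lab[i] != lab[j]) {
          lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Rand index between two partitions given as label vectors
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
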
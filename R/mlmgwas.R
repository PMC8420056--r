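# Mixed-model association scans (Q + K), suggestive thresholding, mQTL
# clustering, and candidate-gene assignment.
#
# The scan uses the P3D/EMMAX approximation: REML variance components are
# estimated once under the null model y = [1, PCs]b + u + e with
# u ~ N(0, sg2*K), via the spectral decomposition of K; every SNP is then
# tested by generalized least squares at the fixed variance ratio.

#' VanRaden centered kinship matrix
#'
#' K = WW' / (2 * sum p_k (1 - p_k)) with W the dosage matrix centered at
#' twice the allele frequency. Missing dosages are mean-imputed per SNP.
#'
#' @param genotypes a [geno_matrix()] with >= 2 lines.
#' @return lines x lines symmetric positive semi-definite matrix.
#' @export
kinship <- function(genotypes) {
  dos <- genotypes$dosages
  if (nrow(dos) < 2L) stop_param("need at least 2 lines")
  dos <- impute_dosages(dos)
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_param("all SNPs are monomorphic")
  w <- sweep(dos[, poly, drop = FALSE], 2L, 2 * p[poly])
  tcrossprod(w) / (2 * sum(p[poly] * (1 - p[poly])))
}

# Mean-impute missing dosages per SNP
#' @noRd
impute_dosages <- function(dos) {
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2L]]
  }
  dos
}

#' Principal components of the genotype matrix
#'
#' @param genotypes a [geno_matrix()].
#' @param n_pc number of components.
#' @return lines x n_pc score matrix.
#' @export
genotype_pcs <- function(genotypes, n_pc = 5L) {
  n_pc <- check_count(n_pc, "n_pc", min = 0L)
  if (n_pc == 0L) {
    return(matrix(numeric(), nrow(genotypes$dosages), 0L))
  }
  dos <- impute_dosages(genotypes$dosages)
  pr <- stats::prcomp(dos, center = TRUE)
  pr$x[, seq_len(min(n_pc, ncol(pr$x))), drop = FALSE]
}

# Spectral REML for y = X0 b + u + e, u ~ N(0, sg2 K): profile the
# restricted likelihood over delta = se2/sg2 on a log grid.
#' @noRd
reml_null <- function(y, x0, K) {
  n <- length(y)
  q <- ncol(x0)
  ek <- eigen(K, symmetric = TRUE)
  lam <- pmax(ek$values, 0)
  u <- ek$vectors
  z <- drop(crossprod(u, y))
  w0 <- crossprod(u, x0)
  crit <- function(log_delta) {
    d <- lam + exp(log_delta)
    wd <- w0 / d
    a <- crossprod(w0, wd)
    b <- drop(crossprod(wd, z))
    beta <- solve(a, b)
    r <- sum(z^2 / d) - sum(b * beta)
    (n - q) * log(max(r, 1e-300)) + sum(log(d)) +
      determinant(a, logarithm = TRUE)$modulus
  }
  opt <- stats::optimize(crit, interval = c(-18, 18))
  delta <- exp(opt$minimum)
  d <- lam + delta
  wd <- w0 / d
  b <- drop(crossprod(wd, z))
  beta <- solve(crossprod(w0, wd), b)
  r <- sum(z^2 / d) - sum(b * beta)
  sg2 <- r / (n - q)
  list(delta = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
       U = u, lambda = lam)
}

#' Mixed linear model association scan (P3D / EMMAX)
#'
#' @param genotypes a [geno_matrix()].
#' @param trait named numeric vector (names = line ids) or unnamed vector
#'   aligned to the genotype lines.
#' @param K kinship matrix; computed by [kinship()] when `NULL`.
#' @param n_pc number of genotype principal components used as
#'   population-structure covariates.
#' @param var_ratio optional fixed value of delta = sigma_e2/sigma_g2;
#'   `Inf` forces the polygenic variance to zero, making the scan ordinary
#'   least squares with PC covariates.
#' @return data.frame of class `mscan` with columns snp_id, chrom, pos, beta,
#'   se, p, pve; skipped monomorphic SNPs recorded in `attr(, "skipped")`;
#'   variance components in `attr(, "varcomp")`.
#' @export
mlm_scan <- function(genotypes, trait, K = NULL, n_pc = 5L, var_ratio = NULL) {
  dos <- genotypes$dosages
  n <- nrow(dos)
  if (!is.null(names(trait))) {
    if (!all(rownames(dos) %in% names(trait))) {
      stop_param("trait names do not cover the genotype lines")
    }
    trait <- trait[rownames(dos)]
  }
  y <- as.numeric(trait)
  if (length(y) != n) stop_param("trait length does not match line count")
  if (anyNA(y)) stop_param("trait contains missing values; subset lines first")
  if (stats::sd(y) == 0) stop_param("trait is constant")
  x0 <- cbind(`(Intercept)` = rep(1, n), genotype_pcs(genotypes, n_pc))
  q <- ncol(x0)
  dos <- impute_dosages(dos)
  sds <- apply(dos, 2L, stats::sd)
  skipped <- colnames(dos)[sds == 0]
  use <- sds > 0
  g <- dos[, use, drop = FALSE]

  if (!is.null(var_ratio) && is.infinite(var_ratio)) {
    ystar <- y; x0star <- x0; gstar <- g
    vc <- list(delta = Inf, sigma_g2 = 0, sigma_e2 = NA_real_)
  } else {
    if (is.null(K)) K <- kinship(genotypes)
    if (is.null(var_ratio)) {
      vc <- reml_null(y, x0, K)
    } else {
      ek <- eigen(K, symmetric = TRUE)
      vc <- list(delta = var_ratio, U = ek$vectors, lambda = pmax(ek$values, 0),
                 sigma_g2 = NA_real_, sigma_e2 = NA_real_)
    }
    sw <- 1 / sqrt(vc$lambda + vc$delta)
    ystar <- drop(crossprod(vc$U, y)) * sw
    x0star <- crossprod(vc$U, x0) * sw
    gstar <- crossprod(vc$U, g) * sw
  }
  qr0 <- qr(x0star)
  y_r <- qr.resid(qr0, ystar)
  g_r <- qr.resid(qr0, gstar)
  sxx <- colSums(g_r^2)
  sxy <- drop(crossprod(g_r, y_r))
  syy <- sum(y_r^2)
  beta <- sxy / sxx
  df <- n - q - 1L
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  t_stat <- beta / se
  p <- pmax(p_from_t(t_stat, df), .Machine$double.xmin)
  # squared standardized effect on the whitened, covariate-adjusted scale
  pve <- pmin(pmax(beta^2 * sxx / syy, 0), 1 - 1e-12)
  out <- data.frame(snp_id = colnames(g),
                    chrom = genotypes$info$chrom[use],
                    pos = genotypes$info$pos[use],
                    beta = beta, se = se, p = p, pve = pve,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mscan", "data.frame")
  attr(out, "skipped") <- skipped
  attr(out, "varcomp") <- vc[c("delta", "sigma_g2", "sigma_e2")]
  out
}

#' Suggestive association threshold from the effective marker number
#'
#' @param meff effective number of independent markers (>= 1).
#' @return 1 / meff.
#' @export
suggestive_threshold <- function(meff) {
  if (!is.numeric(meff) || length(meff) != 1L || !is.finite(meff) || meff < 1) {
    stop_param("`meff` must be a number >= 1")
  }
  1 / meff
}

#' Effective number of independent markers (simpleM-style)
#'
#' Within sliding windows of consecutive SNPs the effective count is the
#' smallest number of top eigenvalues of the SNP correlation matrix that
#' explains >= `ev_frac` of its trace; window counts are summed. The result
#' is always <= the SNP count and >= the chromosome count.
#'
#' @param genotypes a [geno_matrix()].
#' @param window window size in SNPs.
#' @param ev_frac eigenvalue fraction cutoff.
#' @return integer effective marker count.
#' @export
effective_marker_count <- function(genotypes, window = 100L, ev_frac = 0.995) {
  window <- check_count(window, "window")
  dos <- impute_dosages(genotypes$dosages)
  info <- genotypes$info
  total <- 0L
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    starts <- seq(1L, length(idx), by = window)
    for (s in starts) {
      cols <- idx[s:min(s + window - 1L, length(idx))]
      x <- dos[, cols, drop = FALSE]
      x <- x[, apply(x, 2L, stats::sd) > 0, drop = FALSE]
      if (ncol(x) == 0L) next
      if (ncol(x) == 1L) {
        total <- total + 1L
        next
      }
      ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      total <- total + which(cumsum(ev) / sum(ev) >= ev_frac)[1L]
    }
  }
  as.integer(max(total, length(unique(info$chrom))))
}

#' Cluster significant SNPs into mQTL intervals
#'
#' Single-linkage chaining per chromosome: consecutive position-sorted SNPs
#' join the same locus iff their gap is strictly below `gap` base pairs.
#' Traits and conditions are unioned over members; the peak SNP carries the
#' smallest p (ties broken by smaller position).
#'
#' @param significant data.frame with columns snp_id, chrom, pos, p and
#'   optionally trait, condition (one row per SNP x trait association).
#' @param gap clustering gap in bp.
#' @return data.frame with one row per locus: mqtl_id, chrom, start, end,
#'   n_snps, peak_snp, peak_p, and list-columns member_snps, member_pos,
#'   traits, conditions.
#' @export
cluster_mqtl <- function(significant, gap = 10000) {
  empty <- data.frame(mqtl_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_snps = integer(),
                      peak_snp = character(), peak_p = numeric(),
                      stringsAsFactors = FALSE)
  empty$member_snps <- list(); empty$member_pos <- list()
  empty$traits <- list(); empty$conditions <- list()
  if (is.null(significant) || nrow(significant) == 0L) return(empty)
  if (is.null(significant$trait)) significant$trait <- NA_character_
  if (is.null(significant$condition)) significant$condition <- NA_character_
  # one record per distinct SNP: min p, unioned traits/conditions
  agg <- split(significant, significant$snp_id)
  snps <- data.frame(
    snp_id = names(agg),
    chrom = vapply(agg, function(d) d$chrom[1L], character(1L)),
    pos = vapply(agg, function(d) d$pos[1L], numeric(1L)),
    p = vapply(agg, function(d) min(d$p), numeric(1L)),
    stringsAsFactors = FALSE)
  snps$traits <- lapply(agg, function(d) sort(unique(stats::na.omit(d$trait))))
  snps$conditions <- lapply(agg, function(d) sort(unique(stats::na.omit(d$condition))))
  out <- list()
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(s$pos) >= gap)))
    for (gid in unique(grp)) {
      m <- s[grp == gid, , drop = FALSE]
      peak <- m[order(m$p, m$pos), , drop = FALSE][1L, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(m$pos), end = max(m$pos),
        n_snps = nrow(m), peak_snp = peak$snp_id, peak_p = peak$p,
        stringsAsFactors = FALSE)
      out[[length(out)]]$member_snps <- list(m$snp_id)
      out[[length(out)]]$member_pos <- list(m$pos)
      out[[length(out)]]$traits <- list(sort(unique(unlist(m$traits))))
      out[[length(out)]]$conditions <- list(sort(unique(unlist(m$conditions))))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$mqtl_id <- sprintf("mQTL%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("mqtl_id", setdiff(names(res), "mqtl_id"))]
}

#' Assign candidate genes to mQTLs
#'
#' A gene is a candidate iff at least one member significant SNP lies within
#' the gene body (1-based inclusive coordinates).
#'
#' @param mqtls output of [cluster_mqtl()].
#' @param genes data.frame with gene_id, chrom, start, end (e.g. from
#'   [read_gene_models()]).
#' @return `mqtls` with an added list-column `candidate_genes`.
#' @export
assign_candidate_genes <- function(mqtls, genes) {
  if (nrow(mqtls) == 0L) {
    mqtls$candidate_genes <- list()
    return(mqtls)
  }
  snp_pos <- unlist(mqtls$member_pos, use.names = FALSE)
  snp_chrom <- rep(mqtls$chrom, lengths(mqtls$member_pos))
  snp_mqtl <- rep(seq_len(nrow(mqtls)), lengths(mqtls$member_pos))
  snp_gr <- GenomicRanges::GRanges(snp_chrom,
                                   IRanges::IRanges(snp_pos, snp_pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  cand <- rep(list(character()), nrow(mqtls))
  if (length(hits)) {
    df <- data.frame(mqtl = snp_mqtl[S4Vectors::queryHits(hits)],
                     gene = genes$gene_id[S4Vectors::subjectHits(hits)])
    for (i in unique(df$mqtl)) {
      cand[[i]] <- sort(unique(df$gene[df$mqtl == i]))
    }
  }
  mqtls$candidate_genes <- cand
  mqtls
}

#' Co-localization of mQTLs with known QTL intervals
#'
#' An mQTL co-localizes iff its interval overlaps any known interval by at
#' least 1 bp.
#'
#' @param mqtls output of [cluster_mqtl()].
#' @param known data.frame with chrom, start, end in 1-based closed
#'   coordinates (see [read_known_qtl()] for BED input).
#' @return list with `colocalized` (logical per mQTL) and `fraction`.
#' @export
qtl_overlap <- function(mqtls, known) {
  if (nrow(mqtls) == 0L) return(list(colocalized = logical(), fraction = NaN))
  if (is.null(known) || nrow(known) == 0L) {
    return(list(colocalized = rep(FALSE, nrow(mqtls)), fraction = 0))
  }
  mg <- GenomicRanges::GRanges(mqtls$chrom, IRanges::IRanges(mqtls$start, mqtls$end))
  kg <- GenomicRanges::GRanges(known$chrom, IRanges::IRanges(known$start, known$end))
  hit <- GenomicRanges::countOverlaps(mg, kg, minoverlap = 1L) > 0L
  list(colocalized = hit, fraction = mean(hit))
}
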
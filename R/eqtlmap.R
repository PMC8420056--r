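# Expression-QTL mapping: the mixed-model scan applied to log-transformed
# expression traits, locus clustering, cis/trans and shared/dynamic
# classification.

#' eQTL scan over an expression matrix
#'
#' Expression is log2(x+1)-transformed, each gene is scanned with
#' [mlm_scan()], significant SNPs are clustered per gene with the 10-kb rule,
#' and each locus is classified cis/trans by the lead SNP position relative
#' to the gene body +/- `cis_window`.
#'
#' @param genotypes a [geno_matrix()].
#' @param expression an [expr_matrix()] (raw scale).
#' @param gene_models data.frame with gene_id, chrom, start, end.
#' @param K kinship matrix; computed once via [kinship()] when `NULL`.
#' @param threshold genome-wide significance threshold on p.
#' @param n_pc structure covariates for the scan.
#' @param gap locus clustering gap in bp.
#' @param cis_window cis window in bp.
#' @return data.frame with one row per (gene, locus): gene_id, chrom, start,
#'   end, lead_snp, pos, p, condition, kind.
#' @export
eqtl_scan <- function(genotypes, expression, gene_models, K = NULL,
                      threshold = 4.2e-8, n_pc = 5L, gap = 10000,
                      cis_window = 20000L) {
  check_fraction(threshold, "threshold", 0, 1, open_lo = TRUE)
  lines <- intersect(genotypes$line_ids, expression$line_ids)
  if (length(lines) < 10L) stop_param("fewer than 10 shared lines")
  geno <- subset_lines(genotypes, lines)
  if (is.null(K)) K <- kinship(geno)
  expr <- log2(expression$values[, lines, drop = FALSE] + 1)
  recs <- list()
  for (g in rownames(expr)) {
    y <- expr[g, ]
    if (stats::sd(y) == 0) {
      warning("gene ", g, " has zero-variance expression; skipped")
      next
    }
    scan <- mlm_scan(geno, y, K = K, n_pc = n_pc)
    sig <- scan[scan$p < threshold, , drop = FALSE]
    if (nrow(sig) == 0L) next
    loci <- cluster_mqtl(sig, gap = gap)
    recs[[g]] <- data.frame(
      gene_id = g, chrom = loci$chrom, start = loci$start, end = loci$end,
      lead_snp = loci$peak_snp, p = loci$peak_p,
      condition = expression$condition, stringsAsFactors = FALSE)
    recs[[g]]$pos <- vapply(seq_len(nrow(loci)), function(i) {
      loci$member_pos[[i]][match(loci$peak_snp[i], loci$member_snps[[i]])]
    }, numeric(1L))
  }
  if (!length(recs)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      lead_snp = character(), p = numeric(),
                      condition = character(), pos = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$kind <- classify_cis_trans(out$gene_id, out$chrom, out$pos,
                                 gene_models, window = cis_window)
  out
}

#' @noRd
subset_lines <- function(genotypes, lines) {
  g <- geno_matrix(genotypes$dosages[lines, , drop = FALSE], genotypes$info)
  g
}

#' Classify eQTL loci as cis or trans
#'
#' Cis iff the lead SNP lies within `[gene start - window, gene end + window]`
#' (inclusive) on the gene's chromosome; otherwise trans (a different
#' chromosome is always trans). Gene orientation is ignored.
#'
#' @param gene_id,chrom,pos vectors describing lead SNPs (recycled together).
#' @param gene_models data.frame with gene_id, chrom, start, end.
#' @param window window in bp around the gene body.
#' @return character vector, `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(gene_id, chrom, pos, gene_models,
                               window = 20000L) {
  idx <- match(gene_id, gene_models$gene_id)
  if (anyNA(idx)) {
    stop_param("gene(s) absent from models: ",
               paste(utils::head(unique(gene_id[is.na(idx)]), 3), collapse = ", "))
  }
  ifelse(chrom == gene_models$chrom[idx] &
           pos >= gene_models$start[idx] - window &
           pos <= gene_models$end[idx] + window,
         "cis", "trans")
}

#' Label eQTL loci as shared or dynamic across conditions
#'
#' A locus is shared iff, for the same gene, the other condition carries a
#' significant locus whose merged interval overlaps by at least 1 bp;
#' otherwise dynamic.
#'
#' @param records_ww,records_ds per-condition outputs of [eqtl_scan()].
#' @return The row-bound records with an added `sharing` column.
#' @export
classify_sharing <- function(records_ww, records_ds) {
  lab <- function(a, b) {
    if (nrow(a) == 0L) return(character())
    vapply(seq_len(nrow(a)), function(i) {
      m <- b[b$gene_id == a$gene_id[i] & b$chrom == a$chrom[i] &
               b$start <= a$end[i] & b$end >= a$start[i], , drop = FALSE]
      if (nrow(m)) "shared" else "dynamic"
    }, character(1L))
  }
  out <- rbind(records_ww, records_ds)
  out$sharing <- c(lab(records_ww, records_ds), lab(records_ds, records_ww))
  out
}
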
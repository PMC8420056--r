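#' Feature table constructor
#'
#' Container for LC-MS-like feature intensities under one watering condition:
#' per-feature metadata (mass-to-charge, retention time in minutes, ionization
#' mode) and a features x lines intensity matrix (nonnegative, `NA` allowed).
#'
#' @param meta data.frame with columns `feature_id`, `mz`, `rt`, `mode`
#'   (`"positive"` or `"negative"`).
#' @param intensities numeric matrix, features x lines, rownames matching
#'   `meta$feature_id`, colnames the line ids.
#' @param condition `"WW"` (well-watered) or `"DS"` (drought-stressed).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(meta, intensities, condition) {
  condition <- match.arg(condition, c("WW", "DS"))
  stopifnot(is.data.frame(meta),
            all(c("feature_id", "mz", "rt", "mode") %in% names(meta)),
            is.matrix(intensities),
            nrow(intensities) == nrow(meta))
  if (any(meta$rt < 0) || any(meta$mz <= 0)) {
    stop_param("feature metadata invalid: rt must be >= 0 and mz > 0")
  }
  if (!all(meta$mode %in% c("positive", "negative"))) {
    stop_param("ionization mode must be 'positive' or 'negative'")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop_param("feature intensities must be nonnegative where present")
  }
  rownames(intensities) <- meta$feature_id
  structure(list(meta = meta, intensities = intensities, condition = condition),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d lines, condition %s (%.1f%% missing)\n",
              nrow(x$intensities), ncol(x$intensities), x$condition,
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Metabolite matrix constructor
#'
#' Deduplicated metabolite abundances for one condition: lines x metabolites
#' values plus the group map tracing each retained metabolite back to its
#' member features.
#'
#' @param values numeric matrix, lines x metabolites.
#' @param condition `"WW"` or `"DS"`.
#' @param group_map named list: metabolite id -> character vector of member
#'   feature ids.
#' @param log_transformed logical; `TRUE` once [normalize_and_log()] has run.
#' @param raw optional lines x metabolites matrix of normalized raw-scale
#'   intensities (kept for fold-change computation).
#' @return An object of class `metab_matrix`.
#' @export
metab_matrix <- function(values, condition, group_map = NULL,
                         log_transformed = FALSE, raw = NULL) {
  condition <- match.arg(condition, c("WW", "DS"))
  stopifnot(is.matrix(values), !is.null(colnames(values)), !is.null(rownames(values)))
  if (is.null(group_map)) {
    group_map <- stats::setNames(as.list(colnames(values)), colnames(values))
  }
  structure(list(values = values, metabolite_ids = colnames(values),
                 line_ids = rownames(values), condition = condition,
                 group_map = group_map, log_transformed = log_transformed,
                 raw = raw),
            class = "metab_matrix")
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("<metab_matrix> %d lines x %d metabolites, condition %s%s\n",
              nrow(x$values), ncol(x$values), x$condition,
              if (x$log_transformed) ", log scale" else ""))
  invisible(x)
}

#' Genotype matrix constructor
#'
#' Biallelic dosages (0/1/2; `NA` allowed) for a panel of lines, with per-SNP
#' chromosome, position and minor-allele frequency metadata.
#'
#' @param dosages integer/numeric matrix, lines x SNPs, values in {0,1,2,NA};
#'   rownames line ids, colnames SNP ids.
#' @param info data.frame with columns `snp_id`, `chrom`, `pos`, `maf`
#'   (positions strictly increasing within chromosome).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, info) {
  stopifnot(is.matrix(dosages), is.data.frame(info),
            all(c("snp_id", "chrom", "pos") %in% names(info)),
            ncol(dosages) == nrow(info))
  if (!all(dosages %in% c(0, 1, 2, NA))) stop_param("dosages must be 0/1/2 or NA")
  for (ch in unique(info$chrom)) {
    p <- info$pos[info$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop_param("positions must be strictly increasing within each chromosome")
    }
  }
  if (is.null(info$maf)) {
    af <- colMeans(dosages, na.rm = TRUE) / 2
    info$maf <- pmin(af, 1 - af)
  }
  colnames(dosages) <- info$snp_id
  structure(list(dosages = dosages, line_ids = rownames(dosages), info = info),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d lines x %d SNPs on %d chromosome(s), min MAF %.3f\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$info$chrom)),
              min(x$info$maf)))
  invisible(x)
}

#' Expression matrix constructor
#'
#' @param values numeric matrix, genes x lines (raw, nonnegative scale).
#' @param condition `"WW"` or `"DS"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, condition) {
  condition <- match.arg(condition, c("WW", "DS"))
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, gene_ids = rownames(values),
                 line_ids = colnames(values), condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d lines, condition %s\n",
              nrow(x$values), ncol(x$values), x$condition))
  invisible(x)
}
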
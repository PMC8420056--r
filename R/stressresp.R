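# Drought-responsive metabolite detection: PCA of the two conditions,
# two-class OPLS-DA with VIP scoring, paired tests with BH adjustment, and
# the three-criterion intersection call (VIP >= 1, FDR <= 0.05, FC >= 2 or
# <= 0.5).

#' PCA of the stacked two-condition metabolome
#'
#' Rows are line x condition samples; the decomposition is centered (and
#' optionally unit-variance scaled).
#'
#' @param ww,ds [metab_matrix()]s sharing the metabolite set.
#' @param n_pc number of components to return (clamped to the rank, with a
#'   warning).
#' @param scale. scale metabolites to unit variance first.
#' @return list with `scores` (samples x n_pc), `var_frac` (variance
#'   fractions, descending), `condition` (per-row labels).
#' @export
pca_conditions <- function(ww, ds, n_pc = 2L, scale. = FALSE) {
  n_pc <- check_count(n_pc, "n_pc")
  mets <- intersect(colnames(ww$values), colnames(ds$values))
  x <- rbind(ww$values[, mets, drop = FALSE], ds$values[, mets, drop = FALSE])
  cond <- rep(c("WW", "DS"), c(nrow(ww$values), nrow(ds$values)))
  rownames(x) <- paste(rownames(x), cond, sep = ".")
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-12)
  if (n_pc > rank) {
    warning(sprintf("n_pc = %d exceeds rank %d; clamped", n_pc, rank))
    n_pc <- rank
  }
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(n_pc), drop = FALSE],
       var_frac = var_frac[seq_len(n_pc)], condition = cond)
}

#' Fit a two-class orthogonal PLS discriminant model
#'
#' Single-response O-PLS in the Trygg-Wold form: the predictive weight is
#' proportional to X'y (y the centered class indicator); `n_ortho`
#' y-orthogonal components are removed by deflation before the final
#' predictive component is extracted. Metabolites are centered and scaled to
#' unit variance; constant metabolites are excluded with a warning. VIP is
#' computed over the predictive component, so mean(VIP^2) = 1.
#'
#' @param x samples x metabolites matrix.
#' @param labels two-level factor/character vector (e.g. WW/DS) per sample.
#' @param n_ortho number of orthogonal components to remove.
#' @return An object of class `opls_model` with elements `w` (unit predictive
#'   weight), `scores`, `ortho` (scores/loadings/weights per orthogonal
#'   component), `r2y`, `vip` (named, NA for excluded metabolites),
#'   `excluded`.
#' @export
fit_oplsda <- function(x, labels, n_ortho = 1L) {
  n_ortho <- check_count(n_ortho, "n_ortho", min = 0L)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  lab <- factor(labels)
  if (nlevels(lab) != 2L) stop_param("`labels` must contain exactly two classes")
  sds <- apply(x, 2L, stats::sd)
  excluded <- colnames(x)[!is.finite(sds) | sds == 0]
  if (length(excluded)) {
    warning(sprintf("excluding %d zero-variance metabolite(s)", length(excluded)))
  }
  keep <- setdiff(colnames(x), excluded)
  xs <- scale(x[, keep, drop = FALSE])
  y <- as.numeric(lab == levels(lab)[2L])
  y <- y - mean(y)
  e <- xs
  ortho <- list()
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(e, y))
    w <- w / sqrt(sum(w^2))
    t_p <- drop(e %*% w)
    p <- drop(crossprod(e, t_p)) / sum(t_p^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- drop(e %*% w_o)
    p_o <- drop(crossprod(e, t_o)) / sum(t_o^2)
    e <- e - tcrossprod(t_o, p_o)
    ortho[[a]] <- list(scores = t_o, loadings = p_o, weights = w_o)
  }
  w <- drop(crossprod(e, y))
  w <- w / sqrt(sum(w^2))
  t_p <- drop(e %*% w)
  c_coef <- sum(y * t_p) / sum(t_p^2)
  yhat <- c_coef * t_p
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  p_count <- length(keep)
  vip_keep <- sqrt(p_count * w^2) # single predictive component
  vip <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  vip[keep] <- vip_keep
  structure(list(w = stats::setNames(w, keep), scores = t_p, ortho = ortho,
                 r2y = r2y, c_coef = c_coef, vip = vip, excluded = excluded,
                 labels = lab, n_metabolites = p_count),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(paste0("<opls_model> %d metabolites, %d orthogonal component(s), ",
                     "R2Y = %.3f; %d metabolites with VIP >= 1\n"),
              x$n_metabolites, length(x$ortho), x$r2y,
              sum(x$vip >= 1, na.rm = TRUE)))
  invisible(x)
}

#' Paired tests of drought effect per metabolite
#'
#' Two-sided paired t-test on the (log-scale) per-line differences DS - WW,
#' with Benjamini-Hochberg adjustment across metabolites. Lines missing
#' either value for a metabolite are dropped pairwise; metabolites with fewer
#' than 3 complete pairs get `NA` and are excluded from the BH family.
#'
#' @param ww,ds [metab_matrix()]s (log scale), paired by line id.
#' @return data.frame with columns metabolite, n_pairs, t, p, fdr.
#' @export
paired_test <- function(ww, ds) {
  lines <- intersect(rownames(ww$values), rownames(ds$values))
  mets <- intersect(colnames(ww$values), colnames(ds$values))
  if (length(lines) < 3L) stop_param("need at least 3 shared lines")
  d <- ds$values[lines, mets, drop = FALSE] - ww$values[lines, mets, drop = FALSE]
  n <- colSums(!is.na(d))
  m_d <- colMeans(d, na.rm = TRUE)
  s_d <- apply(d, 2L, stats::sd, na.rm = TRUE)
  t_stat <- ifelse(s_d > 0, m_d / (s_d / sqrt(n)),
                   ifelse(abs(m_d) < .Machine$double.eps^0.5, 0, Inf * sign(m_d)))
  p <- ifelse(s_d > 0, p_from_t(t_stat, n - 1L),
              ifelse(t_stat == 0, 1, .Machine$double.xmin))
  p[n < 3L] <- NA_real_
  t_stat[n < 3L] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(metabolite = mets, n_pairs = as.integer(n), t = t_stat, p = p,
             fdr = fdr, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify metabolites as drought-responsive
#'
#' The published intersection rule: responsive iff VIP >= `vip_min` AND
#' FDR <= `fdr_max` AND (FC >= `fc_min` OR FC <= 1/`fc_min`), with FC the
#' raw-scale ratio of DS to WW mean intensities. A metabolite with any
#' missing statistic is never responsive and is flagged incomplete.
#'
#' @param vip named numeric vector of VIP scores.
#' @param fdr named numeric vector of BH-adjusted p-values.
#' @param fc named numeric vector of raw-scale DS/WW fold changes.
#' @param vip_min,fdr_max,fc_min the three gates.
#' @return data.frame with columns metabolite, vip, fc, log2fc, fdr,
#'   responsive, direction (`up`/`down`/`none`), complete.
#' @export
classify_responsive <- function(vip, fdr, fc, vip_min = 1, fdr_max = 0.05,
                                fc_min = 2) {
  mets <- names(fc)
  vip <- vip[mets]
  fdr <- fdr[mets]
  complete <- !is.na(vip) & !is.na(fdr) & !is.na(fc)
  up <- complete & vip >= vip_min & fdr <= fdr_max & fc >= fc_min
  down <- complete & vip >= vip_min & fdr <= fdr_max & fc <= 1 / fc_min
  data.frame(metabolite = mets, vip = unname(vip), fc = unname(fc),
             log2fc = log2(unname(fc)), fdr = unname(fdr),
             responsive = up | down,
             direction = ifelse(up, "up", ifelse(down, "down", "none")),
             complete = complete, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full drought-response analysis of a metabolite-matrix pair
#'
#' Runs OPLS-DA on the stacked log matrices, the paired test, raw-scale fold
#' changes, and the intersection classification.
#'
#' @param ww,ds log-scale [metab_matrix()]s from [normalize_and_log()].
#' @param n_ortho orthogonal components for OPLS-DA.
#' @param vip_min,fdr_max,fc_min classification gates.
#' @return list with `table` (the classification data.frame), `opls` (the
#'   fitted [fit_oplsda()] model), `test` (the [paired_test()] output) and
#'   `summary` (counts of up/down/total responsive).
#' @export
drought_response <- function(ww, ds, n_ortho = 1L, vip_min = 1,
                             fdr_max = 0.05, fc_min = 2) {
  lines <- intersect(rownames(ww$values), rownames(ds$values))
  mets <- intersect(colnames(ww$values), colnames(ds$values))
  stacked <- rbind(ww$values[lines, mets, drop = FALSE],
                   ds$values[lines, mets, drop = FALSE])
  labels <- rep(c("WW", "DS"), each = length(lines))
  opls <- fit_oplsda(stacked, labels, n_ortho = n_ortho)
  test <- paired_test(ww, ds)
  raw_of <- function(mm) {
    if (!is.null(mm$raw)) mm$raw[lines, mets, drop = FALSE]
    else if (mm$log_transformed) exp(mm$values[lines, mets, drop = FALSE])
    else mm$values[lines, mets, drop = FALSE]
  }
  rww <- raw_of(ww); rds <- raw_of(ds)
  both <- !is.na(rww) & !is.na(rds)
  rww[!both] <- NA; rds[!both] <- NA
  fc <- colMeans(rds, na.rm = TRUE) / colMeans(rww, na.rm = TRUE)
  tab <- classify_responsive(opls$vip[mets],
                             stats::setNames(test$fdr, test$metabolite)[mets],
                             stats::setNames(fc, mets),
                             vip_min = vip_min, fdr_max = fdr_max,
                             fc_min = fc_min)
  list(table = tab, opls = opls, test = test,
       summary = list(n_tested = nrow(tab),
                      n_responsive = sum(tab$responsive),
                      n_up = sum(tab$direction == "up"),
                      n_down = sum(tab$direction == "down")))
}
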
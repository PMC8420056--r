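# Feature-table processing: missingness filter, redundancy collapse,
# normalization and log transform.

#' Remove features with excessive missingness in either condition
#'
#' A feature is retained iff its missing fraction is <= `max_missing` under
#' the well-watered AND the drought-stressed condition. Removal is always by
#' feature, never by line.
#'
#' @param ww,ds [feature_table()]s sharing the same line set and feature set.
#' @param max_missing maximum tolerated missing fraction per condition.
#' @return list with filtered `ww` and `ds` tables and the retained
#'   `feature_ids`.
#' @export
filter_missingness <- function(ww, ds, max_missing = 0.2) {
  check_fraction(max_missing, "max_missing", 0, 1)
  if (!setequal(colnames(ww$intensities), colnames(ds$intensities))) {
    stop_param("WW and DS tables must share the same line set")
  }
  ds_int <- ds$intensities[, colnames(ww$intensities), drop = FALSE]
  if (!identical(ww$meta$feature_id, ds$meta$feature_id)) {
    stop_param("WW and DS tables must share the same feature set")
  }
  miss_ww <- rowMeans(is.na(ww$intensities))
  miss_ds <- rowMeans(is.na(ds_int))
  keep <- miss_ww <= max_missing & miss_ds <= max_missing
  list(ww = feature_table(ww$meta[keep, , drop = FALSE],
                          ww$intensities[keep, , drop = FALSE], "WW"),
       ds = feature_table(ds$meta[keep, , drop = FALSE],
                          ds_int[keep, , drop = FALSE], "DS"),
       feature_ids = ww$meta$feature_id[keep])
}

# Pairwise grouping graph for one stage of the collapse: indices of rows of
# `meta` to compare, log profiles in `prof` (features x samples).
collapse_edges <- function(rt, prof, rt_tol, corr_min, compat = NULL,
                           ids = NULL) {
  ord <- order(rt)
  edges <- list()
  k <- 0L
  tol <- rt_tol + 1e-9 # guard the <= boundary against float representation
  for (a in seq_along(ord)) {
    b <- a + 1L
    while (b <= length(ord) && rt[ord[b]] - rt[ord[a]] <= tol) {
      i <- ord[a]; j <- ord[b]
      ok <- TRUE
      if (!is.null(compat) && !is.null(ids)) {
        ok <- isTRUE(compat[ids[i], ids[j]]) || isTRUE(compat[ids[j], ids[i]])
      }
      if (ok) {
        r <- suppressWarnings(stats::cor(prof[i, ], prof[j, ],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r > corr_min) {
          k <- k + 1L
          edges[[k]] <- c(i, j)
        }
      }
      b <- b + 1L
    }
  }
  if (k) do.call(rbind, edges) else matrix(integer(), ncol = 2L)
}

#' Collapse redundant features into nonredundant metabolites
#'
#' Two-stage grouping mirroring the published three-step redundancy removal:
#' within each ionization mode, features are joined when their retention
#' times differ by at most `rt_tol` minutes AND their cross-line intensity
#' correlation exceeds `corr_min` (an optional MS/MS compatibility matrix
#' stands in for the spectral co-occurrence criterion); groups are the
#' connected components of that graph. Positive- and negative-mode groups
#' are then merged across modes by the same retention-time and correlation
#' criteria. The representative intensity of a group is the member with the
#' fewest missing values (ties broken by larger median intensity, then by
#' lexicographic feature id). Correlations are computed on log intensities
#' with both conditions' profiles stacked (configurable via `use_log`).
#'
#' @param ww,ds filtered [feature_table()]s (same feature set).
#' @param rt_tol retention-time tolerance in minutes.
#' @param corr_min correlation threshold in (-1, 1).
#' @param compat optional logical matrix (feature id x feature id): MS/MS
#'   compatibility; when supplied, within-mode edges additionally require it.
#' @param use_log compute correlations on log intensities (default) or raw.
#' @return list with `ww` and `ds` [metab_matrix()]s (raw intensities of the
#'   representative features, lines x metabolites) sharing one group map.
#' @export
collapse_redundant <- function(ww, ds, rt_tol = 0.2, corr_min = 0.95,
                               compat = NULL, use_log = TRUE) {
  if (rt_tol < 0) stop_param("`rt_tol` must be >= 0")
  if (corr_min <= -1 || corr_min >= 1) stop_param("`corr_min` must lie in (-1, 1)")
  meta <- ww$meta
  stacked <- cbind(ww$intensities, ds$intensities)
  prof <- if (use_log) log(stacked) else stacked
  p <- nrow(meta)

  comp <- rep(NA_integer_, p)
  for (mode in c("positive", "negative")) {
    idx <- which(meta$mode == mode)
    if (!length(idx)) next
    e <- collapse_edges(meta$rt[idx], prof[idx, , drop = FALSE], rt_tol,
                        corr_min, compat, meta$feature_id[idx])
    cc <- connected_components(length(idx), e)
    comp[idx] <- paste(mode, cc)
  }
  comp <- match(comp, unique(comp))
  n_grp <- max(comp)

  # stage 2: merge groups across modes by criteria (i) and (iii)
  rep_of <- function(members) {
    n_miss <- rowSums(is.na(stacked[members, , drop = FALSE]))
    meds <- apply(stacked[members, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
    ids <- meta$feature_id[members]
    members[order(n_miss, -meds, ids)][1L]
  }
  grp_members <- split(seq_len(p), comp)
  grp_rep <- vapply(grp_members, rep_of, integer(1L))
  grp_rt <- vapply(grp_members, function(m) stats::median(meta$rt[m]), numeric(1L))
  e2 <- collapse_edges(grp_rt, prof[grp_rep, , drop = FALSE], rt_tol, corr_min)
  # only join groups originating from different modes
  if (nrow(e2)) {
    mode_of <- vapply(grp_members, function(m) meta$mode[m][1L], character(1L))
    e2 <- e2[mode_of[e2[, 1L]] != mode_of[e2[, 2L]], , drop = FALSE]
  }
  cc2 <- connected_components(n_grp, e2)
  final <- cc2[comp]

  members_list <- split(seq_len(p), final)
  rep_idx <- vapply(members_list, rep_of, integer(1L))
  met_ids <- meta$feature_id[rep_idx]
  ord <- order(met_ids)
  members_list <- members_list[ord]
  rep_idx <- rep_idx[ord]
  met_ids <- met_ids[ord]
  group_map <- stats::setNames(
    lapply(members_list, function(m) sort(meta$feature_id[m])), met_ids)

  mk <- function(ft, cond) {
    vals <- t(ft$intensities[rep_idx, , drop = FALSE])
    colnames(vals) <- met_ids
    metab_matrix(vals, cond, group_map = group_map)
  }
  list(ww = mk(ww, "WW"), ds = mk(ds, "DS"))
}

#' Median normalization of an intensity matrix
#'
#' Equalizes per-sample medians to the grand median of sample medians,
#' optionally per batch first (each batch's sample-median median brought to
#' the global value). Exactly idempotent.
#'
#' @param values numeric matrix, lines (samples) x metabolites, positive
#'   where present.
#' @param batch_labels optional per-sample batch ids (length `nrow(values)`).
#' @return The normalized matrix.
#' @export
median_normalize <- function(values, batch_labels = NULL) {
  samp_med <- apply(values, 1L, stats::median, na.rm = TRUE)
  target <- stats::median(samp_med)
  if (!is.null(batch_labels)) {
    stopifnot(length(batch_labels) == nrow(values))
    for (b in unique(batch_labels)) {
      rows <- which(batch_labels == b)
      bmed <- stats::median(samp_med[rows])
      values[rows, ] <- values[rows, , drop = FALSE] * (target / bmed)
    }
    samp_med <- apply(values, 1L, stats::median, na.rm = TRUE)
  }
  values * (target / samp_med)
}

#' Normalize intensities and transform to the log scale
#'
#' Per-batch median scaling, per-sample median normalization, natural-log
#' transform; remaining missing values are imputed as half the per-metabolite
#' minimum (on the normalized raw scale) before the log.
#'
#' @param mm a [metab_matrix()] holding positive raw intensities.
#' @param batch_labels optional per-sample batch ids.
#' @return A [metab_matrix()] with log-scale `values`; the normalized,
#'   imputed raw-scale matrix is kept in `$raw` for fold-change computation.
#' @export
normalize_and_log <- function(mm, batch_labels = NULL) {
  vals <- mm$values
  bad <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_param(sprintf("nonpositive intensity at line '%s', metabolite '%s'",
                       rownames(vals)[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  norm <- median_normalize(vals, batch_labels)
  for (j in seq_len(ncol(norm))) {
    nas <- is.na(norm[, j])
    if (any(nas)) {
      mn <- min(norm[, j], na.rm = TRUE)
      norm[nas, j] <- mn / 2
    }
  }
  metab_matrix(log(norm), mm$condition, group_map = mm$group_map,
               log_transformed = TRUE, raw = norm)
}
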
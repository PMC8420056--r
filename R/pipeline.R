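# End-to-end orchestration: configuration, stage execution, and the summary
# report collecting every count and ratio the analysis produces.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one auditable object,
#' with defaults equal to the published values, plus the scale of the bundled
#' synthetic dataset used when no input paths are given.
#'
#' @param seed master RNG seed.
#' @param out_dir output directory.
#' @param paths named list of optional input paths: genotypes_hapmap,
#'   features_ww, features_ds, expression_ww, expression_ds, gene_models,
#'   known_qtl_bed, pathways_gmt, phenotype. Missing inputs are generated
#'   synthetically at the scale given by `synth`.
#' @param synth named list of synthetic-data scale parameters (n_lines,
#'   n_snps, n_subpops, n_metabolites, n_causal, n_genes, n_cis, n_trans,
#'   pve, drought_frac, fc_log2_mean, missing_rate, redundancy, n_drivers,
#'   h2).
#' @param max_missing,rt_tol,corr_min feature-processing thresholds.
#' @param vip_min,fdr_max,fc_min drought-response gates.
#' @param maf_min,n_pc,mqtl_gap,meff,mtrait_p association-scan settings
#'   (`mtrait_p = NULL` uses 1/meff; `meff = NULL` estimates it from the
#'   data).
#' @param eqtl_p,cis_window eQTL settings.
#' @param ols_edge_p,coexp_p,n_perm,hub_alpha network settings.
#' @param folds,repeats,n_boot prediction settings.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("droughtmet_run_"),
                            paths = list(), synth = list(),
                            max_missing = 0.2, rt_tol = 0.2, corr_min = 0.95,
                            vip_min = 1, fdr_max = 0.05, fc_min = 2,
                            maf_min = 0.05, n_pc = 5L, mqtl_gap = 10000,
                            meff = NULL, mtrait_p = NULL,
                            eqtl_p = 4.2e-8, cis_window = 20000L,
                            ols_edge_p = 1e-5, coexp_p = 4.67e-9,
                            n_perm = 1000L, hub_alpha = 0.01,
                            folds = 10L, repeats = 100L, n_boot = 100L) {
  synth_defaults <- list(n_lines = 120L, n_snps = 2000L, n_subpops = 3L,
                         n_metabolites = 400L, n_causal = 40L,
                         n_genes = 60L, n_cis = 8L, n_trans = 8L, n_hub = 4L,
                         pve = 0.2, drought_frac = 0.25, fc_log2_mean = 2,
                         missing_rate = 0.1, redundancy = 0.5,
                         n_drivers = 15L, h2 = 0.6)
  synth <- utils::modifyList(synth_defaults, synth)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, paths = paths,
              synth = synth,
              max_missing = max_missing, rt_tol = rt_tol, corr_min = corr_min,
              vip_min = vip_min, fdr_max = fdr_max, fc_min = fc_min,
              maf_min = maf_min, n_pc = as.integer(n_pc), mqtl_gap = mqtl_gap,
              meff = meff, mtrait_p = mtrait_p,
              eqtl_p = eqtl_p, cis_window = as.integer(cis_window),
              ols_edge_p = ols_edge_p, coexp_p = coexp_p,
              n_perm = as.integer(n_perm), hub_alpha = hub_alpha,
              folds = as.integer(folds), repeats = as.integer(repeats),
              n_boot = as.integer(n_boot))
  for (nm in c("max_missing", "fdr_max", "hub_alpha", "eqtl_p", "ols_edge_p",
               "coexp_p")) {
    check_fraction(cfg[[nm]], nm, 0, 1, open_lo = FALSE)
  }
  for (nm in c("n_pc", "folds", "repeats", "n_boot", "n_perm")) {
    check_count(cfg[[nm]], nm)
  }
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration (JSON)
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `save_config` returns `path`; `load_config` the configuration.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$paths <- as.list(raw$paths)
  raw$synth <- as.list(raw$synth)
  do.call(pipeline_config, raw[setdiff(names(raw), character())])
}

#' @noRd
stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes feature processing, drought-response calling, metabolite GWAS
#' with mQTL clustering and candidate genes, eQTL mapping, network/hub
#' analysis and metabolomic prediction, writing per-stage outputs plus a
#' summary JSON with every count and ratio. Inputs missing from
#' `config$paths` are generated synthetically (seeded from `config$seed`).
#'
#' @param config a [pipeline_config()].
#' @return The summary list, invisibly; outputs land in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out, "config.json"))
  seed <- config$seed
  sy <- config$synth
  summary <- list(seed = seed)

  # ---- inputs -------------------------------------------------------------
  truth <- list()
  geno <- stage_error("inputs", {
    if (!is.null(config$paths$genotypes_hapmap)) {
      read_genotypes_hapmap(config$paths$genotypes_hapmap)
    } else {
      generate_genotypes(sy$n_lines, sy$n_snps, n_subpops = sy$n_subpops,
                         maf_min = config$maf_min, seed = seed)
    }
  })
  genes <- stage_error("inputs", {
    if (!is.null(config$paths$gene_models)) read_gene_models(config$paths$gene_models)
    else generate_gene_models(geno, sy$n_genes, seed = seed + 1L)
  })
  expr <- stage_error("inputs", {
    if (!is.null(config$paths$expression_ww)) {
      ww <- utils::read.delim(config$paths$expression_ww, row.names = 1L,
                              check.names = FALSE)
      ds <- utils::read.delim(config$paths$expression_ds, row.names = 1L,
                              check.names = FALSE)
      list(ww = expr_matrix(as.matrix(ww), "WW"),
           ds = expr_matrix(as.matrix(ds), "DS"), truth = NULL)
    } else {
      generate_expression(geno, genes, n_cis = sy$n_cis, n_trans = sy$n_trans,
                          pve = max(sy$pve, 0.3), seed = seed + 3L)
    }
  })
  feats <- stage_error("inputs", {
    if (!is.null(config$paths$features_ww)) {
      list(ww = read_feature_table(config$paths$features_ww, "WW"),
           ds = read_feature_table(config$paths$features_ds, "DS"),
           truth = NULL)
    } else {
      # hub genes: one active under both conditions, the rest drought-only
      hubs <- with_seed(seed + 9L,
                        sample(expr$ww$gene_ids, min(sy$n_hub,
                                                     length(expr$ww$gene_ids))))
      lw <- log2(expr$ww$values + 1)
      ld <- log2(expr$ds$values + 1)
      generate_metabolome(geno, n_metabolites = sy$n_metabolites,
                          n_causal = sy$n_causal, pve = sy$pve,
                          drought_frac = sy$drought_frac,
                          fc_log2_mean = sy$fc_log2_mean,
                          missing_rate = sy$missing_rate,
                          redundancy = sy$redundancy,
                          hub_ww = lw[hubs[1L], , drop = FALSE],
                          hub_ds = ld[hubs, , drop = FALSE],
                          seed = seed + 2L)
    }
  })
  write_genotypes_hapmap(geno, file.path(out, "genotypes.hapmap.tsv"),
                         seed = seed)
  write_gene_models(genes, file.path(out, "gene_models.gff3"))

  # ---- featproc -----------------------------------------------------------
  mm <- stage_error("featproc", {
    filt <- filter_missingness(feats$ww, feats$ds,
                               max_missing = config$max_missing)
    coll <- collapse_redundant(filt$ww, filt$ds, rt_tol = config$rt_tol,
                               corr_min = config$corr_min)
    list(ww = normalize_and_log(coll$ww), ds = normalize_and_log(coll$ds),
         n_features_in = nrow(feats$ww$meta),
         n_features_kept = length(filt$feature_ids))
  })
  write_metab_matrix(mm$ww, file.path(out, "metabolites_WW.tsv"), seed = seed)
  write_metab_matrix(mm$ds, file.path(out, "metabolites_DS.tsv"), seed = seed)
  summary$featproc <- list(n_features_in = mm$n_features_in,
                           n_features_kept = mm$n_features_kept,
                           n_metabolites = ncol(mm$ww$values))

  # ---- stressresp ---------------------------------------------------------
  dr <- stage_error("stressresp", drought_response(
    mm$ww, mm$ds, vip_min = config$vip_min, fdr_max = config$fdr_max,
    fc_min = config$fc_min))
  utils::write.table(dr$table, file.path(out, "drought_response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$stressresp <- c(dr$summary, list(
    pct_up = unname(summarize_ratios(max(dr$summary$n_up, 0),
                                     max(dr$summary$n_responsive, 1)))))

  # ---- mlmgwas ------------------------------------------------------------
  gw <- stage_error("mlmgwas", {
    responsive <- dr$table$metabolite[dr$table$responsive]
    K <- kinship(geno)
    meff <- if (!is.null(config$meff)) config$meff else
      effective_marker_count(geno)
    thr <- if (!is.null(config$mtrait_p)) config$mtrait_p else
      suggestive_threshold(meff)
    sig <- list()
    for (cond in c("WW", "DS")) {
      vals <- if (cond == "WW") mm$ww$values else mm$ds$values
      for (met in responsive) {
        scan <- mlm_scan(geno, vals[geno$line_ids, met], K = K,
                         n_pc = config$n_pc)
        s <- scan[scan$p < thr, , drop = FALSE]
        if (nrow(s)) {
          s$trait <- met
          s$condition <- cond
          sig[[length(sig) + 1L]] <- s
        }
      }
    }
    sig <- if (length(sig)) do.call(rbind, sig) else NULL
    mqtls <- cluster_mqtl(sig, gap = config$mqtl_gap)
    mqtls <- assign_candidate_genes(mqtls, genes)
    list(sig = sig, mqtls = mqtls, meff = meff, threshold = thr,
         n_traits_scanned = length(responsive))
  })
  if (!is.null(gw$sig)) {
    utils::write.table(gw$sig, file.path(out, "significant_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  flat_mqtl <- gw$mqtls
  for (lc in c("member_snps", "member_pos", "traits", "conditions",
               "candidate_genes")) {
    flat_mqtl[[lc]] <- vapply(flat_mqtl[[lc]], paste, character(1L),
                              collapse = ",")
  }
  utils::write.table(flat_mqtl, file.path(out, "mqtls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  snp_cond <- if (!is.null(gw$sig)) {
    tapply(gw$sig$condition, gw$sig$snp_id,
           function(x) paste(sort(unique(x)), collapse = "+"))
  } else character()
  n_sig_snps <- length(snp_cond)
  summary$mlmgwas <- list(
    meff = gw$meff, threshold = gw$threshold,
    n_traits_scanned = gw$n_traits_scanned,
    n_traits_with_locus = if (is.null(gw$sig)) 0L else
      length(unique(gw$sig$trait)),
    n_significant_snps = n_sig_snps,
    n_snps_ww_only = sum(snp_cond == "WW"),
    n_snps_ds_only = sum(snp_cond == "DS"),
    n_snps_shared = sum(snp_cond == "DS+WW"),
    pct_snps_shared = if (n_sig_snps) unname(summarize_ratios(
      sum(snp_cond == "DS+WW"), n_sig_snps)) else NA,
    n_mqtl = nrow(gw$mqtls),
    n_candidate_genes = length(unique(unlist(gw$mqtls$candidate_genes))),
    median_pve = if (is.null(gw$sig)) NA else stats::median(gw$sig$pve))
  if (!is.null(config$paths$known_qtl_bed) && nrow(gw$mqtls)) {
    ov <- qtl_overlap(gw$mqtls, read_known_qtl(config$paths$known_qtl_bed))
    summary$mlmgwas$pct_colocalized <- unname(summarize_ratios(
      sum(ov$colocalized), nrow(gw$mqtls)))
    summary$mlmgwas$pct_novel <- unname(summarize_ratios(
      sum(!ov$colocalized), nrow(gw$mqtls)))
  }

  # ---- eqtlmap ------------------------------------------------------------
  eq <- stage_error("eqtlmap", {
    rec_ww <- eqtl_scan(geno, expr$ww, genes, threshold = config$eqtl_p,
                        n_pc = config$n_pc, gap = config$mqtl_gap,
                        cis_window = config$cis_window)
    rec_ds <- eqtl_scan(geno, expr$ds, genes, threshold = config$eqtl_p,
                        n_pc = config$n_pc, gap = config$mqtl_gap,
                        cis_window = config$cis_window)
    classify_sharing(rec_ww, rec_ds)
  })
  utils::write.table(eq, file.path(out, "eqtls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$eqtlmap <- list(
    n_eqtl = nrow(eq),
    n_cis = sum(eq$kind == "cis"), n_trans = sum(eq$kind == "trans"),
    pct_trans = if (nrow(eq)) unname(summarize_ratios(
      sum(eq$kind == "trans"), nrow(eq))) else NA,
    n_shared = sum(eq$sharing == "shared"),
    n_dynamic = sum(eq$sharing == "dynamic"),
    pct_shared = if (nrow(eq)) unname(summarize_ratios(
      sum(eq$sharing == "shared"), nrow(eq))) else NA)

  # ---- netlink ------------------------------------------------------------
  nl <- stage_error("netlink", {
    responsive <- dr$table$metabolite[dr$table$responsive]
    res <- list()
    for (cond in c("WW", "DS")) {
      mmv <- if (cond == "WW") mm$ww else mm$ds
      ex <- if (cond == "WW") expr$ww else expr$ds
      sub <- metab_matrix(mmv$values[, intersect(responsive,
                                                 colnames(mmv$values)),
                                     drop = FALSE],
                          cond, log_transformed = TRUE)
      net <- gene_metabolite_edges(ex, sub, threshold = config$ols_edge_p)
      thr <- hub_threshold(net, n_perm = config$n_perm,
                           alpha = config$hub_alpha, seed = seed + 10L)
      res[[cond]] <- list(net = net, threshold = thr,
                          hubs = hub_calls(net, thr))
    }
    res
  })
  all_edges <- rbind(nl$WW$net$edges, nl$DS$net$edges)
  utils::write.table(all_edges, file.path(out, "gene_metabolite_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hubs <- rbind(nl$WW$hubs, nl$DS$hubs)
  utils::write.table(hubs, file.path(out, "hub_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hub_ww <- nl$WW$hubs$gene_id[nl$WW$hubs$is_hub]
  hub_ds <- nl$DS$hubs$gene_id[nl$DS$hubs$is_hub]
  n_hub <- length(union(hub_ww, hub_ds))
  summary$netlink <- list(
    n_edges_ww = nrow(nl$WW$net$edges), n_edges_ds = nrow(nl$DS$net$edges),
    hub_threshold_ww = as.integer(nl$WW$threshold),
    hub_threshold_ds = as.integer(nl$DS$threshold),
    n_hubs = n_hub,
    n_hubs_ds_specific = length(setdiff(hub_ds, hub_ww)),
    pct_hubs_ds_specific = if (n_hub) unname(summarize_ratios(
      length(setdiff(hub_ds, hub_ww)), n_hub, digits = 0L)) else NA)

  # ---- mpredict -----------------------------------------------------------
  mp <- stage_error("mpredict", {
    ph <- if (!is.null(config$paths$phenotype)) {
      long <- read_phenotype(config$paths$phenotype)
      sv <- long[long$trait == "survival", c("line", "value")]
      names(sv) <- c("line", "survival")
      list(survival = sv, truth = NULL)
    } else {
      resp <- dr$table$metabolite[dr$table$responsive]
      pool <- if (length(resp) >= sy$n_drivers) resp else colnames(mm$ds$values)
      generate_phenotype(mm$ds, n_drivers = min(sy$n_drivers,
                                                ncol(mm$ds$values)),
                         h2 = sy$h2, driver_pool = pool, seed = seed + 4L)
    }
    sv <- ph$survival[ph$survival$survival > 0, , drop = FALSE]
    lines <- intersect(sv$line, rownames(mm$ds$values))
    y <- sv$survival[match(lines, sv$line)]
    responsive <- intersect(dr$table$metabolite[dr$table$responsive],
                            colnames(mm$ds$values))
    if (length(responsive) < 2L) stop("too few responsive metabolites")
    m1 <- mm$ds$values[lines, responsive, drop = FALSE]
    rand_ids <- with_seed(seed + 5L, sample(colnames(mm$ds$values),
                                            length(responsive)))
    m3 <- mm$ds$values[lines, rand_ids, drop = FALSE]
    cv1 <- cross_validate(m1, y, k = config$folds, repeats = config$repeats,
                          seed = seed + 6L)
    cv3 <- cross_validate(m3, y, k = config$folds, repeats = config$repeats,
                          seed = seed + 6L)
    bt <- if (mean(cv3$accuracies) > 0) {
      bootstrap_ratio_test(cv1$accuracies, cv3$accuracies,
                           n_boot = config$n_boot, seed = seed + 7L)
    } else {
      # reference accuracy non-positive: the accuracy ratio is undefined
      list(statistic = NA_real_, p = NA_real_)
    }
    st <- stepwise_select(m1, y, k = 5L, cv_repeats = 10L, seed = seed + 8L)
    list(acc_responsive = mean(cv1$accuracies),
         acc_random = mean(cv3$accuracies),
         ratio = bt$statistic, ratio_p = bt$p,
         n_selected = length(st$selected), stepwise_cv_r2 = st$cv_r2,
         selected = st$selected, truth = ph$truth)
  })
  summary$mpredict <- mp[c("acc_responsive", "acc_random", "ratio",
                           "ratio_p", "n_selected", "stepwise_cv_r2")]
  writeLines(mp$selected, file.path(out, "selected_markers.txt"))

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}
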
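# Synthetic data generation with recorded ground truth.
#
# The generator emulates the structure of a diversity-panel drought study:
# structured genotypes with LD blocks (Balding-Nichols subpopulation allele
# frequencies, so both Q and K confounding exist for the mixed model to
# correct), metabolite feature tables with injected SNP effects, drought
# fold changes, redundant adduct-like duplicate features and MCAR
# missingness, expression matrices with cis/trans eQTLs, and survival-like
# phenotypes driven by a sparse metabolite subset.

#' Ground-truth record for synthetic data
#'
#' @param genotypes the [geno_matrix()] the truth refers to (used to validate
#'   that every causal SNP exists).
#' @param causal_snp_ids character vector of causal variant ids.
#' @param trait_effects named list: trait id -> list(snp_id, beta, pve).
#' @param drought_shifts named numeric vector: metabolite id -> log2 fold
#'   change injected under drought.
#' @param hub_gene_ids character vector.
#' @param metabolite_weights_on_phenotype named numeric vector.
#' @param feature_groups named character vector: feature id -> parent
#'   metabolite id (the exact answer for the redundancy-collapse step).
#' @param extra free-form list for module-specific truth (e.g. eQTL records).
#' @param seed integer.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(genotypes = NULL, causal_snp_ids = character(),
                            trait_effects = list(),
                            drought_shifts = numeric(),
                            hub_gene_ids = character(),
                            metabolite_weights_on_phenotype = numeric(),
                            feature_groups = character(),
                            extra = list(), seed = NA_integer_) {
  if (!is.null(genotypes) && length(causal_snp_ids)) {
    missing <- setdiff(causal_snp_ids, genotypes$info$snp_id)
    if (length(missing)) {
      stop_param("causal SNP(s) absent from genotypes: ",
                 paste(utils::head(missing, 3), collapse = ", "))
    }
  }
  for (tr in names(trait_effects)) {
    pve <- sum(vapply(trait_effects[[tr]], function(e) e$pve, numeric(1L)))
    if (pve <= 0 || pve > 0.95) {
      stop_param("summed PVE for trait '", tr, "' must lie in (0, 0.95]")
    }
  }
  structure(list(causal_snp_ids = causal_snp_ids, trait_effects = trait_effects,
                 drought_shifts = drought_shifts, hub_gene_ids = hub_gene_ids,
                 metabolite_weights_on_phenotype = metabolite_weights_on_phenotype,
                 feature_groups = feature_groups, extra = extra, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d causal SNPs, %d trait effects, ",
                     "%d drought shifts, %d phenotype drivers (seed %s)\n"),
              length(x$causal_snp_ids), length(x$trait_effects),
              length(x$drought_shifts),
              length(x$metabolite_weights_on_phenotype), x$seed))
  invisible(x)
}

#' Simulate structured genotypes with LD blocks
#'
#' Subpopulation allele frequencies follow a Balding-Nichols divergence model
#' around a shared ancestral frequency; within-block LD is produced by a
#' Gaussian copula whose correlation decays with physical distance and resets
#' at block boundaries, so distinct blocks are independent. SNPs are filtered
#' to realized minor-allele frequency >= `maf_min`.
#'
#' @param n_lines number of inbred lines (>= 10).
#' @param n_snps requested number of SNPs passing the MAF filter.
#' @param n_subpops number of subpopulations (lines split evenly).
#' @param ld_block_len LD block length in base pairs.
#' @param maf_min minimum realized minor-allele frequency, in (0, 0.5).
#' @param n_chrom number of chromosomes.
#' @param fst Balding-Nichols divergence parameter (ignored when
#'   `n_subpops == 1`).
#' @param mean_spacing mean inter-SNP distance in bp.
#' @param seed integer RNG seed.
#' @return A [geno_matrix()]; the subpopulation assignment of each line is
#'   attached as `attr(, "subpop")`.
#' @export
generate_genotypes <- function(n_lines, n_snps, n_subpops = 1L,
                               ld_block_len = 5000, maf_min = 0.05,
                               n_chrom = 10L, fst = 0.15,
                               mean_spacing = 2000, seed = 1L) {
  n_lines <- check_count(n_lines, "n_lines", min = 10L)
  n_snps <- check_count(n_snps, "n_snps")
  n_subpops <- check_count(n_subpops, "n_subpops")
  n_chrom <- min(check_count(n_chrom, "n_chrom"), n_snps)
  check_fraction(maf_min, "maf_min", 0, 0.5, open_lo = TRUE, open_hi = TRUE)
  if (ld_block_len <= 0) stop_param("`ld_block_len` must be positive")
  with_seed(seed, {
    n_cand <- ceiling(1.6 * n_snps)
    per_chrom <- diff(round(seq(0, n_cand, length.out = n_chrom + 1L)))
    chrom <- rep(paste0("chr", seq_len(n_chrom)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k) {
      cumsum(pmax(1, round(stats::rexp(k, rate = 1 / mean_spacing))))
    }), use.names = FALSE)
    m <- length(pos)
    # ancestral and subpopulation allele frequencies (Balding-Nichols)
    p0 <- stats::runif(m, 0.1, 0.9)
    freqs <- if (n_subpops > 1L) {
      vapply(seq_len(n_subpops), function(s) {
        stats::rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
      }, numeric(m))
    } else matrix(p0, nrow = m, ncol = 1L)
    freqs <- pmin(pmax(freqs, 0.02), 0.98)
    subpop <- rep(seq_len(n_subpops), length.out = n_lines)
    # copula correlation between consecutive SNPs, reset at block/chrom bounds
    block <- paste(chrom, floor(pos / ld_block_len))
    rho <- c(0, exp(-diff(pos) / (ld_block_len / 2)))
    rho[c(TRUE, block[-1L] != block[-m])] <- 0
    n_hap <- 2L * n_lines
    hap_pop <- rep(subpop, each = 2L)
    alleles <- matrix(0L, nrow = n_hap, ncol = m)
    z <- stats::rnorm(n_hap)
    for (j in seq_len(m)) {
      if (rho[j] > 0) {
        z <- rho[j] * z + sqrt(1 - rho[j]^2) * stats::rnorm(n_hap)
      } else {
        z <- stats::rnorm(n_hap)
      }
      alleles[, j] <- as.integer(z < stats::qnorm(freqs[j, hap_pop]))
    }
    dos <- alleles[seq(1L, n_hap, by = 2L), , drop = FALSE] +
      alleles[seq(2L, n_hap, by = 2L), , drop = FALSE]
    af <- colMeans(dos) / 2
    maf <- pmin(af, 1 - af)
    keep <- which(maf >= maf_min)
    if (length(keep) > n_snps) keep <- keep[seq_len(n_snps)]
    if (length(keep) < n_snps) {
      warning(sprintf("only %d of %d requested SNPs pass MAF >= %g",
                      length(keep), n_snps, maf_min))
    }
    base_pairs <- c("A/G", "A/T", "A/C", "C/G", "C/T", "G/T")
    info <- data.frame(
      snp_id = sprintf("%s_%d", chrom[keep], pos[keep]),
      chrom = chrom[keep], pos = pos[keep], maf = maf[keep],
      alleles = sample(base_pairs, length(keep), replace = TRUE),
      stringsAsFactors = FALSE)
    dos <- dos[, keep, drop = FALSE]
    rownames(dos) <- sprintf("line%03d", seq_len(n_lines))
    g <- geno_matrix(dos, info)
    attr(g, "subpop") <- subpop
    g
  })
}

#' Simulate gene models anchored near SNPs
#'
#' Each gene is placed so that at least one SNP lies inside or near its body,
#' guaranteeing that cis effects can be assigned downstream.
#'
#' @param genotypes a [geno_matrix()] providing the chromosome/position space.
#' @param n_genes number of genes.
#' @param gene_len_mean mean gene length in bp.
#' @param seed integer RNG seed.
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   sorted by chromosome then start.
#' @export
generate_gene_models <- function(genotypes, n_genes, gene_len_mean = 3000,
                                 seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  info <- genotypes$info
  with_seed(seed, {
    anchor <- sample.int(nrow(info), n_genes, replace = n_genes > nrow(info))
    len <- pmax(200L, round(stats::rexp(n_genes, 1 / gene_len_mean)))
    start <- pmax(1L, info$pos[anchor] - floor(stats::runif(n_genes) * len))
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = info$chrom[anchor],
      start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    genes[order(genes$chrom, genes$start), , drop = FALSE]
  })
}

#' Simulate two-condition metabolite feature tables with known truth
#'
#' Metabolite log abundances combine a baseline, an optional SNP dosage
#' effect scaled to a target PVE, an optional drought log2 fold-change shift
#' (drought-stressed condition only), and log-normal noise. Redundant
#' duplicate features share retention time within 0.2 min, carry intensities
#' correlated above 0.95 on the log scale, and alternate ionization modes.
#' Missingness is applied completely at random.
#'
#' @param genotypes a [geno_matrix()].
#' @param n_metabolites number of underlying metabolites.
#' @param n_causal number of metabolites with a causal SNP effect.
#' @param pve target per-SNP proportion of variance explained, in (0, 1).
#' @param drought_frac fraction of metabolites given a drought shift.
#' @param fc_log2_mean mean |log2 fold change| of the drought shifts.
#' @param missing_rate MCAR missingness fraction, in [0, 0.5).
#' @param redundancy expected number of duplicate features per metabolite
#'   (Poisson rate).
#' @param noise_sd residual standard deviation on the natural-log scale.
#' @param prop_up probability that a drought shift is an upregulation.
#' @param hub_ww,hub_ds optional genes x lines matrices of (log-scale)
#'   expression profiles of hub genes active under the respective condition;
#'   each hub gene drives `hub_targets` randomly chosen metabolites, making
#'   its gene-metabolite degree recoverable by the network stage.
#' @param hub_targets metabolites driven per hub gene.
#' @param hub_effect hub effect size in units of `noise_sd`.
#' @param seed integer RNG seed.
#' @return list with elements `ww`, `ds` ([feature_table()] each) and
#'   `truth` ([synthetic_truth()]); hub drivers are recorded in
#'   `truth$hub_gene_ids` and `truth$extra$hub_targets`.
#' @export
generate_metabolome <- function(genotypes, n_metabolites = 400L,
                                n_causal = 40L, pve = 0.2,
                                drought_frac = 0.25, fc_log2_mean = 2,
                                missing_rate = 0.1, redundancy = 0.5,
                                noise_sd = 0.6, prop_up = 0.85,
                                hub_ww = NULL, hub_ds = NULL,
                                hub_targets = 8L, hub_effect = 1.5,
                                seed = 1L) {
  n_metabolites <- check_count(n_metabolites, "n_metabolites")
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_metabolites) {
    stop_param("`n_causal` cannot exceed `n_metabolites`")
  }
  check_fraction(pve, "pve", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_fraction(drought_frac, "drought_frac", 0, 1)
  check_fraction(missing_rate, "missing_rate", 0, 0.5, open_hi = TRUE)
  n <- nrow(genotypes$dosages)
  line_ids <- genotypes$line_ids
  with_seed(seed, {
    met_ids <- sprintf("met%04d", seq_len(n_metabolites))
    mu <- stats::runif(n_metabolites, 10, 18)
    causal_idx <- if (n_causal > 0) sort(sample.int(n_metabolites, n_causal)) else integer()
    causal_snp <- sample.int(ncol(genotypes$dosages), n_causal, replace = TRUE)
    n_shift <- round(drought_frac * n_metabolites)
    shift_idx <- if (n_shift > 0) sort(sample.int(n_metabolites, n_shift)) else integer()
    shift_l2 <- stats::rnorm(n_shift, fc_log2_mean, 0.4) *
      ifelse(stats::runif(n_shift) < prop_up, 1, -1)

    gen_term <- matrix(0, n, n_metabolites)
    beta <- numeric(n_causal)
    for (k in seq_len(n_causal)) {
      g <- genotypes$dosages[, causal_snp[k]]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      beta[k] <- sample(c(-1, 1), 1L) * sqrt(pve / (1 - pve)) * noise_sd / stats::sd(g)
      gen_term[, causal_idx[k]] <- beta[k] * (g - mean(g))
    }
    shift_ln <- numeric(n_metabolites)
    shift_ln[shift_idx] <- shift_l2 * log(2)

    l_ww <- sweep(gen_term, 2L, mu, `+`) +
      matrix(stats::rnorm(n * n_metabolites, 0, noise_sd), n)
    l_ds <- sweep(gen_term, 2L, mu + shift_ln, `+`) +
      matrix(stats::rnorm(n * n_metabolites, 0, noise_sd), n)

    # hub-gene drivers: expression-proportional terms on chosen targets
    hub_df <- NULL
    hub_genes <- union(rownames(hub_ww), rownames(hub_ds))
    if (length(hub_genes)) {
      b <- hub_effect * noise_sd
      rows <- list()
      # hub genes preferentially regulate drought-shifted metabolites (the
      # network stage operates on the responsive subset)
      pool <- if (length(shift_idx) >= hub_targets) shift_idx else
        seq_len(n_metabolites)
      for (hg in hub_genes) {
        targets <- sample(pool, min(hub_targets, length(pool)))
        in_ww <- !is.null(hub_ww) && hg %in% rownames(hub_ww)
        in_ds <- !is.null(hub_ds) && hg %in% rownames(hub_ds)
        if (in_ww) {
          zg <- drop(scale(hub_ww[hg, line_ids]))
          l_ww[, targets] <- l_ww[, targets] + b * zg
        }
        if (in_ds) {
          zg <- drop(scale(hub_ds[hg, line_ids]))
          l_ds[, targets] <- l_ds[, targets] + b * zg
        }
        rows[[hg]] <- data.frame(gene_id = hg, metabolite = met_ids[targets],
                                 ww = in_ww, ds = in_ds,
                                 stringsAsFactors = FALSE)
      }
      hub_df <- do.call(rbind, rows)
      rownames(hub_df) <- NULL
    }

    # expand to features: one primary + Poisson(redundancy) duplicates
    n_dup <- stats::rpois(n_metabolites, redundancy)
    base_rt <- stats::runif(n_metabolites, 0.5, 16)
    base_mz <- stats::runif(n_metabolites, 100, 1500)
    base_mode <- sample(c("positive", "negative"), n_metabolites, replace = TRUE)
    meta_list <- vector("list", n_metabolites)
    ww_list <- vector("list", n_metabolites)
    ds_list <- vector("list", n_metabolites)
    for (i in seq_len(n_metabolites)) {
      k <- n_dup[i] + 1L
      fid <- sprintf("%s_f%02d", met_ids[i], seq_len(k))
      rt <- c(base_rt[i], base_rt[i] + stats::runif(k - 1L, -0.1, 0.1))
      mz <- c(base_mz[i],
              pmax(60, base_mz[i] + stats::runif(k - 1L, 10, 60) *
                     sample(c(-1, 1), k - 1L, replace = TRUE)))
      mode <- ifelse(seq_len(k) %% 2L == 1L, base_mode[i],
                     setdiff(c("positive", "negative"), base_mode[i]))
      scale_ln <- c(0, log(stats::runif(k - 1L, 0.3, 0.9)))
      ww <- ds <- matrix(0, k, n)
      for (j in seq_len(k)) {
        dup_noise_ww <- if (j == 1L) 0 else stats::rnorm(n, 0, 0.05)
        dup_noise_ds <- if (j == 1L) 0 else stats::rnorm(n, 0, 0.05)
        ww[j, ] <- exp(l_ww[, i] + scale_ln[j] + dup_noise_ww)
        ds[j, ] <- exp(l_ds[, i] + scale_ln[j] + dup_noise_ds)
      }
      meta_list[[i]] <- data.frame(feature_id = fid, mz = mz, rt = rt,
                                   mode = mode, stringsAsFactors = FALSE)
      ww_list[[i]] <- ww
      ds_list[[i]] <- ds
    }
    meta <- do.call(rbind, meta_list)
    ww_int <- do.call(rbind, ww_list)
    ds_int <- do.call(rbind, ds_list)
    colnames(ww_int) <- colnames(ds_int) <- line_ids
    if (missing_rate > 0) {
      ww_int[stats::runif(length(ww_int)) < missing_rate] <- NA
      ds_int[stats::runif(length(ds_int)) < missing_rate] <- NA
    }
    feature_groups <- stats::setNames(rep(met_ids, n_dup + 1L), meta$feature_id)
    trait_effects <- stats::setNames(lapply(seq_len(n_causal), function(k) {
      list(list(snp_id = genotypes$info$snp_id[causal_snp[k]],
                beta = beta[k], pve = pve))
    }), met_ids[causal_idx])
    truth <- synthetic_truth(
      genotypes = genotypes,
      causal_snp_ids = genotypes$info$snp_id[causal_snp],
      trait_effects = trait_effects,
      drought_shifts = stats::setNames(shift_l2, met_ids[shift_idx]),
      hub_gene_ids = hub_genes,
      feature_groups = feature_groups,
      extra = if (is.null(hub_df)) list() else list(hub_targets = hub_df),
      seed = seed)
    list(ww = feature_table(meta, ww_int, "WW"),
         ds = feature_table(meta, ds_int, "DS"),
         truth = truth)
  })
}

#' Simulate two-condition expression matrices with cis/trans eQTLs
#'
#' Cis effects are assigned to a SNP within 20 kb of the target gene body,
#' trans effects to a SNP more than 1 Mb away or on another chromosome. A
#' configurable fraction of effects is active under only one condition; the
#' truth records which.
#'
#' @param genotypes a [geno_matrix()].
#' @param gene_models data.frame from [generate_gene_models()] (or
#'   [read_gene_models()]); must be sorted by chromosome and start.
#' @param n_cis,n_trans numbers of cis and trans effects.
#' @param pve target per-SNP proportion of expression variance, in (0, 1).
#' @param condition_specific_frac fraction of effects active in one condition
#'   only.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param cis_window cis window in bp around the gene body.
#' @param seed integer RNG seed.
#' @return list with `ww`, `ds` ([expr_matrix()] each) and `truth`; the truth
#'   `extra$eqtl` data.frame has columns gene_id, snp_id, kind, ww, ds.
#' @export
generate_expression <- function(genotypes, gene_models, n_cis = 10L,
                                n_trans = 10L, pve = 0.3,
                                condition_specific_frac = 0.5,
                                noise_sd = 1, cis_window = 20000L, seed = 1L) {
  n_cis <- check_count(n_cis, "n_cis", min = 0L)
  n_trans <- check_count(n_trans, "n_trans", min = 0L)
  check_fraction(pve, "pve", 0, 1, open_lo = TRUE, open_hi = TRUE)
  genes <- gene_models[order(gene_models$chrom, gene_models$start), , drop = FALSE]
  info <- genotypes$info
  n <- nrow(genotypes$dosages)
  n_genes <- nrow(genes)
  cis_snps <- lapply(seq_len(n_genes), function(i) {
    which(info$chrom == genes$chrom[i] &
            info$pos >= genes$start[i] - cis_window &
            info$pos <= genes$end[i] + cis_window)
  })
  if (n_cis > 0 && !any(lengths(cis_snps) > 0)) {
    stop_param("no SNP available within ", cis_window, " bp of any gene")
  }
  with_seed(seed, {
    mu <- stats::runif(n_genes, 2, 8)
    eff <- data.frame(gene = integer(), snp = integer(), kind = character(),
                      ww = logical(), ds = logical())
    has_cis <- which(lengths(cis_snps) > 0)
    if (n_cis > length(has_cis)) {
      stop_param("only ", length(has_cis), " genes have a SNP within the cis window")
    }
    cis_genes <- sample(has_cis, n_cis)
    for (gi in cis_genes) {
      eff <- rbind(eff, data.frame(gene = gi,
                                   snp = cis_snps[[gi]][sample.int(length(cis_snps[[gi]]), 1L)],
                                   kind = "cis", ww = TRUE, ds = TRUE))
    }
    trans_pool <- setdiff(seq_len(n_genes), cis_genes)
    trans_genes <- sample(trans_pool, min(n_trans, length(trans_pool)))
    for (gi in trans_genes) {
      far <- which(info$chrom != genes$chrom[gi] |
                     abs(info$pos - genes$start[gi]) > 1e6)
      if (!length(far)) stop_param("no SNP available > 1 Mb from gene ",
                                   genes$gene_id[gi])
      eff <- rbind(eff, data.frame(gene = gi, snp = far[sample.int(length(far), 1L)],
                                   kind = "trans", ww = TRUE, ds = TRUE))
    }
    if (nrow(eff)) {
      spec <- stats::runif(nrow(eff)) < condition_specific_frac
      ds_only <- stats::runif(nrow(eff)) < 0.5
      eff$ww[spec & ds_only] <- FALSE
      eff$ds[spec & !ds_only] <- FALSE
    }
    make_cond <- function(active_col) {
      l <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n) + mu
      for (r in seq_len(nrow(eff))) {
        if (!eff[[active_col]][r]) next
        g <- genotypes$dosages[, eff$snp[r]]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        b <- sqrt(pve / (1 - pve)) * noise_sd / stats::sd(g)
        l[eff$gene[r], ] <- l[eff$gene[r], ] + b * (g - mean(g))
      }
      v <- pmax(2^l - 1, 0) # pmax keeps the matrix shape of its first arg
      rownames(v) <- genes$gene_id
      colnames(v) <- genotypes$line_ids
      v
    }
    ww <- make_cond("ww")
    ds <- make_cond("ds")
    truth <- synthetic_truth(
      genotypes = genotypes,
      causal_snp_ids = info$snp_id[eff$snp],
      extra = list(eqtl = data.frame(
        gene_id = genes$gene_id[eff$gene], snp_id = info$snp_id[eff$snp],
        kind = eff$kind, ww = eff$ww, ds = eff$ds, stringsAsFactors = FALSE)),
      seed = seed)
    list(ww = expr_matrix(ww, "WW"), ds = expr_matrix(ds, "DS"), truth = truth)
  })
}

#' Simulate survival-rate and biomass phenotypes driven by metabolites
#'
#' A weighted sum of `n_drivers` standardized metabolite abundances plus noise
#' scaled to heritability `h2` is squashed through a logistic function to give
#' a survival-rate-like phenotype in \[0, 1\]. Fresh weight and dry mass are
#' produced per environment x replicate for mixed-model BLUP testing.
#'
#' @param metabolome a [metab_matrix()] (drought-stressed condition).
#' @param n_drivers number of driver metabolites.
#' @param h2 heritability of the latent trait, in (0, 1).
#' @param driver_pool optional metabolite ids to draw the drivers from
#'   (e.g. the drought-responsive subset); default all metabolites.
#' @param n_env,n_rep environments and replicates for the biomass table.
#' @param seed integer RNG seed.
#' @return list with `survival` (data.frame line, survival), `biomass`
#'   (long-format data.frame) and `truth`.
#' @export
generate_phenotype <- function(metabolome, n_drivers = 15L, h2 = 0.6,
                               driver_pool = NULL, n_env = 2L, n_rep = 2L,
                               seed = 1L) {
  n_drivers <- check_count(n_drivers, "n_drivers")
  check_fraction(h2, "h2", 0, 1)
  vals <- metabolome$values
  pool <- if (is.null(driver_pool)) seq_len(ncol(vals)) else
    which(colnames(vals) %in% driver_pool)
  if (n_drivers > length(pool)) {
    stop_param("`n_drivers` exceeds the number of eligible metabolites")
  }
  n <- nrow(vals)
  with_seed(seed, {
    drivers <- sort(sample(pool, n_drivers))
    w <- stats::runif(n_drivers, 0.5, 1.5) *
      sample(c(-1, 1), n_drivers, replace = TRUE)
    z <- scale(vals[, drivers, drop = FALSE])
    z[is.na(z)] <- 0
    g <- drop(z %*% w)
    g_std <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
    latent <- sqrt(h2) * g_std + sqrt(1 - h2) * stats::rnorm(n)
    survival <- stats::plogis(latent)
    lines <- rownames(vals)
    biomass <- expand.grid(line = lines, environment = paste0("env", seq_len(n_env)),
                           replicate = paste0("rep", seq_len(n_rep)),
                           trait = c("fresh_weight", "dry_mass"),
                           stringsAsFactors = FALSE)
    env_eff <- stats::setNames(stats::rnorm(n_env, 0, 1), paste0("env", seq_len(n_env)))
    rep_eff <- stats::rnorm(n_env * n_rep, 0, 0.5)
    names(rep_eff) <- as.vector(outer(paste0("env", seq_len(n_env)),
                                      paste0("rep", seq_len(n_rep)), paste, sep = ":"))
    line_eff <- stats::setNames(0.7 * g_std + stats::rnorm(n, 0, 0.5), lines)
    trait_mu <- c(fresh_weight = 10, dry_mass = 2)
    biomass$value <- trait_mu[biomass$trait] + env_eff[biomass$environment] +
      rep_eff[paste(biomass$environment, biomass$replicate, sep = ":")] +
      line_eff[biomass$line] + stats::rnorm(nrow(biomass), 0, 0.5)
    truth <- synthetic_truth(
      metabolite_weights_on_phenotype = stats::setNames(w, colnames(vals)[drivers]),
      seed = seed)
    list(survival = data.frame(line = lines, survival = survival,
                               stringsAsFactors = FALSE),
         biomass = biomass, truth = truth)
  })
}
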
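test_that("generators are deterministic under a fixed seed", {
  g1 <- generate_genotypes(60, 150, n_subpops = 2, seed = 5)
  g2 <- generate_genotypes(60, 150, n_subpops = 2, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$info, g2$info)
  m1 <- generate_metabolome(g1, n_metabolites = 30, n_causal = 5, seed = 9)
  m2 <- generate_metabolome(g2, n_metabolites = 30, n_causal = 5, seed = 9)
  expect_identical(m1$ww$intensities, m2$ww$intensities)
  expect_identical(m1$truth$drought_shifts, m2$truth$drought_shifts)
  # the generators restore global RNG state
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(generate_genotypes(12, 20, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generator parameter validation rejects bad inputs", {
  expect_error(generate_genotypes(5, 100), "n_lines")
  expect_error(generate_genotypes(20, 0), "n_snps")
  expect_error(generate_genotypes(20, 50, maf_min = 0.7), "maf_min")
  g <- small_geno(20, 40)
  expect_error(generate_metabolome(g, n_metabolites = 5, n_causal = 9),
               "n_causal")
  expect_error(generate_phenotype(
    metab_matrix(matrix(1, 20, 3, dimnames = list(sprintf("line%03d", 1:20),
                                                  c("a", "b", "c"))), "DS"),
    n_drivers = 10), "n_drivers")
})

test_that("genotypes respect MAF floor, dosage coding and LD structure", {
  g <- generate_genotypes(400, 300, n_subpops = 1, ld_block_len = 1, seed = 21)
  expect_true(all(g$dosages %in% 0:2))
  expect_true(all(g$info$maf >= 0.05))
  # 1-bp blocks: every SNP is its own block; pairwise |r| vanishes
  idx <- seq(1, ncol(g$dosages), by = 3)
  r <- cor(g$dosages[, idx])
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
  # with long blocks, nearby SNPs are correlated
  g2 <- generate_genotypes(200, 200, ld_block_len = 20000, seed = 22)
  same_block <- outer(g2$info$chrom, g2$info$chrom, "==") &
    abs(outer(g2$info$pos, g2$info$pos, "-")) < 2000
  r2 <- cor(g2$dosages)
  near <- same_block & upper.tri(same_block)
  expect_gt(mean(abs(r2[near])), 0.3)
})

test_that("two subpopulations separate on the leading principal component", {
  g <- generate_genotypes(120, 400, n_subpops = 2, seed = 31)
  sp <- attr(g, "subpop")
  # independent eigen-decomposition oracle on the emitted matrix
  x <- scale(g$dosages, scale = FALSE)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  pc1 <- drop(x %*% ev$vectors[, 1L])
  sil <- vapply(seq_along(pc1), function(i) {
    own <- abs(pc1[i] - pc1[sp == sp[i]])
    a <- mean(own[own > 0])
    b <- mean(abs(pc1[i] - pc1[sp != sp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("metabolome respects missingness, null case, and target PVE", {
  g0 <- small_geno(100, 100, seed = 41)
  m0 <- generate_metabolome(g0, n_metabolites = 40, n_causal = 0,
                            missing_rate = 0, seed = 42)
  expect_false(anyNA(m0$ww$intensities))
  expect_false(anyNA(m0$ds$intensities))
  # null case: no drought effect -> uniform paired-test p-values
  mn <- generate_metabolome(g0, n_metabolites = 120, n_causal = 0,
                            drought_frac = 0, fc_log2_mean = 0,
                            missing_rate = 0, redundancy = 0, seed = 43)
  pv <- vapply(seq_len(nrow(mn$ww$meta)), function(i) {
    stats::t.test(log(mn$ds$intensities[i, ]) - log(mn$ww$intensities[i, ]))$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # per-trait OLS oracle: causal SNP R^2 near the target PVE at n = 385
  g <- generate_genotypes(385, 200, seed = 44)
  m <- generate_metabolome(g, n_metabolites = 60, n_causal = 30, pve = 0.2,
                           missing_rate = 0, redundancy = 0, seed = 45)
  r2 <- vapply(names(m$truth$trait_effects), function(tr) {
    snp <- m$truth$trait_effects[[tr]][[1]]$snp_id
    y <- log(m$ds$intensities[paste0(tr, "_f01"), ])
    summary(stats::lm(y ~ g$dosages[, snp]))$r.squared
  }, numeric(1))
  expect_gt(median(r2), 0.15)
  expect_lt(median(r2), 0.25)
  expect_true(all(abs(r2 - 0.2) < 0.1))
})

test_that("redundant duplicate features satisfy the grouping criteria", {
  g <- small_geno(80, 60, seed = 51)
  m <- generate_metabolome(g, n_metabolites = 25, n_causal = 0,
                           missing_rate = 0, redundancy = 1.2, seed = 52)
  meta <- m$ww$meta
  grp <- m$truth$feature_groups[meta$feature_id]
  for (met in unique(grp)) {
    idx <- which(grp == met)
    if (length(idx) < 2) next
    expect_lt(diff(range(meta$rt[idx])), 0.2 + 1e-9)
    prof <- log(cbind(m$ww$intensities, m$ds$intensities)[idx, , drop = FALSE])
    r <- cor(t(prof))
    expect_gt(min(r[upper.tri(r)]), 0.95)
  }
  # duplicates alternate ionization mode
  multi <- names(which(table(grp) >= 2))[1]
  idx <- which(grp == multi)
  expect_gt(length(unique(meta$mode[idx])), 1L)
})

test_that("expression eQTL injection matches truth and the null is flat", {
  g <- generate_genotypes(200, 200, seed = 61)
  gm <- generate_gene_models(g, 20, seed = 62)
  ex0 <- generate_expression(g, gm, n_cis = 0, n_trans = 0, seed = 63)
  l <- log2(ex0$ww$values + 1)
  max_r <- apply(abs(cor(t(l), g$dosages)), 1L, max)
  expect_true(all(max_r < 0.3))
  # cis pairs lie within 20 kb of the gene by construction
  g2 <- generate_genotypes(300, 300, seed = 64)
  gm2 <- generate_gene_models(g2, 25, seed = 65)
  ex <- generate_expression(g2, gm2, n_cis = 8, n_trans = 5, pve = 0.3,
                            condition_specific_frac = 0, seed = 66)
  tt <- ex$truth$extra$eqtl
  for (i in which(tt$kind == "cis")) {
    gi <- gm2[gm2$gene_id == tt$gene_id[i], ]
    si <- g2$info[g2$info$snp_id == tt$snp_id[i], ]
    expect_identical(gi$chrom, si$chrom)
    expect_true(si$pos >= gi$start - 20000 && si$pos <= gi$end + 20000)
  }
  # OLS oracle: single-SNP R^2 at the causal SNP near the 0.3 target
  r2 <- vapply(seq_len(nrow(tt)), function(i) {
    y <- log2(ex$ww$values[tt$gene_id[i], ] + 1)
    summary(stats::lm(y ~ g2$dosages[, tt$snp_id[i]]))$r.squared
  }, numeric(1))
  expect_gt(median(r2), 0.22)
  expect_lt(median(r2), 0.38)
})

test_that("phenotype heritability scaling behaves in the limits", {
  g <- small_geno(300, 60, seed = 71)
  m <- generate_metabolome(g, n_metabolites = 50, n_causal = 0,
                           missing_rate = 0, redundancy = 0, seed = 72)
  mm <- normalize_and_log(collapse_redundant(m$ww, m$ds)$ds)
  # h2 -> 1 with a single driver: survival is monotone in that metabolite
  p1 <- generate_phenotype(mm, n_drivers = 1, h2 = 0.999, seed = 73)
  drv <- names(p1$truth$metabolite_weights_on_phenotype)
  rho <- cor(p1$survival$survival, mm$values[, drv], method = "spearman")
  expect_gt(abs(rho), 0.99)
  # h2 = 0: no model can predict
  p0 <- generate_phenotype(mm, n_drivers = 10, h2 = 0, seed = 74)
  d0 <- names(p0$truth$metabolite_weights_on_phenotype)
  z <- scale(mm$values[, d0]) %*% p0$truth$metabolite_weights_on_phenotype
  expect_lt(abs(cor(p0$survival$survival, z)), 0.15)
  # h2 = 0.6 with 15 drivers: OLS on the truth set lands near h2
  p6 <- generate_phenotype(mm, n_drivers = 15, h2 = 0.6, seed = 75)
  d6 <- names(p6$truth$metabolite_weights_on_phenotype)
  r2 <- summary(stats::lm(p6$survival$survival ~ mm$values[, d6]))$r.squared
  expect_gt(r2, 0.5)
  expect_lt(r2, 0.7)
  expect_true(all(p6$survival$survival >= 0 & p6$survival$survival <= 1))
})

test_that("emitted files round-trip losslessly through the package readers", {
  dir <- withr::local_tempdir()
  g <- small_geno(30, 50, seed = 81)
  write_genotypes_hapmap(g, file.path(dir, "geno.tsv"), seed = 81)
  g2 <- read_genotypes_hapmap(file.path(dir, "geno.tsv"))
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$info$pos, g$info$pos)
  m <- generate_metabolome(g, n_metabolites = 15, n_causal = 2,
                           missing_rate = 0.1, seed = 82)
  write_feature_table(m$ww, file.path(dir, "ww.tsv"), seed = 82)
  ww2 <- read_feature_table(file.path(dir, "ww.tsv"))
  expect_equal(ww2$condition, "WW") # from the sidecar
  expect_equal(ww2$intensities, m$ww$intensities, tolerance = 1e-12)
  expect_equal(ww2$meta$rt, m$ww$meta$rt, tolerance = 1e-12)
  mm <- normalize_and_log(collapse_redundant(
    filter_missingness(m$ww, m$ds)$ww,
    filter_missingness(m$ww, m$ds)$ds)$ds)
  write_metab_matrix(mm, file.path(dir, "mm.tsv"))
  mm2 <- read_metab_matrix(file.path(dir, "mm.tsv"))
  expect_equal(mm2$values, mm$values, tolerance = 1e-12)
  expect_equal(mm2$group_map, mm$group_map)
  expect_true(mm2$log_transformed)
  gm <- generate_gene_models(g, 10, seed = 83)
  write_gene_models(gm, file.path(dir, "genes.gff3"))
  gm2 <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(gm2[, c("gene_id", "chrom", "start", "end")],
               gm[, c("gene_id", "chrom", "start", "end")],
               ignore_attr = TRUE)
  ph <- generate_phenotype(mm, n_drivers = 3, h2 = 0.5, seed = 84)
  write_phenotype(ph$biomass, file.path(dir, "pheno.tsv"))
  ph2 <- read_phenotype(file.path(dir, "pheno.tsv"))
  expect_equal(ph2$value, ph$biomass$value, tolerance = 1e-12)
  # sidecars carry the seed
  side <- jsonlite::read_json(file.path(dir, "geno.tsv.json"))
  expect_equal(side$seed, 81)
})

test_that("synthetic truth validates its invariants", {
  g <- small_geno(20, 30)
  expect_error(synthetic_truth(g, causal_snp_ids = "nope"), "absent")
  expect_error(synthetic_truth(
    g, trait_effects = list(tr = list(list(snp_id = g$info$snp_id[1],
                                           beta = 1, pve = 0.99)))),
    "PVE")
})
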
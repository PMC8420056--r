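test_that("kinship matches the hand formula and is PSD", {
  # 3 lines x 2 SNPs toy: W = dosages - 2p, K = WW'/(2 sum p(1-p))
  dos <- matrix(c(0, 1, 2,
                  2, 2, 0), 3, 2)
  g <- manual_geno(dos, rep("chr1", 2), c(100, 200))
  p <- colMeans(dos) / 2
  w <- sweep(dos, 2, 2 * p)
  k_manual <- tcrossprod(w) / (2 * sum(p * (1 - p)))
  expect_equal(kinship(g), k_manual, tolerance = 1e-12, ignore_attr = TRUE)
  # identical lines are as related to each other as to themselves
  dos2 <- rbind(c(0, 2, 1, 0), c(0, 2, 1, 0), c(2, 0, 1, 2))
  g2 <- manual_geno(dos2, rep("chr1", 4), 1:4 * 100)
  k2 <- kinship(g2)
  expect_equal(k2[1, 2], k2[1, 1], tolerance = 1e-12)
  # Gram-matrix property on random data
  g3 <- small_geno(50, 200, seed = 3)
  expect_gt(min(eigen(kinship(g3), symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  mono <- manual_geno(matrix(2, 3, 2), rep("chr1", 2), c(1, 2))
  expect_error(kinship(mono), "monomorphic")
})

test_that("MLM with identity kinship equals the OLS t-test per SNP", {
  g <- small_geno(80, 120, seed = 5)
  set.seed(6)
  y <- rnorm(80)
  scan <- mlm_scan(g, y, K = diag(80), n_pc = 0)
  ols_p <- apply(g$dosages, 2, function(x) {
    summary(stats::lm(y ~ x))$coefficients[2, 4]
  })
  expect_lt(max(abs(log10(scan$p) - log10(ols_p))), 1e-6)
})

test_that("forcing zero polygenic variance reduces the MLM to PC-adjusted OLS", {
  g <- small_geno(60, 80, seed = 7)
  set.seed(8)
  y <- rnorm(60)
  scan <- mlm_scan(g, y, n_pc = 3, var_ratio = Inf)
  pcs <- genotype_pcs(g, 3)
  ols <- apply(g$dosages, 2, function(x) {
    summary(stats::lm(y ~ pcs + x))$coefficients["x", ]
  })
  expect_equal(scan$p, unname(ols[4, ]), tolerance = 1e-9)
  expect_equal(scan$beta, unname(ols[1, ]), tolerance = 1e-9)
})

test_that("MLM results are invariant to line reordering", {
  g <- small_geno(50, 60, seed = 9)
  met <- generate_metabolome(g, n_metabolites = 5, n_causal = 2, pve = 0.3,
                             missing_rate = 0, redundancy = 0, seed = 10)
  y <- log(met$ds$intensities[1, ])
  s1 <- mlm_scan(g, y, n_pc = 2)
  perm <- sample(nrow(g$dosages))
  gp <- geno_matrix(g$dosages[perm, ], g$info)
  s2 <- mlm_scan(gp, y[perm], n_pc = 2)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
  expect_error(mlm_scan(g, rep(1, 50)), "constant")
})

test_that("the scan finds an injected causal SNP and reports its PVE", {
  g <- generate_genotypes(385, 300, n_subpops = 2, seed = 11)
  met <- generate_metabolome(g, n_metabolites = 4, n_causal = 2, pve = 0.2,
                             missing_rate = 0, redundancy = 0, seed = 12)
  tr <- names(met$truth$trait_effects)[1]
  causal <- met$truth$trait_effects[[tr]][[1]]$snp_id
  y <- log(met$ds$intensities[paste0(tr, "_f01"), ])
  scan <- mlm_scan(g, y, n_pc = 5)
  thr <- suggestive_threshold(effective_marker_count(g))
  expect_lt(scan$p[scan$snp_id == causal], thr)
  expect_gt(scan$pve[scan$snp_id == causal], 0.1)
  expect_lt(scan$pve[scan$snp_id == causal], 0.35)
  expect_true(all(scan$p > 0 & scan$p <= 1))
})

test_that("suggestive threshold is the reciprocal effective marker count", {
  expect_equal(suggestive_threshold(100), 0.01)
  expect_equal(suggestive_threshold(474242), 1 / 474242, tolerance = 1e-15)
  expect_error(suggestive_threshold(0.5), "meff")
})

test_that("effective marker count matches eigen oracles on designed LD", {
  # factorial design: three mutually orthogonal SNP columns
  d1 <- c(0, 0, 0, 0, 2, 2, 2, 2)
  d2 <- c(0, 0, 2, 2, 0, 0, 2, 2)
  d3 <- c(0, 2, 0, 2, 0, 2, 0, 2)
  g_ind <- manual_geno(cbind(d1, d2, d3), rep("chr1", 3), c(100, 200, 300))
  expect_equal(effective_marker_count(g_ind), 3L)
  # perfectly correlated copies collapse to one
  g_dup <- manual_geno(cbind(d1, d1, d1, d1), rep("chr1", 4), 1:4 * 100)
  expect_equal(effective_marker_count(g_dup), 1L)
  # two independent blocks of two duplicated SNPs -> Meff = 2,
  # matching the eigen decomposition of the 4x4 correlation matrix
  g_blk <- manual_geno(cbind(d1, d1, d2, d2), rep("chr1", 4), 1:4 * 100)
  expect_equal(effective_marker_count(g_blk), 2L)
  ev <- eigen(cor(cbind(d1, d1, d2, d2)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(which(cumsum(ev) / sum(ev) >= 0.995)[1], 2L)
  # never below the chromosome count
  g_two <- manual_geno(cbind(d1, d1), c("chr1", "chr2"), c(100, 100))
  expect_gte(effective_marker_count(g_two), 2L)
})

test_that("mQTL clustering follows the strict 10-kb chain rule", {
  sig <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(100, 5000, 30000), p = c(1e-8, 1e-9, 1e-7),
                    stringsAsFactors = FALSE)
  out <- cluster_mqtl(sig)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$n_snps), c(1L, 2L))
  expect_equal(out$peak_snp[out$n_snps == 2], "b")
  expect_equal(out$start[1], 100); expect_equal(out$end[1], 5000)
  # same position on two chromosomes never merges
  sig2 <- data.frame(snp_id = c("a", "b"), chrom = c("chr1", "chr2"),
                     pos = c(500, 500), p = c(1e-8, 1e-8))
  expect_equal(nrow(cluster_mqtl(sig2)), 2L)
  # a gap of exactly 10 kb does NOT merge (strict <)
  sig3 <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                     pos = c(1000, 11000), p = c(1e-8, 1e-8))
  expect_equal(nrow(cluster_mqtl(sig3)), 2L)
  expect_equal(nrow(cluster_mqtl(sig3, gap = 10001)), 1L)
  expect_equal(nrow(cluster_mqtl(sig3[0, ])), 0L)
})

test_that("mQTL clustering equals the O(n^2) closure oracle and is idempotent", {
  set.seed(13)
  n <- 200
  sig <- data.frame(snp_id = sprintf("s%03d", 1:n),
                    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
                    pos = sample.int(3e5, n), p = runif(n, 1e-12, 1e-6),
                    stringsAsFactors = FALSE)
  sig <- sig[!duplicated(sig[, c("chrom", "pos")]), ]
  out <- cluster_mqtl(sig)
  oracle <- closure_oracle(sig$chrom, sig$pos, 10000)
  got <- integer(nrow(sig))
  for (i in seq_len(nrow(out))) {
    got[match(out$member_snps[[i]], sig$snp_id)] <- i
  }
  expect_equal(rand_index(got, oracle), 1)
  expect_equal(sapply(seq_len(nrow(out)), function(i) {
    min(sig$p[match(out$member_snps[[i]], sig$snp_id)])
  }), out$peak_p)
  # idempotence: re-clustering the members reproduces the partition
  again <- cluster_mqtl(sig)
  expect_identical(out$member_snps, again$member_snps)
})

test_that("candidate genes require a member SNP inside the gene body", {
  sig <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                    pos = c(1500, 1000), p = c(1e-8, 1e-9))
  mqtls <- cluster_mqtl(sig)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(1000, 3000, 1501), end = c(2000, 4000, 1600),
                      stringsAsFactors = FALSE)
  out <- assign_candidate_genes(mqtls, genes)
  expect_equal(out$candidate_genes[[1]], "g1") # 1500 in [1000,2000]; boundary 1000 in g1
  # exact boundary: SNP at the gene start is inside (inclusive)
  sig2 <- data.frame(snp_id = "x", chrom = "chr1", pos = 3000, p = 1e-8)
  out2 <- assign_candidate_genes(cluster_mqtl(sig2), genes)
  expect_equal(out2$candidate_genes[[1]], "g2")
  # random SNPs x genes vs brute-force interval membership
  set.seed(15)
  sig3 <- data.frame(snp_id = sprintf("s%02d", 1:50), chrom = "chr1",
                     pos = sample.int(50000, 50), p = runif(50, 1e-10, 1e-6))
  genes3 <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                       start = sample.int(45000, 20), stringsAsFactors = FALSE)
  genes3$end <- genes3$start + sample.int(3000, 20)
  out3 <- assign_candidate_genes(cluster_mqtl(sig3), genes3)
  for (i in seq_len(nrow(out3))) {
    pos <- out3$member_pos[[i]]
    oracle <- genes3$gene_id[vapply(seq_len(20), function(j) {
      any(pos >= genes3$start[j] & pos <= genes3$end[j])
    }, logical(1))]
    expect_setequal(out3$candidate_genes[[i]], oracle)
  }
})

test_that("known-QTL overlap uses the at-least-1-bp rule", {
  sig <- data.frame(snp_id = c("a", "b"), chrom = c("chr1", "chr2"),
                    pos = c(100, 100), p = c(1e-8, 1e-8))
  mq <- cluster_mqtl(sig)
  mq$start <- c(100, 100); mq$end <- c(200, 200)
  known <- data.frame(chrom = "chr1", start = 150, end = 300)
  ov <- qtl_overlap(mq, known)
  expect_equal(ov$colocalized, c(TRUE, FALSE))
  expect_equal(ov$fraction, 0.5)
  # adjacent but not overlapping
  known2 <- data.frame(chrom = "chr1", start = 201, end = 300)
  expect_false(qtl_overlap(mq, known2)$colocalized[1])
  # random intervals vs brute-force pairwise check
  set.seed(17)
  mq2 <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                    start = sample.int(10000, 30))
  mq2$end <- mq2$start + sample.int(500, 30)
  kn <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                   start = sample.int(10000, 15))
  kn$end <- kn$start + sample.int(800, 15)
  got <- qtl_overlap(mq2, kn)$colocalized
  oracle <- vapply(seq_len(30), function(i) {
    any(kn$chrom == mq2$chrom[i] & kn$start <= mq2$end[i] &
          kn$end >= mq2$start[i])
  }, logical(1))
  expect_equal(got, oracle)
})

test_that("BED known-QTL input converts to 1-based closed coordinates", {
  dir <- withr::local_tempdir()
  writeLines("chr1\t99\t200\tqtl1", file.path(dir, "known.bed"))
  kq <- read_known_qtl(file.path(dir, "known.bed"))
  expect_equal(kq$start, 100)
  expect_equal(kq$end, 200)
})
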
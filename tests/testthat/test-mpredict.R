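test_that("ridge solution at fixed lambda equals the normal-equations solve", {
  set.seed(3)
  m <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(12)
  fit <- rrblup_fit(m, y, lambda = 2)
  mc <- scale(m, scale = FALSE)
  vinv <- solve(tcrossprod(mc) + 2 * diag(12))
  one <- rep(1, 12)
  mu <- drop(crossprod(one, vinv %*% y) / crossprod(one, vinv %*% one))
  alpha <- drop(crossprod(mc, vinv %*% (y - mu)))
  expect_equal(unname(fit$alpha), unname(alpha), tolerance = 1e-9)
  expect_equal(fit$mu, mu, tolerance = 1e-9)
  # equivalent ridge normal equations: alpha = (M'M + lambda I)^-1 M'(y - mu)
  alpha2 <- solve(crossprod(mc) + 2 * diag(3), crossprod(mc, y - mu))
  expect_equal(unname(fit$alpha), unname(drop(alpha2)), tolerance = 1e-9)
})

test_that("noiseless response drives lambda to zero and r to one", {
  set.seed(5)
  m <- matrix(rnorm(40 * 60), 40, 60)
  colnames(m) <- paste0("m", 1:60)
  y <- drop(m %*% rnorm(60, 0, 0.3))
  fit <- rrblup_fit(m, y)
  expect_gt(cor(predict(fit, m), y), 0.999)
  expect_error(rrblup_fit(m, rep(1, 40)), "distinct")
  expect_error(rrblup_fit(m[1:5, ], y[1:5]), "10")
})

test_that("cross-validation is seeded, fold-exact and honest under the null", {
  set.seed(7)
  m <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(m %*% runif(10)) + rnorm(30, 0, 0.5)
  cv <- cross_validate(m, y, k = 3, repeats = 2, seed = 42)
  # fold partition equals the documented seeded shuffle, re-run independently
  oracle <- withr::with_seed(42, sample(rep(1:3, length.out = 30)))
  expect_equal(cv$folds[, 1], oracle)
  expect_true(all(table(cv$folds[, 1]) == 10))
  # every line predicted exactly once per repeat
  expect_equal(sort(unique(cv$folds[, 2])), 1:3)
  cv2 <- cross_validate(m, y, k = 3, repeats = 2, seed = 42)
  expect_identical(cv$accuracies, cv2$accuracies)
  expect_error(cross_validate(m, y, k = 40), "exceed")
  # independent response: accuracy near zero
  set.seed(8)
  m0 <- matrix(rnorm(300 * 20), 300, 20)
  y0 <- rnorm(300)
  cv0 <- cross_validate(m0, y0, k = 10, repeats = 5, seed = 9)
  expect_lt(abs(mean(cv0$accuracies)), 0.1)
})

test_that("prediction accuracy tracks heritability on synthetic phenotypes", {
  g <- generate_genotypes(300, 80, seed = 11)
  met <- generate_metabolome(g, n_metabolites = 60, n_causal = 0,
                             missing_rate = 0, redundancy = 0, seed = 12)
  mm <- normalize_and_log(collapse_redundant(met$ww, met$ds)$ds)
  ph <- generate_phenotype(mm, n_drivers = 15, h2 = 0.6, seed = 13)
  cv <- cross_validate(mm$values, ph$survival$survival, k = 10, repeats = 3,
                       seed = 14)
  expect_gt(mean(cv$accuracies), 0.55)
  expect_lt(mean(cv$accuracies), 0.85)
  # the true driver set beats an equal-size random set (paired comparison)
  drivers <- names(ph$truth$metabolite_weights_on_phenotype)
  others <- setdiff(colnames(mm$values), drivers)
  cv_true <- cross_validate(mm$values[, drivers], ph$survival$survival,
                            k = 10, repeats = 10, seed = 15)
  cv_rand <- cross_validate(mm$values[, sample(others, length(drivers))],
                            ph$survival$survival, k = 10, repeats = 10,
                            seed = 15)
  expect_lt(stats::wilcox.test(cv_true$accuracies, cv_rand$accuracies,
                               alternative = "greater")$p.value, 0.01)
  bt <- bootstrap_ratio_test(cv_true$accuracies, cv_rand$accuracies,
                             n_boot = 200, seed = 16)
  expect_gt(bt$statistic, 1)
})

test_that("bootstrap ratio p matches exhaustive enumeration and edge cases", {
  acc <- c(0.5, 0.6, 0.7, 0.55, 0.65)
  # identical vectors: ratio exactly 1, degenerate p = 1
  out <- bootstrap_ratio_test(acc, acc, n_boot = 50, seed = 3)
  expect_equal(out$statistic, 1)
  expect_equal(out$p, 1)
  # constant 2:1 ratio: every replicate equals 2, smallest attainable level
  out2 <- bootstrap_ratio_test(rep(0.8, 10), rep(0.4, 10), n_boot = 99,
                               seed = 4)
  expect_equal(out2$statistic, 2)
  expect_equal(out2$p, 2 / 100)
  expect_error(bootstrap_ratio_test(acc, -acc), "positive")
  # n = 5 pairs: exhaustive bootstrap (5^5 resamples) vs sampled
  a <- c(0.62, 0.55, 0.70, 0.58, 0.66)
  b <- c(0.52, 0.57, 0.60, 0.55, 0.59)
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  theta <- mean(a) / mean(b)
  tstar <- apply(grid, 1, function(i) mean(a[i]) / mean(b[i]))
  ref <- 2 * theta - 1
  p_exh <- min(1, 2 * min(mean(tstar <= ref), mean(tstar >= ref)))
  out3 <- bootstrap_ratio_test(a, b, n_boot = 10000, seed = 5)
  expect_lt(abs(out3$p - p_exh), 0.02)
})

test_that("phenotype BLUPs shrink, center and match the REML optimum", {
  # near-zero noise: BLUPs converge to genotype means minus the grand mean
  set.seed(7)
  lines <- sprintf("L%02d", 1:20)
  d <- expand.grid(line = lines, environment = c("e1", "e2"),
                   replicate = c("r1", "r2"), stringsAsFactors = FALSE)
  gen_eff <- stats::setNames(rnorm(20, 0, 1), lines)
  d$value <- 5 + gen_eff[d$line] + rnorm(nrow(d), 0, 0.05)
  bl <- phenotype_blup(d)
  expect_lt(abs(sum(bl$blups)), 1e-6)
  expect_equal(bl$blups[lines], gen_eff - mean(gen_eff), tolerance = 0.05,
               ignore_attr = TRUE)
  # row order never matters
  bl2 <- phenotype_blup(d[sample(nrow(d)), ])
  expect_equal(bl2$blups[lines], bl$blups[lines], tolerance = 1e-6)
  # REML optimum check on a noisy balanced design: the reported variance
  # components maximize the profile restricted likelihood (local grid)
  d$value <- 5 + gen_eff[d$line] +
    stats::setNames(rnorm(4, 0, 0.5),
                    c("e1.r1", "e1.r2", "e2.r1", "e2.r2"))[
                      paste(d$environment, d$replicate, sep = ".")] +
    rnorm(nrow(d), 0, 0.7)
  bl3 <- phenotype_blup(d)
  x <- stats::model.matrix(~ environment, d)
  z_line <- stats::model.matrix(~ 0 + line, d)
  z_rep <- stats::model.matrix(~ 0 + interaction(environment, replicate), d)
  reml_ll <- function(s_line, s_rep, s_e) {
    v <- s_line * tcrossprod(z_line) + s_rep * tcrossprod(z_rep) +
      s_e * diag(nrow(d))
    vi <- solve(v)
    b <- solve(crossprod(x, vi %*% x), crossprod(x, vi %*% d$value))
    r <- d$value - x %*% b
    -0.5 * (determinant(v)$modulus +
              determinant(crossprod(x, vi %*% x))$modulus +
              drop(crossprod(r, vi %*% r)))
  }
  est <- c(bl3$varcomp["line"], bl3$varcomp["env_rep"], bl3$varcomp["Residual"])
  ll_hat <- reml_ll(est[1], est[2], est[3])
  for (scale in c(0.9, 1.1)) {
    for (j in 1:3) {
      pert <- est
      pert[j] <- pert[j] * scale
      expect_gte(ll_hat, reml_ll(pert[1], pert[2], pert[3]) - 1e-6)
    }
  }
  expect_error(phenotype_blup(d[0, ]), "no observations")
})

test_that("stepwise selection follows the AIC criterion and finds true drivers", {
  set.seed(9)
  n <- 60
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("m", 1:8)))
  y <- x[, 3] # exact copy, rest noise (stats::step warns on the exact fit)
  out <- suppressWarnings(stepwise_select(x, y, seed = 10))
  expect_equal(out$selected[1], "m3")
  # the first pick minimizes the closed-form AIC among single-variable fits
  aic1 <- vapply(1:8, function(j) {
    rss <- sum(stats::lm(y ~ x[, j])$residuals^2)
    n * log(rss / n) + 2 * 2
  }, numeric(1))
  expect_equal(which.min(aic1), 3L)
  # a fit's extractAIC agrees with n log(RSS/n) + 2k
  fit <- stats::lm(y ~ x[, 1] + x[, 2])
  expect_equal(stats::extractAIC(fit)[2],
               n * log(sum(fit$residuals^2) / n) + 2 * 3, tolerance = 1e-9)
  expect_error(stepwise_select(x[1:10, ], y[1:10]), "30")
  # pure noise response: selection stays small and CV R^2 near zero
  y0 <- rnorm(n)
  out0 <- stepwise_select(x, y0, seed = 11)
  expect_lte(length(out0$selected), floor(n / 10))
  expect_lt(out0$cv_r2, 0.3)
})
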
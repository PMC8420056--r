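# Metabolome-based prediction of drought indices: ridge mixed model
# (rrBLUP-style), repeated k-fold cross-validation, bootstrap comparison of
# predictor sets, phenotype BLUPs over environments/replicates, and stepwise
# marker selection.

#' Fit the ridge mixed model y = 1 mu + M alpha + e
#'
#' Marker effects alpha ~ N(0, sigma_a^2 I). The variance ratio
#' lambda = sigma_e^2 / sigma_a^2 is estimated by REML via the spectral
#' decomposition of MM' (or fixed via `lambda`); effects are recovered as
#' alpha_hat = M'(MM' + lambda I)^-1 (y - mu_hat) with mu_hat the GLS
#' intercept.
#'
#' @param predictors lines x markers numeric matrix (centered internally).
#' @param y numeric response per line (>= 2 distinct values, n >= 10).
#' @param lambda optional fixed variance ratio; `NULL` for REML.
#' @return An object of class `rrblup_model` with `mu`, `alpha`, `lambda`,
#'   `sigma_a2`, `sigma_e2`, `centers`.
#' @export
rrblup_fit <- function(predictors, y, lambda = NULL) {
  stopifnot(is.matrix(predictors), nrow(predictors) == length(y))
  n <- length(y)
  if (n < 10L) stop_param("need at least 10 lines")
  if (length(unique(y)) < 2L) stop_param("y must take at least 2 distinct values")
  centers <- colMeans(predictors)
  m <- sweep(predictors, 2L, centers)
  k <- tcrossprod(m)
  ones <- matrix(1, n, 1L)
  if (is.null(lambda)) {
    vc <- reml_null(y, ones, k)
    lambda <- vc$delta
    u <- vc$U; lam <- vc$lambda
    sigma_a2 <- vc$sigma_g2; sigma_e2 <- vc$sigma_e2
  } else {
    ek <- eigen(k, symmetric = TRUE)
    u <- ek$vectors; lam <- pmax(ek$values, 0)
    sigma_a2 <- NA_real_; sigma_e2 <- NA_real_
  }
  d <- lam + lambda
  vinv <- function(x) u %*% (crossprod(u, x) / d) # (MM' + lambda I)^-1 x
  mu <- drop(crossprod(ones, vinv(y)) / crossprod(ones, vinv(ones)))
  alpha <- drop(crossprod(m, vinv(y - mu)))
  structure(list(mu = mu, alpha = stats::setNames(alpha, colnames(predictors)),
                 lambda = lambda, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 centers = centers),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf("<rrblup_model> %d marker effects, lambda = %.4g, mu = %.4g\n",
              length(x$alpha), x$lambda, x$mu))
  invisible(x)
}

#' @export
coef.rrblup_model <- function(object, ...) object$alpha

#' @export
predict.rrblup_model <- function(object, newdata, ...) {
  m <- sweep(as.matrix(newdata), 2L, object$centers)
  drop(object$mu + m %*% object$alpha)
}

#' Repeated k-fold cross-validation of metabolomic prediction
#'
#' Per repeat, lines are shuffled into k random folds (drawn as
#' `sample(rep(seq_len(k), length.out = n))`), the ridge model is fitted on
#' the training folds and accuracy is the Pearson correlation between the
#' assembled out-of-fold predictions and the observations.
#'
#' @param predictors lines x markers matrix.
#' @param y numeric response per line.
#' @param k number of folds.
#' @param repeats number of repeats.
#' @param seed integer RNG seed.
#' @param lambda optional fixed variance ratio passed to [rrblup_fit()].
#' @return list with `accuracies` (length `repeats`), `folds` (n x repeats
#'   fold-assignment matrix), `k`, `repeats`.
#' @export
cross_validate <- function(predictors, y, k = 10L, repeats = 100L, seed = 1L,
                           lambda = NULL) {
  k <- check_count(k, "k", min = 2L)
  repeats <- check_count(repeats, "repeats")
  n <- length(y)
  if (k > n) stop_param("`k` cannot exceed the number of lines")
  with_seed(seed, {
    acc <- numeric(repeats)
    folds <- matrix(NA_integer_, n, repeats)
    for (r in seq_len(repeats)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      folds[, r] <- fold
      pred <- numeric(n)
      for (f in seq_len(k)) {
        test <- fold == f
        fit <- rrblup_fit(predictors[!test, , drop = FALSE], y[!test],
                          lambda = lambda)
        pred[test] <- predict(fit, predictors[test, , drop = FALSE])
      }
      acc[r] <- stats::cor(pred, y)
    }
    list(accuracies = acc, folds = folds, k = k, repeats = repeats)
  })
}

#' Bootstrap test of the ratio of two prediction accuracies
#'
#' The statistic is mean(acc_a)/mean(acc_b); replicates resample the paired
#' repeats (ordinary bootstrap via `boot::boot`); the p-value inverts the
#' basic (reverse-percentile) interval, i.e. the smallest level at which the
#' interval excludes a ratio of 1.
#'
#' @param acc_a,acc_b equal-length paired accuracy vectors (one entry per
#'   CV repeat).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return list with `statistic` (the observed ratio) and `p`.
#' @export
bootstrap_ratio_test <- function(acc_a, acc_b, n_boot = 100L, seed = 1L) {
  stopifnot(length(acc_a) == length(acc_b))
  n_boot <- check_count(n_boot, "n_boot")
  if (mean(acc_b) <= 0) stop_param("mean(acc_b) must be positive (ratio undefined)")
  theta <- mean(acc_a) / mean(acc_b)
  dat <- cbind(a = acc_a, b = acc_b)
  with_seed(seed, {
    bt <- boot::boot(dat, function(d, i) mean(d[i, 1L]) / mean(d[i, 2L]),
                     R = n_boot, sim = "ordinary")
    tstar <- bt$t[, 1L]
    ref <- 2 * theta - 1 # basic interval excludes 1 at the quantile crossing
    lo <- (sum(tstar <= ref) + 1) / (n_boot + 1)
    hi <- (sum(tstar >= ref) + 1) / (n_boot + 1)
    list(statistic = theta, p = min(1, 2 * min(lo, hi)), replicates = tstar)
  })
}

#' Phenotype BLUPs over environments and replicates
#'
#' Mixed model value = mean + environment + replicate(environment) +
#' genotype + error, fitted by REML (lme4): environment fixed (optionally
#' random), replicate-within-environment and genotype random. The genotype
#' BLUPs are the de-noised phenotype.
#'
#' @param long_table data.frame with columns line, environment, replicate,
#'   value (and optionally trait).
#' @param trait trait to fit when a `trait` column with several traits is
#'   present.
#' @param env_fixed treat environment as fixed (default) or random.
#' @return An object of class `blup_model` with `blups` (named genotype
#'   BLUPs), `env_effects`, `varcomp`, `grand_mean`, `fit`.
#' @export
phenotype_blup <- function(long_table, trait = NULL, env_fixed = TRUE) {
  d <- long_table
  if (!is.null(d$trait)) {
    if (is.null(trait)) {
      tr <- unique(d$trait)
      if (length(tr) > 1L) stop_param("several traits present; pass `trait`")
      trait <- tr
    }
    d <- d[d$trait == trait, , drop = FALSE]
  }
  stopifnot(all(c("line", "environment", "replicate", "value") %in% names(d)))
  if (nrow(d) == 0L) stop_param("no observations")
  if (length(unique(d$environment)) < 1L || anyNA(d$value)) {
    stop_param("empty environment or missing values")
  }
  d$env_rep <- interaction(d$environment, d$replicate, drop = TRUE)
  form <- if (env_fixed) {
    value ~ environment + (1 | env_rep) + (1 | line)
  } else {
    value ~ 1 + (1 | environment) + (1 | env_rep) + (1 | line)
  }
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  re <- lme4::ranef(fit)
  blups <- stats::setNames(re$line[[1L]], rownames(re$line))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  structure(list(blups = blups,
                 env_effects = lme4::fixef(fit),
                 grand_mean = lme4::fixef(fit)[[1L]],
                 varcomp = varcomp, fit = fit, trait = trait),
            class = "blup_model")
}

#' @export
print.blup_model <- function(x, ...) {
  cat(sprintf("<blup_model>%s %d genotype BLUPs; variance components: %s\n",
              if (is.null(x$trait)) "" else paste0(" ", x$trait),
              length(x$blups),
              paste(sprintf("%s=%.3g", names(x$varcomp), x$varcomp),
                    collapse = ", ")))
  invisible(x)
}

#' Stepwise selection of metabolite markers for a drought index
#'
#' Bidirectional stepwise ordinary-least-squares selection minimizing
#' AIC = n log(RSS/n) + 2k, hard-capped at floor(n/10) steps, followed by
#' repeated k-fold cross-validation of the selected model reporting the mean
#' squared correlation between held-out predictions and observations.
#'
#' @param candidates lines x metabolites matrix of candidate predictors.
#' @param y numeric response (e.g. survival rate) per line.
#' @param max_steps step cap; default floor(n/10).
#' @param k folds for the post-selection cross-validation.
#' @param cv_repeats cross-validation repeats.
#' @param seed integer RNG seed (cross-validation folds).
#' @return list with `selected` (metabolite ids in selection-path order of
#'   the final model), `cv_r2`, `r2_insample`, `model`, `path`.
#' @export
stepwise_select <- function(candidates, y, max_steps = NULL, k = 5L,
                            cv_repeats = 10L, seed = 1L) {
  stopifnot(is.matrix(candidates), nrow(candidates) == length(y))
  n <- length(y)
  if (n < 30L) stop_param("need at least 30 lines")
  if (is.null(max_steps)) max_steps <- floor(n / 10)
  ids <- colnames(candidates)
  safe <- make.names(ids, unique = TRUE)
  d <- data.frame(.y = y, candidates, check.names = FALSE)
  names(d) <- c(".y", safe)
  upper <- stats::reformulate(safe, response = ".y")
  fit0 <- stats::lm(.y ~ 1, data = d)
  sel_fit <- stats::step(fit0, scope = list(lower = ~1, upper = upper),
                         direction = "both", steps = max_steps, k = 2,
                         trace = 0)
  terms_sel <- attr(stats::terms(sel_fit), "term.labels")
  selected <- ids[match(terms_sel, safe)]
  r2_in <- summary(sel_fit)$r.squared
  if (!length(selected)) {
    return(list(selected = character(), cv_r2 = 0, r2_insample = 0,
                model = sel_fit, path = sel_fit$anova))
  }
  x_sel <- candidates[, selected, drop = FALSE]
  with_seed(seed, {
    r2 <- numeric(cv_repeats)
    for (r in seq_len(cv_repeats)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      pred <- numeric(n)
      for (f in seq_len(k)) {
        test <- fold == f
        cf <- stats::lm.fit(cbind(1, x_sel[!test, , drop = FALSE]), y[!test])$coefficients
        cf[is.na(cf)] <- 0
        pred[test] <- cbind(1, x_sel[test, , drop = FALSE]) %*% cf
      }
      r2[r] <- stats::cor(pred, y)^2
    }
    list(selected = selected, cv_r2 = mean(r2), r2_insample = r2_in,
         model = sel_fit, path = sel_fit$anova)
  })
}
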
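# L2 logistic regression, evaluation metrics, stratified CV and the
# permutation null.

test_that("the penalized objective is minimized", {
  set.seed(4)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(60) > 0, 1, 0)
  fit <- fit_logistic_l2(X, y, lambda = 1)
  obj <- function(par) {
    eta <- par[1] + X %*% par[-1]
    sum(log1p(exp(-(2 * y - 1) * eta))) + sum(par[-1]^2)
  }
  expect_lte(fit$objective, obj(c(0, 0, 0)))
  # grid oracle around the solution: no nearby point does better
  grid <- as.matrix(expand.grid(d0 = seq(-0.1, 0.1, 0.02),
                                d1 = seq(-0.1, 0.1, 0.02),
                                d2 = seq(-0.1, 0.1, 0.02)))
  vals <- apply(grid, 1, function(d) obj(coef(fit) + d))
  expect_lte(fit$objective, min(vals) + 1e-6)

  # heavy regularization shrinks to (almost) zero
  big <- fit_logistic_l2(X, y, lambda = 1e6)
  expect_lt(sqrt(sum(coef(big)[-1]^2)), 1e-2)

  # separable one-dimensional toy
  sep <- fit_logistic_l2(matrix(c(-1, -1, 1, 1), ncol = 1), c(0, 0, 1, 1))
  expect_gt(coef(sep)[2], 0)
  expect_equal(predict(sep, matrix(c(-1, -1, 1, 1), ncol = 1)),
               c(0L, 0L, 1L, 1L))

  expect_error(fit_logistic_l2(matrix(c(1, NA), 2, 1), c(0, 1)),
               "non-finite")
})

test_that("the fit agrees with glmnet's ridge logistic on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 3]))
  lambda <- 1
  mine <- fit_logistic_l2(X, y, lambda = lambda)
  gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = 2 * lambda / n, standardize = FALSE,
                         thresh = 1e-14)
  gcoef <- as.numeric(coef(gfit))
  obj <- function(par) {
    eta <- par[1] + X %*% par[-1]
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(par[-1]^2)
  }
  expect_equal(mine$objective, obj(gcoef), tolerance = 1e-4)
  expect_equal(unname(coef(mine)), gcoef, tolerance = 1e-2)
})

test_that("sensitivity and specificity follow their definitions", {
  expect_equal(sensitivity_specificity(c(TP = 5, FN = 0, TN = 5, FP = 0)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(c(TP = 3, FN = 1, TN = 0, FP = 4)),
               c(sensitivity = 0.75, specificity = 0))
  expect_equal(sensitivity_specificity(c(TP = 0, FN = 5, TN = 2, FP = 1)),
               c(sensitivity = 0, specificity = 2 / 3))
  # zero denominator is explicitly undefined, not silently zero
  und <- sensitivity_specificity(c(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(und["sensitivity"]))
  expect_false(is.na(und["specificity"]))
})

test_that("the proportion CI half-width matches the closed form", {
  expect_equal(proportion_ci_halfwidth(97), 9.95, tolerance = 1e-3)
  expect_equal(proportion_ci_halfwidth(4 * 97),
               proportion_ci_halfwidth(97) / 2)
  expect_equal(proportion_ci_halfwidth(97, p = 0), 0)
  expect_error(proportion_ci_halfwidth(97, p = 1.2), "p must be")
})

test_that("stratified folds keep label ratios within one subject", {
  set.seed(3)
  y <- rep(c(0, 1), c(37, 23))
  for (rep in 1:10) {
    assign <- neurosym:::stratified_folds(y, 5)
    for (f in 1:5) {
      expect_true(abs(sum(assign == f & y == 1) - 23 / 5) < 1)
      expect_true(abs(sum(assign == f) - 12) <= 1)
    }
  }
  expect_error(neurosym:::stratified_folds(rep(c(0, 1), c(57, 3)), 5),
               "cannot stratify")
})

test_that("a strong planted main effect is classified well above chance", {
  cfg <- synthetic_config(
    n_subjects = 200, n_roi = 6, prevalence = 0.5, seed = 13,
    effects = planted_effect("inattention", "main",
                             list(c(2, "theta", 3)), beta = 10))
  out <- generate_cohort(cfg)
  cv <- evaluate_cv(out$cohort, "inattention", "original", folds = 5,
                    repeats = 2, seed = 1)
  expect_gt(mean(cv$accuracy), 0.8)
  # the planted symptom is the one that gained signal
  cv0 <- evaluate_cv(out$cohort, "anxiety", "original", folds = 5,
                     repeats = 2, seed = 1)
  expect_lt(mean(cv0$accuracy), mean(cv$accuracy))
})

test_that("evaluate_cv returns the full confusion geometry", {
  out <- generate_cohort(synthetic_config(n_subjects = 40, n_roi = 4,
                                          prevalence = 0.4, seed = 21))
  cv <- evaluate_cv(out$cohort, "depression", "original", folds = 4,
                    repeats = 3, seed = 2)
  expect_equal(dim(cv$confusion), c(3, 4, 4))
  expect_true(all(apply(cv$confusion, c(1, 2), sum) == 10))
  sm <- summary(cv)
  expect_true(all(is.finite(sm[, "mean"])))
  # determinism under the same seed
  cv2 <- evaluate_cv(out$cohort, "depression", "original", folds = 4,
                     repeats = 3, seed = 2)
  expect_identical(cv$confusion, cv2$confusion)
})

test_that("label permutations preserve class counts and bracket chance", {
  out <- generate_null_cohort(synthetic_config(n_subjects = 97, n_roi = 6,
                                               prevalence = 0.5, seed = 31))
  y <- unname(out$cohort$labels[, "anxiety"])
  pn <- permutation_null(out$cohort, "anxiety", "original", n_perm = 100,
                         folds = 5, seed = 8)
  expect_length(pn$distribution, 100)
  expect_gt(pn$q95, 0.5)
  expect_lt(pn$q95, 0.7)
  expect_gt(mean(pn$distribution > pn$q95 + 1e-12), 0)  # a real quantile
  expect_lte(mean(pn$distribution > pn$q95 + 1e-12), 0.05 + 1e-9)
  # reproducible under the seed
  pn2 <- permutation_null(out$cohort, "anxiety", "original", n_perm = 5,
                          folds = 5, seed = 8)
  pn3 <- permutation_null(out$cohort, "anxiety", "original", n_perm = 5,
                          folds = 5, seed = 8)
  expect_identical(pn2$distribution, pn3$distribution)
})
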
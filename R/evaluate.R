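# Cross-validated evaluation: stratified folds, the three pipeline
# variants, sensitivity/specificity, and the permutation-null control.
#
# Variants:
#   "original"  - the 1020 identity features, logistic regression only.
#   "os"        - identity features + training-fold oversampling.
#   "da_fs_os"  - full pipeline: augmentation, chi-square top-k selection,
#                 oversampling, then logistic regression.
# In the default "fold_safe" mode, selection and log/score calibration are
# fitted on the training folds only; "paper_faithful" reproduces
# whole-cohort selection before splitting (oversampling is train-only in
# both modes).

VARIANTS <- c("original", "os", "da_fs_os")

stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds)
      stop("class ", cls, " has fewer than ", folds,
           " members; cannot stratify")
    idx <- sample(idx)
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
    FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. A zero
#' denominator yields `NA` (explicitly undefined, never silently 0).
#'
#' @param counts named vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return Named vector `c(sensitivity, specificity)`.
#' @examples
#' sensitivity_specificity(c(TP = 3, FN = 1, TN = 0, FP = 4))
#' @export
sensitivity_specificity <- function(counts) {
  counts <- unlist(counts)
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)),
            all(counts >= 0))
  sens <- if (counts["TP"] + counts["FN"] > 0)
    unname(counts["TP"] / (counts["TP"] + counts["FN"])) else NA_real_
  spec <- if (counts["TN"] + counts["FP"] > 0)
    unname(counts["TN"] / (counts["TN"] + counts["FP"])) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Normal-approximation CI half-width for a proportion
#'
#' Returns `100 * z * sqrt(p (1 - p) / n)` in percentage points, the
#' half-width of the level-`level` confidence interval for a proportion
#' based on the standard error; at `n = 97`, `p = 0.5` this is the
#' 50 +/- 9.95 band used as the chance reference.
#'
#' @param n sample size.
#' @param p proportion (default 0.5).
#' @param level confidence level (default 0.95).
#' @return Half-width in percent.
#' @examples
#' proportion_ci_halfwidth(97)  # 9.95
#' @export
proportion_ci_halfwidth <- function(n, p = 0.5, level = 0.95) {
  stopifnot(n >= 1)
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  100 * z * sqrt(p * (1 - p) / n)
}

#' Oversampling options
#'
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @param gaussian_factor number of Gaussian-noise copies appended
#'   (default 9).
#' @param gaussian_scale noise variance as a fraction of the per-feature
#'   variance (default 1/100).
#' @param order whether SMOTE balances before Gaussian replication
#'   (default) or after.
#' @return List of options for [evaluate_cv()] and friends.
#' @export
oversample_options <- function(smote_k = 5L, gaussian_factor = 9L,
                               gaussian_scale = 1 / 100,
                               order = c("smote_first", "gaussian_first")) {
  list(smote_k = smote_k, gaussian_factor = gaussian_factor,
       gaussian_scale = gaussian_scale, order = match.arg(order))
}

apply_oversampling <- function(X, y, opts) {
  if (opts$order == "smote_first") {
    sm <- smote(X, y, k_neighbors = opts$smote_k)
    X <- gaussian_augment(sm$X, factor = opts$gaussian_factor,
                          scale = opts$gaussian_scale)
    y <- rep(sm$y, times = opts$gaussian_factor + 1L)
  } else {
    Xg <- gaussian_augment(X, factor = opts$gaussian_factor,
                           scale = opts$gaussian_scale)
    yg <- rep(y, times = opts$gaussian_factor + 1L)
    sm <- smote(Xg, yg, k_neighbors = opts$smote_k)
    X <- sm$X; y <- sm$y
  }
  list(X = X, y = y)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu, "-"), 2, st$sd, "/")
}

# fit on a prepared train/test split; returns confusion counts
fit_and_score <- function(Xtr, ytr, Xte, yte, variant, lambda, opts) {
  if (variant != "original") {
    ov <- apply_oversampling(Xtr, ytr, opts)
    Xtr <- ov$X; ytr <- ov$y
  }
  st <- standardize_fit(Xtr)
  fit <- fit_logistic_l2(standardize_apply(Xtr, st), ytr, lambda = lambda)
  pred <- predict(fit, standardize_apply(Xte, st), type = "class")
  confusion_counts(yte, pred)
}

#' Cross-validated evaluation of a pipeline variant
#'
#' Repeated stratified k-fold cross-validation of one symptom's binary
#' classification. Folds are stratified so each fold's label ratio is
#' within one subject of the cohort ratio. For the full pipeline variant,
#' feature augmentation, chi-square selection and calibration are fitted
#' inside each training fold (`leakage = "fold_safe"`); the
#' `"paper_faithful"` switch performs whole-cohort selection before
#' splitting. Oversampling always sees training folds only.
#'
#' @param cohort a `cohort` object.
#' @param symptom one of the four symptom names.
#' @param variant `"original"`, `"os"` or `"da_fs_os"`.
#' @param folds,repeats cross-validation geometry (defaults 5 x 5 = 25
#'   fold evaluations).
#' @param k number of features kept by chi-square selection (full-pipeline
#'   variant; default 40000).
#' @param lambda L2 penalty (default 1).
#' @param seed RNG seed controlling fold assignment and oversampling.
#' @param leakage `"fold_safe"` or `"paper_faithful"`.
#' @param oversample options from [oversample_options()].
#' @param calibrate chi-square scoring calibration mode (see
#'   [score_universe()]).
#' @return A `cv_result` with per-fold confusion counts and summary
#'   statistics (mean and sd of sensitivity, specificity, accuracy).
#' @export
evaluate_cv <- function(cohort, symptom, variant = VARIANTS,
                        folds = 5L, repeats = 5L, k = 40000L, lambda = 1,
                        seed = 1L, leakage = c("fold_safe", "paper_faithful"),
                        oversample = oversample_options(),
                        calibrate = c("always", "negative_only")) {
  variant <- match.arg(variant)
  leakage <- match.arg(leakage)
  calibrate <- match.arg(calibrate)
  symptom <- match.arg(symptom, SYMPTOMS)
  stopifnot(inherits(cohort, "cohort"))
  y <- unname(cohort$labels[, symptom])
  n <- length(y)
  set.seed(seed)

  stage1 <- NULL; sel_global <- NULL
  if (variant == "da_fs_os") {
    stage1 <- stage1_features(cohort)
    if (leakage == "paper_faithful")
      sel_global <- select_top_k(stage1, y, k = k, calibrate = calibrate)
  }

  conf <- array(NA_real_, c(repeats, folds, 4L),
                dimnames = list(NULL, NULL, c("TP", "TN", "FP", "FN")))
  for (r in seq_len(repeats)) {
    assign <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      te <- which(assign == f); tr <- which(assign != f)
      if (variant == "da_fs_os") {
        if (leakage == "fold_safe") {
          s1tr <- structure(list(descriptors = stage1$descriptors,
                                 values = stage1$values[tr, , drop = FALSE]),
                            class = "feature_block")
          sel <- select_top_k(s1tr, y[tr], k = k, calibrate = calibrate)
          Xtr <- sel$values
          Xte <- materialize_features(s1tr, sel$records$id,
                                      newdata = stage1$values[te, ,
                                                              drop = FALSE])
        } else {
          Xtr <- sel_global$values[tr, , drop = FALSE]
          Xte <- sel_global$values[te, , drop = FALSE]
        }
      } else {
        Xtr <- cohort$features[tr, , drop = FALSE]
        Xte <- cohort$features[te, , drop = FALSE]
      }
      conf[r, f, ] <- fit_and_score(Xtr, y[tr], Xte, y[te], variant,
                                    lambda, oversample)
    }
  }
  new_cv_result(symptom, variant, conf,
                settings = list(folds = folds, repeats = repeats, k = k,
                                lambda = lambda, seed = seed,
                                leakage = leakage, calibrate = calibrate,
                                n = n))
}

new_cv_result <- function(symptom, variant, conf, settings) {
  sens <- conf[, , "TP"] / (conf[, , "TP"] + conf[, , "FN"])
  spec <- conf[, , "TN"] / (conf[, , "TN"] + conf[, , "FP"])
  acc <- (conf[, , "TP"] + conf[, , "TN"]) /
    (conf[, , "TP"] + conf[, , "TN"] + conf[, , "FP"] + conf[, , "FN"])
  structure(list(symptom = symptom, variant = variant, confusion = conf,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 settings = settings),
            class = "cv_result")
}

#' @export
summary.cv_result <- function(object, ...) {
  stat <- function(m) c(mean = mean(m, na.rm = TRUE),
                        sd = stats::sd(as.numeric(m), na.rm = TRUE))
  out <- rbind(sensitivity = stat(object$sensitivity),
               specificity = stat(object$specificity),
               accuracy = stat(object$accuracy))
  attr(out, "symptom") <- object$symptom
  attr(out, "variant") <- object$variant
  class(out) <- c("summary.cv_result", class(out))
  out
}

#' @export
print.summary.cv_result <- function(x, ...) {
  cat(sprintf("%s / %s (mean +/- sd over fold evaluations)\n",
              attr(x, "symptom"), toupper(attr(x, "variant"))))
  for (m in rownames(x))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x[m, "mean"], x[m, "sd"]))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Permutation-null control for cross-validated accuracy
#'
#' Re-runs the full cross-validated pipeline on label permutations to
#' obtain the null distribution of mean accuracy and its 95th percentile.
#' The stratified fold partition is computed once from the observed labels
#' and held fixed across permutations (class counts are preserved by
#' permutation, so folds stay stratified in expectation); this allows the
#' expensive product/log pass over the feature universe to be shared by
#' all permutations within a fold.
#'
#' @inheritParams evaluate_cv
#' @param n_perm number of label permutations (default 100).
#' @param repeats fold-partition repeats per permutation (default 1).
#' @return A `permutation_null` with the accuracy `distribution`, its
#'   95th percentile `q95`, and settings.
#' @export
permutation_null <- function(cohort, symptom, variant = VARIANTS,
                             n_perm = 100L, folds = 5L, repeats = 1L,
                             k = 40000L, lambda = 1, seed = 1L,
                             oversample = oversample_options(),
                             calibrate = c("always", "negative_only")) {
  variant <- match.arg(variant)
  calibrate <- match.arg(calibrate)
  symptom <- match.arg(symptom, SYMPTOMS)
  stopifnot(inherits(cohort, "cohort"), n_perm >= 1)
  y <- unname(cohort$labels[, symptom])
  n <- length(y)
  set.seed(seed)

  Yperm <- vapply(seq_len(n_perm), function(q) sample(y), integer(n))
  partitions <- replicate(repeats, stratified_folds(y, folds))
  partitions <- matrix(partitions, ncol = repeats)

  stage1 <- if (variant == "da_fs_os") stage1_features(cohort) else NULL
  acc <- matrix(NA_real_, n_perm, folds * repeats)

  col <- 0L
  for (r in seq_len(repeats)) {
    assign <- partitions[, r]
    for (f in seq_len(folds)) {
      col <- col + 1L
      te <- which(assign == f); tr <- which(assign != f)
      if (variant == "da_fs_os") {
        s1tr <- structure(list(descriptors = stage1$descriptors,
                               values = stage1$values[tr, , drop = FALSE]),
                          class = "feature_block")
        cls1 <- colSums(Yperm[tr, , drop = FALSE])
        if (any(cls1 == 0 | cls1 == length(tr)))
          stop("a permutation left a single-class training fold")
        Ytr <- matrix(as.double(Yperm[tr, ]), ncol = n_perm)
        sels <- chisq_scan_cpp(s1tr$values, Ytr,
                               as.integer(min(k, universe_size(
                                 ncol(s1tr$values)))),
                               calibrate == "always", FALSE)$topk
        for (q in seq_len(n_perm)) {
          ids <- sels[[q]]$ids
          Xtr <- materialize_features(s1tr, ids)
          Xte <- materialize_features(s1tr, ids,
                                      newdata = stage1$values[te, ,
                                                              drop = FALSE])
          cc <- fit_and_score(Xtr, Yperm[tr, q], Xte, Yperm[te, q],
                              variant, lambda, oversample)
          acc[q, col] <- (cc["TP"] + cc["TN"]) / sum(cc)
        }
      } else {
        for (q in seq_len(n_perm)) {
          cc <- fit_and_score(cohort$features[tr, , drop = FALSE],
                              Yperm[tr, q],
                              cohort$features[te, , drop = FALSE],
                              Yperm[te, q], variant, lambda, oversample)
          acc[q, col] <- (cc["TP"] + cc["TN"]) / sum(cc)
        }
      }
    }
  }
  dist <- rowMeans(acc)
  structure(list(symptom = symptom, variant = variant,
                 distribution = dist,
                 q95 = unname(quantile(dist, 0.95, type = 7)),
                 n_perm = n_perm,
                 settings = list(folds = folds, repeats = repeats, k = k,
                                 lambda = lambda, seed = seed, n = n)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation null (%s / %s): %d permutations, mean acc %.3f, q95 %.3f\n",
    x$symptom, toupper(x$variant), x$n_perm, mean(x$distribution), x$q95))
  invisible(x)
}
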
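# Synthetic cohort generator.
#
# Emulates the statistical shape of the study cohort: n subjects, each with
# a complete n_roi x 3 x n_task tensor of zero-mean Gaussian
# baseline-corrected amplitudes (so values are signed), optional
# equicorrelation of the 3 x n_task cells within each ROI, and four
# correlated integer symptom scores binarized at a threshold of 5. Signal
# is planted either in single cells (main effects) or in products of two
# cells from distinct ROIs (interaction effects) on the log-odds scale of a
# latent logistic score; integer scores are obtained by rank-binning the
# latent so that the >= 5 rule hits the target prevalence exactly in-sample.

#' Describe a planted effect
#'
#' @param symptom one of `"anxiety"`, `"depression"`, `"inattention"`,
#'   `"hyperactivity"`.
#' @param kind `"main"` (one tensor cell) or `"interaction"` (product of two
#'   cells from distinct ROIs).
#' @param loci a list of one (main) or two (interaction) `c(roi, band, task)`
#'   triples; `band` may be 1..3 or `"theta"`/`"alpha"`/`"beta"`.
#' @param beta effect size in log-odds units applied to the standardized
#'   cell value (main) or product of the two standardized cell values
#'   (interaction).
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(symptom, kind = c("main", "interaction"),
                           loci, beta) {
  kind <- match.arg(kind)
  symptom <- match.arg(symptom, SYMPTOMS)
  if (!is.list(loci)) loci <- list(loci)
  loci <- lapply(loci, function(l) {
    band <- if (is.character(l[2]) || !is.numeric(l)) band_index(l[[2]])
            else as.integer(l[[2]])
    c(roi = as.integer(l[[1]]), band = band, task = as.integer(l[[3]]))
  })
  n_expected <- if (kind == "main") 1L else 2L
  if (length(loci) != n_expected)
    stop(kind, " effect needs ", n_expected, " locus/loci")
  if (kind == "interaction" && loci[[1]]["roi"] == loci[[2]]["roi"])
    stop("interaction loci must involve two distinct ROIs")
  structure(list(symptom = symptom, kind = kind, loci = loci,
                 beta = as.numeric(beta)),
            class = "planted_effect")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions: 97 subjects with a 68 x 3 x 5
#' tensor each. Prevalence defaults to 0.35 per symptom, a plausible rate
#' for mild self-reported symptoms (score >= 5) in a healthy adult sample;
#' the study does not report its label split, so this is configurable.
#'
#' @param n_subjects number of subjects (default 97).
#' @param n_roi,n_task tensor dimensions (defaults 68 and 5; bands are
#'   always theta/alpha/beta).
#' @param noise_sd standard deviation of the Gaussian cell amplitudes
#'   (arbitrary source-localized units, default 1).
#' @param roi_correlation equicorrelation in `[0, 1)` among the 3 x n_task
#'   cells of one ROI (default 0.6: band- and task-wise amplitudes of one
#'   cortical source share most of their variance in practice, and this
#'   within-region coherence is what makes region-pair aggregation
#'   meaningful).
#' @param effects list of [planted_effect()]s.
#' @param prevalence target label prevalence per symptom in (0, 1); scalar
#'   or named vector.
#' @param score_ceilings integer score maxima per symptom (defaults: the
#'   GAD-7 / PHQ-9 / ADHD-RS instrument ranges).
#' @param symptom_correlation loading in `[0, 1)` of a shared per-subject
#'   factor on every symptom's latent score; induces the positive
#'   inter-symptom score correlation seen in self-report batteries
#'   (default 0.6).
#' @param seed integer RNG seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 97L, n_roi = 68L, n_task = 5L,
                             noise_sd = 1, roi_correlation = 0.6,
                             effects = list(), prevalence = 0.35,
                             score_ceilings = SCORE_CEILINGS,
                             symptom_correlation = 0.6, seed = 1L) {
  if (length(prevalence) == 1L)
    prevalence <- stats::setNames(rep(prevalence, 4L), SYMPTOMS)
  stopifnot(n_subjects >= 2, n_roi >= 1, n_task >= 1,
            noise_sd > 0, roi_correlation >= 0, roi_correlation < 1,
            symptom_correlation >= 0, symptom_correlation < 1,
            all(SYMPTOMS %in% names(prevalence)),
            all(prevalence > 0), all(prevalence < 1),
            all(SYMPTOMS %in% names(score_ceilings)),
            all(score_ceilings >= 5))
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  for (e in effects) {
    stopifnot(inherits(e, "planted_effect"))
    for (l in e$loci)
      if (l["roi"] > n_roi || l["task"] > n_task)
        stop("planted locus outside tensor dimensions")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_roi = as.integer(n_roi), n_task = as.integer(n_task),
                 noise_sd = noise_sd, roi_correlation = roi_correlation,
                 effects = effects,
                 prevalence = prevalence[SYMPTOMS],
                 score_ceilings = score_ceilings[SYMPTOMS],
                 symptom_correlation = symptom_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `cohort` (a `cohort` object) and `manifest`
#'   (planted loci, effect sizes, realized prevalences, seed).
#' @examples
#' out <- generate_cohort(synthetic_config(n_subjects = 20, n_roi = 4,
#'                                         seed = 7))
#' out$cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n <- config$n_subjects
  R <- config$n_roi; Tn <- config$n_task
  p <- R * 3L * Tn
  rho <- config$roi_correlation

  z_roi <- matrix(rnorm(n * R), n, R)          # shared within-ROI factor
  eps <- matrix(rnorm(n * p), n, p)
  roi_of_col <- rep(seq_len(R), each = 3L * Tn)
  features <- config$noise_sd *
    (sqrt(rho) * z_roi[, roi_of_col, drop = FALSE] + sqrt(1 - rho) * eps)

  zfeat <- scale(features)                      # empirical standardization
  shared <- rnorm(n)                            # cross-symptom factor

  cell <- function(l) zfeat[, tensor_col(l["roi"], l["band"], l["task"],
                                         3L, Tn)]
  scores <- matrix(NA_integer_, n, 4L,
                   dimnames = list(NULL, SYMPTOMS))
  realized <- numeric(4L); names(realized) <- SYMPTOMS
  for (s in SYMPTOMS) {
    eta <- config$symptom_correlation * shared + rlogis(n)
    for (e in config$effects) {
      if (e$symptom != s) next
      term <- if (e$kind == "main") cell(e$loci[[1]])
              else cell(e$loci[[1]]) * cell(e$loci[[2]])
      eta <- eta + e$beta * term
    }
    if (stats::sd(eta) == 0)
      stop("unsatisfiable prevalence: latent score has zero variance")
    n1 <- round(n * config$prevalence[[s]])
    if (n1 < 1 || n1 > n - 1)
      stop("unsatisfiable prevalence ", config$prevalence[[s]],
           " at n = ", n)
    scores[, s] <- rank_bin_scores(eta, n1, config$score_ceilings[[s]])
    realized[s] <- mean(scores[, s] >= 5)
  }
  score_df <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                         as.data.frame(scores),
                         stringsAsFactors = FALSE)
  cohort <- as_cohort(features, score_df, threshold = 5L,
                      n_roi = R, n_task = Tn,
                      atlas = dk_atlas(min(R, 68L)))
  manifest <- structure(
    list(seed = config$seed, n_subjects = n, n_roi = R, n_task = Tn,
         effects = config$effects,
         target_prevalence = config$prevalence,
         realized_prevalence = realized),
    class = "cohort_manifest")
  list(cohort = cohort, manifest = manifest)
}

# Monotone map of a continuous latent to integer scores: the n1
# highest-latent subjects receive scores spread over [5, ceiling], the rest
# over [0, 4]; within each group the spread is linear in rank. Rank-based
# binning guarantees the target prevalence without distributional
# assumptions on the latent.
rank_bin_scores <- function(eta, n1, ceiling_score) {
  n <- length(eta)
  r <- rank(eta, ties.method = "first")
  hi <- r > (n - n1)
  score <- integer(n)
  r0 <- r[!hi]                       # ranks 1..n0
  n0 <- n - n1
  if (n0 > 0)
    score[!hi] <- pmin(4L, as.integer(floor((r0 - 1) / n0 * 5)))
  r1 <- r[hi] - n0                   # ranks 1..n1
  span <- ceiling_score - 5L + 1L
  score[hi] <- 5L + pmin(span - 1L, as.integer(floor((r1 - 1) / n1 * span)))
  score
}

#' Generate a null cohort (labels independent of features)
#'
#' Identical to [generate_cohort()] with every planted effect removed: the
#' latent scores are pure shared-factor plus logistic noise, so labels carry
#' no information about the tensor.
#'
#' @param config a [synthetic_config()]; any `effects` are ignored.
#' @return A list with `cohort` and `manifest` (manifest lists no loci).
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$effects <- list()
  generate_cohort(config)
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("synthetic cohort manifest: n = %d, %d x 3 x %d tensor, seed %d\n",
              x$n_subjects, x$n_roi, x$n_task, x$seed))
  if (!length(x$effects)) {
    cat("no planted effects (null cohort)\n")
  } else {
    for (e in x$effects) {
      loci <- vapply(e$loci, function(l)
        sprintf("(roi %d, %s, task %d)", l["roi"], BAND_LEVELS[l["band"]],
                l["task"]), "")
      cat(sprintf("  %s: %s effect beta = %.2f at %s\n", e$symptom, e$kind,
                  e$beta, paste(loci, collapse = " x ")))
    }
  }
  cat("realized prevalence:",
      paste(sprintf("%s %.2f", names(x$realized_prevalence),
                    x$realized_prevalence), collapse = ", "), "\n")
  invisible(x)
}

#' Write a ground-truth manifest as key-value text
#' @param manifest a `cohort_manifest`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  lines <- c(
    sprintf("seed=%d", manifest$seed),
    sprintf("n_subjects=%d", manifest$n_subjects),
    sprintf("n_roi=%d", manifest$n_roi),
    sprintf("n_task=%d", manifest$n_task),
    vapply(manifest$effects, function(e) {
      loci <- vapply(e$loci, function(l)
        sprintf("%d:%s:%d", l["roi"], BAND_LEVELS[l["band"]], l["task"]), "")
      sprintf("effect=%s,%s,%s,beta=%g", e$symptom, e$kind,
              paste(loci, collapse = "x"), e$beta)
    }, ""),
    sprintf("realized_prevalence_%s=%g", names(manifest$realized_prevalence),
            manifest$realized_prevalence))
  writeLines(lines, path)
  invisible(path)
}
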
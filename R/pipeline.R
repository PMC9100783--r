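# End-to-end orchestration: validated configuration, staged execution,
# delimited result tables and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Validates every parameter before any computation starts. The
#' configuration is echoed into the run manifest of every output
#' directory.
#'
#' @param features_path,scores_path input tables for [read_cohort()];
#'   leave `NULL` to simulate a cohort instead.
#' @param simulate a [synthetic_config()] used when no input paths are
#'   given.
#' @param symptoms symptoms to analyse (default all four).
#' @param threshold score-to-label threshold (default 5).
#' @param variants pipeline variants to evaluate.
#' @param k chi-square selection size (default 40000).
#' @param lambda L2 penalty (default 1).
#' @param folds,repeats cross-validation geometry.
#' @param n_perm permutation-null iterations (0 disables the null).
#' @param strength_threshold hub-graph edge threshold (default 100).
#' @param leakage `"fold_safe"` or `"paper_faithful"`.
#' @param oversample options from [oversample_options()].
#' @param seed master seed.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(features_path = NULL, scores_path = NULL,
                            simulate = synthetic_config(),
                            symptoms = SYMPTOMS, threshold = 5L,
                            variants = c("original", "da_fs_os"),
                            k = 40000L, lambda = 1, folds = 5L,
                            repeats = 5L, n_perm = 0L,
                            strength_threshold = 100,
                            leakage = c("fold_safe", "paper_faithful"),
                            oversample = oversample_options(), seed = 1L) {
  leakage <- match.arg(leakage)
  symptoms <- match.arg(symptoms, SYMPTOMS, several.ok = TRUE)
  variants <- match.arg(variants, VARIANTS, several.ok = TRUE)
  if (xor(is.null(features_path), is.null(scores_path)))
    stop("provide both features_path and scores_path, or neither")
  stopifnot(k >= 1, lambda > 0, folds >= 2, repeats >= 1, n_perm >= 0,
            strength_threshold >= 0, threshold >= 0)
  if (is.null(features_path)) stopifnot(inherits(simulate,
                                                 "synthetic_config"))
  structure(list(features_path = features_path, scores_path = scores_path,
                 simulate = simulate, symptoms = symptoms,
                 threshold = threshold, variants = variants, k = k,
                 lambda = lambda, folds = folds, repeats = repeats,
                 n_perm = n_perm, strength_threshold = strength_threshold,
                 leakage = leakage, oversample = oversample,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full analysis pipeline
#'
#' Executes, per symptom: cross-validated evaluation of each configured
#' variant, the optional permutation null, whole-cohort chi-square top-k
#' selection, ROI-pair strength aggregation, hub-graph construction and
#' current-flow centralities. All results are written as UTF-8
#' tab-delimited tables plus a JSON run manifest; identical configuration
#' and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of the in-memory results and written paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                fileEncoding = "UTF-8")
    path
  }

  stage_msg("stage: cohort")
  if (!is.null(config$features_path)) {
    cohort <- read_cohort(config$features_path, config$scores_path,
                          threshold = config$threshold)
    manifest_extra <- list(source = "files")
  } else {
    sim <- generate_cohort(config$simulate)
    cohort <- sim$cohort
    write_manifest(sim$manifest, file.path(out_dir, "cohort_manifest.txt"))
    manifest_extra <- list(source = "simulated",
                           realized_prevalence =
                             as.list(sim$manifest$realized_prevalence))
  }

  cv_rows <- list(); null_rows <- list()
  results <- list()
  for (s in config$symptoms) {
    res <- list()
    for (v in config$variants) {
      stage_msg("stage: evaluate ", s, " / ", v)
      cv <- evaluate_cv(cohort, s, variant = v, folds = config$folds,
                        repeats = config$repeats, k = config$k,
                        lambda = config$lambda, seed = config$seed,
                        leakage = config$leakage,
                        oversample = config$oversample)
      sm <- summary(cv)
      cv_rows[[paste(s, v)]] <- data.frame(
        symptom = s, variant = v,
        metric = rownames(sm), mean = sm[, "mean"], sd = sm[, "sd"])
      res[[v]] <- cv
    }
    if (config$n_perm > 0) {
      stage_msg("stage: permutation null ", s)
      pn <- permutation_null(cohort, s,
                             variant = config$variants[length(
                               config$variants)],
                             n_perm = config$n_perm, folds = config$folds,
                             repeats = 1L, k = config$k,
                             lambda = config$lambda, seed = config$seed,
                             oversample = config$oversample)
      null_rows[[s]] <- data.frame(symptom = s, variant = pn$variant,
                                   mean_null = mean(pn$distribution),
                                   q95 = pn$q95, n_perm = pn$n_perm)
      res$null <- pn
    }

    stage_msg("stage: strengths & hubs ", s)
    sm <- roi_pair_strengths(cohort, s)
    stage1 <- stage1_features(cohort)
    sel <- select_top_k(stage1, unname(cohort$labels[, s]),
                        k = min(config$k,
                                universe_size(ncol(stage1$values))))
    tsv(sel$records[, c("rank", "chi2", "encoded")],
        paste0("topk_", s, ".tsv"))
    g <- build_graph(sm, threshold = config$strength_threshold)
    cent <- current_flow_centralities(g)
    tsv(cent, paste0("centralities_", s, ".tsv"))
    tsv(top_hubs(cent), paste0("top_hubs_", s, ".tsv"))
    write_graph_files(g, file.path(out_dir,
                                   paste0("graph_edges_", s, ".tsv")),
                      file.path(out_dir, paste0("graph_", s, ".graphml")))
    ut <- which(upper.tri(sm$strength) & sm$strength > 0, arr.ind = TRUE)
    tsv(data.frame(roi_i = ut[, 1], roi_j = ut[, 2],
                   strength = sm$strength[ut]),
        paste0("strength_", s, ".tsv"))
    res$strength <- sm; res$graph <- g; res$centralities <- cent
    results[[s]] <- res
  }
  tsv(do.call(rbind, cv_rows), "cv_results.tsv")
  if (length(null_rows)) tsv(do.call(rbind, null_rows),
                             "permutation_null.tsv")

  manifest <- c(list(
    package_version = as.character(utils::packageVersion("neurosym")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), c("simulate", "oversample"))],
    oversample = config$oversample), manifest_extra)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(cohort = cohort, results = results, out_dir = out_dir))
}
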
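# Cohort container and delimited-file IO.
#
# A cohort holds, per subject, a complete ROI x band x task tensor of
# baseline-corrected spectral amplitudes (values may be negative) plus the
# four integer symptom self-report scores and their binarized labels.
# Tensors are stored flattened row-wise per subject in a fixed order:
# roi-major, then band (theta, alpha, beta), then task (1..n_task), i.e.
# column index = ((roi-1)*n_band + (band-1))*n_task + task.

band_index <- function(band) {
  b <- tolower(trimws(as.character(band)))
  b[b %in% c("θ")] <- "theta"
  b[b %in% c("α")] <- "alpha"
  b[b %in% c("β")] <- "beta"
  idx <- match(b, BAND_LEVELS)
  if (anyNA(idx)) {
    bad <- unique(band[is.na(idx)])
    stop("unknown band token(s): ", paste(bad, collapse = ", "))
  }
  idx
}

tensor_col <- function(roi, band, task, n_band, n_task) {
  ((roi - 1L) * n_band + (band - 1L)) * n_task + task
}

new_cohort <- function(subjects, features, scores, labels, atlas, dims) {
  structure(
    list(subjects = subjects, features = features, scores = scores,
         labels = labels, atlas = atlas, dims = dims),
    class = "cohort")
}

#' Assemble a cohort from a feature matrix and symptom scores
#'
#' @param features numeric matrix, subjects x (n_roi * 3 * n_task), columns in
#'   the package's fixed flattening order (roi-major, then band
#'   theta/alpha/beta, then task), or a 4-d array subjects x roi x band x task.
#' @param scores data.frame with columns `subject_id`, `anxiety`,
#'   `depression`, `inattention`, `hyperactivity` (non-negative integers).
#' @param threshold labeling threshold: label 1 iff score >= threshold.
#' @param n_roi,n_task tensor dimensions (bands are always
#'   theta/alpha/beta).
#' @param atlas optional atlas data.frame (`roi`, `region`, `hemisphere`).
#' @return A `cohort` object.
#' @export
as_cohort <- function(features, scores, threshold = 5L,
                      n_roi = 68L, n_task = 5L, atlas = NULL) {
  if (is.array(features) && length(dim(features)) == 4L) {
    d <- dim(features)
    n_roi <- d[2]; n_task <- d[4]
    stopifnot(d[3] == 3L)
    # column-major flatten of (subject, task, band, roi) puts task fastest
    features <- matrix(aperm(features, c(1, 4, 3, 2)), nrow = d[1])
  }
  features <- as.matrix(features)
  stopifnot(ncol(features) == n_roi * 3L * n_task)
  req <- c("subject_id", SYMPTOMS)
  if (!all(req %in% names(scores)))
    stop("scores must have columns: ", paste(req, collapse = ", "))
  scores <- scores[, req]
  subjects <- as.character(scores$subject_id)
  if (anyDuplicated(subjects)) stop("duplicate subject_id in scores")
  if (nrow(features) != length(subjects))
    stop("features and scores disagree on subject count")
  if (any(!is.finite(features))) stop("non-finite feature values")
  ord <- order(subjects)
  subjects <- subjects[ord]
  features <- features[ord, , drop = FALSE]
  scores <- scores[ord, , drop = FALSE]
  rownames(features) <- subjects
  rownames(scores) <- NULL
  labels <- binarize_labels(scores, threshold = threshold)
  if (is.null(atlas)) atlas <- dk_atlas(min(n_roi, 68L))
  new_cohort(subjects, features, scores, labels, atlas,
             dims = c(n_roi = n_roi, n_band = 3L, n_task = n_task))
}

#' Binarize symptom scores at a threshold
#'
#' A subject is labeled 1 ("with symptoms") for a given instrument iff the
#' integer self-report score is greater than or equal to the threshold
#' (default 5), independently per symptom.
#'
#' @param scores data.frame with a `subject_id` column and numeric score
#'   columns, or a numeric vector/matrix of scores.
#' @param threshold non-negative labeling threshold (default 5).
#' @return Integer 0/1 labels with the same shape as the score columns; for
#'   a data.frame input, a matrix with one column per symptom.
#' @examples
#' binarize_labels(c(0, 4, 5, 21))
#' @export
binarize_labels <- function(scores, threshold = 5L) {
  stopifnot(length(threshold) == 1L, threshold >= 0)
  if (is.data.frame(scores)) {
    cols <- setdiff(names(scores), "subject_id")
    m <- as.matrix(scores[, cols, drop = FALSE])
    out <- binarize_labels(m, threshold)
    rownames(out) <- as.character(scores$subject_id)
    return(out)
  }
  x <- scores
  if (any(!is.finite(x))) stop("non-finite score")
  if (any(x < 0)) stop("negative score")
  if (any(x != round(x))) stop("scores must be integers")
  lab <- (x >= threshold) + 0L
  storage.mode(lab) <- "integer"
  lab
}

#' Read a cohort from delimited feature and score tables
#'
#' The feature table is a long-format UTF-8 tab- or comma-delimited file
#' with header columns `subject_id`, `roi_id`, `band`, `task`, `value`; the
#' score table has `subject_id` plus the four symptom score columns. Every
#' subject must have a complete roi x band x task grid; gaps, duplicates and
#' unknown band/task tokens are errors. Band tokens are matched
#' case-insensitively and the Greek letters are accepted.
#'
#' @param features_path,scores_path file paths.
#' @param threshold labeling threshold passed to [binarize_labels()].
#' @param atlas optional atlas override.
#' @return A `cohort` object, subjects ordered by `subject_id`.
#' @export
read_cohort <- function(features_path, scores_path, threshold = 5L,
                        atlas = NULL) {
  feat <- read_delim_auto(features_path)
  req <- c("subject_id", "roi_id", "band", "task", "value")
  if (!all(req %in% names(feat)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  scores <- read_delim_auto(scores_path)

  subj <- as.character(feat$subject_id)
  roi <- as.integer(feat$roi_id)
  task <- suppressWarnings(as.integer(feat$task))
  if (anyNA(task) || any(task < 1))
    stop("unknown task token; tasks must be integers >= 1")
  band <- band_index(feat$band)
  n_roi <- max(roi); n_task <- max(task)
  if (any(roi < 1)) stop("roi_id must be >= 1")

  subjects <- sort(unique(subj))
  n <- length(subjects)
  si <- match(subj, subjects)
  col <- tensor_col(roi, band, task, 3L, n_task)
  key <- (si - 1) * (n_roi * 3L * n_task) + col
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate cell: subject %s roi %d band %s task %d",
                 subj[d], roi[d], BAND_LEVELS[band[d]], task[d]))
  }
  p <- n_roi * 3L * n_task
  if (length(key) != n * p) {
    # name the first few gaps
    have <- logical(n * p)
    have[key] <- TRUE
    miss <- which(!have)[seq_len(min(5L, n * p - length(key)))]
    mi <- (miss - 1) %/% p + 1
    mc <- (miss - 1) %% p
    mroi <- mc %/% (3L * n_task) + 1
    mband <- (mc %/% n_task) %% 3L + 1
    mtask <- mc %% n_task + 1
    stop("incomplete tensor; missing cells include: ",
         paste(sprintf("(subject %s, roi %d, band %s, task %d)",
                       subjects[mi], mroi, BAND_LEVELS[mband], mtask),
               collapse = "; "))
  }
  features <- matrix(NA_real_, n, p)
  features[cbind(si, col)] <- as.numeric(feat$value)
  rownames(features) <- subjects

  scores$subject_id <- as.character(scores$subject_id)
  if (!setequal(scores$subject_id, subjects))
    stop("feature and score tables disagree on subjects")
  as_cohort(features, scores, threshold = threshold,
            n_roi = n_roi, n_task = n_task, atlas = atlas)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a cohort back to delimited tables
#'
#' Inverse of [read_cohort()]: emits the long-format feature table (ordered
#' by subject, roi, band, task) and the score table.
#'
#' @param cohort a `cohort` object.
#' @param features_path,scores_path output paths.
#' @param sep field delimiter (default tab).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, features_path, scores_path, sep = "\t") {
  d <- cohort$dims
  n <- length(cohort$subjects)
  grid <- expand.grid(task = seq_len(d[["n_task"]]),
                      band = seq_len(3L),
                      roi = seq_len(d[["n_roi"]]))
  # grid rows enumerate columns in flattening order (task fastest)
  long <- data.frame(
    subject_id = rep(cohort$subjects, each = nrow(grid)),
    roi_id = rep(grid$roi, times = n),
    band = rep(BAND_LEVELS[grid$band], times = n),
    task = rep(grid$task, times = n),
    value = as.vector(t(cohort$features)),
    stringsAsFactors = FALSE)
  write.table(long, features_path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  write.table(cohort$scores, scores_path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(features = features_path, scores = scores_path))
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$dims
  cat(sprintf("cohort: %d subjects, %d x %d x %d tensor (%d features)\n",
              length(x$subjects), d[["n_roi"]], d[["n_band"]], d[["n_task"]],
              ncol(x$features)))
  prev <- colMeans(x$labels)
  cat("label prevalence:",
      paste(sprintf("%s %.2f", colnames(x$labels), prev), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract one subject's tensor as a roi x band x task array
#' @param cohort a `cohort` object.
#' @param subject subject id or index.
#' @return numeric array `n_roi x 3 x n_task`.
#' @export
subject_tensor <- function(cohort, subject) {
  i <- if (is.character(subject)) match(subject, cohort$subjects)
       else as.integer(subject)
  if (is.na(i) || i < 1 || i > length(cohort$subjects))
    stop("unknown subject")
  d <- cohort$dims
  v <- cohort$features[i, ]
  arr <- array(NA_real_, c(d[["n_roi"]], 3L, d[["n_task"]]),
               dimnames = list(NULL, BAND_LEVELS, NULL))
  for (roi in seq_len(d[["n_roi"]]))
    for (b in 1:3)
      arr[roi, b, ] <- v[tensor_col(roi, b, seq_len(d[["n_task"]]),
                                    3L, d[["n_task"]])]
  arr
}
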
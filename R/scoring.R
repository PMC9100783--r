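# Continuous chi-square feature scoring and top-k selection.
#
# The chi-square statistic here is the extension to non-negative continuous
# features: S_ec is the sum of feature values in class c, E_ec the expected
# sum (total sum times the class proportion), and the statistic is
# sum over classes of (S - E)^2 / E. It is used purely as a ranking score.
# Because baseline-corrected amplitudes and their products can be negative
# while the statistic requires non-negative sums, features containing a
# negative value are min-max calibrated to [0, 1] before scoring; this
# calibration is a documented reconstruction, not part of the original
# statistic.

#' Non-negativity calibration for chi-square scoring
#'
#' Min-max rescales a feature to `[0, 1]`. By default the rescale is only
#' applied when the feature contains a negative value (already non-negative
#' features pass through unchanged); a constant feature always maps to all
#' zeros.
#'
#' @param values numeric vector, length >= 2.
#' @param only_if_negative if `TRUE` (default), leave non-negative features
#'   untouched.
#' @return Calibrated vector.
#' @examples
#' nonneg_calibrate(c(-2, 0, 2))   # 0, 0.5, 1
#' nonneg_calibrate(c(30, 20, 40)) # unchanged
#' @export
nonneg_calibrate <- function(values, only_if_negative = TRUE) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  rng <- max(values) - min(values)
  if (rng == 0) return(rep(0, length(values)))
  if (only_if_negative && min(values) >= 0) return(values)
  (values - min(values)) / rng
}

#' Continuous chi-square statistic of one feature
#'
#' @param values non-negative numeric vector (one value per subject).
#' @param labels 0/1 vector, both classes non-empty.
#' @param details if `TRUE`, also return the per-class observed sums
#'   `S`, expected sums `E` and class proportions `P`.
#' @return The statistic (non-negative scalar), or a list when
#'   `details = TRUE`.
#' @examples
#' chi_square(c(30, 20, 40), c(1, 0, 1))  # 5
#' @export
chi_square <- function(values, labels, details = FALSE) {
  stopifnot(length(values) == length(labels))
  if (any(!is.finite(values))) stop("non-finite values")
  if (any(values < 0))
    stop("values must be non-negative; see nonneg_calibrate()")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  S <- c(`0` = sum(values[labels == 0]), `1` = sum(values[labels == 1]))
  tot <- sum(S)
  if (tot == 0) {
    if (!details) return(0)
    return(list(chi2 = 0, S = S, E = S * 0, P = c(`0` = n0, `1` = n1) /
                  (n0 + n1)))
  }
  P <- c(`0` = n0, `1` = n1) / (n0 + n1)
  E <- tot * P
  chi2 <- sum((S - E)^2 / E)
  if (!details) return(chi2)
  list(chi2 = chi2, S = S, E = E, P = P)
}

# Vectorized chi-square over the columns of a value matrix, with the same
# calibration rules as the compiled kernel applied per column.
chisq_block <- function(V, labels, calibrate = c("always", "negative_only")) {
  calibrate <- match.arg(calibrate)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  cmin <- apply(V, 2, min)
  cmax <- apply(V, 2, max)
  s1 <- colSums(V[labels == 1, , drop = FALSE])
  s0 <- colSums(V[labels == 0, , drop = FALSE])
  rng <- cmax - cmin
  calib <- (if (calibrate == "always") rep(TRUE, length(cmin))
            else cmin < 0) & rng > 0
  s1[calib] <- (s1[calib] - n1 * cmin[calib]) / rng[calib]
  s0[calib] <- (s0[calib] - n0 * cmin[calib]) / rng[calib]
  tot <- s0 + s1
  p1 <- n1 / (n0 + n1)
  e1 <- tot * p1
  e0 <- tot - e1
  chi2 <- ifelse(rng == 0 | tot <= 0, 0,
                 (s1 - e1)^2 / e1 + (s0 - e0)^2 / e0)
  as.numeric(chi2)
}

#' Score the whole augmented universe against one label vector
#'
#' Single pass over every universe feature (stage-1 singletons, all
#' pairwise products, and the calibrated log twin of each), computing the
#' continuous chi-square statistic of each. Uses the compiled streaming
#' kernel; memory stays at one value per base feature.
#'
#' @param stage1 a `feature_block` from [stage1_features()].
#' @param labels 0/1 vector over subjects.
#' @param calibrate `"always"` (default): min-max calibrate every raw
#'   feature to `[0, 1]` before scoring, so the ranking is invariant to
#'   per-feature scale; `"negative_only"`: calibrate only features
#'   containing a negative value, passing non-negative features through on
#'   their native scale (the statistic then grows linearly with feature
#'   scale, which distorts cross-feature ranking).
#' @return A `universe_scores` object: chi2 vectors `raw` and `log` indexed
#'   by base feature (singletons then pairs, lexicographic), the base
#'   feature `min`/`max`, and `n_stage1`.
#' @export
score_universe <- function(stage1, labels,
                           calibrate = c("always", "negative_only")) {
  calibrate <- match.arg(calibrate)
  stopifnot(inherits(stage1, "feature_block"))
  y <- matrix(as.double(labels), ncol = 1L)
  res <- chisq_scan_cpp(stage1$values, y, 0L,
                        calibrate == "always", TRUE)
  structure(list(raw = res$raw, log = res$log,
                 min = res$min, max = res$max,
                 n_stage1 = ncol(stage1$values),
                 n_universe = universe_size(ncol(stage1$values))),
            class = "universe_scores")
}

#' @export
print.universe_scores <- function(x, ...) {
  cat(sprintf("universe_scores: %d stage-1 features, %.0f universe features\n",
              x$n_stage1, x$n_universe))
  invisible(x)
}

#' Stream every chi-square record to a sink
#'
#' Scores the full universe and then emits every (feature, chi2) record in
#' stream order to `sink` in bounded-size chunks, without retaining the
#' records. Each chunk is a data.frame with columns `id` (universe id),
#' `f1`, `f2` (constituent stage-1 indices; `f2` is `NA` for singletons),
#' `log` and `chi2`. This is the feed for the ROI-pair strength aggregator.
#'
#' @param stage1 a `feature_block`.
#' @param labels 0/1 labels.
#' @param sink function called on each chunk.
#' @param chunk_size records per chunk.
#' @return Invisibly, the number of records emitted.
#' @export
score_all_for_strength <- function(stage1, labels, sink,
                                   chunk_size = 200000L,
                                   calibrate = c("always", "negative_only")) {
  scores <- score_universe(stage1, labels, calibrate = match.arg(calibrate))
  p <- scores$n_stage1
  nbase <- p + choose(p, 2)
  emitted <- 0
  start <- 1
  while (start <= nbase) {
    idx <- start:min(start + chunk_size / 2 - 1, nbase)
    f1 <- idx; f2 <- rep(NA_integer_, length(idx))
    pairs <- idx > p
    if (any(pairs)) {
      ij <- pair_unrank(idx[pairs] - p, p)
      f1[pairs] <- ij[, "i"]; f2[pairs] <- ij[, "j"]
    }
    chunk <- data.frame(
      id = c(2 * idx - 1, 2 * idx),
      f1 = c(f1, f1), f2 = c(f2, f2),
      log = rep(c(FALSE, TRUE), each = length(idx)),
      chi2 = c(scores$raw[idx], scores$log[idx]))
    sink(chunk)
    emitted <- emitted + nrow(chunk)
    start <- max(idx) + 1
  }
  invisible(emitted)
}

#' Select the top-k universe features by chi-square
#'
#' Exact top-k over the full augmented universe. `method = "kernel"` (the
#' default) scores with the compiled single-pass kernel holding a bounded
#' heap; `method = "stream"` iterates materialized blocks from
#' [product_stream()] and keeps a running top-k, which is slower but serves
#' as an independent route on small universes. Ties in chi-square are
#' broken toward the earlier stream position. A second pass materializes
#' the selected columns.
#'
#' @param stage1 a `feature_block` (the training partition in
#'   cross-validation).
#' @param labels 0/1 labels.
#' @param k number of features to keep (the analysis default at full scale
#'   is 40000); capped at the universe size.
#' @param method `"kernel"` or `"stream"`.
#' @param block_size streamed block width for `method = "stream"`.
#' @return A `topk_selection`: data.frame `records` (rank, id, chi2,
#'   constituents, encoded descriptor) and matrix `values`
#'   (subjects x k, columns in rank order).
#' @export
select_top_k <- function(stage1, labels, k = 40000L,
                         method = c("kernel", "stream"),
                         block_size = 8192L,
                         calibrate = c("always", "negative_only")) {
  method <- match.arg(method)
  calibrate <- match.arg(calibrate)
  stopifnot(inherits(stage1, "feature_block"), k >= 1)
  y <- as.integer(labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both classes must be non-empty")
  U <- universe_size(ncol(stage1$values))
  k <- as.integer(min(k, U))

  if (method == "kernel") {
    res <- chisq_scan_cpp(stage1$values, matrix(as.double(y), ncol = 1L),
                          k, calibrate == "always", FALSE)$topk[[1]]
    ids <- res$ids; chi2 <- res$chi2
  } else {
    st <- product_stream(stage1, block_size = block_size)
    ids <- numeric(0); chi2 <- numeric(0)
    repeat {
      blk <- st$next_block()
      if (is.null(blk)) break
      bc <- chisq_block(blk$values, y, calibrate = calibrate)
      ids <- c(ids, blk$ids); chi2 <- c(chi2, bc)
      ord <- order(-chi2, ids)[seq_len(min(k, length(ids)))]
      ids <- ids[ord]; chi2 <- chi2[ord]
    }
  }
  desc <- describe_features(ids, stage1$descriptors)
  records <- data.frame(rank = seq_along(ids), id = ids, chi2 = chi2,
                        f1 = desc$f1, f2 = desc$f2, log = desc$log,
                        encoded = desc$encoded, stringsAsFactors = FALSE)
  values <- materialize_features(stage1, ids)
  structure(list(records = records, values = values, k = k,
                 n_universe = U),
            class = "topk_selection")
}

#' @export
print.topk_selection <- function(x, ...) {
  cat(sprintf("topk_selection: %d of %.0f universe features\n",
              nrow(x$records), x$n_universe))
  print(head(x$records[, c("rank", "chi2", "encoded")], 10))
  invisible(x)
}

#' Materialize universe features by id
#'
#' Computes the actual feature columns for given universe ids. Raw features
#' are the plain singleton values or elementwise products; log features
#' apply `log(1 + (x - min)/(max - min))` with the min/max taken from the
#' reference (training) block, clipping out-of-range values from `newdata`
#' to the reference range so the transform stays defined.
#'
#' @param stage1 reference `feature_block` (defines log calibration).
#' @param ids universe feature ids.
#' @param newdata optional stage-1 value matrix for other subjects
#'   (defaults to the reference block's own values).
#' @return Matrix, subjects x length(ids).
#' @export
materialize_features <- function(stage1, ids, newdata = NULL) {
  V <- stage1$values
  X <- if (is.null(newdata)) V else newdata
  p <- ncol(V)
  stopifnot(ncol(X) == p)
  out <- matrix(NA_real_, nrow(X), length(ids))
  bb <- id_to_base(ids)
  for (m in seq_along(ids)) {
    b <- bb$base[m]
    if (b <= p) {
      u <- X[, b]; uref <- V[, b]
    } else {
      ij <- pair_unrank(b - p, p)
      u <- X[, ij[1, "i"]] * X[, ij[1, "j"]]
      uref <- V[, ij[1, "i"]] * V[, ij[1, "j"]]
    }
    if (bb$log[m]) {
      mn <- min(uref); rng <- max(uref) - mn
      out[, m] <- if (rng == 0) 0 else
        log1p((pmin(pmax(u, mn), max(uref)) - mn) / rng)
    } else out[, m] <- u
  }
  out
}
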
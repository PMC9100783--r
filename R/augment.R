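# Feature augmentation: stage-1 statistical summaries, the streamed
# pairwise-product universe, and the calibrated log transform.
#
# Stage 1 appends, to the identity features, seven statistical measures
# (max, min, range, mean, std, q75, q25) computed three ways: over the ROI
# axis for each (band, task), over the task axis for each (roi, band), and
# over the band axis for each (roi, task). Stage 2 is the universe of
# pairwise products of all stage-1 features, and every feature (stage-1 or
# product) additionally gets a calibrated log twin
# log(1 + (x - min) / (max - min)), doubling the universe. The full
# universe is never materialized; it is streamed in fixed-size blocks in a
# canonical order (see `product_stream`).
#
# Conventions fixed here so streamed values are deterministic: std is the
# population standard deviation (divide by n), and quantiles use linear
# interpolation between order statistics (R type 7).

STAT7 <- function(v) {
  m <- mean(v)
  q <- stats::quantile(v, c(0.75, 0.25), names = FALSE, type = 7)
  c(max(v), min(v), max(v) - min(v), m,
    sqrt(max(0, mean(v * v) - m * m)), q[1], q[2])
}

row_stats <- function(M) {
  # n x 7 matrix of the seven measures applied to each row of M
  t(apply(M, 1, STAT7))
}

#' Stage-1 descriptor table
#'
#' Enumerates the stage-1 features in their fixed order: the identity
#' features (roi-major, band theta/alpha/beta, then task), then the seven
#' measures aggregated over ROIs for each (band, task), over tasks for each
#' (roi, band), and over bands for each (roi, task). `NA` in a column means
#' that axis was aggregated over.
#'
#' @param n_roi,n_task tensor dimensions.
#' @return data.frame with columns `measure`, `roi`, `band`, `task`.
#' @export
stage1_descriptors <- function(n_roi, n_task) {
  R <- n_roi; Tn <- n_task
  ident <- data.frame(
    measure = "identity",
    roi = rep(seq_len(R), each = 3L * Tn),
    band = rep(rep(1:3, each = Tn), times = R),
    task = rep(seq_len(Tn), times = 3L * R))
  agg_roi <- expand.grid(measure = seq_along(MEASURES), task = seq_len(Tn),
                         band = 1:3)[, c("measure", "band", "task")]
  agg_roi <- data.frame(measure = MEASURES[agg_roi$measure], roi = NA_integer_,
                        band = agg_roi$band, task = agg_roi$task)
  agg_task <- expand.grid(measure = seq_along(MEASURES), band = 1:3,
                          roi = seq_len(R))[, c("measure", "roi", "band")]
  agg_task <- data.frame(measure = MEASURES[agg_task$measure],
                         roi = agg_task$roi, band = agg_task$band,
                         task = NA_integer_)
  agg_band <- expand.grid(measure = seq_along(MEASURES), task = seq_len(Tn),
                          roi = seq_len(R))[, c("measure", "roi", "task")]
  agg_band <- data.frame(measure = MEASURES[agg_band$measure],
                         roi = agg_band$roi, band = NA_integer_,
                         task = agg_band$task)
  out <- rbind(ident, agg_roi, agg_task, agg_band)
  rownames(out) <- NULL
  out
}

#' Compute stage-1 features for a cohort
#'
#' @param cohort a `cohort` object.
#' @return A `feature_block`: list with `descriptors` (see
#'   [stage1_descriptors()]) and `values` (subjects x n_stage1 matrix).
#' @examples
#' out <- generate_cohort(synthetic_config(n_subjects = 10, n_roi = 4))
#' dim(stage1_features(out$cohort)$values)  # 10 x (60 + 7*(15 + 12 + 20))
#' @export
stage1_features <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$dims
  R <- d[["n_roi"]]; Tn <- d[["n_task"]]
  X <- cohort$features
  n <- nrow(X)
  desc <- stage1_descriptors(R, Tn)
  vals <- matrix(NA_real_, n, nrow(desc))
  vals[, seq_len(R * 3L * Tn)] <- X
  pos <- R * 3L * Tn
  # over ROIs, per (band, task)
  for (b in 1:3) for (tk in seq_len(Tn)) {
    cols <- tensor_col(seq_len(R), b, tk, 3L, Tn)
    vals[, pos + 1:7] <- row_stats(X[, cols, drop = FALSE])
    pos <- pos + 7L
  }
  # over tasks, per (roi, band)
  for (r in seq_len(R)) for (b in 1:3) {
    cols <- tensor_col(r, b, seq_len(Tn), 3L, Tn)
    vals[, pos + 1:7] <- row_stats(X[, cols, drop = FALSE])
    pos <- pos + 7L
  }
  # over bands, per (roi, task)
  for (r in seq_len(R)) for (tk in seq_len(Tn)) {
    cols <- tensor_col(r, 1:3, tk, 3L, Tn)
    vals[, pos + 1:7] <- row_stats(X[, cols, drop = FALSE])
    pos <- pos + 7L
  }
  stopifnot(pos == nrow(desc))
  structure(list(descriptors = desc, values = vals), class = "feature_block")
}

#' Augmented feature-universe counts
#'
#' Pure arithmetic on the tensor dimensions: the stage-1 count
#' `R*B*T + 7*(B*T + R*B + R*T)`, the count after adding all unordered
#' pairwise products, and the count after doubling with calibrated log
#' twins.
#'
#' @param R,B,T number of ROIs, bands, tasks.
#' @return Named numeric vector `stage1`, `with_products`, `with_logs`, with
#'   attribute `components` giving the stage-1 group sizes.
#' @examples
#' count_augmented(68, 3, 5)  # 4933, 12169711, 24339422
#' @export
count_augmented <- function(R, B, T) {
  stopifnot(R >= 1, B >= 1, T >= 1)
  comp <- c(identity = R * B * T, agg_roi = 7 * B * T,
            agg_task = 7 * R * B, agg_band = 7 * R * T)
  s1 <- sum(comp)
  out <- c(stage1 = s1, with_products = s1 + choose(s1, 2),
           with_logs = 2 * (s1 + choose(s1, 2)))
  attr(out, "components") <- comp
  out
}

#' Calibrated log transform of one feature
#'
#' Maps a per-subject feature vector to `log(1 + (x - min)/(max - min))`,
#' so the minimum maps to 0 and the maximum to `log 2`. A constant feature
#' (max = min) maps to all zeros, the limit of the formula as the spread
#' shrinks.
#'
#' @param values numeric vector (one value per subject), length >= 2.
#' @return Transformed vector in `[0, log 2]`.
#' @examples
#' log_calibrate(c(0, 1, 3))  # 0, log(4/3), log(2)
#' @export
log_calibrate <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  rng <- max(values) - min(values)
  if (rng == 0) return(rep(0, length(values)))
  log1p((values - min(values)) / rng)
}

# ---- canonical universe indexing --------------------------------------
#
# Base features: b = 1..p are the stage-1 features (pass-through
# singletons); b = p+1 .. p+choose(p,2) are the unordered pairs (i, j),
# i < j, in lexicographic order. Universe feature ids interleave each base
# feature with its log twin: raw id = 2b - 1, log id = 2b, so logs are
# generated alongside each product rather than in a second pass. Stream
# order (and the tie-break order for selection) is ascending id.

pair_unrank <- function(q, p) {
  # lexicographic (i < j) pair index -> (i, j)
  cum <- cumsum(c(0, (p - 1):1))
  i <- findInterval(q - 0.5, cum)
  j <- i + (q - cum[i])
  cbind(i = i, j = j)
}

pair_rank <- function(i, j, p) {
  (i - 1) * p - i * (i - 1) / 2 + (j - i)
}

universe_size <- function(p) 2 * (p + choose(p, 2))

id_to_base <- function(id) list(base = (id + 1) %/% 2, log = id %% 2 == 0)

#' Describe universe feature ids
#'
#' @param ids integer universe feature ids (ascending stream order).
#' @param descriptors stage-1 descriptor table of the block the ids refer
#'   to.
#' @return data.frame with the two constituent stage-1 indices (`f2` is NA
#'   for pass-through singletons), the `log` flag, and a compact text
#'   encoding `measure:roi:band:task[*measure:roi:band:task][,log]`
#'   (`agg` marks an aggregated axis).
#' @export
describe_features <- function(ids, descriptors) {
  p <- nrow(descriptors)
  bb <- id_to_base(ids)
  b <- bb$base
  f1 <- integer(length(b)); f2 <- rep(NA_integer_, length(b))
  single <- b <= p
  f1[single] <- b[single]
  if (any(!single)) {
    ij <- pair_unrank(b[!single] - p, p)
    f1[!single] <- ij[, "i"]
    f2[!single] <- ij[, "j"]
  }
  enc1 <- encode_stage1(descriptors, f1)
  enc <- ifelse(is.na(f2), enc1,
                paste0(enc1, "*", encode_stage1(descriptors, f2)))
  enc <- ifelse(bb$log, paste0(enc, ",log"), enc)
  data.frame(id = ids, f1 = f1, f2 = f2, log = bb$log, encoded = enc,
             stringsAsFactors = FALSE)
}

encode_stage1 <- function(descriptors, idx) {
  d <- descriptors[idx, , drop = FALSE]
  paste(d$measure,
        ifelse(is.na(d$roi), "agg", d$roi),
        ifelse(is.na(d$band), "agg", BAND_LEVELS[d$band]),
        ifelse(is.na(d$task), "agg", d$task), sep = ":")
}

#' Stream the augmented feature universe in blocks
#'
#' Returns an iterator over the full augmented universe built from a
#' stage-1 block: every stage-1 feature passed through as a singleton,
#' every unordered product of two distinct stage-1 features exactly once
#' (lexicographic order), each immediately followed by its calibrated log
#' twin. Calling `$next_block()` yields a list with `ids`, `values`
#' (subjects x width matrix) and `done`, or `NULL` when exhausted;
#' `$reset()` rewinds.
#'
#' @param stage1 a `feature_block` from [stage1_features()].
#' @param block_size maximum number of universe features per block.
#' @return An iterator object (list of closures) with `$next_block()`,
#'   `$reset()`, and `$n_total`.
#' @export
product_stream <- function(stage1, block_size = 4096L) {
  stopifnot(inherits(stage1, "feature_block"), block_size >= 1)
  V <- stage1$values
  p <- ncol(V)
  n_total <- universe_size(p)
  pos <- 0L

  next_block <- function() {
    if (pos >= n_total) return(NULL)
    ids <- (pos + 1):min(pos + block_size, n_total)
    pos <<- max(ids)
    bb <- id_to_base(ids)
    vals <- matrix(NA_real_, nrow(V), length(ids))
    ub <- unique(bb$base)
    base_vals <- matrix(NA_real_, nrow(V), length(ub))
    for (k in seq_along(ub)) {
      b <- ub[k]
      base_vals[, k] <- if (b <= p) V[, b] else {
        ij <- pair_unrank(b - p, p)
        V[, ij[1, "i"]] * V[, ij[1, "j"]]
      }
    }
    for (k in seq_along(ids)) {
      col <- base_vals[, match(bb$base[k], ub)]
      vals[, k] <- if (bb$log[k]) log_calibrate(col) else col
    }
    list(ids = ids, values = vals, done = pos >= n_total)
  }
  list(next_block = next_block,
       reset = function() { pos <<- 0L; invisible(NULL) },
       n_total = n_total,
       n_stage1 = p)
}
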
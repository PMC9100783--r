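# ROI-pair strength aggregation, the thresholded hub graph, and
# current-flow centralities.
#
# Every product feature whose two constituents carry concrete, distinct
# ROIs contributes its chi-square statistic to the cumulative "strength" of
# that ROI pair (i1 < i2), summed over both constituents' bands, tasks and
# the log flag. Constituents with an aggregated band/task attribute still
# contribute to the pair strength, but only concrete levels compete when
# asking which band or task dominates a pair. Products of two features
# within one ROI, and features without two concrete ROIs, are skipped and
# counted.

new_strength_matrix <- function(n_roi, n_task, symptom = NA_character_) {
  structure(list(
    symptom = symptom, n_roi = n_roi, n_task = n_task,
    strength = matrix(0, n_roi, n_roi),
    band_acc = array(0, c(n_roi, n_roi, 4L)),   # theta/alpha/beta/agg
    task_acc = array(0, c(n_roi, n_roi, n_task + 1L)),
    log_acc = array(0, c(n_roi, n_roi, 2L)),    # raw/log
    n_records = 0, n_skipped = 0),
    class = "strength_matrix")
}

add_sym <- function(M, lo, hi, w) {
  # accumulate w into symmetric matrix M at (lo, hi) with duplicates summed
  n <- nrow(M)
  agg <- rowsum(w, (lo - 1) * n + hi)
  key <- as.integer(rownames(agg))
  alo <- (key - 1) %/% n + 1
  ahi <- (key - 1) %% n + 1
  M[cbind(alo, ahi)] <- M[cbind(alo, ahi)] + agg[, 1]
  M[cbind(ahi, alo)] <- M[cbind(ahi, alo)] + agg[, 1]
  M
}

#' Accumulate chi-square records into an ROI-pair strength matrix
#'
#' Single-pass, order-independent aggregation: can be called once with all
#' records or repeatedly with chunks, passing the previous result as
#' `into`.
#'
#' @param records data.frame with columns `f1`, `f2` (stage-1 feature
#'   indices; `f2` `NA` for singletons), `log`, `chi2` — the chunks emitted
#'   by [score_all_for_strength()].
#' @param descriptors the stage-1 descriptor table.
#' @param n_roi,n_task tensor dimensions.
#' @param symptom optional symptom tag.
#' @param into an existing `strength_matrix` to update.
#' @return A `strength_matrix`: symmetric zero-diagonal `strength` plus
#'   per-pair band/task/log sub-accumulators and skip counts.
#' @export
accumulate_strengths <- function(records, descriptors, n_roi, n_task,
                                 symptom = NA_character_, into = NULL) {
  sm <- into %||% new_strength_matrix(n_roi, n_task, symptom)
  stopifnot(inherits(sm, "strength_matrix"))
  roi1 <- descriptors$roi[records$f1]
  roi2 <- descriptors$roi[ifelse(is.na(records$f2), 1L, records$f2)]
  roi2[is.na(records$f2)] <- NA_integer_
  ok <- !is.na(roi1) & !is.na(roi2) & roi1 != roi2
  sm$n_records <- sm$n_records + nrow(records)
  sm$n_skipped <- sm$n_skipped + sum(!ok)
  if (!any(ok)) return(sm)

  r <- records[ok, , drop = FALSE]
  lo <- pmin(roi1[ok], roi2[ok]); hi <- pmax(roi1[ok], roi2[ok])
  w <- r$chi2
  sm$strength <- add_sym(sm$strength, lo, hi, w)

  lvl <- function(x, agg_level) ifelse(is.na(x), agg_level, x)
  b1 <- lvl(descriptors$band[r$f1], 4L)
  b2 <- lvl(descriptors$band[r$f2], 4L)
  for (lev in 1:4) {
    hit <- b1 == lev | b2 == lev
    if (any(hit))
      sm$band_acc[, , lev] <- add_sym(sm$band_acc[, , lev],
                                      lo[hit], hi[hit], w[hit])
  }
  t1 <- lvl(descriptors$task[r$f1], n_task + 1L)
  t2 <- lvl(descriptors$task[r$f2], n_task + 1L)
  for (lev in seq_len(n_task + 1L)) {
    hit <- t1 == lev | t2 == lev
    if (any(hit))
      sm$task_acc[, , lev] <- add_sym(sm$task_acc[, , lev],
                                      lo[hit], hi[hit], w[hit])
  }
  for (lev in 1:2) {
    hit <- r$log == (lev == 2)
    if (any(hit))
      sm$log_acc[, , lev] <- add_sym(sm$log_acc[, , lev],
                                     lo[hit], hi[hit], w[hit])
  }
  sm
}

#' ROI-pair strengths for one symptom of a cohort
#'
#' High-level wrapper: computes stage-1 features, scores the full
#' augmented universe against the symptom labels, and aggregates all
#' product features with two concrete distinct ROIs into the strength
#' matrix.
#'
#' @param cohort a `cohort`.
#' @param symptom symptom name.
#' @param labels optional 0/1 override of the cohort's labels.
#' @param calibrate chi-square calibration mode (see [score_universe()]).
#' @return A `strength_matrix`.
#' @export
roi_pair_strengths <- function(cohort, symptom, labels = NULL,
                               calibrate = c("always", "negative_only")) {
  calibrate <- match.arg(calibrate)
  stopifnot(inherits(cohort, "cohort"))
  symptom <- match.arg(symptom, SYMPTOMS)
  y <- labels %||% unname(cohort$labels[, symptom])
  stage1 <- stage1_features(cohort)
  d <- cohort$dims
  sm <- new_strength_matrix(d[["n_roi"]], d[["n_task"]], symptom)
  score_all_for_strength(stage1, y, sink = function(chunk) {
    sm <<- accumulate_strengths(chunk, stage1$descriptors,
                                d[["n_roi"]], d[["n_task"]],
                                symptom, into = sm)
  }, calibrate = calibrate)
  sm
}

#' @export
print.strength_matrix <- function(x, ...) {
  cat(sprintf(
    "strength_matrix (%s): %d ROIs, %.0f records (%.0f without two concrete ROIs)\n",
    x$symptom, x$n_roi, x$n_records, x$n_skipped))
  top <- which(x$strength == max(x$strength), arr.ind = TRUE)[1, ]
  cat(sprintf("max pair strength %.2f at (%d, %d)\n",
              max(x$strength), min(top), max(top)))
  invisible(x)
}

#' Vertex strength: total pair strength incident to one ROI
#'
#' @param m a `strength_matrix`.
#' @param i ROI id (omit for all).
#' @return Numeric vector of row sums of the strength matrix.
#' @export
vertex_strength <- function(m, i = NULL) {
  stopifnot(inherits(m, "strength_matrix"))
  vs <- rowSums(m$strength)
  if (is.null(i)) vs else vs[i]
}

#' Dominant band or task of an ROI pair or vertex
#'
#' The level with the largest accumulated chi-square mass. Only concrete
#' levels compete (records whose constituents aggregated over the factor
#' are excluded from the argmax); ties break toward the earlier level
#' (theta < alpha < beta; task 1 < ... < n_task); an all-zero accumulator
#' returns `"undetermined"`.
#'
#' @param m a `strength_matrix`.
#' @param pair integer pair `c(i, j)`; or
#' @param vertex single ROI id (accumulators summed over all its pairs).
#' @param factor `"band"` or `"task"`.
#' @return Band name, task id (as character), or `"undetermined"`.
#' @export
dominant_factor <- function(m, pair = NULL, vertex = NULL,
                            factor = c("band", "task")) {
  factor <- match.arg(factor)
  stopifnot(inherits(m, "strength_matrix"), is.null(pair) != is.null(vertex))
  acc <- if (factor == "band") m$band_acc else m$task_acc
  n_lev <- dim(acc)[3] - 1L  # concrete levels only
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2)
    mass <- acc[pair[1], pair[2], seq_len(n_lev)]
  } else {
    mass <- colSums(matrix(acc[vertex, , seq_len(n_lev)], ncol = n_lev))
  }
  if (all(mass == 0)) return("undetermined")
  lev <- which.max(mass)  # which.max takes the earliest maximum
  if (factor == "band") BAND_LEVELS[lev] else as.character(lev)
}

#' Build the thresholded ROI hub graph
#'
#' Creates an undirected weighted graph over the ROIs. In the default
#' `"pair"` mode an edge joins `(i, j)` when their pair strength exceeds
#' the threshold (default 100), weighted by that strength. The
#' `"vertex_sum"` mode is an alternative reading in which the criterion is
#' the sum of the two endpoints' vertex strengths (pairs with zero mass
#' never gain an edge).
#'
#' @param m a `strength_matrix`.
#' @param threshold edge threshold (default 100).
#' @param mode `"pair"` or `"vertex_sum"`.
#' @param atlas optional atlas for vertex labels.
#' @return An `roi_graph` wrapping an igraph object with vertex attributes
#'   `strength`, `region`, `hemisphere` and edge attribute `weight`.
#' @export
build_graph <- function(m, threshold = 100, mode = c("pair", "vertex_sum"),
                        atlas = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "strength_matrix"), threshold >= 0)
  n <- m$n_roi
  vs <- vertex_strength(m)
  ut <- which(upper.tri(m$strength), arr.ind = TRUE)
  w <- m$strength[ut]
  keep <- if (mode == "pair") w > threshold
          else w > 0 & (vs[ut[, 1]] + vs[ut[, 2]]) > threshold
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (is.null(atlas)) atlas <- dk_atlas(min(n, 68L))
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$region <- atlas$region[seq_len(n)]
  igraph::V(g)$hemisphere <- atlas$hemisphere[seq_len(n)]
  igraph::V(g)$strength <- vs
  if (any(keep)) {
    ed <- t(ut[keep, , drop = FALSE])
    g <- igraph::add_edges(g, as.vector(ed), weight = w[keep])
  }
  structure(list(graph = g, threshold = threshold, mode = mode,
                 symptom = m$symptom),
            class = "roi_graph")
}

#' @export
print.roi_graph <- function(x, ...) {
  cat(sprintf("roi_graph (%s): %d vertices, %d edges (strength > %g, %s mode)\n",
              x$symptom, igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, x$mode))
  invisible(x)
}

#' @export
plot.roi_graph <- function(x, ...) {
  g <- x$graph
  vs <- igraph::V(g)$strength
  size <- 4 + 12 * sqrt(vs / max(vs, 1e-12))
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    vertex.size = size, vertex.label.cex = 0.6,
    vertex.label = paste0(igraph::V(g)$region,
                          igraph::V(g)$hemisphere), ...)
  invisible(x)
}

#' Current-flow closeness and betweenness centralities
#'
#' Treats the hub graph as a resistor network with edge weights as
#' conductances and computes, per connected component with at least two
#' vertices, the current-flow closeness
#' `(n_c - 1) / sum_j r_ij` (with `r` the effective resistance from the
#' component Laplacian's pseudo-inverse) and the current-flow betweenness
#' (mean over source/sink pairs of the current throughput of each interior
#' vertex, normalized by `(n_c - 1)(n_c - 2)/2` pairs, hence in `[0, 1]`).
#' Vertices in singleton components get `NA` for both.
#'
#' @param g an `roi_graph` (or igraph with a `weight` edge attribute).
#' @return data.frame with `roi`, `region`, `hemisphere`, `component`,
#'   `closeness`, `betweenness`.
#' @export
current_flow_centralities <- function(g) {
  graph <- if (inherits(g, "roi_graph")) g$graph else g
  n <- igraph::vcount(graph)
  comp <- igraph::components(graph)
  closeness <- rep(NA_real_, n)
  betweenness <- rep(NA_real_, n)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    nv <- length(vids)
    if (nv < 2) next
    sub <- igraph::induced_subgraph(graph, vids)
    W <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    L <- diag(rowSums(W)) - W
    Linv <- MASS::ginv(L)
    dL <- diag(Linv)
    Rmat <- outer(dL, dL, "+") - 2 * Linv   # effective resistances
    closeness[vids] <- (nv - 1) / rowSums(Rmat)
    bet <- numeric(nv)
    if (nv > 2) {
      el <- igraph::as_edgelist(sub, names = FALSE)
      ew <- igraph::E(sub)$weight
      for (s in 1:(nv - 1)) for (t in (s + 1):nv) {
        phi <- Linv[, s] - Linv[, t]
        cur <- abs(ew * (phi[el[, 1]] - phi[el[, 2]]))
        tv <- numeric(nv)
        tv[sort(unique(el[, 1]))] <-
          rowsum(cur, el[, 1])[, 1]
        agg2 <- rowsum(cur, el[, 2])
        tv[as.integer(rownames(agg2))] <-
          tv[as.integer(rownames(agg2))] + agg2[, 1]
        tv <- tv / 2
        tv[c(s, t)] <- 0
        bet <- bet + tv
      }
      bet <- bet / ((nv - 1) * (nv - 2) / 2)
    }
    betweenness[vids] <- bet
  }
  atlas <- dk_atlas(min(n, 68L))
  data.frame(roi = seq_len(n),
             region = atlas$region[seq_len(n)],
             hemisphere = atlas$hemisphere[seq_len(n)],
             component = comp$membership,
             closeness = closeness, betweenness = betweenness)
}

#' Top hub table (per-symptom centrality ranking)
#'
#' @param centralities output of [current_flow_centralities()].
#' @param n_top rows per metric (default 5).
#' @return data.frame of the top ROIs by closeness and by betweenness.
#' @export
top_hubs <- function(centralities, n_top = 5L) {
  byc <- centralities[order(-centralities$closeness), ]
  byb <- centralities[order(-centralities$betweenness), ]
  rbind(cbind(metric = "closeness", head(byc, n_top)),
        cbind(metric = "betweenness", head(byb, n_top)))
}

#' Write the hub graph as a weighted edge list and GraphML
#'
#' @param g an `roi_graph`.
#' @param edge_list_path tab-delimited `roi_i`, `roi_j`, `strength` output.
#' @param graphml_path optional GraphML output.
#' @return Invisibly, the path(s).
#' @export
write_graph_files <- function(g, edge_list_path, graphml_path = NULL) {
  stopifnot(inherits(g, "roi_graph"))
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  df <- data.frame(roi_i = el[, 1], roi_j = el[, 2],
                   strength = igraph::E(g$graph)$weight)
  write.table(df, edge_list_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(g$graph, graphml_path, format = "graphml")
  invisible(c(edge_list_path, graphml_path))
}
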
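# Independent oracles and small fixture builders used across the suite.

# Direct transcription of the continuous chi-square definition: per-class
# observed sums vs expected sums from class proportions. Kept free of any
# package internals so it can vouch for them.
oracle_chi2 <- function(values, labels) {
  n <- length(values)
  out <- 0
  for (cls in c(0, 1)) {
    S <- sum(values[labels == cls])
    E <- sum(values) * (sum(labels == cls) / n)
    out <- out + (S - E)^2 / E
  }
  out
}

# Brute-force scoring of a whole materialized universe (block iterator
# route), returning a data.frame sorted the way selection must sort.
oracle_score_universe <- function(stage1, y, calibrate = "always") {
  st <- product_stream(stage1, block_size = 997L)
  ids <- numeric(0); chi2 <- numeric(0)
  repeat {
    blk <- st$next_block()
    if (is.null(blk)) break
    V <- blk$values
    bc <- vapply(seq_len(ncol(V)), function(j) {
      v <- V[, j]
      if (max(v) == min(v)) return(0)
      if (calibrate == "always" || min(v) < 0)
        v <- (v - min(v)) / (max(v) - min(v))
      oracle_chi2(v, y)
    }, 0)
    ids <- c(ids, blk$ids); chi2 <- c(chi2, bc)
  }
  df <- data.frame(id = ids, chi2 = chi2)
  df[order(-df$chi2, df$id), ]
}

# Dense electrical-network oracle for current-flow centralities: for every
# source/sink pair, solve the grounded Laplacian system directly for node
# potentials, read off edge currents and effective resistances. Written
# from the physics, independently of the package's pseudo-inverse route.
oracle_current_flow <- function(W) {
  nv <- nrow(W)
  L <- diag(rowSums(W)) - W
  rsum <- numeric(nv)
  bet <- numeric(nv)
  el <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  for (s in 1:(nv - 1)) for (t in (s + 1):nv) {
    b <- numeric(nv); b[s] <- 1; b[t] <- -1
    keep <- setdiff(seq_len(nv), nv)     # ground the last node
    phi <- numeric(nv)
    phi[keep] <- solve(L[keep, keep], b[keep])
    r <- phi[s] - phi[t]                 # effective resistance
    rsum[s] <- rsum[s] + r; rsum[t] <- rsum[t] + r
    if (nv > 2 && nrow(el)) {
      cur <- abs(W[el] * (phi[el[, 1]] - phi[el[, 2]]))
      tv <- numeric(nv)
      for (e in seq_len(nrow(el))) {
        tv[el[e, 1]] <- tv[el[e, 1]] + cur[e]
        tv[el[e, 2]] <- tv[el[e, 2]] + cur[e]
      }
      tv <- tv / 2
      tv[c(s, t)] <- 0
      bet <- bet + tv
    }
  }
  list(closeness = (nv - 1) / rsum,
       betweenness = if (nv > 2) bet / ((nv - 1) * (nv - 2) / 2)
                     else numeric(nv))
}

# Random connected weighted adjacency matrix on nv vertices.
random_weighted_graph <- function(nv, p_edge = 0.6) {
  repeat {
    W <- matrix(0, nv, nv)
    ut <- which(upper.tri(W), arr.ind = TRUE)
    on <- runif(nrow(ut)) < p_edge
    # spanning chain keeps the graph connected
    for (i in seq_len(nv - 1)) on[ut[, 1] == i & ut[, 2] == i + 1] <- TRUE
    w <- runif(nrow(ut), 0.2, 3)
    W[ut[on, , drop = FALSE]] <- w[on]
    W <- W + t(W)
    if (any(W > 0)) return(W)
  }
}

# Tiny cohort with a caller-supplied tensor (subjects x roi x band x task).
toy_cohort <- function(arr, scores = NULL) {
  n <- dim(arr)[1]
  if (is.null(scores))
    scores <- data.frame(subject_id = sprintf("T%02d", seq_len(n)),
                         anxiety = rep(c(0L, 7L), length.out = n),
                         depression = 0L, inattention = 0L,
                         hyperactivity = 0L)
  as_cohort(arr, scores)
}

# strength_matrix from hand-made records (for the aggregation examples)
toy_strength <- function(n_roi, pairs) {
  sm <- neurosym:::new_strength_matrix(n_roi, 5L)
  for (p in pairs) {
    i <- p[[1]]; j <- p[[2]]; w <- p[[3]]
    sm$strength[i, j] <- sm$strength[i, j] + w
    sm$strength[j, i] <- sm$strength[j, i] + w
  }
  sm
}
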
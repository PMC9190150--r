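# Independent oracles, coded straight from the definitions and kept free
# of the package's own implementation paths.

# Connectance between zones i and j, looped term by term.
oracle_connectance <- function(T_, i, j) {
  n <- nrow(T_)
  rowsum_i <- 0; rowsum_j <- 0; colsum_i <- 0; colsum_j <- 0
  for (k in seq_len(n)) {
    rowsum_i <- rowsum_i + T_[i, k]
    rowsum_j <- rowsum_j + T_[j, k]
    colsum_i <- colsum_i + T_[k, i]
    colsum_j <- colsum_j + T_[k, j]
  }
  t1 <- 0
  if (colsum_j > 0 && rowsum_i > 0) t1 <- (T_[i, j] / colsum_j) * (T_[i, j] / rowsum_i)
  t2 <- 0
  if (colsum_i > 0 && rowsum_j > 0) t2 <- (T_[j, i] / colsum_i) * (T_[j, i] / rowsum_j)
  t1 + t2
}

oracle_supply_sc <- function(T_, i) {
  rs <- sum(T_[i, ])
  if (rs == 0) 1 else T_[i, i] / rs
}

oracle_demand_sc <- function(T_, j) {
  cs <- sum(T_[, j])
  if (cs == 0) 1 else T_[j, j] / cs
}

# One merge iteration by exhaustive enumeration of the step definitions:
# candidate = argmin over zones of min(demand, supply) (tie: smallest id);
# partner = argmax over other zones of connectance (tie: smallest id),
# falling back to longest shared boundary when all connectance is zero.
oracle_merge_step <- function(T_, boundary = NULL) {
  ids <- rownames(T_)
  best_sc <- Inf; cand <- NULL
  for (z in sort(ids)) {
    sc <- min(oracle_demand_sc(T_, z), oracle_supply_sc(T_, z))
    if (sc < best_sc) { best_sc <- sc; cand <- z }
  }
  best_c <- -Inf; partner <- NULL
  for (z in sort(setdiff(ids, cand))) {
    cv <- oracle_connectance(T_, cand, z)
    if (cv > best_c) { best_c <- cv; partner <- z }
  }
  if (best_c == 0 && !is.null(boundary)) {
    best_b <- -Inf
    for (z in sort(setdiff(ids, cand))) {
      if (boundary[cand, z] > best_b) { best_b <- boundary[cand, z]; partner <- z }
    }
  }
  list(candidate = cand, candidate_sc = best_sc, partner = partner,
       connectance = max(best_c, 0))
}

# Random integer zone flow matrix with a diagonal-heavy option.
random_flow_matrix <- function(n, max_count = 50, diag_boost = 0) {
  ids <- sprintf("Z%02d", seq_len(n))
  T_ <- matrix(sample(0:max_count, n * n, replace = TRUE), n, n,
               dimnames = list(ids, ids))
  diag(T_) <- diag(T_) + diag_boost
  T_
}

# Ray-casting point-in-polygon, independent of mgcv.
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Adjusted Rand Index between two labelled partitions over the same units.
partition_ari <- function(labels_a, labels_b) {
  mclust::adjustedRandIndex(labels_a, labels_b)
}

# Tiny rectangular-lattice geography built by hand (independent of the
# package generator): nr x nc unit squares of side `s`, row-major ids.
make_lattice_geo <- function(nr, nc, s = 1, districts = NULL) {
  ids <- sprintf("u%02d", seq_len(nr * nc))
  if (is.null(districts)) districts <- rep("d1", nr * nc)
  geom <- list()
  k <- 0
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      k <- k + 1
      x0 <- (cc - 1) * s; y0 <- (r - 1) * s
      geom[[k]] <- matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s),
                          ncol = 2, byrow = TRUE)
    }
  }
  unit_geography(tibble::tibble(unit_id = ids, district_id = districts,
                                geometry = geom))
}
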
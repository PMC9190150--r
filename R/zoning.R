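# The adapted TTWA engine: self-containment, connectance, the iterative
# merge loop, and automated contiguity repair.

#' Supply-side self-containment
#'
#' Internal flows of a zone as a proportion of all flows originating in it:
#' `T[i, i] / rowsum_i`. A zone generating no trips is vacuously
#' self-contained (returns 1).
#'
#' @param T_ Square zone flow matrix (see [zone_flow_matrix()]).
#' @param i Zone id or index; `NULL` (default) returns the named vector for
#'   all zones.
#' @return Fraction(s) in \[0, 1\].
#' @export
supply_self_containment <- function(T_, i = NULL) {
  rs <- rowSums(T_)
  sc <- ifelse(rs == 0, 1, diag(T_) / ifelse(rs == 0, 1, rs))
  names(sc) <- rownames(T_)
  if (is.null(i)) sc else unname(sc[i])
}

#' Demand-side self-containment
#'
#' Internal flows of a zone as a proportion of all flows ending in it:
#' `T[j, j] / colsum_j`. A zone receiving no trips returns 1.
#'
#' @inheritParams supply_self_containment
#' @param j Zone id or index; `NULL` (default) returns all zones.
#' @return Fraction(s) in \[0, 1\].
#' @export
demand_self_containment <- function(T_, j = NULL) {
  cs <- colSums(T_)
  sc <- ifelse(cs == 0, 1, diag(T_) / ifelse(cs == 0, 1, cs))
  names(sc) <- colnames(T_)
  if (is.null(j)) sc else unname(sc[j])
}

#' Per-zone self-containment table
#'
#' @inheritParams supply_self_containment
#' @return Tibble `zone_id`, `demand`, `supply`, `minimum`.
#' @export
self_containment <- function(T_) {
  tibble::tibble(
    zone_id = rownames(T_),
    demand = unname(demand_self_containment(T_)),
    supply = unname(supply_self_containment(T_))
  ) |>
    dplyr::mutate(minimum = pmin(.data$demand, .data$supply))
}

#' Least self-contained zone
#'
#' The merge candidate: the zone minimising min(demand-side, supply-side)
#' self-containment, ties broken by smallest zone identifier.
#'
#' @inheritParams supply_self_containment
#' @return One-row tibble `zone_id`, `demand`, `supply`, `minimum`.
#' @export
least_self_contained <- function(T_) {
  if (nrow(T_) < 2) stop("nothing to merge: the zone system has a single zone")
  sc <- self_containment(T_)
  sc[order(sc$minimum, sc$zone_id, method = "radix")[1], ]
}

#' Connectance between two zones
#'
#' The symmetric strength of flow linkage between zones i and j: the
#' forward flow share product plus the reverse one,
#' `C_ij = T_ij^2 / (colsum_j * rowsum_i) + T_ji^2 / (colsum_i * rowsum_j)`.
#' Any term with a zero denominator contributes 0. The index is symmetric
#' and lies in \[0, 2\].
#'
#' @inheritParams supply_self_containment
#' @param i,j Distinct zone ids or indices.
#' @return Numeric connectance value.
#' @export
connectance <- function(T_, i, j) {
  if (is.character(i)) i <- match(i, rownames(T_))
  if (is.character(j)) j <- match(j, rownames(T_))
  if (is.na(i) || is.na(j)) stop("unknown zone id")
  if (i == j) stop("connectance is defined between distinct zones")
  rs <- rowSums(T_); cs <- colSums(T_)
  term <- function(flow, d1, d2) {
    if (d1 == 0 || d2 == 0) 0 else (flow / d1) * (flow / d2)
  }
  unname(term(T_[i, j], cs[j], rs[i]) + term(T_[j, i], cs[i], rs[j]))
}

#' Best-connected partner zone
#'
#' The zone with the highest connectance to the merge candidate, ties by
#' smallest zone id. When the candidate exchanges no flow with any other
#' zone (all connectance values zero) the partner falls back to the
#' spatially adjacent zone with the longest shared boundary, so isolated
#' zones cannot stall the loop.
#'
#' @inheritParams supply_self_containment
#' @param candidate Zone id of the merge candidate.
#' @param boundary Optional square matrix of zone-to-zone shared boundary
#'   lengths (see the delineation loop) used by the fallback.
#' @return List with `zone_id` and `connectance` (0 when the fallback
#'   fired).
#' @export
best_connected_partner <- function(T_, candidate, boundary = NULL) {
  ids <- rownames(T_)
  others <- setdiff(ids, candidate)
  if (!length(others)) stop("nothing to pair: single-zone system")
  cv <- vapply(others, function(z) connectance(T_, candidate, z), numeric(1))
  if (max(cv) > 0) {
    best <- others[order(-cv, others, method = "radix")[1]]
    return(list(zone_id = best, connectance = unname(cv[best])))
  }
  if (!is.null(boundary)) {
    bl <- boundary[candidate, others]
    if (max(bl) > 0) {
      best <- others[order(-bl, others, method = "radix")[1]]
      return(list(zone_id = best, connectance = 0))
    }
  }
  list(zone_id = others[order(others, method = "radix")[1]], connectance = 0)
}

#' Merge two zones of a zone system
#'
#' Reassigns the units of zone `a` to zone `b` (the absorbing zone keeps
#' the partner's identifier) and unions the anchor facility sets. Zones are
#' only ever merged, never dissolved or split.
#'
#' @param zones A [zone_system()].
#' @param a,b Distinct existing zone ids; `a` is absorbed into `b`.
#' @return The merged [zone_system()].
#' @export
merge_zones <- function(zones, a, b) {
  ids <- zone_ids(zones)
  if (!all(c(a, b) %in% ids)) stop("unknown zone id: ", paste(setdiff(c(a, b), ids), collapse = ", "))
  if (a == b) stop("cannot merge a zone with itself")
  asg <- tibble::as_tibble(zones)
  asg$zone_id[asg$zone_id == a] <- b
  anc <- zone_anchors(zones)
  anc$zone_id[anc$zone_id == a] <- b
  anc <- dplyr::distinct(anc)
  zone_system(asg, anc)
}

# Collapse rows/cols a into b of a square zone matrix (flows or boundary).
#' @keywords internal
merge_matrix <- function(M, a, b) {
  M[b, ] <- M[b, ] + M[a, ]
  M[, b] <- M[, b] + M[, a]
  keep <- setdiff(rownames(M), a)
  M[keep, keep, drop = FALSE]
}

#' @keywords internal
internal_flow_share <- function(T_) {
  tot <- sum(T_)
  if (tot == 0) return(1)
  sum(diag(T_)) / tot
}

#' Delineate natural catchment health districts
#'
#' The adapted travel-to-work-area loop. Starting from hospital-anchored
#' seed zones, it repeatedly finds the zone with the lowest
#' min(demand-side, supply-side) self-containment, finds its
#' best-connected partner by the connectance index, and merges the pair,
#' until every zone meets the self-containment threshold (or one zone
#' remains). Zones are only merged, never dissolved. Spatial contiguity is
#' then repaired automatically; self-containment is reported both before
#' and after repair because repair can perturb it.
#'
#' @param flows Unit-level flow table.
#' @param geo A [unit_geography()] object.
#' @param facilities Data frame with columns `facility_id`, `unit_id`.
#' @param threshold Minimum self-containment each zone must reach
#'   (default 0.96).
#' @param contiguity `"rook"` or `"queen"` adjacency for the boundary
#'   fallback and contiguity repair.
#' @param seed_zones Optional starting [zone_system()]; defaults to
#'   [initial_zones()] on the same inputs.
#' @param repair Apply [contiguity_repair()] to the converged zones
#'   (default `TRUE`).
#' @return An object of class `nchd_delineation`: a list with the final
#'   `zones` (after repair), `zones_before_repair`, the merge `trace`
#'   tibble, self-containment tables `sc_before` and `sc_after`, the final
#'   flow matrices, and the inputs needed by plotting and summary methods.
#' @export
delineate <- function(flows, geo, facilities, threshold = 0.96,
                      contiguity = c("rook", "queen"), seed_zones = NULL,
                      repair = TRUE) {
  contiguity <- match.arg(contiguity)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  fl <- as_flow_table(flows)
  zones <- if (is.null(seed_zones)) initial_zones(fl, geo, facilities) else seed_zones
  adj <- unit_adjacency(geo, rule = contiguity)
  T_ <- zone_flow_matrix(fl, zones, facilities)
  B <- zone_boundary_matrix(zones, adj)

  trace <- list()
  it <- 0L
  while (nrow(T_) > 1) {
    cand <- least_self_contained(T_)
    if (cand$minimum >= threshold) break
    partner <- best_connected_partner(T_, cand$zone_id, boundary = B)
    zones <- merge_zones(zones, cand$zone_id, partner$zone_id)
    T_ <- merge_matrix(T_, cand$zone_id, partner$zone_id)
    B <- merge_matrix(B, cand$zone_id, partner$zone_id)
    diag(B) <- 0
    it <- it + 1L
    trace[[it]] <- tibble::tibble(
      iteration = it,
      candidate_zone = cand$zone_id,
      candidate_sc = cand$minimum,
      partner_zone = partner$zone_id,
      connectance = partner$connectance,
      n_zones = nrow(T_),
      internal_share = internal_flow_share(T_)
    )
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble(
    iteration = integer(), candidate_zone = character(), candidate_sc = numeric(),
    partner_zone = character(), connectance = numeric(), n_zones = integer(),
    internal_share = numeric()
  )

  zones_pre <- zones
  sc_before <- self_containment(T_)
  if (repair) {
    zones_post <- contiguity_repair(zones, geo, facilities, rule = contiguity)
  } else {
    zones_post <- zones
  }
  T_post <- zone_flow_matrix(fl, zones_post, facilities)
  structure(list(
    zones = zones_post,
    zones_before_repair = zones_pre,
    trace = trace,
    threshold = threshold,
    contiguity = contiguity,
    sc_before = sc_before,
    sc_after = self_containment(T_post),
    flow_matrix = T_post,
    flow_matrix_before_repair = T_,
    flows = fl,
    geo = geo,
    facilities = tibble::as_tibble(facilities),
    baseline = FALSE
  ), class = "nchd_delineation")
}

#' Repair spatially fragmented zones
#'
#' Flow-led merging can leave a zone spatially disconnected (for example a
#' sub-district whose women mostly bypass local hospitals for a distant
#' one). For each zone the connected components of its member units are
#' found under the chosen adjacency; the component holding the zone's
#' anchor hospitals is retained (the largest component when anchors are
#' split or absent) and every other component is reassigned wholesale to
#' the adjacent zone sharing the longest total boundary with it, repeating
#' until all zones are spatially connected. Anchor sets are recomputed from
#' the facilities' locations afterwards.
#'
#' @param zones A [zone_system()].
#' @param geo A [unit_geography()] object.
#' @param facilities Data frame with columns `facility_id`, `unit_id`.
#' @param rule Adjacency rule, `"rook"` or `"queen"`.
#' @return A spatially connected [zone_system()].
#' @export
contiguity_repair <- function(zones, geo, facilities, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  adj <- unit_adjacency(geo, rule = rule)
  fac <- tibble::as_tibble(facilities)
  fac$facility_id <- as.character(fac$facility_id)
  fac$unit_id <- as.character(fac$unit_id)
  g <- igraph::graph_from_data_frame(adj[c("unit_a", "unit_b")],
                                     directed = FALSE,
                                     vertices = geo$unit_id)
  asg <- stats::setNames(zones$zone_id, zones$unit_id)
  anchors <- zone_anchors(zones)

  adj_a <- adj$unit_a; adj_b <- adj$unit_b; adj_len <- adj$shared_length
  max_pass <- 10L * nrow(geo)
  for (pass in seq_len(max_pass)) {
    fragments <- list()
    for (z in sort(unique(asg), method = "radix")) {
      members <- names(asg)[asg == z]
      sub <- igraph::induced_subgraph(g, members)
      comp <- igraph::components(sub)
      if (comp$no <= 1) next
      groups <- split(names(comp$membership), comp$membership)
      anchor_units <- fac$unit_id[fac$facility_id %in%
                                    anchors$facility_id[anchors$zone_id == z]]
      holds <- vapply(groups, function(u) any(anchor_units %in% u), logical(1))
      keep_idx <- if (sum(holds) == 1) {
        which(holds)
      } else {
        sizes <- lengths(groups)
        firsts <- vapply(groups, function(u) min(u), character(1))
        order(-sizes, firsts, method = "radix")[1]
      }
      fragments <- c(fragments, unname(groups[-keep_idx]))
    }
    if (!length(fragments)) break
    # reassign the first fragment (deterministic order), then re-derive
    frag <- fragments[[order(vapply(fragments, min, character(1)), method = "radix")[1]]]
    zfrag <- asg[frag[1]]
    cross <- adj_a %in% frag & !(adj_b %in% frag)
    nb_zone <- asg[adj_b[cross]]
    ok <- nb_zone != zfrag
    if (!any(ok)) stop("fragment ", paste(frag, collapse = "+"),
                       " has no adjacent zone to join")
    lens <- tapply(adj_len[cross][ok], nb_zone[ok], sum)
    # queen corner-only contacts all have zero length; fall back to contact counts
    if (max(lens) == 0) lens <- tapply(rep(1, sum(ok)), nb_zone[ok], sum)
    targets <- names(lens)
    best <- targets[order(-as.numeric(lens), targets, method = "radix")[1]]
    asg[frag] <- best
    if (pass == max_pass) stop("contiguity repair failed to converge")
  }

  new_asg <- tibble::tibble(unit_id = names(asg), zone_id = unname(asg))
  new_anchors <- fac |>
    dplyr::mutate(zone_id = unname(asg[.data$unit_id])) |>
    dplyr::select("zone_id", "facility_id")
  if (anyNA(new_anchors$zone_id)) {
    stop("facilities located in units outside the zone system")
  }
  zone_system(new_asg, dplyr::filter(new_anchors, !is.na(.data$zone_id)))
}
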
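#' Scale-matched comparable zones (baseline delineation)
#'
#' A simpler control delineation used to judge the scale effect on
#' self-containment: starting from the same plurality-assigned
#' hospital-anchored seed zones, the zone with the smallest supply-side
#' self-containment is repeatedly merged into its contiguous (rook
#' adjacent) neighbour with the smallest supply-side self-containment,
#' until a target number of zones remains. Comparing the main delineation
#' against this baseline at equal zone counts isolates what the
#' connectance-guided merging adds beyond mere aggregation.
#'
#' @param flows Unit-level flow table.
#' @param geo A [unit_geography()] object.
#' @param facilities Data frame with columns `facility_id`, `unit_id`.
#' @param target_count Number of zones to stop at (>= 1); typically the
#'   zone count produced by [delineate()] on the same inputs.
#' @param contiguity Adjacency rule for what counts as a contiguous
#'   neighbour.
#' @param seed_zones Optional starting [zone_system()].
#' @return An object of class `nchd_delineation` with `baseline = TRUE`;
#'   no contiguity repair is applied (merging follows adjacency).
#' @export
comparable_zones <- function(flows, geo, facilities, target_count,
                             contiguity = c("rook", "queen"),
                             seed_zones = NULL) {
  contiguity <- match.arg(contiguity)
  if (!(is.numeric(target_count) && target_count >= 1 &&
        target_count == round(target_count))) {
    stop("target_count must be a positive integer")
  }
  fl <- as_flow_table(flows)
  zones <- if (is.null(seed_zones)) initial_zones(fl, geo, facilities) else seed_zones
  adj <- unit_adjacency(geo, rule = contiguity)
  T_ <- zone_flow_matrix(fl, zones, facilities)
  B <- zone_boundary_matrix(zones, adj)
  if (target_count > nrow(T_)) {
    stop("target_count (", target_count, ") exceeds the initial zone count (",
         nrow(T_), ")")
  }

  trace <- list()
  it <- 0L
  while (nrow(T_) > target_count) {
    supply <- supply_self_containment(T_)
    ids <- rownames(T_)
    cand <- ids[order(supply, ids, method = "radix")[1]]
    nb <- ids[B[cand, ] > 0 & ids != cand]
    if (!length(nb)) {
      # spatially isolated candidate (possible with fragmented seed zones):
      # take the contiguous pick among all other zones by smallest supply SC
      nb <- setdiff(ids, cand)
    }
    partner <- nb[order(supply[nb], nb, method = "radix")[1]]
    zones <- merge_zones(zones, cand, partner)
    T_ <- merge_matrix(T_, cand, partner)
    B <- merge_matrix(B, cand, partner)
    diag(B) <- 0
    it <- it + 1L
    trace[[it]] <- tibble::tibble(
      iteration = it,
      candidate_zone = cand,
      candidate_sc = unname(supply[cand]),
      partner_zone = partner,
      connectance = NA_real_,
      n_zones = nrow(T_),
      internal_share = internal_flow_share(T_)
    )
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble(
    iteration = integer(), candidate_zone = character(), candidate_sc = numeric(),
    partner_zone = character(), connectance = numeric(), n_zones = integer(),
    internal_share = numeric()
  )
  sc <- self_containment(T_)
  structure(list(
    zones = zones,
    zones_before_repair = zones,
    trace = trace,
    threshold = NA_real_,
    contiguity = contiguity,
    sc_before = sc,
    sc_after = sc,
    flow_matrix = T_,
    flow_matrix_before_repair = T_,
    flows = fl,
    geo = geo,
    facilities = tibble::as_tibble(facilities),
    baseline = TRUE
  ), class = "nchd_delineation")
}
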
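#' Create a zone system
#'
#' A zone system is a total partition of sub-district units into zones,
#' each zone anchored by the hospitals located inside it. It is stored as
#' an assignment tibble (`unit_id`, `zone_id`) carrying the anchor table
#' (`zone_id`, `facility_id`) as an attribute.
#'
#' @param assignment Data frame with columns `unit_id`, `zone_id`; every
#'   unit exactly once.
#' @param anchors Data frame with columns `zone_id`, `facility_id`.
#' @return A tibble of class `nchd_zones`.
#' @export
zone_system <- function(assignment, anchors) {
  asg <- tibble::as_tibble(as.data.frame(assignment)[c("unit_id", "zone_id")])
  asg$unit_id <- as.character(asg$unit_id)
  asg$zone_id <- as.character(asg$zone_id)
  if (anyDuplicated(asg$unit_id)) {
    stop("assignment is not a partition: duplicated unit_id")
  }
  anc <- tibble::as_tibble(as.data.frame(anchors)[c("zone_id", "facility_id")])
  anc$zone_id <- as.character(anc$zone_id)
  anc$facility_id <- as.character(anc$facility_id)
  if (!all(anc$zone_id %in% asg$zone_id)) {
    stop("anchor table references zones with no member units")
  }
  asg <- dplyr::arrange(asg, .data$unit_id)
  attr(asg, "anchors") <- dplyr::arrange(anc, .data$zone_id, .data$facility_id)
  class(asg) <- c("nchd_zones", class(tibble::tibble()))
  asg
}

#' Anchor hospitals of a zone system
#' @param zones A [zone_system()] object.
#' @return Tibble `zone_id`, `facility_id`.
#' @export
zone_anchors <- function(zones) attr(zones, "anchors")

#' @keywords internal
zone_ids <- function(zones) sort(unique(zones$zone_id), method = "radix")

#' Build the first hospital-anchored zone system
#'
#' Every hospital seeds one candidate zone, and each sub-district unit is
#' assigned to the zone of the hospital receiving the plurality of its
#' outgoing flows (ties broken by smallest facility identifier). Membership
#' assignment never rewrites the underlying flow records, so cross-zone
#' flows remain visible to the merge loop. A hospital whose own unit
#' plurality-chose another hospital does not seed a zone of its own; it
#' co-anchors the zone its unit was assigned to.
#'
#' @param flows Unit-level flow table; every unit of `geo` must have at
#'   least one outgoing flow (run [merge_birthless_units()] first).
#' @param geo A [unit_geography()] object.
#' @param facilities Data frame with columns `facility_id`, `unit_id`.
#' @return A [zone_system()]; zone ids are the seed hospitals' facility
#'   ids.
#' @export
initial_zones <- function(flows, geo, facilities) {
  fl <- as_flow_table(flows)
  fac <- tibble::as_tibble(facilities)
  fac$facility_id <- as.character(fac$facility_id)
  fac$unit_id <- as.character(fac$unit_id)
  unknown <- setdiff(fl$dest_facility_id, fac$facility_id)
  if (length(unknown)) {
    stop("flows reference unknown facilities: ", paste(sort(unknown), collapse = ", "))
  }
  missing_units <- setdiff(geo$unit_id, fl$origin_id)
  if (length(missing_units)) {
    stop("units without outgoing flows (merge birthless units first): ",
         paste(missing_units, collapse = ", "))
  }
  stray <- setdiff(fl$origin_id, geo$unit_id)
  if (length(stray)) {
    stop("flows originate from units absent from the geography: ",
         paste(stray, collapse = ", "))
  }
  choice <- fl |>
    dplyr::group_by(.data$origin_id) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$dest_facility_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(unit_id = .data$origin_id, zone_id = .data$dest_facility_id)
  # a seed hospital's zone exists iff some unit plurality-chose it;
  # the remaining hospitals co-anchor the zone of the unit they sit in
  anchors <- fac |>
    dplyr::left_join(choice, by = "unit_id") |>
    dplyr::mutate(zone_id = dplyr::if_else(.data$facility_id %in% choice$zone_id,
                                           .data$facility_id, .data$zone_id)) |>
    dplyr::select("zone_id", "facility_id")
  if (anyNA(anchors$zone_id)) {
    bad <- anchors$facility_id[is.na(anchors$zone_id)]
    stop("facilities located outside every assigned unit: ",
         paste(bad, collapse = ", "))
  }
  zone_system(choice, anchors)
}

#' Zone-by-zone flow matrix
#'
#' Tabulates the square matrix T whose entry T\[i, j\] counts women
#' resident in zone i who gave birth at a facility located in zone j. The
#' grand total equals the total of the underlying flow table exactly.
#'
#' @param flows Unit-level flow table.
#' @param zones A [zone_system()] covering every origin unit.
#' @param facilities Data frame with columns `facility_id`, `unit_id`
#'   locating every destination facility.
#' @return Integer matrix with zone ids (sorted) as dimnames.
#' @export
zone_flow_matrix <- function(flows, zones, facilities) {
  fl <- as_flow_table(flows)
  fac <- tibble::as_tibble(facilities)
  unit_zone <- stats::setNames(zones$zone_id, zones$unit_id)
  fac_zone <- stats::setNames(unname(unit_zone[as.character(fac$unit_id)]),
                              as.character(fac$facility_id))
  if (anyNA(fac_zone)) {
    stop("facilities located in units not covered by the zone system: ",
         paste(names(fac_zone)[is.na(fac_zone)], collapse = ", "))
  }
  oz <- unit_zone[fl$origin_id]
  dz <- fac_zone[fl$dest_facility_id]
  if (anyNA(oz)) {
    stop("flows originate from units not covered by the zone system: ",
         paste(sort(unique(fl$origin_id[is.na(oz)])), collapse = ", "))
  }
  if (anyNA(dz)) {
    stop("flows reference facilities with no location: ",
         paste(sort(unique(fl$dest_facility_id[is.na(dz)])), collapse = ", "))
  }
  ids <- zone_ids(zones)
  T_ <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  tab <- tapply(fl$count, list(factor(oz, ids), factor(dz, ids)), sum)
  tab[is.na(tab)] <- 0
  T_[] <- as.integer(tab)
  T_
}

# Zone-by-zone shared boundary length matrix, from unit adjacency.
#' @keywords internal
zone_boundary_matrix <- function(zones, adjacency) {
  ids <- zone_ids(zones)
  unit_zone <- stats::setNames(zones$zone_id, zones$unit_id)
  B <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  za <- unit_zone[adjacency$unit_a]
  zb <- unit_zone[adjacency$unit_b]
  keep <- !is.na(za) & !is.na(zb) & za != zb
  if (any(keep)) {
    agg <- stats::aggregate(adjacency$shared_length[keep],
                            list(a = za[keep], b = zb[keep]), sum)
    B[cbind(agg$a, agg$b)] <- agg$x
  }
  B
}

#' @export
print.nchd_zones <- function(x, ...) {
  ids <- zone_ids(x)
  cat("<zone system> ", length(ids), " zones over ", nrow(x), " units\n", sep = "")
  NextMethod()
}
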
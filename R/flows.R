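#' Normalise an origin-destination flow table
#'
#' Canonicalises a table of birth-admission flows: drops zero-count records,
#' sums duplicated (origin, destination) pairs, and checks counts are
#' non-negative whole numbers. Works at either community or sub-district
#' origin resolution.
#'
#' @param flows Data frame with columns `origin_id`, `dest_facility_id`,
#'   `count`.
#' @return A tibble with one row per (origin, destination) pair,
#'   `count` > 0, sorted by origin then destination.
#' @export
as_flow_table <- function(flows) {
  need <- c("origin_id", "dest_facility_id", "count")
  miss <- setdiff(need, names(flows))
  if (length(miss)) {
    stop("flow table is missing column(s): ", paste(miss, collapse = ", "))
  }
  fl <- tibble::as_tibble(as.data.frame(flows)[need])
  fl$origin_id <- as.character(fl$origin_id)
  fl$dest_facility_id <- as.character(fl$dest_facility_id)
  if (!is.numeric(fl$count) || any(!is.finite(fl$count)) ||
      any(fl$count < 0) || any(fl$count != round(fl$count))) {
    stop("flow counts must be non-negative integers")
  }
  fl$count <- as.integer(round(fl$count))
  fl |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$origin_id, .data$dest_facility_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$origin_id, .data$dest_facility_id)
}

#' Aggregate community-level flows to sub-district units
#'
#' Flows recorded between residential communities and hospitals are summed
#' to the sub-district units containing the communities, conserving the
#' total count exactly. Communities absent from the lookup are an error
#' (manual gazetteer matching is outside this package).
#'
#' @param community_flows Flow table with `origin_id` at community
#'   resolution.
#' @param community_lookup Data frame with columns `community_id`,
#'   `unit_id`.
#' @return A flow tibble with `origin_id` at unit resolution.
#' @export
aggregate_to_units <- function(community_flows, community_lookup) {
  fl <- as_flow_table(community_flows)
  lk <- tibble::as_tibble(community_lookup)
  stopifnot(all(c("community_id", "unit_id") %in% names(lk)))
  lk <- dplyr::distinct(lk, community_id = as.character(.data$community_id),
                        unit_id = as.character(.data$unit_id))
  if (anyDuplicated(lk$community_id)) {
    stop("community lookup maps some communities to several units")
  }
  unmapped <- setdiff(fl$origin_id, lk$community_id)
  if (length(unmapped)) {
    stop("communities missing from the unit lookup: ",
         paste(sort(unmapped), collapse = ", "))
  }
  fl |>
    dplyr::inner_join(lk, by = c(origin_id = "community_id")) |>
    dplyr::group_by(origin_id = .data$unit_id, .data$dest_facility_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$origin_id, .data$dest_facility_id)
}

#' Merge birthless sub-districts into same-district neighbours
#'
#' Units with no located facility and no recorded outgoing flow cannot seed
#' or join a catchment on their own evidence, so each is unioned into a
#' nearby unit of the same administrative district before delineation: the
#' same-district rook neighbour with the longest shared boundary, or, if no
#' same-district neighbour exists, the nearest same-district unit by
#' centroid distance. Chains (a birthless unit whose chosen neighbour is
#' itself birthless) resolve to the final receiving unit. The receiving
#' unit absorbs the merged polygons (its geometry becomes multi-ring) so
#' areas, adjacency and zonal statistics stay complete.
#'
#' @param geo A [unit_geography()] object.
#' @param flows Unit-level flow table.
#' @param facilities Data frame with columns `facility_id`, `unit_id`
#'   giving hospital locations.
#' @return A list with `geo` (the reduced geography) and `merge_map`, a
#'   tibble `old_unit`, `new_unit` covering every input unit (identity rows
#'   for unchanged units).
#' @export
merge_birthless_units <- function(geo, flows, facilities) {
  fl <- as_flow_table(flows)
  fac_units <- as.character(facilities$unit_id)
  has_flow <- geo$unit_id %in% fl$origin_id
  has_fac <- geo$unit_id %in% fac_units
  birthless <- geo$unit_id[!has_flow & !has_fac]

  target <- stats::setNames(geo$unit_id, geo$unit_id)
  if (length(birthless)) {
    adj <- unit_adjacency(geo, rule = "rook")
    cen <- unit_centroids(geo)
    district <- stats::setNames(geo$district_id, geo$unit_id)
    for (u in sort(birthless, method = "radix")) {
      same <- geo$unit_id[district == district[u] & geo$unit_id != u]
      if (!length(same)) {
        stop("district ", district[u], " has no partner unit for birthless unit ", u)
      }
      nb <- adj |>
        dplyr::filter(.data$unit_a == u, .data$unit_b %in% same) |>
        dplyr::arrange(dplyr::desc(.data$shared_length), .data$unit_b)
      if (nrow(nb)) {
        target[u] <- nb$unit_b[1]
      } else {
        cu <- cen[cen$unit_id == u, ]
        cs <- cen[cen$unit_id %in% same, ]
        d <- sqrt((cs$x - cu$x)^2 + (cs$y - cu$y)^2)
        target[u] <- cs$unit_id[order(d, cs$unit_id)[1]]
      }
    }
    # resolve chains of birthless units; a cycle (mutual best neighbours,
    # all birthless) falls back to the nearest live same-district unit
    for (u in birthless) {
      seen <- u
      while (target[u] %in% birthless) {
        nxt <- target[target[u]]
        if (nxt %in% seen) {
          live <- geo$unit_id[(has_flow | has_fac) & district == district[u]]
          if (!length(live)) {
            stop("district ", district[u], " consists only of birthless units")
          }
          cu <- cen[cen$unit_id == u, ]
          cs <- cen[cen$unit_id %in% live, ]
          d <- sqrt((cs$x - cu$x)^2 + (cs$y - cu$y)^2)
          target[u] <- cs$unit_id[order(d, cs$unit_id)[1]]
          break
        }
        seen <- c(seen, target[u])
        target[u] <- nxt
      }
    }
  }
  merge_map <- tibble::tibble(old_unit = geo$unit_id,
                              new_unit = unname(target[geo$unit_id])) |>
    dplyr::arrange(.data$old_unit)

  keep <- geo[!(geo$unit_id %in% birthless), ]
  absorbed <- merge_map[merge_map$old_unit != merge_map$new_unit, ]
  if (nrow(absorbed)) {
    rings <- stats::setNames(geo$geometry, geo$unit_id)
    extra <- split(absorbed$old_unit, absorbed$new_unit)
    keep$geometry <- purrr::map2(keep$geometry, keep$unit_id, function(g, id) {
      if (is.null(extra[[id]])) g else c(geom_rings(g), unlist(lapply(rings[extra[[id]]], geom_rings), recursive = FALSE))
    })
    keep$area_km2 <- vapply(keep$geometry, geom_area, numeric(1))
  }
  attr(keep, "crs") <- attr(geo, "crs")
  class(keep) <- class(geo)
  list(geo = keep, merge_map = merge_map)
}
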
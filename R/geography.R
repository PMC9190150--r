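#' Construct a validated unit geography
#'
#' A unit geography is the spatial building-block layer of a delineation:
#' one row per sub-district unit with its district membership and polygon
#' geometry in a planar projected coordinate system (km). A unit's geometry
#' is one polygon ring, or several after birthless units have been unioned
#' into it. Areas are computed from the geometry; validation rejects
#' degenerate or overlapping polygons.
#'
#' @param units A data frame with columns `unit_id`, `district_id` and a
#'   `geometry` list-column whose entries are n x 2 vertex matrices (planar
#'   km) or lists of such matrices.
#' @param crs Character label describing the planar coordinate system; kept
#'   as an attribute and written to GeoJSON output.
#' @return A tibble of class `nchd_geography` with columns `unit_id`,
#'   `district_id`, `geometry` and `area_km2`, sorted by `unit_id`.
#' @export
unit_geography <- function(units, crs = "urn:nchdzone:planar-km") {
  stopifnot(is.data.frame(units))
  need <- c("unit_id", "district_id", "geometry")
  miss <- setdiff(need, names(units))
  if (length(miss)) {
    stop("unit geography is missing column(s): ", paste(miss, collapse = ", "))
  }
  geo <- tibble::as_tibble(as.data.frame(units)[need])
  geo$unit_id <- as.character(geo$unit_id)
  geo$district_id <- as.character(geo$district_id)
  if (anyDuplicated(geo$unit_id)) {
    stop("duplicate unit_id values: ",
         paste(unique(geo$unit_id[duplicated(geo$unit_id)]), collapse = ", "))
  }
  geo$geometry <- lapply(geo$geometry, geom_rings)
  bad <- vapply(geo$geometry, function(g) {
    any(vapply(g, function(r) nrow(r) < 3 || any(!is.finite(r)) || ring_area(r) <= 0,
               logical(1)))
  }, logical(1))
  if (any(bad)) {
    stop("invalid polygon geometry for unit(s): ",
         paste(geo$unit_id[bad], collapse = ", "))
  }
  geo$area_km2 <- vapply(geo$geometry, geom_area, numeric(1))
  overlaps <- find_overlapping_units(geo)
  if (nrow(overlaps)) {
    stop("overlapping unit polygons: ",
         paste(paste0(overlaps$unit_a, "/", overlaps$unit_b), collapse = ", "))
  }
  geo <- geo[order(geo$unit_id, method = "radix"), ]
  attr(geo, "crs") <- crs
  class(geo) <- c("nchd_geography", class(tibble::tibble()))
  geo
}

# Interior-overlap screen for tessellations: two units overlap if a probe
# point from the interior of one (ring centroid, or edge midpoints inset
# slightly towards it so that legitimately shared boundaries never fire)
# lies inside the other. Exact for convex tiles; a pragmatic screen for
# general tessellated input.
#' @keywords internal
find_overlapping_units <- function(geo) {
  n <- nrow(geo)
  bb <- t(vapply(geo$geometry, geom_bbox, numeric(4)))
  probes <- lapply(geo$geometry, function(g) {
    do.call(rbind, lapply(geom_rings(g), function(ring) {
      r <- ring_close(ring)
      cen <- ring_centroid(ring)
      mids <- (r[-1, , drop = FALSE] + r[-nrow(r), , drop = FALSE]) / 2
      inset <- mids + 1e-6 * sweep(-mids, 2, cen, "+")
      rbind(matrix(cen, ncol = 2), inset)
    }))
  })
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (bb[i, "xmin"] >= bb[j, "xmax"] || bb[j, "xmin"] >= bb[i, "xmax"] ||
            bb[i, "ymin"] >= bb[j, "ymax"] || bb[j, "ymin"] >= bb[i, "ymax"]) next
        hit <- any(points_in_geom(probes[[i]], geo$geometry[[j]])) ||
          any(points_in_geom(probes[[j]], geo$geometry[[i]]))
        if (hit) out[[length(out) + 1L]] <- c(geo$unit_id[i], geo$unit_id[j])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(unit_a = character(), unit_b = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(unit_a = m[, 1], unit_b = m[, 2])
}

#' Unit-level spatial adjacency
#'
#' Derives the neighbour relation between units of a tessellation. Rook
#' contiguity requires a shared boundary of positive length; queen also
#' accepts a shared corner vertex. The relation is returned in symmetric
#' long form (each neighbouring pair appears in both directions) together
#' with the total shared boundary length.
#'
#' @param geo A [unit_geography()] object.
#' @param rule `"rook"` (shared edges, the default) or `"queen"` (shared
#'   edges or corners).
#' @return A tibble with columns `unit_a`, `unit_b`, `shared_length` (km;
#'   0 for corner-only queen contacts).
#' @export
unit_adjacency <- function(geo, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  segs <- purrr::map2_dfr(geo$geometry, geo$unit_id, function(g, id) {
    s <- geom_segments(g)
    s$unit_id <- id
    s
  })
  shared <- segs |>
    dplyr::inner_join(segs, by = "key", suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$unit_id_a != .data$unit_id_b) |>
    dplyr::group_by(unit_a = .data$unit_id_a, unit_b = .data$unit_id_b) |>
    dplyr::summarise(shared_length = sum(.data$length_a), .groups = "drop")
  if (rule == "queen") {
    verts <- purrr::map2_dfr(geo$geometry, geo$unit_id, function(g, id) {
      tibble::tibble(key = geom_vertex_keys(g), unit_id = id)
    })
    corner <- verts |>
      dplyr::inner_join(verts, by = "key", suffix = c("_a", "_b"),
                        relationship = "many-to-many") |>
      dplyr::filter(.data$unit_id_a != .data$unit_id_b) |>
      dplyr::distinct(unit_a = .data$unit_id_a, unit_b = .data$unit_id_b) |>
      dplyr::anti_join(shared, by = c("unit_a", "unit_b")) |>
      dplyr::mutate(shared_length = 0)
    shared <- dplyr::bind_rows(shared, corner)
  }
  dplyr::arrange(shared, .data$unit_a, .data$unit_b)
}

#' Assign planar points to the units containing them
#'
#' Each point is assigned to the unit polygon containing it; points falling
#' on shared boundaries go to the first containing unit in identifier order,
#' and points outside every unit get `NA`.
#'
#' @param pts A data frame with columns `x` and `y` (planar km).
#' @param geo A [unit_geography()] object.
#' @return Character vector of unit ids, one per point (`NA` = outside).
#' @export
locate_units <- function(pts, geo) {
  pts <- as.data.frame(pts)[, c("x", "y")]
  m <- as.matrix(pts)
  out <- rep(NA_character_, nrow(m))
  bb <- t(vapply(geo$geometry, geom_bbox, numeric(4)))
  for (i in seq_len(nrow(geo))) {
    open <- which(is.na(out))
    if (!length(open)) break
    cand <- open[m[open, 1] >= bb[i, "xmin"] & m[open, 1] <= bb[i, "xmax"] &
                   m[open, 2] >= bb[i, "ymin"] & m[open, 2] <= bb[i, "ymax"]]
    if (!length(cand)) next
    hit <- points_in_geom(m[cand, , drop = FALSE], geo$geometry[[i]])
    out[cand[hit]] <- geo$unit_id[i]
  }
  out
}

#' @keywords internal
unit_centroids <- function(geo) {
  cen <- t(vapply(geo$geometry, geom_centroid, numeric(2)))
  tibble::tibble(unit_id = geo$unit_id, x = cen[, 1], y = cen[, 2])
}
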
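# Readers and writers for the standard file set: flow CSV, facility CSV,
# unit geography GeoJSON, population grid CSV, zone GeoJSON, merge-trace
# CSV, indicator CSV, plus the completeness report and map filter.

#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Data-completeness report
#'
#' Summarises how much of the routine register survives each processing
#' stage: aggregate monthly counts, individual records, and records with a
#' geocoded residence. Percentages are rounded half-up to one decimal. An
#' individual count exceeding the aggregate count raises a warning
#' (possible double entry), not an error.
#'
#' @param n_aggregate,n_individual,n_geocoded Non-negative integers with
#'   `n_geocoded <= n_individual`.
#' @return One-row tibble with the three counts,
#'   `pct_individual_of_aggregate` and `pct_geocoded_of_individual`.
#' @export
completeness_report <- function(n_aggregate, n_individual, n_geocoded) {
  stopifnot(n_aggregate >= 0, n_individual >= 0, n_geocoded >= 0,
            n_geocoded <= n_individual)
  if (n_individual > n_aggregate) {
    warning("individual records exceed aggregate counts (possible double entry)")
  }
  pct <- function(num, den) if (den == 0) 0 else round_half_up(100 * num / den, 1)
  tibble::tibble(
    n_aggregate = as.integer(n_aggregate),
    n_individual = as.integer(n_individual),
    n_geocoded = as.integer(n_geocoded),
    pct_individual_of_aggregate = pct(n_individual, n_aggregate),
    pct_geocoded_of_individual = pct(n_geocoded, n_individual)
  )
}

#' Filter flows for mapping
#'
#' Retains only flows of at least `min_count` women, the conventional
#' screen against graphical clutter when drawing flow maps (default: six
#' or more).
#'
#' @param flows Flow table.
#' @param min_count Minimum count to retain (>= 0).
#' @return The filtered flow tibble; the input is not modified.
#' @export
filter_flows_for_map <- function(flows, min_count = 6) {
  stopifnot(min_count >= 0)
  dplyr::filter(as_flow_table(flows), .data$count >= min_count)
}

#' Read / write a flow CSV
#'
#' The flow CSV schema is `origin_id,dest_facility_id,count` with a header
#' row, UTF-8. Reading validates the schema and reports offending lines.
#'
#' @param path File path.
#' @return `read_flow_csv()` returns a canonical flow tibble.
#' @export
read_flow_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("origin_id", "dest_facility_id", "count"), names(df))
  if (length(miss)) {
    stop("flow CSV ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  suppressWarnings(cnt <- as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    stop("flow CSV ", path, ": non-integer or negative count on data line(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  df$count <- cnt
  as_flow_table(df)
}

#' @rdname read_flow_csv
#' @param flows Flow table to write.
#' @export
write_flow_csv <- function(flows, path) {
  readr::write_csv(as_flow_table(flows), path)
  invisible(path)
}

#' Read / write a facility CSV
#'
#' Schema: `facility_id,unit_id,sector,midwives` followed by the nine
#' 0/1 signal-function columns (see [signal_functions()]); optional
#' `x`, `y` coordinate columns are preserved.
#'
#' @param path File path.
#' @return `read_facility_csv()` returns the facility tibble with logical
#'   signal-function columns.
#' @export
read_facility_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("facility_id", "unit_id", "sector", "midwives", SIGNAL_FUNCTIONS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("facility CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (sf in SIGNAL_FUNCTIONS) {
    v <- df[[sf]]
    if (!all(v %in% c(0, 1, TRUE, FALSE))) {
      stop("facility CSV ", path, ": column ", sf, " must be 0/1")
    }
    df[[sf]] <- as.logical(as.integer(v))
  }
  if (any(df$midwives < 0 | df$midwives != round(df$midwives))) {
    stop("facility CSV ", path, ": midwives must be non-negative integers")
  }
  df$facility_id <- as.character(df$facility_id)
  df$unit_id <- as.character(df$unit_id)
  tibble::as_tibble(df)
}

#' @rdname read_facility_csv
#' @param facilities Facility table to write (signal functions written as
#'   0/1).
#' @export
write_facility_csv <- function(facilities, path) {
  df <- tibble::as_tibble(facilities)
  for (sf in intersect(SIGNAL_FUNCTIONS, names(df))) {
    df[[sf]] <- as.integer(df[[sf]])
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Read / write the unit geography as GeoJSON
#'
#' Units are written as a GeoJSON FeatureCollection of Polygon /
#' MultiPolygon features with `unit_id` and `district_id` properties and a
#' named planar CRS member. Reading validates the schema, requires a
#' planar (projected) CRS — geographic longitude/latitude input is an
#' error — and runs the tessellation validity checks of
#' [unit_geography()].
#'
#' @param path File path.
#' @return `read_unit_geojson()` returns a [unit_geography()].
#' @export
read_unit_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("GeoJSON ", path, ": expected a FeatureCollection")
  }
  crs_name <- gj$crs$properties$name
  if (is.null(crs_name)) {
    stop("GeoJSON ", path, ": no CRS member; a planar projected CRS is required ",
         "(plain RFC 7946 longitude/latitude input is not supported)")
  }
  if (grepl("CRS84|4326|WGS ?84", crs_name, ignore.case = TRUE)) {
    stop("GeoJSON ", path, ": geographic CRS '", crs_name,
         "' not supported; supply planar projected coordinates")
  }
  feats <- gj$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    p <- f$properties
    if (is.null(p$unit_id) || is.null(p$district_id)) {
      stop("GeoJSON ", path, ": feature ", i, " lacks unit_id/district_id")
    }
    gtype <- f$geometry$type
    coords <- f$geometry$coordinates
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    }
    rings <- switch(gtype,
      Polygon = list(ring_mat(coords[[1]])),
      MultiPolygon = lapply(coords, function(poly) ring_mat(poly[[1]])),
      stop("GeoJSON ", path, ": feature ", i, " has unsupported geometry type ", gtype)
    )
    tibble::tibble(unit_id = as.character(p$unit_id),
                   district_id = as.character(p$district_id),
                   geometry = list(rings))
  })
  unit_geography(dplyr::bind_rows(rows), crs = crs_name)
}

#' @rdname read_unit_geojson
#' @param geo A [unit_geography()] to write.
#' @export
write_unit_geojson <- function(geo, path) {
  feats <- lapply(seq_len(nrow(geo)), function(i) {
    rings <- geom_rings(geo$geometry[[i]])
    closed <- lapply(rings, function(r) {
      rc <- ring_close(r)
      lapply(seq_len(nrow(rc)), function(k) c(rc[k, 1], rc[k, 2]))
    })
    geom <- if (length(closed) == 1) {
      list(type = "Polygon", coordinates = list(closed[[1]]))
    } else {
      list(type = "MultiPolygon", coordinates = lapply(closed, list))
    }
    list(type = "Feature",
         properties = list(unit_id = geo$unit_id[i],
                           district_id = geo$district_id[i]),
         geometry = geom)
  })
  gj <- list(
    type = "FeatureCollection",
    crs = list(type = "name",
               properties = list(name = attr(geo, "crs") %||% "urn:nchdzone:planar-km")),
    features = feats
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write delineated zones as GeoJSON
#'
#' Each zone becomes one MultiPolygon feature holding its member-unit
#' polygons, with properties `zone_id`, the member unit list, anchor
#' facilities, demand- and supply-side self-containment, and a `baseline`
#' flag.
#'
#' @param delin An `nchd_delineation` object (from [delineate()] or
#'   [comparable_zones()]).
#' @param path File path.
#' @export
write_zone_geojson <- function(delin, path) {
  stopifnot(inherits(delin, "nchd_delineation"))
  zones <- delin$zones
  geo <- delin$geo
  anchors <- zone_anchors(zones)
  sc <- delin$sc_after
  feats <- lapply(zone_ids(zones), function(z) {
    members <- zones$unit_id[zones$zone_id == z]
    rings <- unlist(lapply(geo$geometry[match(members, geo$unit_id)], geom_rings),
                    recursive = FALSE)
    closed <- lapply(rings, function(r) {
      rc <- ring_close(r)
      list(lapply(seq_len(nrow(rc)), function(k) c(rc[k, 1], rc[k, 2])))
    })
    scz <- sc[sc$zone_id == z, ]
    list(type = "Feature",
         properties = list(
           zone_id = z,
           units = as.list(members),
           anchor_facilities = as.list(anchors$facility_id[anchors$zone_id == z]),
           demand_self_containment = scz$demand,
           supply_self_containment = scz$supply,
           baseline = isTRUE(delin$baseline)
         ),
         geometry = list(type = "MultiPolygon", coordinates = closed))
  })
  gj <- list(
    type = "FeatureCollection",
    crs = list(type = "name",
               properties = list(name = attr(geo, "crs") %||% "urn:nchdzone:planar-km")),
    features = feats
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a gridded population CSV
#'
#' Schema: `x,y,pop` — planar cell-centre coordinates and persons per
#' cell.
#'
#' @param path File path.
#' @return `read_population_grid()` returns a tibble `x`, `y`, `pop`.
#' @export
read_population_grid <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("x", "y", "pop"), names(df))
  if (length(miss)) {
    stop("population grid ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(!is.finite(df$pop)) || any(df$pop < 0)) {
    stop("population grid ", path, ": pop must be finite and non-negative")
  }
  tibble::as_tibble(df[c("x", "y", "pop")])
}

#' @rdname read_population_grid
#' @param surface Grid tibble to write.
#' @export
write_population_grid <- function(surface, path) {
  readr::write_csv(tibble::as_tibble(surface)[c("x", "y", "pop")], path)
  invisible(path)
}

#' Write a merge trace CSV
#'
#' One row per merge iteration of a delineation, in order.
#'
#' @param delin An `nchd_delineation` object.
#' @param path File path.
#' @export
write_trace_csv <- function(delin, path) {
  stopifnot(inherits(delin, "nchd_delineation"))
  readr::write_csv(delin$trace, path)
  invisible(path)
}

#' Write a zone indicator CSV
#'
#' @param indicators Tibble from [compute_indicators()].
#' @param path File path.
#' @export
write_indicator_csv <- function(indicators, path) {
  readr::write_csv(tibble::as_tibble(indicators), path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records what produced a set of outputs: input files, configuration,
#' seed, package and R versions, and a timestamp.
#'
#' @param path JSON file path.
#' @param inputs Named list or character vector of input descriptions.
#' @param config Configuration object or list (stored as-is, minus
#'   functions).
#' @param seed Integer seed used for the run (or `NULL`).
#' @export
write_run_manifest <- function(path, inputs = list(), config = list(), seed = NULL) {
  cfg <- config
  if (inherits(cfg, "nchd_config")) cfg <- unclass(cfg)
  manifest <- list(
    package = "nchdzone",
    package_version = as.character(utils::packageVersion("nchdzone")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    config = cfg
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA, force = TRUE)
  invisible(path)
}
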
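# Access-to-birthing-services indicators per zone or district.

# The nine EmONC signal functions that define CEmONC readiness.
#' @keywords internal
SIGNAL_FUNCTIONS <- c(
  "parenteral_antibiotics", "uterotonics", "parenteral_anticonvulsants",
  "manual_placenta_removal", "removal_retained_products",
  "assisted_vaginal_delivery", "neonatal_resuscitation",
  "caesarean_section", "blood_transfusion"
)

#' Names of the nine EmONC signal functions
#'
#' Column names expected in a facility assessment table, each a logical
#' (or 0/1) flag recording whether the facility performed that signal
#' function in the last 3 months.
#'
#' @return Character vector of length nine.
#' @export
signal_functions <- function() SIGNAL_FUNCTIONS

#' CEmONC readiness classification
#'
#' A hospital is ready to provide Comprehensive Emergency Obstetric and
#' Newborn Care if it performed all nine signal functions (parenteral
#' antibiotics, uterotonics, parenteral anticonvulsants, manual removal of
#' the placenta, removal of retained products, assisted vaginal delivery,
#' neonatal resuscitation, caesarean section and blood transfusion) in the
#' last 3 months.
#'
#' @param assessment Data frame with the nine signal-function columns (see
#'   [signal_functions()]), logical or 0/1.
#' @return Logical vector, one element per facility row.
#' @export
is_cemonc_ready <- function(assessment) {
  miss <- setdiff(SIGNAL_FUNCTIONS, names(assessment))
  if (length(miss)) {
    stop("facility assessment is missing signal-function column(s): ",
         paste(miss, collapse = ", "))
  }
  m <- sapply(as.data.frame(assessment)[SIGNAL_FUNCTIONS], function(x) {
    if (is.logical(x)) x else as.integer(x) == 1L
  })
  m <- matrix(m, ncol = length(SIGNAL_FUNCTIONS))
  if (anyNA(m)) stop("signal-function columns contain missing values")
  rowSums(m) == length(SIGNAL_FUNCTIONS)
}

#' Zonal population from a gridded surface
#'
#' Sums a gridded population surface within each zone by the cell-centre
#' rule: each cell's population is credited to the zone containing its
#' centre point; cells outside every zone are ignored. When the zones tile
#' the surface extent the zonal sums partition the grand total.
#'
#' @param surface Data frame with columns `x`, `y` (cell centres, planar
#'   km, matching the geography's coordinate system) and `pop` (persons
#'   per cell, >= 0).
#' @param zones A [zone_system()].
#' @param geo A [unit_geography()] object.
#' @return Tibble `zone_id`, `population`, one row per zone (zones with no
#'   cells get 0).
#' @export
zonal_population <- function(surface, zones, geo) {
  surface <- tibble::as_tibble(surface)
  stopifnot(all(c("x", "y", "pop") %in% names(surface)))
  if (any(surface$pop < 0)) stop("population cells must be non-negative")
  unit <- locate_units(surface[c("x", "y")], geo)
  unit_zone <- stats::setNames(zones$zone_id, zones$unit_id)
  zone <- unit_zone[unit]
  ids <- zone_ids(zones)
  kept <- !is.na(zone)
  pops <- tapply(surface$pop[kept], factor(zone[kept], ids), sum)
  pops[is.na(pops)] <- 0
  tibble::tibble(zone_id = ids, population = as.numeric(pops))
}

#' Access-to-care indicators per zone
#'
#' Computes, for each zone of a partition (administrative districts or
#' delineated catchment districts alike): hospital and CEmONC counts,
#' CEmONC hospitals per 100,000, midwives per 10,000, EmOC facilities per
#' 500,000, and flags against the WHO benchmarks of 22.8 and 33.45 skilled
#' health workers per 10,000 population and five EmOC facilities per
#' 500,000 population (all thresholds inclusive).
#'
#' @param zones A [zone_system()].
#' @param facilities Facility table with columns `facility_id`, `unit_id`,
#'   `midwives` and the nine signal-function columns.
#' @param population Data frame `zone_id`, `population` (e.g. from
#'   [zonal_population()]); every zone needs population > 0.
#' @param denominator `"population"` (default) or `"pregnancies"`; the
#'   latter scales the denominator by `pregnancy_rate` for rates meant per
#'   expected pregnancy rather than per resident.
#' @param pregnancy_rate Expected pregnancies per resident per year, used
#'   only with `denominator = "pregnancies"`.
#' @return Tibble, one row per zone: `zone_id`, `population`,
#'   `n_hospitals`, `n_cemonc`, `midwives`, `cemonc_per_100k`,
#'   `midwives_per_10k`, `emoc_per_500k`, `meets_who_22_8`,
#'   `meets_who_33_45`, `meets_emoc_5_per_500k`.
#' @export
compute_indicators <- function(zones, facilities, population,
                               denominator = c("population", "pregnancies"),
                               pregnancy_rate = 0.04) {
  denominator <- match.arg(denominator)
  fac <- tibble::as_tibble(facilities)
  fac$facility_id <- as.character(fac$facility_id)
  fac$unit_id <- as.character(fac$unit_id)
  if (!("midwives" %in% names(fac))) stop("facility table lacks a 'midwives' column")
  if (any(fac$midwives < 0)) stop("midwife counts must be non-negative")
  pop <- tibble::as_tibble(population)
  stopifnot(all(c("zone_id", "population") %in% names(pop)))
  pop$zone_id <- as.character(pop$zone_id)

  ids <- zone_ids(zones)
  missing_pop <- setdiff(ids, pop$zone_id)
  if (length(missing_pop)) {
    stop("no population supplied for zone(s): ", paste(missing_pop, collapse = ", "))
  }
  if (any(pop$population[pop$zone_id %in% ids] <= 0)) {
    bad <- pop$zone_id[pop$zone_id %in% ids & pop$population <= 0]
    stop("zero or negative population for zone(s): ", paste(bad, collapse = ", "))
  }

  unit_zone <- stats::setNames(zones$zone_id, zones$unit_id)
  fac$zone_id <- unname(unit_zone[fac$unit_id])
  if (anyNA(fac$zone_id)) {
    stop("facilities located in units outside the zone system: ",
         paste(fac$facility_id[is.na(fac$zone_id)], collapse = ", "))
  }
  fac$cemonc <- is_cemonc_ready(fac)

  per_zone <- fac |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(n_hospitals = dplyr::n(),
                     n_cemonc = sum(.data$cemonc),
                     midwives = sum(.data$midwives), .groups = "drop")

  tibble::tibble(zone_id = ids) |>
    dplyr::left_join(per_zone, by = "zone_id") |>
    dplyr::mutate(dplyr::across(c("n_hospitals", "n_cemonc", "midwives"),
                                \(x) dplyr::coalesce(x, 0L))) |>
    dplyr::left_join(pop[c("zone_id", "population")], by = "zone_id") |>
    dplyr::mutate(
      denom = if (denominator == "pregnancies") .data$population * pregnancy_rate
              else .data$population,
      cemonc_per_100k = 1e5 * .data$n_cemonc / .data$denom,
      midwives_per_10k = 1e4 * .data$midwives / .data$denom,
      emoc_per_500k = 5e5 * .data$n_hospitals / .data$denom,
      meets_who_22_8 = .data$midwives_per_10k >= 22.8,
      meets_who_33_45 = .data$midwives_per_10k >= 33.45,
      meets_emoc_5_per_500k = .data$emoc_per_500k >= 5
    ) |>
    dplyr::select(-"denom") |>
    dplyr::relocate("population", .after = "zone_id")
}
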
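# Synthetic scenario generator: tessellated sub-districts grouped into
# districts, hospitals, gridded population, communities with right-skewed
# birth counts, and gravity-model (Huff) destination choice with a
# long-range bypass stream. A planted-partition mode provides ground-truth
# zones for recovery experiments.

#' Scenario configuration
#'
#' Collects every tunable of the synthetic world. The defaults emulate the
#' Ghana Eastern Region setting the package is designed around: ~250
#' sub-district units in 33 districts, 27 hospitals, around four
#' residential communities per unit, a right-skewed births-per-community
#' distribution (median near 7, mean under 30), distance-decaying
#' destination choice, and a strong long-range bypass stream towards one
#' high-attractiveness hospital near the region's edge.
#'
#' @param n_units Number of sub-district units (lattice cells).
#' @param n_districts Number of administrative districts.
#' @param n_hospitals Number of hospitals.
#' @param unit_km Side length of a lattice cell, km.
#' @param communities_per_unit Residential communities per unit.
#' @param births_meanlog,births_sdlog Lognormal parameters of births per
#'   community (rounded up to at least one birth).
#' @param beta Distance-decay exponent of the gravity choice rule (> 0).
#' @param hospital_layout `"clustered"` (default; hospitals gather at
#'   `n_centres` well-separated towns, emulating multi-hospital natural
#'   catchments) or `"scattered"` (one hospital per randomly chosen
#'   district).
#' @param n_centres Number of hospital towns for the clustered layout.
#' @param attract_range Range (min, max) of hospital attractiveness.
#' @param bypass_fraction Share of communities that are bypass sources:
#'   communities sending most of their births to the designated distant
#'   high-attractiveness hospital (the long-range streams observed in
#'   routine data, and the cause of enclave zones).
#' @param bypass_strength Share of a bypass community's births routed to
#'   the bypass hospital.
#' @param pop_cells_per_unit_side Population-grid resolution: cells per
#'   unit side (cell size = `unit_km / pop_cells_per_unit_side`).
#' @param pop_meanlog,pop_sdlog Lognormal parameters of persons per grid
#'   cell.
#' @param cemonc_ready_frac Probability a hospital performs all nine
#'   signal functions.
#' @param midwives_lambda Poisson mean of midwives per hospital.
#' @param planted `NULL`, or `list(k =, within_prob =)` to plant a
#'   k-block ground-truth partition instead of gravity flows.
#' @param seed Mandatory integer seed; identical config and seed give a
#'   byte-identical scenario.
#' @return A list of class `nchd_config`.
#' @export
scenario_config <- function(n_units = 250, n_districts = 33, n_hospitals = 27,
                            unit_km = 8, communities_per_unit = 4,
                            births_meanlog = log(7), births_sdlog = 1.7,
                            beta = 6, attract_range = c(1, 10),
                            hospital_layout = c("clustered", "scattered"),
                            n_centres = 11,
                            bypass_fraction = 0.03, bypass_strength = 0.8,
                            pop_cells_per_unit_side = 4,
                            pop_meanlog = log(500), pop_sdlog = 1,
                            cemonc_ready_frac = 0.6, midwives_lambda = 45,
                            planted = NULL, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_units >= 1, n_districts >= 1, n_districts <= n_units,
            n_hospitals >= 1, n_hospitals <= n_units,
            communities_per_unit >= 1, unit_km > 0,
            bypass_fraction >= 0, bypass_fraction <= 1,
            bypass_strength >= 0, bypass_strength <= 1,
            pop_cells_per_unit_side >= 1)
  hospital_layout <- match.arg(hospital_layout)
  if (beta <= 0) stop("the distance-decay exponent beta must be positive")
  stopifnot(n_centres >= 1)
  if (!is.null(planted)) {
    stopifnot(is.list(planted), !is.null(planted$k), !is.null(planted$within_prob))
    if (planted$k > n_hospitals) stop("planted k exceeds the number of hospitals")
    if (!(planted$within_prob > 0.5 && planted$within_prob <= 1)) {
      stop("planted within_prob must be in (0.5, 1]")
    }
  }
  structure(list(
    n_units = as.integer(n_units), n_districts = as.integer(n_districts),
    n_hospitals = as.integer(n_hospitals), unit_km = unit_km,
    communities_per_unit = as.integer(communities_per_unit),
    births_meanlog = births_meanlog, births_sdlog = births_sdlog,
    beta = beta, attract_range = attract_range,
    hospital_layout = hospital_layout, n_centres = as.integer(n_centres),
    bypass_fraction = bypass_fraction, bypass_strength = bypass_strength,
    pop_cells_per_unit_side = as.integer(pop_cells_per_unit_side),
    pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
    cemonc_ready_frac = cemonc_ready_frac, midwives_lambda = midwives_lambda,
    planted = planted, seed = as.integer(seed)
  ), class = "nchd_config")
}

# Run code under a fixed seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Boustrophedon (snake) ordering of lattice cells: consecutive cells are
# always rook neighbours, so consecutive runs form contiguous groups.
#' @keywords internal
snake_cells <- function(n_units) {
  ncol_ <- ceiling(sqrt(n_units))
  nrow_ <- ceiling(n_units / ncol_)
  cells <- list()
  k <- 0L
  for (r in seq_len(nrow_)) {
    cols <- if (r %% 2 == 1) seq_len(ncol_) else rev(seq_len(ncol_))
    for (cc in cols) {
      k <- k + 1L
      if (k > n_units) break
      cells[[k]] <- c(row = r, col = cc)
    }
  }
  do.call(rbind, cells)
}

# Balanced split of 1..n into k consecutive chunks.
#' @keywords internal
chunk_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}

#' Generate the synthetic unit geography
#'
#' Lays out `n_units` square cells on a lattice in boustrophedon order and
#' groups consecutive runs of cells into `n_districts` contiguous
#' districts of balanced size. Deterministic given the config (no random
#' draws are used for the tessellation itself).
#'
#' @param config A [scenario_config()].
#' @return A [unit_geography()] with an attribute `snake_order` (unit ids
#'   in lattice traversal order) used by the planted-partition mode.
#' @export
generate_geography <- function(config) {
  cells <- snake_cells(config$n_units)
  s <- config$unit_km
  ids <- sprintf("U%03d", seq_len(config$n_units))
  dist_sizes <- chunk_sizes(config$n_units, config$n_districts)
  district <- rep(sprintf("D%02d", seq_len(config$n_districts)), dist_sizes)
  geom <- lapply(seq_len(config$n_units), function(i) {
    x0 <- (cells[i, "col"] - 1) * s; y0 <- (cells[i, "row"] - 1) * s
    matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s),
           ncol = 2, byrow = TRUE)
  })
  geo <- unit_geography(tibble::tibble(unit_id = ids, district_id = district,
                                       geometry = geom))
  attr(geo, "snake_order") <- ids
  geo
}

# Place hospitals. Two layouts:
#  - "clustered" (default): hospitals gather at well-separated town
#    centres (farthest-point sampling), several hospitals per town. This
#    reproduces the structure of real hospital networks, where a town's
#    hospitals share one natural catchment: moderate initial
#    self-containment (women split between a town's hospitals) but strong
#    separation between towns.
#  - "scattered": one hospital per randomly chosen district, at most
#    ceiling(n_hospitals / n_districts) per district.
#' @keywords internal
place_facilities <- function(geo, config) {
  cen <- unit_centroids(geo)
  if (identical(config$hospital_layout, "scattered")) {
    districts <- sort(unique(geo$district_id), method = "radix")
    order_d <- sample(districts)
    picks <- rep_len(order_d, config$n_hospitals)
    unit_pick <- character(config$n_hospitals)
    for (i in seq_len(config$n_hospitals)) {
      cand <- setdiff(geo$unit_id[geo$district_id == picks[i]], unit_pick)
      if (!length(cand)) cand <- setdiff(geo$unit_id, unit_pick)
      unit_pick[i] <- cand[sample.int(length(cand), 1)]
    }
  } else {
    k <- min(config$n_centres, config$n_hospitals)
    # farthest-point sampling of town-centre units
    centre <- geo$unit_id[sample.int(nrow(geo), 1)]
    while (length(centre) < k) {
      d2min <- vapply(seq_len(nrow(geo)), function(i) {
        min((cen$x[i] - cen$x[match(centre, cen$unit_id)])^2 +
              (cen$y[i] - cen$y[match(centre, cen$unit_id)])^2)
      }, numeric(1))
      centre <- c(centre, geo$unit_id[which.max(d2min)])
    }
    # balanced hospital counts per town, towns in random order
    sizes <- chunk_sizes(config$n_hospitals, k)[sample.int(k)]
    town_of <- rep(centre, sizes)
    adj <- unit_adjacency(geo, rule = "rook")
    unit_pick <- character(config$n_hospitals)
    for (i in seq_len(config$n_hospitals)) {
      nbhd <- c(town_of[i], adj$unit_b[adj$unit_a == town_of[i]])
      cand <- setdiff(nbhd, unit_pick)
      if (!length(cand)) cand <- nbhd
      unit_pick[i] <- cand[sample.int(length(cand), 1)]
    }
  }
  xy <- cen[match(unit_pick, cen$unit_id), ]
  jit <- matrix(stats::runif(2 * config$n_hospitals, -0.25, 0.25) * config$unit_km,
                ncol = 2)
  fac <- tibble::tibble(
    facility_id = sprintf("H%02d", seq_len(config$n_hospitals)),
    unit_id = unit_pick,
    x = xy$x + jit[, 1], y = xy$y + jit[, 2],
    attractiveness = stats::runif(config$n_hospitals,
                                  config$attract_range[1], config$attract_range[2])
  )
  # the bypass magnet: the hospital nearest the south-east corner of the
  # region (standing in for the big regional hospital near the border),
  # given the maximum attractiveness
  corner <- c(max(vapply(geo$geometry, function(g) geom_bbox(g)["xmax"], numeric(1))), 0)
  d2 <- (fac$x - corner[1])^2 + (fac$y - corner[2])^2
  bypass <- which.min(d2)
  fac$attractiveness[bypass] <- max(config$attract_range)
  fac$bypass <- seq_len(nrow(fac)) == bypass
  fac
}

#' @keywords internal
generate_communities <- function(geo, config) {
  cen <- unit_centroids(geo)
  n <- nrow(geo) * config$communities_per_unit
  unit <- rep(geo$unit_id, each = config$communities_per_unit)
  base <- cen[match(unit, cen$unit_id), ]
  off <- matrix(stats::runif(2 * n, -0.45, 0.45) * config$unit_km, ncol = 2)
  births <- pmax(1, round(stats::rlnorm(n, config$births_meanlog, config$births_sdlog)))
  tibble::tibble(
    community_id = sprintf("C%04d", seq_len(n)),
    unit_id = unit,
    x = base$x + off[, 1], y = base$y + off[, 2],
    births = as.integer(births)
  )
}

#' Gravity-model destination choice flows
#'
#' Assigns each community's births to hospitals by a Huff-type rule:
#' choice probability proportional to attractiveness times distance to the
#' power -beta, mixed with a fixed bypass share routed to the designated
#' distant bypass hospital, then drawn multinomially. Flows decay with
#' distance, as observed in routine birth-admission data.
#'
#' @param geo Unit geography (from [generate_geography()]).
#' @param facilities Facility table (with `x`, `y`, `attractiveness`,
#'   `bypass`).
#' @param communities Community table (from the generator).
#' @param config A [scenario_config()].
#' @return Community-level flow tibble `origin_id`, `dest_facility_id`,
#'   `count`.
#' @export
generate_flows <- function(geo, facilities, communities, config) {
  if (config$beta <= 0) stop("the distance-decay exponent beta must be positive")
  D <- sqrt(outer(communities$x, facilities$x, "-")^2 +
              outer(communities$y, facilities$y, "-")^2)
  D <- pmax(D, 1) # floor at 1 km so a co-located hospital cannot dominate numerically
  P <- sweep(D^(-config$beta), 2, facilities$attractiveness, "*")
  P <- P / rowSums(P)
  bypass_col <- which(facilities$bypass)[1]
  if (config$bypass_fraction > 0 && !is.na(bypass_col)) {
    n_src <- round(config$bypass_fraction * nrow(communities))
    src <- sample.int(nrow(communities), n_src)
    P[src, ] <- (1 - config$bypass_strength) * P[src, , drop = FALSE]
    P[src, bypass_col] <- P[src, bypass_col] + config$bypass_strength
  }
  counts <- vapply(seq_len(nrow(communities)), function(i) {
    stats::rmultinom(1, communities$births[i], P[i, ])[, 1]
  }, integer(nrow(facilities)))
  dimnames(counts) <- list(facilities$facility_id, communities$community_id)
  tibble::as_tibble(as.table(counts), .name_repair = "minimal") |>
    stats::setNames(c("dest_facility_id", "origin_id", "count")) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::select("origin_id", "dest_facility_id", "count") |>
    dplyr::mutate(count = as.integer(.data$count)) |>
    dplyr::arrange(.data$origin_id, .data$dest_facility_id)
}

#' Planted-partition flows with ground-truth labels
#'
#' Partitions the units into `k` contiguous blocks (consecutive runs of
#' the lattice traversal), guarantees each block holds at least one
#' hospital by relocating surplus hospitals if needed, and routes each
#' birth to a uniformly chosen hospital inside its own block with
#' probability `within_prob`, otherwise to a uniformly chosen outside
#' hospital. The returned labels are the recovery target for the
#' delineation loop.
#'
#' @inheritParams generate_flows
#' @param k Number of planted zones.
#' @param within_prob Probability a birth stays inside its block (in
#'   (0.5, 1\]).
#' @return List with `flows` (community-level flow tibble), `labels`
#'   (tibble `unit_id`, `true_zone`) and `facilities` (possibly with
#'   relocated hospitals).
#' @export
planted_partition_flows <- function(geo, facilities, communities, k, within_prob,
                                    config) {
  if (k > nrow(facilities)) stop("k exceeds the number of hospitals")
  if (!(within_prob > 0.5 && within_prob <= 1)) {
    stop("within_prob must be in (0.5, 1]")
  }
  snake <- attr(geo, "snake_order")
  if (is.null(snake)) stop("planted partitions need the generator's lattice geography")
  snake <- snake[snake %in% geo$unit_id]
  blocks <- rep(sprintf("B%02d", seq_len(k)), chunk_sizes(length(snake), k))
  labels <- tibble::tibble(unit_id = snake, true_zone = blocks) |>
    dplyr::arrange(.data$unit_id)
  unit_block <- stats::setNames(labels$true_zone, labels$unit_id)

  fac <- facilities
  fac$block <- unname(unit_block[fac$unit_id])
  for (b in sprintf("B%02d", seq_len(k))) {
    if (!any(fac$block == b)) {
      donor_block <- names(sort(table(fac$block), decreasing = TRUE))[1]
      donor <- which(fac$block == donor_block)[1]
      new_unit <- sample(labels$unit_id[labels$true_zone == b], 1)
      cen <- unit_centroids(geo)
      fac$unit_id[donor] <- new_unit
      fac$x[donor] <- cen$x[cen$unit_id == new_unit]
      fac$y[donor] <- cen$y[cen$unit_id == new_unit]
      fac$block[donor] <- b
    }
  }

  com_block <- unname(unit_block[communities$unit_id])
  counts <- matrix(0L, nrow(facilities), nrow(communities),
                   dimnames = list(fac$facility_id, communities$community_id))
  for (i in seq_len(nrow(communities))) {
    inside <- which(fac$block == com_block[i])
    outside <- which(fac$block != com_block[i])
    n_in <- stats::rbinom(1, communities$births[i], within_prob)
    n_out <- communities$births[i] - n_in
    if (n_in > 0) {
      draw <- stats::rmultinom(1, n_in, rep(1, length(inside)))[, 1]
      counts[inside, i] <- counts[inside, i] + as.integer(draw)
    }
    if (n_out > 0 && length(outside)) {
      draw <- stats::rmultinom(1, n_out, rep(1, length(outside)))[, 1]
      counts[outside, i] <- counts[outside, i] + as.integer(draw)
    } else if (n_out > 0) {
      counts[inside, i] <- counts[inside, i] +
        stats::rmultinom(1, n_out, rep(1, length(inside)))[, 1]
    }
  }
  flows <- tibble::as_tibble(as.table(counts), .name_repair = "minimal") |>
    stats::setNames(c("dest_facility_id", "origin_id", "count")) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::select("origin_id", "dest_facility_id", "count") |>
    dplyr::mutate(count = as.integer(.data$count)) |>
    dplyr::arrange(.data$origin_id, .data$dest_facility_id)
  list(flows = flows, labels = labels, facilities = dplyr::select(fac, -"block"))
}

#' @keywords internal
generate_population <- function(geo, config) {
  s <- config$unit_km / config$pop_cells_per_unit_side
  bb <- apply(t(vapply(geo$geometry, geom_bbox, numeric(4))), 2, range)
  xs <- seq(bb[1, "xmin"] + s / 2, bb[2, "xmax"] - s / 2 + 1e-9, by = s)
  ys <- seq(bb[1, "ymin"] + s / 2, bb[2, "ymax"] - s / 2 + 1e-9, by = s)
  grid <- expand.grid(x = xs, y = ys)
  grid$pop <- stats::rlnorm(nrow(grid), config$pop_meanlog, config$pop_sdlog)
  tibble::as_tibble(grid)
}

#' @keywords internal
generate_assessment <- function(facilities, config) {
  n <- nrow(facilities)
  fac <- facilities
  fac$sector <- sample(c("government", "private", "faith-based"), n,
                       replace = TRUE, prob = c(0.6, 0.2, 0.2))
  fac$midwives <- stats::rpois(n, config$midwives_lambda)
  ready <- stats::runif(n) < config$cemonc_ready_frac
  sf <- matrix(TRUE, n, length(SIGNAL_FUNCTIONS),
               dimnames = list(NULL, SIGNAL_FUNCTIONS))
  for (i in which(!ready)) {
    n_fail <- sample.int(3, 1)
    sf[i, sample.int(length(SIGNAL_FUNCTIONS), n_fail)] <- FALSE
  }
  dplyr::bind_cols(fac, tibble::as_tibble(sf))
}

#' Generate a complete synthetic scenario
#'
#' Orchestrates the full synthetic world under a single seed: geography,
#' hospitals with EmONC assessment, communities with births, patient flows
#' (gravity model, or planted partition when `config$planted` is set),
#' the gridded population surface, and the unit-level aggregated flow
#' table. Identical config and seed reproduce the scenario exactly.
#'
#' @param config A [scenario_config()].
#' @return A list of class `nchd_scenario` with elements `config`, `geo`,
#'   `facilities`, `communities`, `community_lookup`, `flows`
#'   (community-level), `unit_flows`, `population` and `labels`
#'   (planted mode only, else `NULL`).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "nchd_config"))
  with_seed(config$seed, {
    geo <- generate_geography(config)
    fac <- place_facilities(geo, config)
    com <- generate_communities(geo, config)
    labels <- NULL
    if (is.null(config$planted)) {
      flows <- generate_flows(geo, fac, com, config)
    } else {
      pp <- planted_partition_flows(geo, fac, com, config$planted$k,
                                    config$planted$within_prob, config)
      flows <- pp$flows
      labels <- pp$labels
      fac <- pp$facilities
    }
    pop <- generate_population(geo, config)
    fac <- generate_assessment(fac, config)
    lookup <- tibble::tibble(community_id = com$community_id, unit_id = com$unit_id)
    structure(list(
      config = config, geo = geo, facilities = fac, communities = com,
      community_lookup = lookup, flows = flows,
      unit_flows = aggregate_to_units(flows, lookup),
      population = pop, labels = labels
    ), class = "nchd_scenario")
  })
}

#' @export
print.nchd_scenario <- function(x, ...) {
  cat("<synthetic scenario> ", nrow(x$geo), " units, ",
      length(unique(x$geo$district_id)), " districts, ",
      nrow(x$facilities), " hospitals, ",
      nrow(x$communities), " communities, total births ",
      sum(x$flows$count), if (!is.null(x$labels)) " (planted partition)" else "",
      "\n", sep = "")
  invisible(x)
}
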
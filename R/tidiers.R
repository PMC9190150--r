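# broom-style tidiers and ggplot2 methods for delineation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a delineation: one row per zone
#'
#' Per-zone demand- and supply-side self-containment and membership size,
#' at both stages of the procedure (`"before_repair"`: straight out of the
#' merge loop; `"after_repair"`: after contiguity repair; identical for
#' the baseline, which needs no repair).
#'
#' @param x An `nchd_delineation` object.
#' @param ... Unused.
#' @return Tibble `stage`, `zone_id`, `n_units`, `demand`, `supply`,
#'   `minimum`.
#' @method tidy nchd_delineation
#' @export
tidy.nchd_delineation <- function(x, ...) {
  count_units <- function(zones) {
    dplyr::count(tibble::as_tibble(zones), .data$zone_id, name = "n_units")
  }
  dplyr::bind_rows(
    dplyr::mutate(dplyr::left_join(x$sc_before, count_units(x$zones_before_repair),
                                   by = "zone_id"),
                  stage = "before_repair"),
    dplyr::mutate(dplyr::left_join(x$sc_after, count_units(x$zones),
                                   by = "zone_id"),
                  stage = "after_repair")
  ) |>
    dplyr::select("stage", "zone_id", "n_units", "demand", "supply", "minimum")
}

#' One-row summary of a delineation
#'
#' @param x An `nchd_delineation` object.
#' @param ... Unused.
#' @return Tibble with `n_zones`, `n_iterations`, `threshold`,
#'   `internal_share` (global share of flows starting and ending in the
#'   same zone), `min_self_containment_before` and
#'   `min_self_containment_after` repair, and `baseline`.
#' @method glance nchd_delineation
#' @export
glance.nchd_delineation <- function(x, ...) {
  tibble::tibble(
    n_zones = length(zone_ids(x$zones)),
    n_iterations = nrow(x$trace),
    threshold = x$threshold,
    internal_share = internal_flow_share(x$flow_matrix),
    min_self_containment_before = min(x$sc_before$minimum),
    min_self_containment_after = min(x$sc_after$minimum),
    baseline = isTRUE(x$baseline)
  )
}

#' @export
print.nchd_delineation <- function(x, ...) {
  g <- glance(x)
  cat("<", if (g$baseline) "baseline comparable zones" else "NCHD delineation",
      "> ", g$n_zones, " zones after ", g$n_iterations, " merges\n", sep = "")
  cat(sprintf("  global internal-flow share: %.3f\n", g$internal_share))
  cat(sprintf("  minimum zone self-containment: %.3f (before repair), %.3f (after)\n",
              g$min_self_containment_before, g$min_self_containment_after))
  invisible(x)
}

# Long-form polygon table for ggplot2.
#' @keywords internal
fortify_geo <- function(geo) {
  purrr::map2_dfr(geo$geometry, geo$unit_id, function(g, id) {
    rings <- geom_rings(g)
    purrr::imap_dfr(rings, function(r, k) {
      rc <- ring_close(r)
      tibble::tibble(unit_id = id, ring = paste0(id, ".", k),
                     x = rc[, 1], y = rc[, 2])
    })
  })
}

#' Map of delineated zones
#'
#' Draws the unit tessellation coloured by final zone membership, with
#' anchor hospitals overplotted.
#'
#' @param object An `nchd_delineation` object.
#' @param stage `"after_repair"` (default) or `"before_repair"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nchd_delineation
#' @export
autoplot.nchd_delineation <- function(object, stage = c("after_repair", "before_repair"),
                                      ...) {
  stage <- match.arg(stage)
  zones <- if (stage == "after_repair") object$zones else object$zones_before_repair
  poly <- fortify_geo(object$geo) |>
    dplyr::left_join(tibble::as_tibble(zones), by = "unit_id")
  fac <- object$facilities
  p <- ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y, group = .data$ring,
                                          fill = .data$zone_id)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "zone", x = "km", y = "km") +
    ggplot2::theme_minimal()
  if (all(c("x", "y") %in% names(fac))) {
    p <- p + ggplot2::geom_point(data = fac,
                                 ggplot2::aes(.data$x, .data$y),
                                 inherit.aes = FALSE, shape = 3, size = 1.6)
  }
  p
}

#' Merge-trace diagnostics plot
#'
#' Global internal-flow share and the merge candidate's self-containment
#' along the iterations of a delineation.
#'
#' @param delin An `nchd_delineation` object.
#' @return A ggplot object.
#' @export
plot_merge_trace <- function(delin) {
  stopifnot(inherits(delin, "nchd_delineation"))
  tr <- delin$trace |>
    tidyr::pivot_longer(c("internal_share", "candidate_sc"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "merge iteration", y = "share of flows") +
    ggplot2::theme_minimal()
}

#' Map of a synthetic scenario
#'
#' Units shaded by district with hospitals marked; a quick look at the
#' generated world.
#'
#' @param object An `nchd_scenario` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nchd_scenario
#' @export
autoplot.nchd_scenario <- function(object, ...) {
  poly <- fortify_geo(object$geo) |>
    dplyr::left_join(tibble::as_tibble(object$geo)[c("unit_id", "district_id")],
                     by = "unit_id")
  ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y, group = .data$ring,
                                     fill = .data$district_id)) +
    ggplot2::geom_polygon(colour = "white", linewidth = 0.15, show.legend = FALSE) +
    ggplot2::geom_point(data = object$facilities,
                        ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
                        shape = 17, size = 1.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km") +
    ggplot2::theme_minimal()
}
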
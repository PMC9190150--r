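test_that("flow ingest sums duplicates, drops zeros, rejects bad counts", {
  fl <- as_flow_table(tibble::tibble(
    origin_id = c("u1", "u1", "u2", "u3"),
    dest_facility_id = c("H1", "H1", "H2", "H1"),
    count = c(3, 4, 0, 5)
  ))
  expect_equal(fl$count[fl$origin_id == "u1"], 7L)
  expect_false("u2" %in% fl$origin_id)
  expect_equal(sum(fl$count), 12L)
  expect_error(as_flow_table(data.frame(origin_id = "a", dest_facility_id = "H",
                                        count = -1)), "non-negative")
  expect_error(as_flow_table(data.frame(origin_id = "a", dest_facility_id = "H",
                                        count = 1.5)), "non-negative integers")
  expect_error(as_flow_table(data.frame(origin_id = "a", x = 1)), "missing column")
})

test_that("community aggregation conserves totals and matches groupby sums", {
  lk <- tibble::tibble(community_id = c("c1", "c2"), unit_id = "u")
  out <- aggregate_to_units(
    tibble::tibble(origin_id = c("c1", "c2"), dest_facility_id = "H1",
                   count = c(3, 4)), lk)
  expect_equal(out, tibble::tibble(origin_id = "u", dest_facility_id = "H1",
                                   count = 7L))

  empty <- aggregate_to_units(
    tibble::tibble(origin_id = character(), dest_facility_id = character(),
                   count = integer()), lk)
  expect_equal(nrow(empty), 0)

  set.seed(42)
  units <- sprintf("u%02d", 1:10)
  coms <- sprintf("c%03d", 1:60)
  lk2 <- tibble::tibble(community_id = coms, unit_id = sample(units, 60, TRUE))
  fl <- tibble::tibble(origin_id = sample(coms, 1000, TRUE),
                       dest_facility_id = sample(c("H1", "H2", "H3"), 1000, TRUE),
                       count = sample(1:9, 1000, TRUE))
  got <- aggregate_to_units(fl, lk2)
  expect_equal(sum(got$count), sum(fl$count))
  # brute-force accumulation
  want <- new.env()
  for (i in seq_len(nrow(fl))) {
    u <- lk2$unit_id[lk2$community_id == fl$origin_id[i]]
    key <- paste(u, fl$dest_facility_id[i])
    assign(key, (if (exists(key, want)) get(key, want) else 0) + fl$count[i], want)
  }
  for (r in seq_len(nrow(got))) {
    expect_equal(got$count[r],
                 get(paste(got$origin_id[r], got$dest_facility_id[r]), want))
  }
  expect_error(
    aggregate_to_units(tibble::tibble(origin_id = "nowhere",
                                      dest_facility_id = "H1", count = 1), lk2),
    "nowhere")
})

test_that("birthless units merge into the same-district neighbour with the longest border", {
  # 5x5 lattice, left 3 columns district A, right 2 district B
  districts <- ifelse((seq_len(25) - 1) %% 5 < 3, "A", "B")
  geo <- make_lattice_geo(5, 5, districts = districts)
  fac <- tibble::tibble(facility_id = "H1", unit_id = "u01")
  live <- setdiff(geo$unit_id, c("u07", "u13", "u25"))
  flows <- tibble::tibble(origin_id = live, dest_facility_id = "H1", count = 5)

  res <- merge_birthless_units(geo, flows, fac)
  mm <- res$merge_map
  expect_equal(sort(mm$old_unit), sort(geo$unit_id))
  changed <- mm[mm$old_unit != mm$new_unit, ]
  expect_setequal(changed$old_unit, c("u07", "u13", "u25"))
  # all rook borders tie at length 1; smallest same-district neighbour wins
  expect_equal(mm$new_unit[mm$old_unit == "u07"], "u02")
  expect_equal(mm$new_unit[mm$old_unit == "u13"], "u08")
  expect_equal(mm$new_unit[mm$old_unit == "u25"], "u20")
  # district membership preserved
  dist <- setNames(districts, geo$unit_id)
  expect_true(all(dist[changed$old_unit] == dist[changed$new_unit]))
  # receiving units absorbed the geometry
  expect_equal(sum(res$geo$area_km2), 25)
  expect_equal(nrow(res$geo), 22)
})

test_that("all-live inputs give an identity merge map", {
  geo <- make_lattice_geo(2, 2)
  flows <- tibble::tibble(origin_id = geo$unit_id, dest_facility_id = "H1", count = 1)
  res <- merge_birthless_units(geo, flows,
                               tibble::tibble(facility_id = "H1", unit_id = "u01"))
  expect_equal(res$merge_map$old_unit, res$merge_map$new_unit)
  expect_equal(nrow(res$geo), 4)
})

test_that("an entirely birthless district is an error", {
  geo <- make_lattice_geo(2, 2, districts = c("A", "A", "B", "B"))
  flows <- tibble::tibble(origin_id = c("u01", "u02"), dest_facility_id = "H1",
                          count = 3)
  expect_error(
    merge_birthless_units(geo, flows,
                          tibble::tibble(facility_id = "H1", unit_id = "u01")),
    "birthless")
})

test_that("initial zones follow the plurality rule with lexicographic ties", {
  geo <- make_lattice_geo(1, 3)
  fac <- tibble::tibble(facility_id = c("H1", "H2"), unit_id = c("u01", "u03"))
  flows <- tibble::tibble(
    origin_id = c("u01", "u01", "u02", "u02", "u03"),
    dest_facility_id = c("H1", "H2", "H1", "H2", "H2"),
    count = c(7, 3, 5, 5, 9)
  )
  z <- initial_zones(flows, geo, fac)
  asg <- setNames(z$zone_id, z$unit_id)
  expect_equal(unname(asg["u01"]), "H1")
  expect_equal(unname(asg["u02"]), "H1") # 5-5 tie -> smaller facility id
  expect_equal(unname(asg["u03"]), "H2")
  anc <- zone_anchors(z)
  expect_setequal(anc$zone_id, c("H1", "H2"))
})

test_that("random assignments equal per-unit argmax computed independently", {
  set.seed(7)
  geo <- make_lattice_geo(4, 5)
  fac <- tibble::tibble(facility_id = c("H1", "H2", "H3"),
                        unit_id = c("u01", "u10", "u20"))
  fl <- expand.grid(origin_id = geo$unit_id,
                    dest_facility_id = fac$facility_id,
                    stringsAsFactors = FALSE)
  fl$count <- sample(1:50, nrow(fl), TRUE)
  z <- initial_zones(fl, geo, fac)
  asg <- setNames(z$zone_id, z$unit_id)
  for (u in geo$unit_id) {
    rows <- fl[fl$origin_id == u, ]
    rows <- rows[order(-rows$count, rows$dest_facility_id), ]
    expect_equal(unname(asg[u]), rows$dest_facility_id[1])
  }
})

test_that("initial zones is idempotent and rejects unknown facilities", {
  geo <- make_lattice_geo(2, 2)
  fac <- tibble::tibble(facility_id = "H1", unit_id = "u01")
  fl <- tibble::tibble(origin_id = geo$unit_id, dest_facility_id = "H1", count = 2)
  expect_identical(initial_zones(fl, geo, fac), initial_zones(fl, geo, fac))
  fl2 <- dplyr::mutate(fl, dest_facility_id = "HX")
  expect_error(initial_zones(fl2, geo, fac), "unknown facilities.*HX")
})

test_that("zone flow matrix tabulates exactly and conserves the total", {
  geo <- make_lattice_geo(1, 2)
  fac <- tibble::tibble(facility_id = c("H1", "H2"), unit_id = c("u01", "u02"))
  zones <- zone_system(tibble::tibble(unit_id = c("u01", "u02"),
                                      zone_id = c("Z1", "Z2")),
                       tibble::tibble(zone_id = c("Z1", "Z2"),
                                      facility_id = c("H1", "H2")))
  fl <- tibble::tibble(
    origin_id = c("u01", "u01", "u02", "u02"),
    dest_facility_id = c("H1", "H2", "H1", "H2"),
    count = c(10, 5, 2, 20)
  )
  T_ <- zone_flow_matrix(fl, zones, fac)
  expect_equal(T_, matrix(c(10L, 2L, 5L, 20L), 2,
                          dimnames = list(c("Z1", "Z2"), c("Z1", "Z2"))))

  # one-zone system: grand total
  z1 <- zone_system(tibble::tibble(unit_id = c("u01", "u02"), zone_id = "Z"),
                    tibble::tibble(zone_id = c("Z", "Z"),
                                   facility_id = c("H1", "H2")))
  expect_equal(zone_flow_matrix(fl, z1, fac),
               matrix(37L, 1, dimnames = list("Z", "Z")))
})

test_that("zone flow matrix equals a brute-force double loop on random scenarios", {
  set.seed(31)
  geo <- make_lattice_geo(5, 10)
  fac <- tibble::tibble(facility_id = sprintf("H%d", 1:6),
                        unit_id = sample(geo$unit_id, 6))
  fl <- expand.grid(origin_id = geo$unit_id, dest_facility_id = fac$facility_id,
                    stringsAsFactors = FALSE)
  fl$count <- rpois(nrow(fl), 3)
  fl <- fl[fl$count > 0, ]
  zid <- sample(sprintf("Z%d", 1:4), nrow(geo), TRUE)
  zones <- zone_system(
    tibble::tibble(unit_id = geo$unit_id, zone_id = zid),
    tibble::tibble(zone_id = zid[match(fac$unit_id, geo$unit_id)],
                   facility_id = fac$facility_id))
  T_ <- zone_flow_matrix(fl, zones, fac)
  expect_equal(sum(T_), sum(fl$count))
  uz <- setNames(zid, geo$unit_id)
  fz <- setNames(uz[fac$unit_id], fac$facility_id)
  want <- matrix(0L, nrow(T_), ncol(T_), dimnames = dimnames(T_))
  for (r in seq_len(nrow(fl))) {
    want[uz[fl$origin_id[r]], fz[fl$dest_facility_id[r]]] <-
      want[uz[fl$origin_id[r]], fz[fl$dest_facility_id[r]]] + fl$count[r]
  }
  expect_equal(T_, want)
})
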
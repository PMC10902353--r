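test_that("emissions weight stock and slaughtered heads by ALS/12", {
  w <- manual_world(stock = 1000, slaughtered = 0, ef_ent = 100,
                    als_stock = 12, als_slaughtered = 6)
  cube <- compute_emissions(w$panel, w$ent, w$man, w$climate, w$pars)
  expect_equal(cube$records[pathway == "enteric", emissions_gg], 0.1,
               tolerance = 1e-12)

  ws <- manual_world(stock = 1000, slaughtered = 1000, ef_ent = 100,
                     als_stock = 12, als_slaughtered = 6)
  cubes <- compute_emissions(ws$panel, ws$ent, ws$man, ws$climate, ws$pars)
  expect_equal(cubes$records[pathway == "enteric", emissions_gg],
               0.1 + 0.05, tolerance = 1e-12)

  # stocked sheep emit for 5.6 of 12 months
  wsheep <- manual_world(stock = 1000, slaughtered = 0, ef_ent = 100)
  wsheep$pars$lifespans$horse$stock <- 5.6
  cubesh <- compute_emissions(wsheep$panel, wsheep$ent, wsheep$man,
                              wsheep$climate, wsheep$pars)
  expect_equal(cubesh$records[pathway == "enteric", emissions_gg],
               0.1 * 5.6 / 12, tolerance = 1e-12)

  # empty panel -> empty cube; NA heads refused
  empty <- w$panel[0]
  expect_identical(nrow(compute_emissions(empty, w$ent, w$man, w$climate,
                                          w$pars)$records), 0L)
  bad <- data.table::copy(w$panel)[1, stock_head := NA_real_]
  expect_error(compute_emissions(bad, w$ent, w$man, w$climate, w$pars),
               "gap-fill")
  # EF coverage gaps are refused
  expect_error(compute_emissions(w$panel, w$ent[0], w$man, w$climate,
                                 w$pars), "enteric EF")
})

test_that("aggregation sums exactly and commutes with the pathway split", {
  w <- tiny_world()
  city <- aggregate_emissions(w$cube, "city")
  prov <- aggregate_emissions(w$cube, "province")
  natl <- aggregate_emissions(w$cube, "national")

  byprov <- city[, .(emissions_gg = sum(emissions_gg)),
                 keyby = .(province_id, year, pathway)]
  expect_equal(byprov$emissions_gg, prov$emissions_gg, tolerance = 1e-12)
  bynatl <- prov[, .(emissions_gg = sum(emissions_gg)),
                 keyby = .(year, pathway)]
  expect_equal(bynatl$emissions_gg, natl$emissions_gg, tolerance = 1e-12)

  # national total equals the sum of all city records to 1e-9 relative
  expect_equal(natl[, sum(emissions_gg)],
               w$cube$records[, sum(emissions_gg)], tolerance = 1e-9)
  expect_error(aggregate_emissions(w$cube, "continent"))

  # hand-sized example: two cities 0.1 + 0.2 -> province 0.3
  rec <- data.table(
    city_id = c("A", "B"), province_id = "P", year = 2015L,
    category = "swine", pathway = "manure", emissions_gg = c(0.1, 0.2))
  cube2 <- structure(list(records = rec,
                          cities = unique(rec[, .(city_id, province_id)])),
                     class = "ch4_inventory_cube")
  expect_equal(aggregate_emissions(cube2, "province")$emissions_gg, 0.3)
  # single-city province: province record equals the city record
  expect_equal(
    aggregate_emissions(cube2, "city")[city_id == "A", emissions_gg],
    0.1)
})

test_that("ruminant/nonruminant split partitions the totals", {
  w <- tiny_world()
  rn <- split_ruminant(w$cube)
  expect_identical(nrow(rn), 2L * w$spec$n_cities * length(w$spec$years))
  tot <- aggregate_emissions(w$cube, "city")[
    , .(emissions_gg = sum(emissions_gg)), by = .(city_id, year)]
  rnsum <- rn[, .(emissions_gg = sum(emissions_gg)), by = .(city_id, year)]
  expect_equal(rnsum[order(city_id, year)]$emissions_gg,
               tot[order(city_id, year)]$emissions_gg, tolerance = 1e-12)

  swine_only <- manual_world(stock = 1000, ef_ent = 1, ef_man = 5,
                             category = "swine")
  swine_only$panel[, subclass := "whole_herd"]
  cube_s <- compute_emissions(swine_only$panel, swine_only$ent,
                              swine_only$man, swine_only$climate,
                              swine_only$pars)
  rn_s <- split_ruminant(cube_s)
  expect_identical(rn_s[animal_class == "ruminant", emissions_gg], 0)
  expect_gt(rn_s[animal_class == "nonruminant", emissions_gg], 0)

  cattle_only <- manual_world(stock = 1000, ef_ent = 50, category = "camel")
  cube_c <- compute_emissions(cattle_only$panel, cattle_only$ent,
                              cattle_only$man, cattle_only$climate,
                              cattle_only$pars)
  expect_identical(split_ruminant(cube_c)[animal_class == "nonruminant",
                                          emissions_gg], 0)
})

test_that("conservation holds on randomised cubes", {
  set.seed(77)
  all_cats <- livestock_categories()$category
  for (i in 1:5) {
    n_city <- sample(5:25, 1)
    rec <- CJ(city_id = sprintf("C%02d", 1:n_city), year = 2010:2012,
              category = sample(all_cats, sample(3:12, 1)),
              pathway = c("enteric", "manure"))
    rec[, province_id := paste0("P", (match(city_id, unique(city_id)) %% 4) + 1)]
    rec[, emissions_gg := stats::rexp(.N)]
    cube <- structure(list(records = rec,
                           cities = unique(rec[, .(city_id, province_id)])),
                      class = "ch4_inventory_cube")
    total <- rec[, sum(emissions_gg)]
    expect_equal(aggregate_emissions(cube, "national")[, sum(emissions_gg)],
                 total, tolerance = 1e-9)
    expect_equal(aggregate_emissions(cube, "province")[, sum(emissions_gg)],
                 total, tolerance = 1e-9)
    expect_equal(aggregate_emissions(cube, "national", by_category = TRUE)[
      , sum(emissions_gg)], total, tolerance = 1e-9)
    expect_equal(split_ruminant(cube)[, sum(emissions_gg)], total,
                 tolerance = 1e-9)
  }
})

test_that("the inventory is linear in activity data", {
  w <- tiny_world()
  scaled <- data.table::copy(w$filled)
  scaled[, `:=`(stock_head = 3 * stock_head,
                slaughtered_head = 3 * slaughtered_head)]
  cube3 <- compute_emissions(scaled, w$ent, w$man, w$tc$climate, w$pars)
  expect_equal(cube3$records$emissions_gg,
               3 * w$cube$records$emissions_gg, tolerance = 1e-12)
})

test_that("export writes six coherent files deterministically", {
  w <- tiny_world()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- export_dataset(w$cube, d1)
  p2 <- export_dataset(w$cube, d2)
  expect_length(p1, 6L)

  n_cells <- w$spec$n_cities * length(w$spec$years)
  f1 <- fread(p1[["city_total"]])
  expect_identical(nrow(f1), n_cells)
  expect_identical(nrow(fread(p1[["city_enteric"]])), n_cells)
  expect_identical(nrow(fread(p1[["city_manure"]])), n_cells)
  expect_identical(nrow(fread(p1[["city_ruminant"]])), 2L * n_cells)

  # byte-identical re-export
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))

  # partitions survive the round trip through the files
  natl <- fread(p1[["national_provincial"]])[level == "national"]
  bycat <- fread(p1[["category_national"]])
  merged <- merge(bycat[, .(cat_sum = sum(emissions_gg)),
                        by = .(year, pathway)],
                  natl[pathway != "total",
                       .(year, pathway, emissions_gg)],
                  by = c("year", "pathway"))
  expect_equal(merged$cat_sum, merged$emissions_gg, tolerance = 1e-9)
  # enteric + manure = total in the exported national series
  tot <- merge(natl[pathway != "total",
                    .(sum_path = sum(emissions_gg)), by = year],
               natl[pathway == "total", .(year, emissions_gg)], by = "year")
  expect_equal(tot$sum_path, tot$emissions_gg, tolerance = 1e-9)
  # city totals file = enteric + manure files
  f2 <- fread(p1[["city_enteric"]]); f3 <- fread(p1[["city_manure"]])
  expect_equal(f1[order(city_id, year), emissions_gg],
               f2[order(city_id, year), emissions_gg] +
                 f3[order(city_id, year), emissions_gg], tolerance = 1e-9)
})
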
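factors_path <- system.file("extdata", "equivalent_factors_template.csv",
                            package = "luccesv")
factors <- read_factors_csv(factors_path)

test_that("food production unit value follows its closed form", {
  crops <- crop_economics(data.frame(
    crop = c("a", "b"), sowing_area_hm2 = c(60, 40),
    price_yuan_per_t = c(2000, 1500), yield_t_per_hm2 = c(4, 2)
  ))
  expect_equal(round(food_production_unit_value(crops), 2), 857.14)

  unit <- crop_economics(data.frame(
    crop = "w", sowing_area_hm2 = 100, price_yuan_per_t = 7,
    yield_t_per_hm2 = 1
  ))
  expect_equal(food_production_unit_value(unit), 1)

  free <- crop_economics(data.frame(
    crop = c("a", "b"), sowing_area_hm2 = c(1, 2),
    price_yuan_per_t = c(0, 0), yield_t_per_hm2 = c(3, 3)
  ))
  expect_equal(food_production_unit_value(free), 0)
})

test_that("unit prices scale the factors elementwise", {
  up <- unit_price_table(857.14, factors)
  expect_equal(up["climate regulation", "wetland"], 13.55 * 857.14)
  expect_equal(unname(unit_price_table(0, factors)[3, 2]), 0)
  expect_equal(round(2.5 * 857.14, 2), 2142.85) # e = 2.5 worked value
})

test_that("esv respects the km2-to-hm2 conversion on one class", {
  # single ecosystem with service prices summing to 1000 Yuan/hm2/a
  f1 <- equivalent_factor_table(data.frame(
    service = service_names(), eco = c(1000, rep(0, 8))
  ))
  up <- unit_price_table(1, f1)
  mapping <- class_ecosystem_mapping("cropland", "eco")
  res <- esv_totals(data.frame(class = "cropland", area_km2 = 1), up,
                    mapping = mapping)
  expect_equal(res$total_yuan, 100000)
})

test_that("zero areas give zero value everywhere", {
  up <- unit_price_table(500, factors)
  res <- esv_totals(data.frame(class = legend_names(leg7), area_km2 = 0), up)
  expect_equal(res$total_yuan, 0)
  expect_true(all(res$by_service$esv_yuan == 0))
})

test_that("by-class and by-service decompositions agree and scale linearly", {
  g <- generate_landscape(64, 64, rep(1 / 7, 7), patchiness = 12, seed = 40)
  up <- unit_price_table(food_production_unit_value(
    generate_crop_economics(41)
  ), factors)
  res <- esv_totals(g, up)
  expect_equal(sum(res$by_class$esv_yuan), res$total_yuan,
               tolerance = 1e-9)
  expect_equal(sum(res$by_service$esv_yuan), res$total_yuan,
               tolerance = 1e-9)
  areas <- class_areas(g)
  doubled <- esv_totals(dplyr::mutate(areas, area_km2 = 2 * area_km2), up)
  expect_equal(doubled$total_yuan, 2 * res$total_yuan, tolerance = 1e-12)

  # construction land is zero-valued under the default mapping
  cons <- res$by_class$esv_yuan[res$by_class$class == "construction"]
  expect_equal(cons, 0)
})

test_that("an unmapped class with positive area is an error", {
  up <- unit_price_table(500, factors)
  mapping <- default_class_mapping()[1:3]
  expect_error(
    esv_totals(data.frame(class = "unused", area_km2 = 5), up,
               mapping = mapping),
    "unused"
  )
})

test_that("zonal ESV reconciles with the regional total", {
  g <- generate_landscape(96, 96, rep(1 / 7, 7), patchiness = 15, seed = 42)
  z <- generate_zones(96, 96, 38, seed = 43)
  up <- unit_price_table(700, factors)
  by_zone <- esv_by_zone(g, z, up)
  total <- esv_totals(g, up)$total_yuan
  expect_equal(nrow(by_zone), 38)
  expect_equal(sum(by_zone$esv_yuan), total, tolerance = 1e-9)
  expect_equal(sum(by_zone$area_km2), n_cells(g) * cell_area_km2(g))

  # single zone equals the regional computation
  z1 <- zone_map(matrix(1L, 96, 96))
  one <- esv_by_zone(g, z1, up)
  expect_equal(one$esv_yuan, total)

  # uniform landscape split into two equal zones: each holds half
  gu <- grid_of(matrix(3L, 10, 10))
  z2 <- zone_map(matrix(rep(c(1L, 2L), each = 50), 10))
  two <- esv_by_zone(gu, z2, up)
  expect_equal(two$esv_yuan[1], two$esv_yuan[2])
  expect_equal(sum(two$esv_yuan), esv_totals(gu, up)$total_yuan)
})

test_that("hm2-based and km2-based computations agree (scale invariance)", {
  up <- unit_price_table(650, factors)
  areas_km2 <- data.frame(class = "grassland", area_km2 = 123.4)
  res <- esv_totals(areas_km2, up)
  price_per_hm2 <- sum(unclass(up)[, "grassland"])
  expect_equal(res$total_yuan, 123.4 * 100 * price_per_hm2)
})
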
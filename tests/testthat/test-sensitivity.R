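factors <- read_factors_csv(system.file(
  "extdata", "equivalent_factors_template.csv", package = "luccesv"
))

test_that("sensitivity index follows its closed form", {
  expect_equal(sensitivity_index(100, 110, R = 2, t1 = 0, t2 = 10), 50)
  expect_equal(sensitivity_index(77, 77, R = 1.3, t1 = 1990, t2 = 2000), 0)
  # homogeneity: doubling R halves SI
  expect_equal(sensitivity_index(100, 110, 4, 0, 10),
               sensitivity_index(100, 110, 2, 0, 10) / 2)
  # adding a constant to both ESVs leaves SI unchanged only via the
  # difference; the formula depends on ESVs only through it
  expect_equal(sensitivity_index(200, 210, 2, 0, 10),
               sensitivity_index(100, 110, 2, 0, 10))
  expect_true(is.na(sensitivity_index(100, 120, R = 0, t1 = 0, t2 = 10)))
  expect_error(sensitivity_index(1, 2, 1, t1 = 10, t2 = 10), "greater")
})

test_that("only changing zones get a positive SI; R = 0 zones are flagged", {
  # 4 quadrant zones; change confined to quadrant 1
  m1 <- matrix(3L, 40, 40)
  m2 <- m1
  m2[1:10, 1:10] <- 4L # wetland gain inside zone 1 only
  zvals <- matrix(0L, 40, 40)
  zvals[1:20, 1:20] <- 1L; zvals[1:20, 21:40] <- 2L
  zvals[21:40, 1:20] <- 3L; zvals[21:40, 21:40] <- 4L
  z <- zone_map(zvals)
  up <- unit_price_table(600, factors)
  si <- si_by_zone(grid_of(m1), grid_of(m2), z, up, t1 = 2000, t2 = 2010)
  expect_equal(nrow(si), 4)
  expect_true(si$defined[si$zone == 1])
  expect_gt(si$si[si$zone == 1], 0)
  expect_true(all(!si$defined[si$zone != 1]))
  expect_true(all(is.na(si$si[si$zone != 1])))
})

test_that("a single zone reproduces the regional index", {
  g1 <- generate_landscape(64, 64, rep(1 / 7, 7), patchiness = 10, seed = 50)
  g2 <- evolve_landscape(g1, kernel7(0.9), clustering_strength = 0.2,
                         seed = 51)
  z1 <- zone_map(matrix(1L, 64, 64))
  up <- unit_price_table(600, factors)
  si <- si_by_zone(g1, g2, z1, up, t1 = 1990, t2 = 2000)
  tm <- crosstab(g1, g2, 10)
  R <- cludd(tm)
  e1 <- esv_totals(g1, up)$total_yuan * 1e-9
  e2 <- esv_totals(g2, up)$total_yuan * 1e-9
  expect_equal(si$si, sensitivity_index(e1, e2, R, 1990, 2000))
  expect_equal(si$cludd_pct_per_year, R)
})

test_that("area-weighted zonal dynamic degrees reproduce the regional one", {
  g1 <- generate_landscape(64, 64, rep(1 / 7, 7), patchiness = 10, seed = 52)
  g2 <- evolve_landscape(g1, kernel7(0.9), clustering_strength = 0.1,
                         seed = 53)
  z <- generate_zones(64, 64, 6, seed = 54)
  up <- unit_price_table(600, factors)
  si <- si_by_zone(g1, g2, z, up, t1 = 2000, t2 = 2010)
  R_region <- cludd(crosstab(g1, g2, 10))
  R_weighted <- sum(si$cludd_pct_per_year * si$area_km2) / sum(si$area_km2)
  expect_equal(R_weighted, R_region, tolerance = 1e-12)
  # zonal ESVs sum to the regional ESV
  expect_equal(sum(si$esv_t2), esv_totals(g2, up)$total_yuan * 1e-9,
               tolerance = 1e-9)
})

test_that("si change classification splits zones and shares sum to 100", {
  si_a <- tibble::tibble(zone = 1:4, si = c(1, 2, 3, 4),
                         area_km2 = c(10, 10, 20, 20), defined = TRUE)
  si_b <- tibble::tibble(zone = 1:4, si = c(2, 1, 3.5, 2),
                         area_km2 = c(10, 10, 20, 20), defined = TRUE)
  sm <- classify_si_change(si_a, si_b)
  expect_equal(sort(sm$change), c("decrease", "increase"))
  expect_equal(sum(sm$n_zones), 4)
  expect_equal(sum(sm$zone_share_pct), 100)
  expect_equal(sum(sm$area_share_pct), 100)
  dec <- sm[sm$change == "decrease", ]
  expect_equal(dec$n_zones, 2)
  expect_equal(dec$area_km2, 30)

  # all-decrease edge: one group holding 100%
  sm2 <- classify_si_change(si_a, dplyr::mutate(si_b, si = si_a$si - 1))
  expect_equal(sm2$change, "decrease")
  expect_equal(sm2$area_share_pct, 100)

  # two equal-area zones, one up one down
  sm3 <- classify_si_change(
    tibble::tibble(zone = 1:2, si = c(1, 2), area_km2 = c(5, 5)),
    tibble::tibble(zone = 1:2, si = c(2, 1), area_km2 = c(5, 5))
  )
  expect_equal(sort(sm3$area_share_pct), c(50, 50))

  # undefined SI zones are excluded with a warning
  si_na <- dplyr::mutate(si_b, si = replace(si, 1, NA))
  expect_warning(sm4 <- classify_si_change(si_a, si_na), "excluded")
  expect_equal(sum(sm4$n_zones), 3)
})

test_that("published group areas give the published decrease share", {
  groups <- qinghai_si_change_groups()
  first <- groups[groups$comparison == "1990-2000_vs_2000-2010", ]
  share <- 100 * first$area_1e4_km2 / sum(first$area_1e4_km2)
  expect_equal(round(share[first$change == "decrease"], 2), 70.08)
  expect_equal(round(share[first$change == "increase"], 2), 29.92)
})
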
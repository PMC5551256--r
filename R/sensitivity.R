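#' Sensitivity index of ESV to land-use change
#'
#' An elasticity-style index: `SI = |(ESV_t2 - ESV_t1) / R| / (t2 - t1) *
#' 100`, where R is the comprehensive land-use dynamic degree of the same
#' period expressed as a percentage number (e.g. 1.61, not 0.0161). A high
#' SI means a small amount of land conversion moved a large amount of
#' service value. SI is 0 exactly when ESV did not change; when R is 0 the
#' index is undefined and returned as NA rather than an error.
#'
#' The scale of the ESV inputs propagates linearly into SI, so pick one
#' convention and keep it; the zonal wrapper uses ESV in 1e9 Yuan.
#'
#' @param esv_t1,esv_t2 ESV at the period start and end (same unit).
#' @param R Comprehensive dynamic degree of the period, percent per year.
#' @param t1,t2 Period start and end in years (t2 > t1).
#' @return SI (unitless given a fixed ESV unit), or NA when R = 0.
#' @examples
#' sensitivity_index(100, 110, R = 2, t1 = 0, t2 = 10) # 50
#' @export
sensitivity_index <- function(esv_t1, esv_t2, R, t1, t2) {
  if (any(t2 <= t1)) stop("`t2` must be greater than `t1`", call. = FALSE)
  out <- abs((esv_t2 - esv_t1) / R) / (t2 - t1) * 100
  out[R == 0] <- NA_real_
  out
}

#' Per-zone sensitivity of ESV to land-use change
#'
#' For each zone, cross-tabulates the zone's cells between the two dates to
#' get a zonal comprehensive dynamic degree, values the zone's land at both
#' dates, and applies the sensitivity index. Zones with no land change
#' (R = 0) get NA with `defined = FALSE`. ESV enters the index in units of
#' `esv_scale` Yuan (default 1e-9, i.e. 1e9-Yuan units).
#'
#' @param grid_t1,grid_t2 Aligned [land_cover_grid()]s for the period ends.
#' @param zones A [zone_map()] aligned to the grids.
#' @param prices A [unit_price_table()].
#' @param t1,t2 Period start/end in years.
#' @param mapping Class-to-ecosystem mapping.
#' @param services Optional character vector restricting the valuation to a
#'   subset of the nine services (e.g. `"soil conservation"`).
#' @param esv_scale Multiplier applied to Yuan before the index (default
#'   1e-9).
#' @return A tibble with columns `zone`, `area_km2`, `esv_t1`, `esv_t2`
#'   (in scaled units), `cludd_pct_per_year`, `si`, `defined`.
#' @export
si_by_zone <- function(grid_t1, grid_t2, zones, prices, t1, t2,
                       mapping = default_class_mapping(), services = NULL,
                       esv_scale = 1e-9) {
  check_aligned(grid_t1, grid_t2)
  if (!identical(dim(grid_t1$values), dim(zones$values))) {
    stop("zone map shape does not match the grids", call. = FALSE)
  }
  if (!is.null(services)) {
    bad <- setdiff(services, rownames(prices))
    if (length(bad) > 0) {
      stop("unknown service(s): ", paste(bad, collapse = "; "), call. = FALSE)
    }
    prices_sub <- prices[services, , drop = FALSE]
    class(prices_sub) <- class(prices)
  } else {
    prices_sub <- prices
  }
  period <- t2 - t1
  nd <- legend_nodata(grid_t1$legend)
  keep <- grid_t1$values != nd & grid_t2$values != nd & !is.na(zones$values)
  zvals <- zones$values[keep]
  v1 <- grid_t1$values[keep]
  v2 <- grid_t2$values[keep]
  ca <- cell_area_km2(grid_t1)
  codes <- legend_codes(grid_t1$legend)
  nm <- legend_names(grid_t1$legend)
  ep_sum <- colSums(class_unit_prices(nm, prices_sub, mapping)) * 100 # /km2
  ids <- sort(unique(zvals))
  rows <- lapply(ids, function(z) {
    in_z <- zvals == z
    a <- v1[in_z]; b <- v2[in_z]
    n_z <- sum(in_z)
    changed <- sum(a != b)
    R <- changed / n_z / period * 100
    areas1 <- tabulate(match(a, codes), nbins = length(codes)) * ca
    areas2 <- tabulate(match(b, codes), nbins = length(codes)) * ca
    e1 <- sum(areas1 * ep_sum) * esv_scale
    e2 <- sum(areas2 * ep_sum) * esv_scale
    tibble::tibble(
      zone = z, area_km2 = n_z * ca, esv_t1 = e1, esv_t2 = e2,
      cludd_pct_per_year = R,
      si = sensitivity_index(e1, e2, R, t1, t2),
      defined = R != 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify per-zone sensitivity change between two periods
#'
#' Joins two per-zone SI tables (same zone set), drops zones whose SI is
#' undefined in either period, and splits the rest into increase, decrease
#' and tie groups with counts, total areas, and area/count shares.
#'
#' @param si_a,si_b Tibbles from [si_by_zone()] (or any tibble with `zone`,
#'   `si`, `area_km2`, optional `defined`) for the earlier and later period
#'   comparison.
#' @return An `si_change_summary` tibble with columns `change` (increase /
#'   decrease / tie), `n_zones`, `zone_share_pct`, `area_km2`,
#'   `area_share_pct`; attribute `n_excluded` counts zones dropped for
#'   undefined SI.
#' @export
classify_si_change <- function(si_a, si_b) {
  j <- dplyr::inner_join(
    dplyr::select(si_a, "zone", si_a = "si", area_km2 = "area_km2"),
    dplyr::select(si_b, "zone", si_b = "si"),
    by = "zone"
  )
  dropped <- nrow(si_a) + nrow(si_b) - 2 * nrow(j)
  ok <- !is.na(j$si_a) & !is.na(j$si_b)
  n_excluded <- sum(!ok) + dropped
  if (n_excluded > 0) {
    warning(n_excluded, " zone record(s) excluded (missing or undefined SI)",
            call. = FALSE)
  }
  j <- j[ok, ]
  j$change <- dplyr::case_when(
    j$si_b > j$si_a ~ "increase",
    j$si_b < j$si_a ~ "decrease",
    TRUE ~ "tie"
  )
  out <- j |>
    dplyr::group_by(.data$change) |>
    dplyr::summarise(n_zones = dplyr::n(),
                     area_km2 = sum(.data$area_km2), .groups = "drop") |>
    dplyr::mutate(
      zone_share_pct = 100 * .data$n_zones / sum(.data$n_zones),
      area_share_pct = 100 * .data$area_km2 / sum(.data$area_km2)
    ) |>
    dplyr::select("change", "n_zones", "zone_share_pct", "area_km2",
                  "area_share_pct")
  structure(out, n_excluded = n_excluded,
            class = c("si_change_summary", class(out)))
}
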
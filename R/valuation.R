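#' Economic value of cropland food production per unit area
#'
#' `E_a = (1/7) * sum(m_i * p_i * q_i) / M` in Yuan/hm2/a, where m_i is the
#' sowing area of crop i (hm2), p_i its mean price (Yuan/t), q_i its yield
#' (t/hm2/a), and M the total sowing area. The 1/7 factor is the standard
#' equivalent-factor convention: one value unit is one seventh of the mean
#' grain market value per hectare.
#'
#' @param crops A [crop_economics()] tibble.
#' @return E_a in Yuan/hm2/a.
#' @examples
#' crops <- crop_economics(data.frame(
#'   crop = c("a", "b"), sowing_area_hm2 = c(60, 40),
#'   price_yuan_per_t = c(2000, 1500), yield_t_per_hm2 = c(4, 2)
#' ))
#' food_production_unit_value(crops) # 857.14
#' @export
food_production_unit_value <- function(crops) {
  M <- attr(crops, "M")
  if (is.null(M)) M <- sum(crops$sowing_area_hm2)
  if (M <= 0) stop("total sowing area M must be positive", call. = FALSE)
  sum(crops$sowing_area_hm2 * crops$price_yuan_per_t *
        crops$yield_t_per_hm2) / M / 7
}

#' Unit-price table of ecosystem services
#'
#' Scales the equivalent factors by the cropland food-production value:
#' `E_ij = e_ij * E_a` (Yuan/hm2/a) for service i of ecosystem j.
#'
#' @param E_a Food-production unit value (Yuan/hm2/a, >= 0).
#' @param factors An [equivalent_factor_table()].
#' @return A `unit_price_table`: 9 x n_ecosystem matrix of Yuan/hm2/a with
#'   attribute `E_a`.
#' @export
unit_price_table <- function(E_a, factors) {
  if (E_a < 0) stop("`E_a` must be >= 0", call. = FALSE)
  m <- unclass(factors) * E_a
  structure(m, E_a = E_a,
            class = c("unit_price_table", "matrix", "array"))
}

#' Map land-cover classes to ecosystem columns of a price table
#'
#' The factor table has one column per ecosystem; a landscape legend may
#' have more classes than ecosystems (e.g. construction land carries no
#' ecosystem value). The mapping is explicit configuration: every class
#' must either name an ecosystem column or be `NA` (zero-value).
#'
#' @param classes Character vector of land-cover class names.
#' @param ecosystems Character vector, same length: ecosystem column name
#'   for each class, or NA for a zero-value class.
#' @return A named character vector (class -> ecosystem, NA allowed).
#' @export
class_ecosystem_mapping <- function(classes, ecosystems) {
  if (length(classes) != length(ecosystems)) {
    stop("`classes` and `ecosystems` must have the same length", call. = FALSE)
  }
  stats::setNames(as.character(ecosystems), classes)
}

#' Default class-to-ecosystem mapping for the seven-class legend
#'
#' Cropland, forestland, grassland, wetland and waterbody map to the
#' like-named ecosystems, unused land to desert, and construction land to
#' zero value (its ecosystem function is considered lost).
#'
#' @return A mapping as returned by [class_ecosystem_mapping()].
#' @export
default_class_mapping <- function() {
  class_ecosystem_mapping(
    classes = c("cropland", "forestland", "grassland", "wetland",
                "waterbody", "construction", "unused"),
    ecosystems = c("cropland", "forest", "grassland", "wetland",
                   "waterbody", NA, "desert")
  )
}

# per-class total price Sum_i E_ij in Yuan/hm2/a, NA-mapped classes -> 0
class_unit_prices <- function(classes, prices, mapping) {
  unmapped <- setdiff(classes, names(mapping))
  if (length(unmapped) > 0) {
    stop("no ecosystem mapping for class(es): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  eco <- mapping[classes]
  out <- matrix(0, nrow = nrow(prices), ncol = length(classes),
                dimnames = list(rownames(prices), classes))
  has <- !is.na(eco)
  bad <- setdiff(eco[has], colnames(prices))
  if (length(bad) > 0) {
    stop("ecosystem column(s) absent from the price table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out[, has] <- unclass(prices)[, eco[has], drop = FALSE]
  out
}

#' Total, per-class, and per-service ecosystem service value
#'
#' `ESV = sum_j A_j * sum_i E_ij` with areas converted from km2 to hm2
#' (1 km2 = 100 hm2). Classes mapped to NA contribute zero. A class with
#' positive area but no entry in the mapping is an error.
#'
#' @param areas Data frame with columns `class` and `area_km2` (e.g. from
#'   [class_areas()]), or a [land_cover_grid()].
#' @param prices A [unit_price_table()].
#' @param mapping Class-to-ecosystem mapping (default
#'   [default_class_mapping()]).
#' @param year_label Optional label recorded in the result.
#' @return An `esv_result`: list with `total_yuan`, tibbles `by_class`
#'   (class, area_km2, esv_yuan) and `by_service` (service, esv_yuan), and
#'   `year_label`.
#' @export
esv_totals <- function(areas, prices, mapping = default_class_mapping(),
                       year_label = "") {
  if (inherits(areas, "land_cover_grid")) areas <- class_areas(areas)
  if (!all(c("class", "area_km2") %in% names(areas))) {
    stop("`areas` needs columns `class` and `area_km2`", call. = FALSE)
  }
  ep <- class_unit_prices(areas$class, prices, mapping) # service x class
  a_hm2 <- areas$area_km2 * 100
  per_class <- as.vector(colSums(ep) * a_hm2)
  per_service <- as.vector(ep %*% a_hm2)
  structure(list(
    total_yuan = sum(per_class),
    by_class = tibble::tibble(class = areas$class,
                              area_km2 = areas$area_km2,
                              esv_yuan = per_class),
    by_service = tibble::tibble(service = rownames(ep),
                                esv_yuan = per_service),
    year_label = year_label
  ), class = "esv_result")
}

#' @export
print.esv_result <- function(x, ...) {
  cat(sprintf("<esv_result>%s total %.2f x 1e9 Yuan\n",
              if (nzchar(x$year_label)) paste0(" ", x$year_label) else "",
              x$total_yuan / 1e9))
  print(dplyr::mutate(x$by_class, esv_1e9_yuan = .data$esv_yuan / 1e9))
  invisible(x)
}

#' Tidy an ESV result
#' @param x An `esv_result`.
#' @param ... Unused.
#' @return The per-class tibble with a `year` column.
#' @export
tidy.esv_result <- function(x, ...) {
  dplyr::mutate(x$by_class, year = x$year_label, .before = 1)
}

#' One-row summary of an ESV result
#' @param x An `esv_result`.
#' @param ... Unused.
#' @return A tibble with the total in Yuan and 1e9 Yuan.
#' @export
glance.esv_result <- function(x, ...) {
  tibble::tibble(year = x$year_label, total_yuan = x$total_yuan,
                 total_1e9_yuan = x$total_yuan / 1e9)
}

#' Zonal ecosystem service value
#'
#' Computes per-zone class areas from an aligned zone map and values them
#' with the same price table, adding ESV per unit zone area. Zone totals sum
#' to the regional total when the zones cover every non-nodata cell.
#'
#' @param grid A [land_cover_grid()].
#' @param zones A [zone_map()] aligned to `grid`.
#' @param prices A [unit_price_table()].
#' @param mapping Class-to-ecosystem mapping.
#' @param year_label Optional label.
#' @return A tibble with columns `zone`, `area_km2`, `esv_yuan`,
#'   `esv_yuan_per_km2`, `year`.
#' @export
esv_by_zone <- function(grid, zones, prices,
                        mapping = default_class_mapping(), year_label = "") {
  if (!identical(dim(grid$values), dim(zones$values))) {
    stop("zone map shape does not match the grid", call. = FALSE)
  }
  nd <- legend_nodata(grid$legend)
  keep <- grid$values != nd & !is.na(zones$values)
  ca <- cell_area_km2(grid)
  counts <- table(zone = zones$values[keep],
                  class = factor(grid$values[keep],
                                 levels = legend_codes(grid$legend),
                                 labels = legend_names(grid$legend)))
  ep_sum <- colSums(class_unit_prices(colnames(counts), prices, mapping))
  area_km2 <- unclass(counts) * ca
  esv <- as.vector(area_km2 %*% (ep_sum * 100)) # km2 -> hm2
  zone_area <- rowSums(area_km2)
  tibble::tibble(
    zone = as.integer(rownames(counts)),
    area_km2 = unname(zone_area),
    esv_yuan = esv,
    esv_yuan_per_km2 = ifelse(zone_area > 0, esv / zone_area, NA_real_),
    year = year_label
  )
}
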
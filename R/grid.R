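#' Categorical land-cover grid
#'
#' A `land_cover_grid` holds a rectangular integer matrix of class codes
#' (row-major, row 1 = top of the map), the side length of a square cell in
#' meters, a [class_legend()], and a free-text date label. All change and
#' valuation math is per-cell; georeferencing beyond the cell size is not
#' carried.
#'
#' @param values Integer matrix of class codes; nodata cells carry the
#'   legend's nodata code (NA values are converted to it).
#' @param legend A [class_legend()].
#' @param cell_size_m Cell side length in meters (> 0). A 30 m cell covers
#'   0.0009 km2.
#' @param date_label Optional text label, e.g. `"2000"`.
#'
#' @return An object of class `land_cover_grid`.
#' @examples
#' g <- land_cover_grid(matrix(3L, 10, 10), default_legend(), date_label = "t0")
#' n_cells(g)
#' @export
land_cover_grid <- function(values, legend, cell_size_m = 30, date_label = "") {
  stopifnot_legend(legend)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  storage.mode(values) <- "integer"
  nd <- legend_nodata(legend)
  values[is.na(values)] <- nd
  bad <- setdiff(unique(as.vector(values)), c(legend_codes(legend), nd))
  if (length(bad) > 0) {
    stop("grid contains codes not in the legend: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0) {
    stop("`cell_size_m` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, cell_size_m = as.numeric(cell_size_m),
         legend = legend, date_label = as.character(date_label)),
    class = "land_cover_grid"
  )
}

#' @export
print.land_cover_grid <- function(x, ...) {
  v <- x$values
  nd <- legend_nodata(x$legend)
  cat(sprintf("<land_cover_grid> %d x %d cells, %.0f m cells%s\n",
              nrow(v), ncol(v), x$cell_size_m,
              if (nzchar(x$date_label)) paste0(", date ", x$date_label) else ""))
  tab <- table(factor(v[v != nd], levels = legend_codes(x$legend),
                      labels = legend_names(x$legend)))
  print(tab)
  invisible(x)
}

#' @export
dim.land_cover_grid <- function(x) dim(x$values)

#' Number of analysed (non-nodata) cells in a grid
#' @param grid A [land_cover_grid()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  sum(grid$values != legend_nodata(grid$legend))
}

#' Area of one cell in km2
#' @param grid A [land_cover_grid()].
#' @return Cell area in km2 (cell_size_m^2 / 1e6).
#' @export
cell_area_km2 <- function(grid) grid$cell_size_m^2 / 1e6

#' Per-class areas of a grid
#'
#' @param grid A [land_cover_grid()].
#' @return A tibble with columns `code`, `class`, `cells`, `area_km2`;
#'   one row per legend class (zero rows included).
#' @export
class_areas <- function(grid) {
  nd <- legend_nodata(grid$legend)
  v <- grid$values[grid$values != nd]
  counts <- tabulate(match(v, legend_codes(grid$legend)),
                     nbins = nrow(grid$legend))
  tibble::tibble(
    code = legend_codes(grid$legend),
    class = legend_names(grid$legend),
    cells = counts,
    area_km2 = counts * cell_area_km2(grid)
  )
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("grids have different shapes", call. = FALSE)
  }
  if (!identical(legend_codes(a$legend), legend_codes(b$legend))) {
    stop("grids have different legends", call. = FALSE)
  }
  if (a$cell_size_m != b$cell_size_m) {
    stop("grids have different cell sizes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Zone map aligned to a land-cover grid
#'
#' Zones are administrative units (townships in the motivating application)
#' used for zonal ESV and sensitivity aggregation. Zone ids are non-negative
#' integers; cells with NA are outside every zone.
#'
#' @param values Integer matrix of zone ids, same shape as the grids it will
#'   be used with; NA marks cells outside all zones.
#' @param zone_names Optional named character vector mapping id to name.
#' @return An object of class `zone_map`.
#' @export
zone_map <- function(values, zone_names = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  storage.mode(values) <- "integer"
  ids <- sort(unique(as.vector(values[!is.na(values)])))
  if (length(ids) > 0 && any(ids < 0L)) {
    stop("zone ids must be >= 0", call. = FALSE)
  }
  if (is.null(zone_names)) {
    zone_names <- stats::setNames(paste0("zone_", ids), ids)
  }
  structure(list(values = values, zone_ids = ids, zone_names = zone_names),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d x %d cells, %d zones\n",
              nrow(x$values), ncol(x$values), length(x$zone_ids)))
  invisible(x)
}
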
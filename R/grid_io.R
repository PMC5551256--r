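#' Read a categorical land-cover raster from an ESRI ASCII grid
#'
#' Reads a single-band integer raster in ESRI ASCII grid (.asc) format and
#' validates every value against the legend. The cell size is taken from the
#' `cellsize` header and interpreted as meters; when the header is missing a
#' 30 m cell is assumed.
#'
#' @param path Path to an .asc file.
#' @param legend A [class_legend()]; codes in the file outside the legend
#'   (other than the file's own nodata value) raise an error naming them.
#' @param date_label Optional date label for the returned grid.
#' @return A [land_cover_grid()].
#' @export
read_landcover_asc <- function(path, legend, date_label = "") {
  stopifnot_legend(legend)
  parsed <- parse_asc(path)
  v <- parsed$values
  v[v == parsed$nodata] <- NA_integer_
  land_cover_grid(v, legend, cell_size_m = parsed$cellsize,
                  date_label = date_label)
}

#' Write a land-cover grid as an ESRI ASCII grid
#'
#' Round-trips bit-exactly with [read_landcover_asc()]: values, the nodata
#' mask and the cell size are preserved.
#'
#' @param grid A [land_cover_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landcover_asc <- function(grid, path) {
  write_asc(grid$values, path, cellsize = grid$cell_size_m,
            nodata = legend_nodata(grid$legend))
  invisible(path)
}

#' Read a zone raster from an ESRI ASCII grid
#'
#' @param path Path to an .asc file of integer zone ids.
#' @return A [zone_map()]; file nodata becomes NA (outside all zones).
#' @export
read_zones_asc <- function(path) {
  parsed <- parse_asc(path)
  v <- parsed$values
  v[v == parsed$nodata] <- NA_integer_
  zone_map(v)
}

#' Write a zone map as an ESRI ASCII grid
#' @param zones A [zone_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones_asc <- function(zones, path) {
  v <- zones$values
  v[is.na(v)] <- -9999L
  write_asc(v, path, cellsize = 30, nodata = -9999L)
  invisible(path)
}

# ESRI ASCII grid: six-line header then rows top-to-bottom.
parse_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows)) {
    stop("not an ESRI ASCII grid (missing ncols/nrows header): ", path,
         call. = FALSE)
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  cs <- if (is.null(hdr$cellsize)) 30 else hdr$cellsize
  nodata <- if (is.null(hdr$nodata_value)) -9999L else as.integer(hdr$nodata_value)
  vals <- scan(path, what = integer(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals),
                 path), call. = FALSE)
  }
  # file order is row-major from the top row; R fills column-major
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(values = values, cellsize = cs, nodata = nodata)
}

write_asc <- function(values, path, cellsize, nodata) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(values, con, row.names = FALSE, col.names = FALSE)
}

#' Read a crop-economics table
#'
#' Expects a CSV with columns `crop`, `sowing_area_hm2`, `price_yuan_per_t`,
#' `yield_t_t_per_hm2` or `yield_t_per_hm2`. Negative areas, prices or yields
#' are validation errors. The total sowing area M is the column sum.
#'
#' @param path Path to the crops CSV.
#' @return A `crop_economics` tibble with attribute `M` (total sowing area,
#'   hm2).
#' @export
read_crops_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  crop_economics(df)
}

#' Construct a validated crop-economics table
#'
#' @param df Data frame with columns `crop`, `sowing_area_hm2`,
#'   `price_yuan_per_t`, `yield_t_per_hm2`.
#' @return A `crop_economics` tibble; attribute `M` holds total sowing area.
#' @export
crop_economics <- function(df) {
  need <- c("crop", "sowing_area_hm2", "price_yuan_per_t", "yield_t_per_hm2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("crops table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[need])
  num <- df[-1]
  if (any(vapply(num, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    stop("sowing area, price and yield must all be >= 0", call. = FALSE)
  }
  M <- sum(df$sowing_area_hm2)
  if (!is.finite(M) || M <= 0) {
    stop("total sowing area M must be positive", call. = FALSE)
  }
  structure(df, M = M, class = c("crop_economics", class(df)))
}

#' The nine ecosystem-service names, in canonical order
#' @return Character vector of length 9.
#' @export
service_names <- function() {
  c("food production", "raw material production", "gas regulation",
    "climate regulation", "hydrology regulation", "waste treatment",
    "soil conservation", "biodiversity maintenance",
    "aesthetic landscape provision")
}

#' Read an equivalent-factor table
#'
#' The equivalent-factor (benefit-transfer) method expresses each service of
#' each ecosystem as a unitless multiple e_ij of the value of cropland food
#' production. The CSV has a `service` column holding the nine canonical
#' service names (see [service_names()]) and one column per ecosystem class.
#' A missing service row is an error naming the service.
#'
#' @param path Path to the factors CSV.
#' @return An `equivalent_factor_table`: a 9 x n_ecosystem numeric matrix
#'   with service rownames.
#' @export
read_factors_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  equivalent_factor_table(df)
}

#' Construct a validated equivalent-factor table
#'
#' @param df Data frame with a `service` column (the nine canonical names)
#'   and one numeric column per ecosystem.
#' @return An `equivalent_factor_table` matrix (9 services x ecosystems).
#' @export
equivalent_factor_table <- function(df) {
  if (!"service" %in% names(df)) {
    stop("factor table needs a `service` column", call. = FALSE)
  }
  want <- service_names()
  miss <- setdiff(want, df$service)
  if (length(miss) > 0) {
    stop("factor table missing service rows: ",
         paste(miss, collapse = "; "), call. = FALSE)
  }
  df <- df[match(want, df$service), ]
  m <- as.matrix(df[setdiff(names(df), "service")])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    stop("equivalent factors must be >= 0", call. = FALSE)
  }
  rownames(m) <- want
  structure(m, class = c("equivalent_factor_table", "matrix", "array"))
}

#' Load crop-economics and equivalent-factor tables together
#'
#' @param crops_path Path to the crops CSV (see [read_crops_csv()]).
#' @param factors_path Path to the factors CSV (see [read_factors_csv()]).
#' @return A list with elements `crops` and `factors`.
#' @export
load_tables <- function(crops_path, factors_path) {
  list(crops = read_crops_csv(crops_path),
       factors = read_factors_csv(factors_path))
}
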
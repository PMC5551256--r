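#' Class legend for categorical land-cover rasters
#'
#' A legend maps small integer raster codes to land-cover class names and
#' declares which code marks nodata. Every grid operation in the package
#' validates its input against a legend, so an unexpected code is always an
#' error rather than a silent remap.
#'
#' @param codes Integer vector of class codes (unique, non-negative).
#' @param names Character vector of class names, same length as `codes`.
#' @param nodata_code Integer nodata marker; must not collide with `codes`.
#'
#' @return An object of class `class_legend`: a tibble with columns `code`
#'   and `name`, plus a `nodata_code` attribute.
#' @examples
#' class_legend(1:3, c("cropland", "grassland", "waterbody"))
#' @export
class_legend <- function(codes, names, nodata_code = -9999L) {
  codes <- as.integer(codes)
  if (anyNA(codes) || any(codes < 0L)) {
    stop("legend codes must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(codes)) stop("legend codes must be unique", call. = FALSE)
  if (anyDuplicated(names)) stop("legend names must be unique", call. = FALSE)
  if (length(codes) != length(names)) {
    stop("`codes` and `names` must have the same length", call. = FALSE)
  }
  nodata_code <- as.integer(nodata_code)
  if (nodata_code %in% codes) {
    stop("`nodata_code` must not be one of the class codes", call. = FALSE)
  }
  out <- tibble::tibble(code = codes, name = as.character(names))
  structure(out, nodata_code = nodata_code,
            class = c("class_legend", class(out)))
}

#' Default seven-class land-cover legend
#'
#' The class set used throughout the examples: cropland, forestland,
#' grassland, wetland, waterbody, construction land, and unused land, coded
#' 1 through 7.
#'
#' @param nodata_code Integer nodata marker (default -9999).
#' @return A [class_legend()].
#' @export
default_legend <- function(nodata_code = -9999L) {
  class_legend(
    codes = 1:7,
    names = c("cropland", "forestland", "grassland", "wetland",
              "waterbody", "construction", "unused"),
    nodata_code = nodata_code
  )
}

legend_codes <- function(legend) legend$code
legend_names <- function(legend) legend$name
legend_nodata <- function(legend) attr(legend, "nodata_code")

stopifnot_legend <- function(legend) {
  if (!inherits(legend, "class_legend")) {
    stop("expected a `class_legend` object", call. = FALSE)
  }
  invisible(legend)
}
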
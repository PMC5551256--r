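#' Cross-tabulate two land-cover grids into a transition matrix
#'
#' Entry (i, j) is the area in km2 that was class i at the first date and
#' class j at the second. Cells that are nodata in either grid are excluded
#' from both, so row totals equal per-class areas at t1 and column totals
#' equal per-class areas at t2 on the analysed cells.
#'
#' @param grid_t1,grid_t2 Aligned [land_cover_grid()]s (same shape, legend,
#'   cell size).
#' @param period_years Length of the period in years (> 0).
#' @return A `transition_matrix`: a list with `areas` (n_class x n_class km2
#'   matrix with class-name dimnames), `period_years`, and `legend`.
#' @examples
#' leg <- default_legend()
#' a <- land_cover_grid(matrix(c(1L, 2L, 1L, 2L), 2), leg)
#' crosstab(a, a, period_years = 10)
#' @export
crosstab <- function(grid_t1, grid_t2, period_years) {
  check_aligned(grid_t1, grid_t2)
  if (period_years <= 0) stop("`period_years` must be > 0", call. = FALSE)
  nd <- legend_nodata(grid_t1$legend)
  keep <- grid_t1$values != nd & grid_t2$values != nd
  if (!any(keep)) stop("no overlapping non-nodata cells", call. = FALSE)
  nm <- legend_names(grid_t1$legend)
  f1 <- factor(grid_t1$values[keep], levels = legend_codes(grid_t1$legend),
               labels = nm)
  f2 <- factor(grid_t2$values[keep], levels = legend_codes(grid_t2$legend),
               labels = nm)
  counts <- table(f1, f2)
  areas <- unclass(counts) * cell_area_km2(grid_t1)
  dimnames(areas) <- list(from = nm, to = nm)
  transition_matrix(areas, period_years, legend = grid_t1$legend)
}

#' Construct a transition matrix from an area table
#'
#' Use this to enter a published class-by-class converted-area table
#' directly (e.g. from a regional change study) without the underlying
#' rasters.
#'
#' @param areas Square numeric matrix of converted areas in km2, rows =
#'   origin classes, columns = destination classes, with class-name
#'   dimnames.
#' @param period_years Period length in years.
#' @param legend Optional [class_legend()] consistent with the dimnames.
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(areas, period_years, legend = NULL) {
  if (!is.matrix(areas) || nrow(areas) != ncol(areas)) {
    stop("`areas` must be a square matrix", call. = FALSE)
  }
  if (any(areas < 0)) stop("converted areas must be >= 0", call. = FALSE)
  if (period_years <= 0) stop("`period_years` must be > 0", call. = FALSE)
  if (is.null(dimnames(areas))) {
    nm <- paste0("class_", seq_len(nrow(areas)))
    dimnames(areas) <- list(from = nm, to = nm)
  }
  structure(list(areas = areas, period_years = as.numeric(period_years),
                 legend = legend),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes over %g years, total %.2f km2\n",
              nrow(x$areas), x$period_years, sum(x$areas)))
  print(round(x$areas, 2))
  invisible(x)
}

#' Tidy a transition matrix into long form
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `area_km2`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  m <- x$areas
  tibble::tibble(
    from = rep(rownames(m), times = ncol(m)),
    to = rep(colnames(m), each = nrow(m)),
    area_km2 = as.vector(m)
  )
}

#' One-row summary of a transition matrix
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with total area, changed (off-diagonal) area, the
#'   changed fraction, period length, and the comprehensive dynamic degree.
#' @export
glance.transition_matrix <- function(x, ...) {
  total <- sum(x$areas)
  changed <- total - sum(diag(x$areas))
  tibble::tibble(
    total_area_km2 = total,
    changed_area_km2 = changed,
    changed_fraction = changed / total,
    period_years = x$period_years,
    cludd_pct_per_year = cludd(x)
  )
}

#' Single land-use dynamic degree (annual percent change of one class)
#'
#' `K = (U_b - U_a) / U_a * (1 / T) * 100`, the annualized percent change
#' rate of one class's area over a period of `T` years. Positive K means the
#' class expanded.
#'
#' @param area_start Class area at the period start (U_a, km2; must be > 0 —
#'   a class absent at the start has an undefined rate).
#' @param area_end Class area at the period end (U_b, km2).
#' @param period_years Period length T in years.
#' @return K in percent per year (full precision; round for reporting).
#' @examples
#' sludd(685.52, 913.00, 10) # 3.32 %/yr
#' @export
sludd <- function(area_start, area_end, period_years) {
  if (any(period_years <= 0)) stop("`period_years` must be > 0", call. = FALSE)
  if (any(area_start <= 0)) {
    stop("`area_start` must be > 0; a class absent at the period start has ",
         "an undefined dynamic degree", call. = FALSE)
  }
  (area_end - area_start) / area_start / period_years * 100
}

#' Per-class dynamic degrees of a transition matrix
#'
#' Computes each class's single land-use dynamic degree from the matrix
#' marginals (row totals = start areas, column totals = end areas). Classes
#' absent at the start get NA with a `defined` flag of FALSE rather than an
#' infinite rate.
#'
#' @param tm A `transition_matrix`.
#' @return A tibble with columns `class`, `area_start_km2`, `area_end_km2`,
#'   `net_change_km2`, `sludd_pct_per_year`, `defined`.
#' @export
dynamic_degrees <- function(tm) {
  ua <- rowSums(tm$areas)
  ub <- colSums(tm$areas)
  defined <- ua > 0
  k <- rep(NA_real_, length(ua))
  k[defined] <- sludd(ua[defined], ub[defined], tm$period_years)
  tibble::tibble(
    class = rownames(tm$areas),
    area_start_km2 = unname(ua),
    area_end_km2 = unname(ub),
    net_change_km2 = unname(ub - ua),
    sludd_pct_per_year = unname(k),
    defined = unname(defined)
  )
}

#' Comprehensive land-use dynamic degree (annual percent of area changed)
#'
#' `R = (sum of off-diagonal converted areas) / (total area at period start)
#' * (1 / T) * 100`: the annualized percentage of the landscape that changed
#' class. R is 0 exactly when no cell changed.
#'
#' @param tm A `transition_matrix`.
#' @return R in percent per year (full precision).
#' @export
cludd <- function(tm) {
  total <- sum(tm$areas)
  if (total <= 0) stop("transition matrix has zero total area", call. = FALSE)
  changed <- total - sum(diag(tm$areas))
  changed / total / tm$period_years * 100
}

#' Cohen's kappa agreement between two categorical maps
#'
#' Chance-corrected cell-wise agreement on the jointly non-nodata cells:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement p_o and the
#' marginal-product expected agreement p_e. kappa is 1 exactly when the maps
#' are identical on the analysed cells.
#'
#' @param grid_a,grid_b Aligned [land_cover_grid()]s.
#' @return A tibble with one row: `p_observed`, `p_expected`, `kappa`,
#'   `n_cells`.
#' @export
cohen_kappa <- function(grid_a, grid_b) {
  check_aligned(grid_a, grid_b)
  nd <- legend_nodata(grid_a$legend)
  keep <- grid_a$values != nd & grid_b$values != nd
  if (!any(keep)) stop("no overlapping non-nodata cells", call. = FALSE)
  lv <- legend_codes(grid_a$legend)
  conf <- table(factor(grid_a$values[keep], levels = lv),
                factor(grid_b$values[keep], levels = lv))
  kappa_from_confusion(unclass(conf))
}

#' Cohen's kappa from a confusion-count matrix
#'
#' @param counts Square matrix of agreement counts (rows = map a, columns =
#'   map b).
#' @return A tibble with `p_observed`, `p_expected`, `kappa`, `n_cells`.
#' @examples
#' kappa_from_confusion(matrix(c(45, 5, 5, 45), 2)) # kappa 0.80
#' @export
kappa_from_confusion <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(counts)) / n
  p_e <- sum(rowSums(counts) * colSums(counts)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  tibble::tibble(p_observed = p_o, p_expected = p_e, kappa = kappa,
                 n_cells = as.integer(n))
}
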
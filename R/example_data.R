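#' Published Qinghai Lake region case-study tables
#'
#' The package ships, as plain CSV under `inst/extdata`, three small tables
#' from a published Landsat-based change study of the Qinghai Lake region
#' (Tibetan Plateau, 38 townships, ~55,836 km2): the 1990-2000 land-use
#' transition matrix in km2, per-class ecosystem service values for
#' 1990-2020 in 1e9 Yuan, and the grouped township areas behind the
#' sensitivity-change summary. They make worked examples and regression
#' checks possible without the (undeposited) rasters. An illustrative
#' equivalent-factor template (`equivalent_factors_template.csv`, synthetic
#' values with the canonical 9-service x 6-ecosystem structure) and an
#' example crops table are shipped alongside.
#'
#' @return `qinghai_transition_1990_2000()`: a [transition_matrix()] with
#'   `period_years = 10`. `qinghai_esv_by_class()`: a tibble (year x class,
#'   1e9 Yuan). `qinghai_si_change_groups()`: a tibble of grouped township
#'   counts and areas (1e4 km2).
#' @name qinghai_case_study
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "luccesv")
  if (!nzchar(path)) { # running from a source tree
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' @rdname qinghai_case_study
#' @export
qinghai_transition_1990_2000 <- function() {
  df <- readr::read_csv(extdata("qinghai_transition_1990_2000.csv"),
                        show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$from
  dimnames(m) <- list(from = df$from, to = colnames(m))
  transition_matrix(m, period_years = 10)
}

#' @rdname qinghai_case_study
#' @details `qinghai_marginals_1990_2000()` returns the transition table's
#'   published per-class area totals for 1990 and 2000. They differ from
#'   the cell sums of the converted-area matrix by up to 0.02 km2 because
#'   the published matrix cells are themselves rounded; change rates quoted
#'   against the published totals should be computed from these marginals.
#' @export
qinghai_marginals_1990_2000 <- function() {
  readr::read_csv(extdata("qinghai_marginals_1990_2000.csv"),
                  show_col_types = FALSE)
}

#' @rdname qinghai_case_study
#' @export
qinghai_esv_by_class <- function() {
  readr::read_csv(extdata("qinghai_esv_by_class.csv"),
                  show_col_types = FALSE)
}

#' @rdname qinghai_case_study
#' @export
qinghai_si_change_groups <- function() {
  readr::read_csv(extdata("qinghai_si_change_groups.csv"),
                  show_col_types = FALSE)
}
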
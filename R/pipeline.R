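#' Run the full change-valuation-sensitivity workflow from one config
#'
#' Orchestrates the whole study shape: for each consecutive pair of observed
#' dates it cross-tabulates a transition matrix and dynamic degrees; it
#' calibrates a Markov model on the most recent observed pair and simulates
#' one further period with the CA allocator; it values every date (observed
#' and simulated) with the equivalent-factor method; it computes per-zone
#' sensitivity indices for every period and classifies SI change between
#' consecutive periods. All tabular artifacts are written as CSV, rasters as
#' ESRI ASCII grids, and a machine-readable JSON report ties them together.
#' The run is deterministic given the seed recorded in the config.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{rasters}{named list date_label -> .asc path (>= 2 dates, in
#'       chronological order); date labels must be numeric years.}
#'     \item{legend}{optional; defaults to [default_legend()].}
#'     \item{zones}{path to a zone .asc (optional; zonal stages skipped
#'       without it).}
#'     \item{crops}{named list date_label -> crops CSV path, or one path
#'       used for all dates.}
#'     \item{factors}{path to the equivalent-factor CSV.}
#'     \item{mapping}{optional data frame/list with `class` and `ecosystem`
#'       columns; defaults to [default_class_mapping()].}
#'     \item{ca}{list with `seed` (default 1), `epsilon` (0.1),
#'       `area_tolerance` (0.005), `horizon_years` (defaults to the last
#'       observed period length).}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @return A `run_report` list: config echo, file inventory, and headline
#'   numbers (CLUDD per period, ESV totals per date, SI change summaries),
#'   also written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  legend <- cfg$legend
  dates <- names(cfg$rasters)
  yrs <- as.numeric(dates)

  message("stage: load rasters")
  grids <- lapply(dates, function(d) {
    read_landcover_asc(cfg$rasters[[d]], legend, date_label = d)
  })
  names(grids) <- dates
  zones <- if (!is.null(cfg$zones)) read_zones_asc(cfg$zones) else NULL

  message("stage: change metrics")
  outputs <- character(0)
  metrics <- list()
  for (i in seq_len(length(dates) - 1)) {
    lab <- paste0(dates[i], "_", dates[i + 1])
    tm <- crosstab(grids[[i]], grids[[i + 1]], yrs[i + 1] - yrs[i])
    dd <- dynamic_degrees(tm)
    p_tm <- file.path(cfg$out_dir, paste0("transition_", lab, ".csv"))
    p_dd <- file.path(cfg$out_dir, paste0("dynamic_degrees_", lab, ".csv"))
    readr::write_csv(tidy(tm), p_tm)
    readr::write_csv(dd, p_dd)
    outputs <- c(outputs, p_tm, p_dd)
    metrics[[lab]] <- list(tm = tm, cludd = cludd(tm), dd = dd)
  }

  message("stage: Markov-CA simulation")
  n <- length(dates)
  calib <- metrics[[length(metrics)]]$tm
  model <- estimate_transition_probs(calib)
  horizon <- cfg$ca$horizon_years %||% calib$period_years
  sim <- ca_simulate(grids[[n]], model, iterations = max(1L, round(horizon)),
                     seed = cfg$ca$seed, epsilon = cfg$ca$epsilon,
                     area_tolerance = cfg$ca$area_tolerance)
  sim_label <- as.character(yrs[n] + horizon)
  sim$date_label <- sim_label
  p_sim <- file.path(cfg$out_dir, paste0("simulated_", sim_label, ".asc"))
  write_landcover_asc(sim, p_sim)
  outputs <- c(outputs, p_sim)
  all_grids <- c(grids, stats::setNames(list(sim), sim_label))
  all_dates <- c(dates, sim_label)
  all_yrs <- c(yrs, yrs[n] + horizon)

  message("stage: valuation")
  prices_by_date <- lapply(all_dates, function(d) {
    crops_path <- if (is.list(cfg$crops)) {
      cfg$crops[[d]] %||% cfg$crops[[length(cfg$crops)]]
    } else cfg$crops
    crops <- read_crops_csv(crops_path)
    unit_price_table(food_production_unit_value(crops), cfg$factors)
  })
  names(prices_by_date) <- all_dates
  esv_list <- lapply(all_dates, function(d) {
    esv_totals(all_grids[[d]], prices_by_date[[d]], mapping = cfg$mapping,
               year_label = d)
  })
  names(esv_list) <- all_dates
  esv_tbl <- dplyr::bind_rows(lapply(esv_list, tidy))
  p_esv <- file.path(cfg$out_dir, "esv_by_class.csv")
  readr::write_csv(esv_tbl, p_esv)
  p_svc <- file.path(cfg$out_dir, "esv_by_service.csv")
  readr::write_csv(dplyr::bind_rows(lapply(all_dates, function(d) {
    dplyr::mutate(esv_list[[d]]$by_service, year = d, .before = 1)
  })), p_svc)
  outputs <- c(outputs, p_esv, p_svc)

  si_tables <- list()
  summaries <- list()
  if (!is.null(zones)) {
    message("stage: zonal sensitivity")
    for (i in seq_len(length(all_dates) - 1)) {
      lab <- paste0(all_dates[i], "_", all_dates[i + 1])
      si <- si_by_zone(all_grids[[i]], all_grids[[i + 1]], zones,
                       prices_by_date[[i + 1]], t1 = all_yrs[i],
                       t2 = all_yrs[i + 1], mapping = cfg$mapping)
      p_si <- file.path(cfg$out_dir, paste0("si_", lab, ".csv"))
      readr::write_csv(si, p_si)
      outputs <- c(outputs, p_si)
      si_tables[[lab]] <- si
    }
    if (length(si_tables) >= 2) {
      labs <- names(si_tables)
      for (i in seq_len(length(labs) - 1)) {
        cmp <- paste0(labs[i], "_vs_", labs[i + 1])
        sm <- classify_si_change(si_tables[[labs[i]]],
                                 si_tables[[labs[i + 1]]])
        p_sm <- file.path(cfg$out_dir, paste0("si_change_", cmp, ".csv"))
        readr::write_csv(sm, p_sm)
        outputs <- c(outputs, p_sm)
        summaries[[cmp]] <- sm
      }
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("luccesv")),
    seed = cfg$ca$seed,
    dates = all_dates,
    outputs = outputs,
    cludd_pct_per_year = lapply(metrics, function(m) m$cludd),
    esv_total_1e9_yuan = lapply(esv_list, function(e) e$total_yuan / 1e9),
    si_zones = lapply(si_tables, function(s) {
      stats::setNames(s$si, s$zone)
    }),
    si_change = lapply(summaries, function(s) {
      as.list(stats::setNames(s$area_share_pct, s$change))
    })
  )
  p_rep <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, p_rep, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$outputs <- c(report$outputs, p_rep)
  structure(report, class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  if (is.null(config$rasters) || length(config$rasters) < 2) {
    stop("config needs at least two dated rasters", call. = FALSE)
  }
  if (is.null(names(config$rasters)) || any(!nzchar(names(config$rasters)))) {
    stop("`rasters` must be a named list (date label -> path)", call. = FALSE)
  }
  if (anyNA(suppressWarnings(as.numeric(names(config$rasters))))) {
    stop("raster date labels must be numeric years", call. = FALSE)
  }
  if (is.null(config$crops)) stop("config needs `crops`", call. = FALSE)
  if (is.null(config$factors)) stop("config needs `factors`", call. = FALSE)
  legend <- config$legend %||% default_legend()
  factors <- if (is.character(config$factors)) {
    read_factors_csv(config$factors)
  } else config$factors
  mapping <- config$mapping %||% default_class_mapping()
  if (is.data.frame(mapping) || is.list(mapping) && !is.null(mapping$class)) {
    mapping <- class_ecosystem_mapping(mapping$class, mapping$ecosystem)
  }
  ca <- config$ca %||% list()
  list(
    rasters = config$rasters,
    legend = legend,
    zones = config$zones,
    crops = config$crops,
    factors = factors,
    mapping = mapping,
    ca = list(seed = ca$seed %||% 1L, epsilon = ca$epsilon %||% 0.1,
              area_tolerance = ca$area_tolerance %||% 0.005,
              horizon_years = ca$horizon_years),
    out_dir = config$out_dir %||% tempfile("luccesv_run_")
  )
}
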
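#' Generate a synthetic patchy categorical landscape
#'
#' Builds a neutral landscape by seeded multi-source region growing: roughly
#' `n_cells / patchiness` seed cells are planted at random, each seed is
#' assigned a class so that seed counts match `class_weights` exactly
#' (largest-remainder allocation), and unlabeled cells repeatedly adopt the
#' label of a random labeled 4-neighbor until the grid is full. The result
#' has contiguous patches with mean size close to `patchiness` and expected
#' class proportions equal to `class_weights`.
#'
#' @param nrow,ncol Grid dimensions.
#' @param class_weights Probability vector over legend codes (sums to 1
#'   within 1e-9).
#' @param patchiness Mean patch size in cells (>= 1); 1 gives i.i.d. noise.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @param legend A [class_legend()] (default [default_legend()]).
#' @param cell_size_m Cell side in meters (default 30).
#' @param date_label Date label for the returned grid.
#' @return A [land_cover_grid()].
#' @examples
#' g <- generate_landscape(64, 64, rep(1 / 7, 7), patchiness = 20, seed = 1)
#' class_areas(g)
#' @export
generate_landscape <- function(nrow, ncol, class_weights, patchiness = 25,
                               seed = 1L, legend = default_legend(),
                               cell_size_m = 30, date_label = "") {
  stopifnot_legend(legend)
  codes <- legend_codes(legend)
  if (length(class_weights) != length(codes)) {
    stop("`class_weights` length must match the legend", call. = FALSE)
  }
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stop("`class_weights` must sum to 1", call. = FALSE)
  }
  if (patchiness < 1) stop("`patchiness` must be >= 1", call. = FALSE)
  n <- nrow * ncol
  n_seeds <- max(length(codes), min(n, round(n / patchiness)))
  withr_seed(seed, {
    lab <- grow_labels(nrow, ncol, n_seeds)
    seed_counts <- largest_remainder(class_weights * n_seeds)
    seed_class <- sample(rep(codes, seed_counts))
    v <- matrix(seed_class[lab], nrow, ncol)
  })
  land_cover_grid(v, legend, cell_size_m = cell_size_m,
                  date_label = date_label)
}

#' Evolve a landscape one period under a known Markov kernel
#'
#' Each cell's new class is drawn from the kernel row of its current class,
#' with probability mass re-weighted toward classes present in the cell's
#' radius-2 von Neumann neighborhood: the row entry for class j is scaled by
#' `(1 + clustering_strength * f_j)` where f_j is the neighbor fraction of
#' class j, then renormalized. With `clustering_strength = 0` this is exact
#' independent sampling from the kernel, which is what makes the generating
#' kernel recoverable by cross-tabulation.
#'
#' @param grid A [land_cover_grid()].
#' @param kernel Row-stochastic matrix, one row/column per legend class.
#' @param clustering_strength Number in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [land_cover_grid()] with the same legend and cell size.
#' @export
evolve_landscape <- function(grid, kernel, clustering_strength = 0, seed = 1L) {
  codes <- legend_codes(grid$legend)
  check_kernel(kernel, length(codes))
  nd <- legend_nodata(grid$legend)
  v <- grid$values
  live <- which(v != nd)
  cls_idx <- match(v[live], codes)
  w <- kernel[cls_idx, , drop = FALSE]
  if (clustering_strength > 0) {
    nf <- neighbor_fractions(v, codes, nd)
    fmat <- vapply(nf$frac, function(m) m[live], numeric(length(live)))
    w <- w * (1 + clustering_strength * fmat)
    w <- w / rowSums(w)
  }
  ncls <- length(codes)
  up <- matrix(0, ncls, ncls)
  up[upper.tri(up, diag = TRUE)] <- 1
  cw <- w %*% up # row-wise cumulative sums
  withr_seed(seed, {
    u <- stats::runif(length(live))
  })
  pick <- 1L + as.integer(rowSums(cw < u))
  pick[pick > ncls] <- ncls
  out <- v
  out[live] <- codes[pick]
  land_cover_grid(out, grid$legend, cell_size_m = grid$cell_size_m,
                  date_label = paste0(grid$date_label, "+1"))
}

#' Generate a contiguous zone partition
#'
#' Plants `n_zones` distinct seed cells and grows them simultaneously
#' (random-neighbor dilation), yielding a Voronoi-like partition of
#' contiguous, non-empty zones covering every cell.
#'
#' @param nrow,ncol Grid dimensions.
#' @param n_zones Number of zones (1 <= n_zones <= nrow * ncol).
#' @param seed Integer seed.
#' @return A [zone_map()] with zone ids `1:n_zones`.
#' @export
generate_zones <- function(nrow, ncol, n_zones, seed = 1L) {
  if (n_zones < 1) stop("`n_zones` must be >= 1", call. = FALSE)
  if (n_zones > nrow * ncol) {
    stop("`n_zones` exceeds the number of cells", call. = FALSE)
  }
  withr_seed(seed, {
    lab <- grow_labels(nrow, ncol, n_zones)
  })
  zone_map(matrix(lab, nrow, ncol))
}

#' Generate a plausible crop-economics fixture
#'
#' Three grain crops (wheat, coarse cereal, tuber) with sowing areas,
#' prices and yields in the range typical of high-altitude rain-fed
#' agriculture; used to exercise the valuation stage without yearbook data.
#'
#' @param seed Integer seed.
#' @return A `crop_economics` tibble (see [crop_economics()]).
#' @export
generate_crop_economics <- function(seed = 1L) {
  withr_seed(seed, {
    df <- tibble::tibble(
      crop = c("wheat", "coarse cereal", "tuber"),
      sowing_area_hm2 = round(stats::runif(3, 5000, 40000)),
      price_yuan_per_t = round(stats::runif(3, 1200, 2600)),
      yield_t_per_hm2 = round(stats::runif(3, 1.5, 4.5), 2)
    )
  })
  crop_economics(df)
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# multi-source region growing: seeds labeled 1..n_seeds, unlabeled cells
# adopt the label of a random labeled 4-neighbor, sweep until full.
# Caller owns the RNG state.
grow_labels <- function(nr, nc, n_seeds) {
  lab <- matrix(0L, nr, nc)
  lab[sample.int(nr * nc, n_seeds)] <- seq_len(n_seeds)
  off <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  while (any(lab == 0L)) {
    best_lab <- matrix(0L, nr, nc)
    best_scr <- matrix(-1, nr, nc)
    for (k in 1:4) {
      cand <- shift_mat(lab, off[k, 1], off[k, 2], fill = 0L)
      scr <- matrix(stats::runif(nr * nc), nr, nc)
      scr[cand == 0L] <- -1
      take <- scr > best_scr
      best_lab[take] <- cand[take]
      best_scr[take] <- scr[take]
    }
    fill <- lab == 0L & best_lab > 0L
    lab[fill] <- best_lab[fill]
  }
  lab
}

check_kernel <- function(kernel, n_class) {
  if (!is.matrix(kernel) || nrow(kernel) != n_class ||
      ncol(kernel) != n_class) {
    stop("kernel must be a ", n_class, " x ", n_class, " matrix",
         call. = FALSE)
  }
  if (any(kernel < 0)) stop("kernel entries must be >= 0", call. = FALSE)
  if (any(abs(rowSums(kernel) - 1) > 1e-9)) {
    stop("kernel rows must each sum to 1", call. = FALSE)
  }
  invisible(kernel)
}
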
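#' Estimate Markov transition probabilities from a transition matrix
#'
#' `P[i, j] = area(i -> j) / area(i at t1)`, the conditional probability of
#' a cell of class i at the period start being class j at the period end.
#' Rows for classes absent at the start become identity rows so P remains
#' row-stochastic.
#'
#' @param tm A [transition_matrix()].
#' @return A `markov_model`: list with row-stochastic matrix `P`, the class
#'   names, and `period_years`.
#' @export
estimate_transition_probs <- function(tm) {
  a <- tm$areas
  rs <- rowSums(a)
  P <- a
  nonzero <- rs > 0
  P[nonzero, ] <- a[nonzero, , drop = FALSE] / rs[nonzero]
  if (any(!nonzero)) {
    P[!nonzero, ] <- 0
    P[cbind(which(!nonzero), which(!nonzero))] <- 1
  }
  structure(list(P = P, classes = rownames(a),
                 period_years = tm$period_years, legend = tm$legend),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d classes, period %g years\n",
              nrow(x$P), x$period_years))
  print(round(x$P, 4))
  invisible(x)
}

#' Tidy a Markov model into long form
#' @param x A `markov_model`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `probability`.
#' @export
tidy.markov_model <- function(x, ...) {
  tibble::tibble(
    from = rep(rownames(x$P), times = ncol(x$P)),
    to = rep(colnames(x$P), each = nrow(x$P)),
    probability = as.vector(x$P)
  )
}

#' One-row summary of a Markov model
#' @param x A `markov_model`.
#' @param ... Unused.
#' @return A tibble with class count, period, and mean diagonal
#'   (persistence) probability.
#' @export
glance.markov_model <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$P),
    period_years = x$period_years,
    mean_persistence = mean(diag(x$P))
  )
}

#' Project per-class areas one Markov period forward
#'
#' `areas_{t+T} = areas_t %*% P`. Total area is conserved because P is
#' row-stochastic. Applying a model estimated from a transition matrix to
#' that matrix's row totals reproduces its column totals exactly.
#'
#' @param model A `markov_model`.
#' @param areas Numeric vector of per-class areas (km2 or cells), in the
#'   model's class order.
#' @return Numeric vector of projected areas, named by class.
#' @export
project_areas <- function(model, areas) {
  if (length(areas) != nrow(model$P)) {
    stop("`areas` length must equal the number of classes", call. = FALSE)
  }
  out <- as.vector(areas %*% model$P)
  names(out) <- model$classes
  out
}

#' Per-class suitability surfaces from Markov conditional probabilities
#'
#' For each class j the surface value at a cell is `P[c, j]` where c is the
#' cell's current class: the probability of that location turning into class
#' j over the model period, given only its history. This is the
#' driver-free suitability map the CA allocator scores against.
#'
#' @param grid A [land_cover_grid()].
#' @param model A `markov_model` whose classes match the grid legend.
#' @return A named list of matrices (one per class), values in `[0, 1]`; NA
#'   at nodata cells.
#' @export
suitability_surfaces <- function(grid, model) {
  codes <- legend_codes(grid$legend)
  if (length(codes) != nrow(model$P)) {
    stop("model classes do not match the grid legend", call. = FALSE)
  }
  nd <- legend_nodata(grid$legend)
  idx <- match(grid$values, codes) # NA at nodata
  out <- lapply(seq_along(codes), function(j) {
    s <- matrix(model$P[idx, j], nrow(grid$values), ncol(grid$values))
    s
  })
  names(out) <- model$classes
  out
}

#' Simulate a future land-cover map with a Markov-CA allocator
#'
#' Couples the Markov model (how much area each class gains or loses) with
#' a cellular automaton (where the change lands). Final per-class cell
#' targets come from projecting the current class counts through `P` and
#' rounding by largest remainder. The run is split into `iterations` annual
#' steps with per-step targets interpolated linearly between the initial
#' and final counts. Each step, classes above their interim target release
#' their lowest-scoring cells and classes below it claim released cells by
#' descending score, where the score of cell x for class j is
#' `S_j(x) * (epsilon + f_j(x))`: the Markov suitability of the cell's
#' current class for j times its radius-2 von Neumann neighbor fraction of
#' class j, floored by `epsilon` so new patches can nucleate away from
#' existing ones. Ties are broken by a seeded random permutation, making the
#' run deterministic under `seed`. Nodata cells never change; unselected
#' cells keep their class; total cell count is conserved every step.
#'
#' @param grid A [land_cover_grid()] giving the initial state.
#' @param model A `markov_model` spanning the whole simulated period.
#' @param iterations Number of annual CA steps (>= 1).
#' @param seed Integer seed for tie-breaking.
#' @param epsilon Neighborhood floor (> 0, default 0.1).
#' @param area_tolerance Allowed fraction of the landscape by which final
#'   counts may miss their targets (default 0.005); exceeding it is an
#'   error, not a warning, since the allocator is exact by construction.
#' @return A [land_cover_grid()] of the simulated end state.
#' @export
ca_simulate <- function(grid, model, iterations = NULL, seed = 1L,
                        epsilon = 0.1, area_tolerance = 0.005) {
  if (is.null(iterations)) iterations <- max(1L, round(model$period_years))
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  codes <- legend_codes(grid$legend)
  ncls <- length(codes)
  if (ncls != nrow(model$P)) {
    stop("model classes do not match the grid legend", call. = FALSE)
  }
  nd <- legend_nodata(grid$legend)
  v <- grid$values
  live <- v != nd
  n_live <- sum(live)
  counts0 <- tabulate(match(v[live], codes), nbins = ncls)
  target_final <- largest_remainder(as.vector(counts0 %*% model$P))
  if (any(target_final < 0)) stop("infeasible negative targets", call. = FALSE)
  withr_seed(seed, {
    tiebreak <- matrix(stats::runif(length(v)), nrow(v), ncol(v))
  })
  for (k in seq_len(iterations)) {
    interim <- largest_remainder(counts0 + (k / iterations) *
                                   (target_final - counts0))
    v <- ca_step(v, codes, nd, model$P, interim, epsilon, tiebreak)
  }
  achieved <- tabulate(match(v[v != nd], codes), nbins = ncls)
  if (max(abs(achieved - target_final)) > area_tolerance * n_live) {
    stop("CA allocation missed its area targets beyond tolerance",
         call. = FALSE)
  }
  land_cover_grid(v, grid$legend, cell_size_m = grid$cell_size_m,
                  date_label = paste0(grid$date_label, "+", iterations))
}

# one CA allocation step toward `target` per-class cell counts
ca_step <- function(v, codes, nd, P, target, epsilon, tiebreak) {
  ncls <- length(codes)
  live <- which(v != nd)
  cls_idx <- match(v[live], codes)
  current <- tabulate(cls_idx, nbins = ncls)
  delta <- current - target
  if (all(delta == 0)) return(v)
  nf <- neighbor_fractions(v, codes, nd)
  # score of each live cell for each class
  smat <- P[cls_idx, , drop = FALSE] # suitability from current class row
  fmat <- vapply(nf$frac, function(m) m[live], numeric(length(live)))
  score <- smat * (epsilon + fmat)
  tb <- tiebreak[live]

  # over-target classes release their lowest-scoring cells (own-class score)
  released <- integer(0)
  for (i in which(delta > 0)) {
    members <- which(cls_idx == i)
    own <- score[members, i]
    ord <- order(own, tb[members])
    released <- c(released, members[ord[seq_len(delta[i])]])
  }
  if (length(released) == 0) return(v)

  # under-target classes claim released cells by descending score
  deficits <- pmax(-delta, 0L)
  cand <- expand.grid(cell = released, class = which(deficits > 0))
  cand$score <- score[cbind(cand$cell, cand$class)]
  cand$tb <- tb[cand$cell]
  cand <- cand[order(-cand$score, cand$tb, cand$class), ]
  assigned <- rep(NA_integer_, length(released))
  names(assigned) <- as.character(released)
  remaining <- deficits
  for (r in seq_len(nrow(cand))) {
    cell <- cand$cell[r]; cl <- cand$class[r]
    key <- as.character(cell)
    if (!is.na(assigned[key]) || remaining[cl] == 0L) next
    assigned[key] <- cl
    remaining[cl] <- remaining[cl] - 1L
    if (all(remaining == 0L)) break
  }
  new_v <- v
  got <- !is.na(assigned)
  new_v[live[released[got]]] <- codes[assigned[got]]
  new_v
}
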
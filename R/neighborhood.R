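# Radius-2 von Neumann neighborhood (Manhattan distance <= 2, center
# excluded): 12 offsets. One neighborhood convention is used across the
# whole package (CA allocation and synthetic evolution).

vn2_offsets <- function() {
  off <- expand.grid(di = -2:2, dj = -2:2)
  off <- off[abs(off$di) + abs(off$dj) >= 1 & abs(off$di) + abs(off$dj) <= 2, ]
  as.matrix(off)
}

# shift a matrix by (di, dj), padding with `fill`
shift_mat <- function(m, di, dj, fill = NA_integer_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - di):min(nr, nr - di)
  src_c <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(src_r) > 0 && length(src_c) > 0) {
    out[src_r + di, src_c + dj] <- m[src_r, src_c]
  }
  out
}

# Per-class neighbor fractions f_j over the radius-2 von Neumann
# neighborhood, truncated at borders and ignoring nodata neighbors.
# Returns list(frac = list of matrices, one per code in `codes`).
neighbor_fractions <- function(values, codes, nodata) {
  off <- vn2_offsets()
  valid <- values != nodata
  avail <- matrix(0L, nrow(values), ncol(values))
  counts <- lapply(codes, function(.) matrix(0L, nrow(values), ncol(values)))
  names(counts) <- as.character(codes)
  for (k in seq_len(nrow(off))) {
    sv <- shift_mat(values, off[k, 1], off[k, 2], fill = nodata)
    ok <- sv != nodata
    avail <- avail + ok
    for (ci in seq_along(codes)) {
      counts[[ci]] <- counts[[ci]] + (ok & sv == codes[ci])
    }
  }
  frac <- lapply(counts, function(cm) {
    f <- cm / pmax(avail, 1L)
    f[avail == 0L] <- 0
    f
  })
  list(frac = frac, avail = avail)
}

# largest-remainder rounding of non-negative targets to integers preserving
# round(sum(x)); ties broken by index order
largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- x - fl
  short <- as.integer(total - sum(fl))
  out <- as.integer(fl)
  if (short > 0) {
    idx <- order(-rem, seq_along(x))[seq_len(short)]
    out[idx] <- out[idx] + 1L
  } else if (short < 0) {
    # can only happen via accumulated float error; take from largest floors
    idx <- order(rem, -fl, seq_along(x))[seq_len(-short)]
    out[idx] <- out[idx] - 1L
  }
  out
}
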
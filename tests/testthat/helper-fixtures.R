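# shared in-code fixtures; everything is generated, nothing read from disk
leg7 <- default_legend()

# tiny grid from a matrix of codes
grid_of <- function(m, date = "", cell = 30) {
  land_cover_grid(m, leg7, cell_size_m = cell, date_label = date)
}

# mean like-class adjacency (4-neighbor): fraction of horizontal+vertical
# neighbor pairs sharing a class; independent oracle for clustering checks
like_adjacency <- function(values) {
  h <- values[, -1] == values[, -ncol(values)]
  v <- values[-1, ] == values[-nrow(values), ]
  mean(c(h, v))
}

# a mildly off-diagonal row-stochastic 7-class kernel used in several tests
kernel7 <- function(stay = 0.85) {
  n <- 7
  P <- matrix((1 - stay) / (n - 1), n, n)
  diag(P) <- stay
  P
}

# the published 1990-2000 transition table, entered from the package fixture
tm_qinghai <- function() qinghai_transition_1990_2000()
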
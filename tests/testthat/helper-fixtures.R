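# programmatic fixtures shared across test files

# random categorical raster: mixes iid noise and clumpy (smoothed) fields so
# the oracle suite sees both fragmented and aggregated patterns
random_raster <- function(nr, nc, n_classes = 3, clumpy = FALSE,
                          cell_size = 30) {
  codes <- sort(sample(0:10, n_classes))
  if (!clumpy) {
    g <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  } else {
    field <- matrix(rnorm(nr * nc), nr, nc)
    for (i in 1:3) { # crude smoothing by neighbor averaging
      padded <- rbind(field[1, ], field, field[nr, ])
      padded <- cbind(padded[, 1], padded, padded[, nc])
      field <- (padded[2:(nr + 1), 2:(nc + 1)] +
        padded[1:nr, 2:(nc + 1)] + padded[3:(nr + 2), 2:(nc + 1)] +
        padded[2:(nr + 1), 1:nc] + padded[2:(nr + 1), 3:(nc + 2)]) / 5
    }
    brks <- quantile(field, probs = seq(0, 1, length.out = n_classes + 1))
    brks[1] <- -Inf
    brks[n_classes + 1] <- Inf
    g <- matrix(codes[as.integer(cut(field, brks))], nr, nc)
  }
  invadescape::landscape_raster(g, cell_size_m = cell_size)
}

checkerboard_raster <- function(n = 8, codes = c(1L, 6L)) {
  g <- matrix(codes[1], n, n)
  g[(row(g) + col(g)) %% 2 == 0] <- codes[2]
  invadescape::landscape_raster(g)
}

uniform_raster <- function(n = 16, code = 1L) {
  invadescape::landscape_raster(matrix(code, n, n))
}

# a small mixed landscape with grassland, crop, water, and a road, used by
# simulator invariant tests
mixed_raster <- function(n = 32) {
  g <- matrix(1L, n, n)
  g[, seq(1, n, by = 4)] <- 6L
  g[1:floor(n / 4), 1:floor(n / 4)] <- 9L
  g[floor(n / 2), ] <- 7L
  invadescape::landscape_raster(g)
}
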
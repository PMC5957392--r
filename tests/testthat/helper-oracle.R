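# Independent brute-force implementations used as oracles: every metric is
# computed directly from its definition with explicit loops, sharing no code
# with the package internals (conventions for degenerate cases mirror the
# documented package conventions so results are comparable).

# flood-fill patch labeling with an explicit stack
o_label <- function(grid, connectivity = 8) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  labels <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(
      c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
      c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)
    )
  }
  lab <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) { # row-major scan fixes label order
      if (labels[r, cc] != 0L) next
      lab <- lab + 1L
      stack <- list(c(r, cc))
      labels[r, cc] <- lab
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in nb) {
          r2 <- cur[1] + d[1]
          c2 <- cur[2] + d[2]
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (labels[r2, c2] != 0L && labels[r2, c2] != lab) next
          if (labels[r2, c2] == lab) next
          if (grid[r2, c2] != grid[cur[1], cur[2]]) next
          labels[r2, c2] <- lab
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  labels
}

# double-count adjacency tally g[i, k]: for every cell and each of its 4
# orthogonal neighbors, count the ordered class pair
o_adjacency <- function(grid) {
  g <- matrix(0, 11, 11)
  nr <- nrow(grid)
  nc <- ncol(grid)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]
        c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        g[grid[r, cc] + 1, grid[r2, c2] + 1] <-
          g[grid[r, cc] + 1, grid[r2, c2] + 1] + 1
      }
    }
  }
  g
}

# brute-force minimum enclosing circle: try every pair (as diameter) and
# every triple (circumcircle) of hull points, keep the smallest that contains
# all points
o_mec_radius <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1) return(0)
  if (nrow(pts) > 3) {
    pts <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  }
  n <- nrow(pts)
  contains <- function(ctr, rad) {
    all(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <= rad + 1e-9)
  }
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ctr <- (pts[i, ] + pts[j, ]) / 2
      rad <- sqrt(sum((pts[i, ] - ctr)^2))
      if (rad < best && contains(ctr, rad)) best <- rad
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
          d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
            c[1] * (a[2] - b[2]))
          if (abs(d) < 1e-12) next
          ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
            (sum(c^2)) * (a[2] - b[2])) / d
          uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
            (sum(c^2)) * (b[1] - a[1])) / d
          rad <- sqrt((a[1] - ux)^2 + (a[2] - uy)^2)
          if (rad < best && contains(c(ux, uy), rad)) best <- rad
        }
      }
    }
  }
  best
}

# full 50-metric vector straight from the definitions
o_metric_vector <- function(raster, connectivity = 8) {
  grid <- raster$grid
  cs <- raster$cell_size_m
  nr <- nrow(grid)
  nc <- ncol(grid)
  n_cells <- nr * nc
  A_ha <- n_cells * cs^2 / 1e4

  counts <- sapply(0:10, function(k) sum(grid == k))
  comp <- counts / n_cells

  labels <- o_label(grid, connectivity)
  np <- max(labels)
  p_cells <- lapply(seq_len(np), function(i) which(labels == i, arr.ind = TRUE))
  p_n <- sapply(p_cells, nrow)
  p_code <- sapply(seq_len(np), function(i) grid[p_cells[[i]][1, 1], p_cells[[i]][1, 2]])

  # perimeter: per cell, edges facing a different patch or the boundary
  p_perim <- sapply(seq_len(np), function(i) {
    tot <- 0
    for (q in seq_len(p_n[i])) {
      r <- p_cells[[i]][q, 1]
      cc <- p_cells[[i]][q, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]
        c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || labels[r2, c2] != i) {
          tot <- tot + 1
        }
      }
    }
    tot
  })

  area_ha <- p_n * cs^2 / 1e4
  area_m2 <- p_n * cs^2
  perim_m <- p_perim * cs

  gyrate <- sapply(seq_len(np), function(i) {
    x <- (p_cells[[i]][, 2] - 0.5) * cs
    y <- (p_cells[[i]][, 1] - 0.5) * cs
    mean(sqrt((x - mean(x))^2 + (y - mean(y))^2))
  })

  shape <- sapply(seq_len(np), function(i) {
    a <- p_n[i]
    nn <- floor(sqrt(a))
    minp <- if (a == nn^2) 4 * nn else if (a <= nn * (nn + 1)) 4 * nn + 2 else 4 * nn + 4
    p_perim[i] / minp
  })

  frac <- sapply(seq_len(np), function(i) {
    if (abs(log(area_m2[i])) < 1e-12) 1 else 2 * log(0.25 * perim_m[i]) / log(area_m2[i])
  })
  para <- perim_m / area_m2

  circle <- sapply(seq_len(np), function(i) {
    xy <- p_cells[[i]]
    corners <- unique(rbind(
      cbind(xy[, 2] - 1, xy[, 1] - 1), cbind(xy[, 2], xy[, 1] - 1),
      cbind(xy[, 2] - 1, xy[, 1]), cbind(xy[, 2], xy[, 1])
    )) * cs
    r <- o_mec_radius(corners)
    1 - area_m2[i] / (pi * r^2)
  })

  contig <- sapply(seq_len(np), function(i) {
    vals <- numeric(p_n[i])
    for (q in seq_len(p_n[i])) {
      r <- p_cells[[i]][q, 1]
      cc <- p_cells[[i]][q, 2]
      v <- 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && labels[r2, c2] == i) v <- v + 2
      }
      for (d in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && labels[r2, c2] == i) v <- v + 1
      }
      vals[q] <- v
    }
    (mean(vals) - 1) / 12
  })

  enn <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    same <- which(p_code == p_code[i])
    same <- setdiff(same, i)
    if (!length(same)) next
    best <- Inf
    for (j in same) {
      for (q in seq_len(p_n[i])) {
        d2 <- (p_cells[[j]][, 1] - p_cells[[i]][q, 1])^2 +
          (p_cells[[j]][, 2] - p_cells[[i]][q, 2])^2
        best <- min(best, min(d2))
      }
    }
    enn[i] <- sqrt(best) * cs
  }

  am <- function(x, w = area_ha) sum(x * w) / sum(w)
  psd <- function(x) if (length(x) <= 1) 0 else sqrt(sum((x - mean(x))^2) / length(x))
  d3 <- function(x) c(am(x), median(x), psd(x))

  if (all(is.na(enn))) {
    enn3 <- c(sqrt(nr^2 + nc^2) * cs, sqrt(nr^2 + nc^2) * cs, 0)
  } else {
    x <- enn[!is.na(enn)]
    enn3 <- c(am(x, area_ha[!is.na(enn)]), median(x), psd(x))
  }

  # pafrac: 2 x slope of ln p on ln a
  la <- log(area_m2)
  lp <- log(perim_m)
  if (np < 2 || psd(la) < 1e-12) {
    pafrac <- 1
  } else {
    fit <- lm(lp ~ la)
    pafrac <- 2 * unname(coef(fit)[2])
  }

  g <- o_adjacency(grid)
  present <- which(counts > 0)
  m <- length(present)
  P <- counts / n_cells

  tot_adj <- sum(g)
  pladj <- if (tot_adj == 0) 100 else 100 * sum(diag(g)) / tot_adj

  if (m < 2 || tot_adj == 0) {
    contag <- 100
  } else {
    acc <- 0
    for (i in present) {
      gi <- sum(g[i, ])
      if (gi == 0) next
      for (k in present) {
        q <- P[i] * g[i, k] / gi
        if (q > 0) acc <- acc + q * log(q)
      }
    }
    contag <- 100 * (1 + acc / (2 * log(m)))
  }

  iji <- 0
  if (m >= 3) {
    e <- c()
    for (a in seq_along(present)) {
      for (b in seq_along(present)) {
        if (b <= a) next
        e <- c(e, g[present[a], present[b]])
      }
    }
    E <- sum(e)
    if (E > 0) {
      fr <- e[e > 0] / E
      iji <- -sum(fr * log(fr)) / log(m * (m - 1) / 2) * 100
    }
  }

  ai <- 0
  for (i in present) {
    a <- counts[i]
    nn <- floor(sqrt(a))
    mm <- a - nn^2
    maxg <- if (mm == 0) 2 * nn * (nn - 1) else if (mm <= nn) 2 * nn * (nn - 1) + 2 * mm - 1 else 2 * nn * (nn - 1) + 2 * mm - 2
    if (maxg > 0) ai <- ai + (g[i, i] / 2 / maxg) * P[i]
  }
  ai <- ai * 100

  pp <- comp[comp > 0]
  shdi <- -sum(pp * log(pp))
  sidi <- 1 - sum(pp^2)
  shei <- if (m > 1) shdi / log(m) else 0
  siei <- if (m > 1) sidi / (1 - 1 / m) else 0

  te <- (sum(g) - sum(diag(g))) / 2 * cs

  c(
    setNames(comp, paste0("prop_", invadescape::habitat_classes()$name)),
    np = np, pd = np / A_ha * 100, lpi = 100 * max(area_ha) / A_ha,
    te = te, ed = te / A_ha,
    area_am = d3(area_ha)[1], area_md = d3(area_ha)[2], area_sd = d3(area_ha)[3],
    gyrate_am = d3(gyrate)[1], gyrate_md = d3(gyrate)[2], gyrate_sd = d3(gyrate)[3],
    shape_am = d3(shape)[1], shape_md = d3(shape)[2], shape_sd = d3(shape)[3],
    frac_am = d3(frac)[1], frac_md = d3(frac)[2], frac_sd = d3(frac)[3],
    para_am = d3(para)[1], para_md = d3(para)[2], para_sd = d3(para)[3],
    circle_am = d3(circle)[1], circle_md = d3(circle)[2], circle_sd = d3(circle)[3],
    contig_am = d3(contig)[1], contig_md = d3(contig)[2], contig_sd = d3(contig)[3],
    pafrac = pafrac,
    enn_am = enn3[1], enn_md = enn3[2], enn_sd = enn3[3],
    contag = contag, pladj = pladj, iji = iji,
    pr = m, shdi = shdi, sidi = sidi, shei = shei, siei = siei, ai = ai
  )
}

# random-walk Metropolis reference sampler for the Bayesian lasso posterior
# on a small problem: exact log posterior with the Laplace prior, no
# scale-mixture augmentation
o_mh_lasso <- function(X, y, tau, n_iter = 60000, burnin = 10000,
                       step = 0.05) {
  n <- nrow(X)
  p <- ncol(X)
  log_post <- function(theta) {
    beta0 <- theta[1]
    beta <- theta[2:(p + 1)]
    sigma <- theta[p + 2]
    if (sigma <= 0.001 || sigma >= 30) return(-Inf)
    resid <- y - beta0 - X %*% beta
    -n * log(sigma) - sum(resid^2) / (2 * sigma^2) -
      tau * sum(abs(beta)) - 0.005 * beta0^2
  }
  theta <- c(mean(y), rep(0, p), sd(y))
  lp <- log_post(theta)
  keep <- matrix(NA_real_, n_iter - burnin, p + 2)
  acc <- 0
  for (it in seq_len(n_iter)) {
    prop <- theta + rnorm(p + 2, 0, step)
    lp2 <- log_post(prop)
    if (log(runif(1)) < lp2 - lp) {
      theta <- prop
      lp <- lp2
      acc <- acc + 1
    }
    if (it > burnin) keep[it - burnin, ] <- theta
  }
  attr(keep, "accept_rate") <- acc / n_iter
  keep
}

# Monte-Carlo standard error by batch means
o_mcse <- function(x, n_batches = 30) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- sapply(seq_len(n_batches), function(i) {
    mean(x[((i - 1) * bs + 1):(i * bs)])
  })
  sd(means) / sqrt(n_batches)
}
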
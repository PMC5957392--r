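#' The 50-entry landscape metric registry
#'
#' Names, order, and units of the 50 landscape characteristics computed by
#' [compute_metric_vector()]: 11 composition proportions followed by 39
#' landscape-level spatial-structure metrics (FRAGSTATS conventions;
#' core-area and contrast families are deliberately absent). Distribution
#' metrics summarize per-patch values by area-weighted mean (`_am`), median
#' (`_md`), and (population) standard deviation (`_sd`).
#'
#' @return A tibble with `position` (1--50), `name`, `label`, `aspect`
#'   (`"composition"` or `"structure"`), and `units`.
#' @export
#' @examples
#' metric_registry()
metric_registry <- function() {
  hc <- habitat_classes()
  comp <- tibble::tibble(
    position = 1:11,
    name = paste0("prop_", hc$name),
    label = paste("Proportion", tolower(hc$label)),
    aspect = "composition",
    units = "proportion"
  )
  st <- function(name, label, units) {
    tibble::tibble(name = name, label = label, units = units)
  }
  dist3 <- function(stem, label, units) {
    st(
      paste0(stem, c("_am", "_md", "_sd")),
      paste0(label, c(": area-weighted mean", ": median",
                      ": standard deviation")),
      units
    )
  }
  struct <- dplyr::bind_rows(
    st("np", "Number of patches", "count"),
    st("pd", "Patch density", "patches/100 ha"),
    st("lpi", "Largest patch index", "percent"),
    st("te", "Total edge", "m"),
    st("ed", "Edge density", "m/ha"),
    dist3("area", "Patch area", "ha"),
    dist3("gyrate", "Radius of gyration", "m"),
    dist3("shape", "Shape index", "unitless"),
    dist3("frac", "Fractal dimension index", "unitless"),
    dist3("para", "Perimeter-area ratio", "m/m^2"),
    dist3("circle", "Related circumscribing circle", "unitless"),
    dist3("contig", "Contiguity index", "unitless"),
    st("pafrac", "Perimeter-area fractal dimension", "unitless"),
    dist3("enn", "Euclidean nearest neighbor", "m"),
    st("contag", "Contagion", "percent"),
    st("pladj", "Percentage of like adjacencies", "percent"),
    st("iji", "Interspersion and juxtaposition index", "percent"),
    st("pr", "Patch richness", "count"),
    st("shdi", "Shannon's diversity index", "unitless"),
    st("sidi", "Simpson's diversity index", "unitless"),
    st("shei", "Shannon's evenness index", "unitless"),
    st("siei", "Simpson's evenness index", "unitless"),
    st("ai", "Aggregation index", "percent")
  )
  struct$position <- 12:50
  struct$aspect <- "structure"
  dplyr::bind_rows(comp, struct)[, c(
    "position", "name", "label", "aspect", "units"
  )]
}

#' Landscape composition proportions
#'
#' Proportion of cells in each of the 11 habitat classes, in registry order
#' (positions 1--11 of the metric vector). The 11 entries sum to exactly 1.
#'
#' @param raster A [landscape_raster()].
#' @return A named numeric vector of length 11 (`prop_unsuitable`, ...,
#'   `prop_shrubland`).
#' @export
composition_proportions <- function(raster) {
  stopifnot(inherits(raster, "landscape_raster"))
  hc <- habitat_classes()
  counts <- tabulate(as.vector(raster$grid) + 1L, 11L)
  setNames(counts / length(raster$grid), paste0("prop_", hc$name))
}

# single-count 4-neighbor adjacency matrix (11 x 11, by class code + 1);
# each adjacent cell pair tallied once
.adjacency_single <- function(grid) {
  S <- matrix(0, 11, 11)
  nr <- nrow(grid)
  nc <- ncol(grid)
  tally <- function(a, b) {
    t <- table(factor(a, levels = 0:10), factor(b, levels = 0:10))
    S <<- S + unclass(t)
  }
  if (nr > 1) tally(grid[-nr, , drop = FALSE], grid[-1, , drop = FALSE])
  if (nc > 1) tally(grid[, -nc, drop = FALSE], grid[, -1, drop = FALSE])
  S
}

# per-patch quantity table; all FRAGSTATS patch-level definitions used by the
# landscape distribution metrics
.patch_quantities <- function(patch_map) {
  pt <- patch_map$patches
  cs <- patch_map$cell_size_m
  cells <- .patch_cells(patch_map)
  labels <- patch_map$labels
  nr <- nrow(labels)
  nc <- ncol(labels)

  area_m2 <- pt$n_cells * cs^2
  perim_m <- pt$perimeter_edges * cs

  # radius of gyration: mean distance of cell centers to the patch centroid
  gyrate <- vapply(cells, function(xy) {
    x <- (xy[, "col"] - 0.5) * cs
    y <- (xy[, "row"] - 0.5) * cs
    mean(sqrt((x - mean(x))^2 + (y - mean(y))^2))
  }, numeric(1))

  # shape index: perimeter over the minimum perimeter possible for the cell
  # count (raster normalization)
  min_perim <- vapply(pt$n_cells, function(a) {
    n <- floor(sqrt(a))
    if (a == n^2) 4 * n else if (a <= n * (n + 1)) 4 * n + 2 else 4 * n + 4
  }, numeric(1))
  shape <- pt$perimeter_edges / min_perim

  frac <- ifelse(
    abs(log(area_m2)) < 1e-12, 1,
    2 * log(0.25 * perim_m) / log(area_m2)
  )
  para <- perim_m / area_m2

  # related circumscribing circle over cell corners
  circle <- vapply(seq_along(cells), function(i) {
    xy <- cells[[i]]
    corners <- unique(rbind(
      cbind(xy[, "col"] - 1, xy[, "row"] - 1),
      cbind(xy[, "col"], xy[, "row"] - 1),
      cbind(xy[, "col"] - 1, xy[, "row"]),
      cbind(xy[, "col"], xy[, "row"])
    )) * cs
    mec <- .min_enclosing_circle(corners)
    1 - area_m2[i] / (pi * mec$r^2)
  }, numeric(1))

  # contiguity: average 13-point template value over patch cells
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  tmpl <- matrix(1, nr, nc)
  orth <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  diag <- list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  for (d in orth) {
    sh <- pad[2:(nr + 1L) + d[1], 2:(nc + 1L) + d[2]]
    tmpl <- tmpl + 2 * (sh == ctr)
  }
  for (d in diag) {
    sh <- pad[2:(nr + 1L) + d[1], 2:(nc + 1L) + d[2]]
    tmpl <- tmpl + 1 * (sh == ctr)
  }
  tmpl_sum <- tapply(as.vector(tmpl), as.vector(labels), sum)
  contig <- (as.numeric(tmpl_sum)[order(as.integer(names(tmpl_sum)))] /
    pt$n_cells - 1) / 12

  enn <- .patch_enn(patch_map, cells)

  tibble::tibble(
    patch_id = pt$patch_id, code = pt$code, n_cells = pt$n_cells,
    area_ha = area_m2 / 1e4, perim_m = perim_m,
    gyrate = gyrate, shape = shape, frac = frac, para = para,
    circle = circle, contig = contig, enn = enn
  )
}

# Euclidean nearest neighbor: minimum center-to-center distance to another
# patch of the same class (m); NA when the class has a single patch
.patch_enn <- function(patch_map, cells) {
  pt <- patch_map$patches
  cs <- patch_map$cell_size_m
  enn <- rep(NA_real_, nrow(pt))
  for (code in unique(pt$code)) {
    ids <- pt$patch_id[pt$code == code]
    if (length(ids) < 2) next
    for (i in ids) {
      xy_i <- cells[[i]]
      best <- Inf
      for (j in ids) {
        if (j == i) next
        xy_j <- cells[[j]]
        # chunk the larger side to bound memory on big patches
        step <- max(1L, floor(2e6 / nrow(xy_j)))
        for (s in seq(1L, nrow(xy_i), by = step)) {
          rows <- s:min(s + step - 1L, nrow(xy_i))
          d2 <- outer(xy_i[rows, "row"], xy_j[, "row"], "-")^2 +
            outer(xy_i[rows, "col"], xy_j[, "col"], "-")^2
          best <- min(best, min(d2))
        }
      }
      enn[i] <- sqrt(best) * cs
    }
  }
  enn
}

#' Distribution summaries of a per-patch quantity
#'
#' Summarizes one per-patch quantity over all patches of the landscape by
#' area-weighted mean, median, and population standard deviation (the three
#' distribution descriptors retained in the metric registry).
#'
#' @param patch_map A [label_patches()] result.
#' @param quantity One of `"area"`, `"radius_of_gyration"`, `"shape_index"`,
#'   `"fractal_index"`, `"perim_area_ratio"`, `"circumscribing_circle"`,
#'   `"contiguity"`, `"euclidean_nn"`.
#' @return A one-row tibble with `quantity`, `area_weighted_mean`, `median`,
#'   `standard_deviation`, and `n_defined` (patches with a defined value;
#'   relevant for `euclidean_nn`).
#' @export
patch_distribution_stats <- function(patch_map, quantity) {
  cols <- c(
    area = "area_ha", radius_of_gyration = "gyrate", shape_index = "shape",
    fractal_index = "frac", perim_area_ratio = "para",
    circumscribing_circle = "circle", contiguity = "contig",
    euclidean_nn = "enn"
  )
  if (!quantity %in% names(cols)) {
    stop(sprintf("unknown patch quantity '%s'", quantity), call. = FALSE)
  }
  pq <- .patch_quantities(patch_map)
  x <- pq[[cols[[quantity]]]]
  w <- pq$area_ha
  ok <- !is.na(x)
  x <- x[ok]
  w <- w[ok]
  if (length(x) == 0) {
    return(tibble::tibble(
      quantity = quantity, area_weighted_mean = NA_real_,
      median = NA_real_, standard_deviation = NA_real_, n_defined = 0L
    ))
  }
  tibble::tibble(
    quantity = quantity,
    area_weighted_mean = sum(x * w) / sum(w),
    median = median(x),
    standard_deviation = sqrt(mean((x - mean(x))^2)),
    n_defined = length(x)
  )
}

#' Aggregation-family landscape metrics
#'
#' Contagion, percentage of like adjacencies (PLADJ), interspersion and
#' juxtaposition index (IJI), and aggregation index (AI), all in percent,
#' computed from 4-neighbor cell adjacencies (double-count convention for
#' contagion and PLADJ, single-count like adjacencies for AI). Degenerate
#' inputs use documented conventions: a single-class landscape has contagion
#' 100; IJI needs at least three classes and is otherwise imputed to 0; both
#' imputations are flagged.
#'
#' @param raster A [landscape_raster()].
#' @return A one-row tibble with `contag`, `pladj`, `iji`, `ai`,
#'   `flag_contag_imputed`, `flag_iji_imputed`.
#' @export
aggregation_metrics <- function(raster) {
  stopifnot(inherits(raster, "landscape_raster"))
  g <- raster$grid
  S <- .adjacency_single(g)
  G <- S + t(S) # double-count
  counts <- tabulate(as.vector(g) + 1L, 11L)
  present <- which(counts > 0)
  m <- length(present)
  A <- length(g)
  P <- counts / A

  tot_adj <- sum(G)
  pladj <- if (tot_adj == 0) 100 else 100 * sum(diag(G)) / tot_adj

  flag_contag <- FALSE
  if (m < 2 || tot_adj == 0) {
    contag <- 100
    flag_contag <- TRUE
  } else {
    acc <- 0
    for (i in present) {
      gi <- sum(G[i, ])
      if (gi == 0) next
      for (k in present) {
        q <- P[i] * G[i, k] / gi
        if (q > 0) acc <- acc + q * log(q)
      }
    }
    contag <- 100 * (1 + acc / (2 * log(m)))
  }

  flag_iji <- FALSE
  E <- 0
  if (m >= 3) {
    e <- c()
    for (i in seq_along(present)) {
      for (k in seq_along(present)) {
        if (k <= i) next
        e <- c(e, G[present[i], present[k]])
      }
    }
    E <- sum(e)
  }
  if (m < 3 || E == 0) {
    iji <- 0
    flag_iji <- TRUE
  } else {
    frac <- e[e > 0] / E
    iji <- -sum(frac * log(frac)) / log(m * (m - 1) / 2) * 100
  }

  ai <- 0
  for (i in present) {
    a <- counts[i]
    n <- floor(sqrt(a))
    mm <- a - n^2
    maxg <- if (mm == 0) {
      2 * n * (n - 1)
    } else if (mm <= n) {
      2 * n * (n - 1) + 2 * mm - 1
    } else {
      2 * n * (n - 1) + 2 * mm - 2
    }
    if (maxg > 0) ai <- ai + (S[i, i] / maxg) * P[i]
  }
  ai <- 100 * ai

  tibble::tibble(
    contag = contag, pladj = pladj, iji = iji, ai = ai,
    flag_contag_imputed = flag_contag, flag_iji_imputed = flag_iji
  )
}

#' Diversity-family landscape metrics
#'
#' Patch richness (number of classes present), Shannon and Simpson diversity
#' of the class proportions, and their evenness normalizations. Evenness is
#' defined as 0 for a single-class landscape.
#'
#' @param raster A [landscape_raster()].
#' @return A one-row tibble with `pr`, `shdi`, `sidi`, `shei`, `siei`.
#' @export
diversity_metrics <- function(raster) {
  stopifnot(inherits(raster, "landscape_raster"))
  p <- composition_proportions(raster)
  p <- p[p > 0]
  m <- length(p)
  shdi <- -sum(p * log(p))
  sidi <- 1 - sum(p^2)
  tibble::tibble(
    pr = m,
    shdi = shdi,
    sidi = sidi,
    shei = if (m > 1) shdi / log(m) else 0,
    siei = if (m > 1) sidi / (1 - 1 / m) else 0
  )
}

#' Compute the full 50-metric vector of a landscape
#'
#' All 50 registry entries in fixed order (see [metric_registry()]): 11
#' composition proportions, then number of patches, patch density, largest
#' patch index, total edge, edge density, patch area / radius of gyration /
#' shape / fractal / perimeter-area / circumscribing circle / contiguity
#' distribution summaries, perimeter-area fractal dimension, Euclidean
#' nearest-neighbor summaries, contagion, PLADJ, IJI, richness and diversity
#' indices, and aggregation index. The landscape boundary is not counted as
#' edge. Undefined entries are imputed by documented conventions and flagged
#' (`flag_*` columns): nearest-neighbor distances with no same-class patch
#' pair become the raster diagonal, contagion 100, IJI 0, single-patch
#' standard deviations 0, and the perimeter-area fractal dimension 1 when
#' fewer than two patches (or degenerate areas) prevent the regression, with
#' a low-confidence flag below 10 patches.
#'
#' @param raster A [landscape_raster()].
#' @param connectivity Patch neighborhood rule, 4 or 8 (default 8).
#' @return A one-row tibble: 50 metric columns in registry order, then flag
#'   columns.
#' @export
#' @examples
#' r <- landscape_raster(matrix(1L, 16, 16))
#' compute_metric_vector(r)$np
compute_metric_vector <- function(raster, connectivity = 8) {
  stopifnot(inherits(raster, "landscape_raster"))
  cs <- raster$cell_size_m
  g <- raster$grid
  A_ha <- length(g) * cs^2 / 1e4

  comp <- composition_proportions(raster)
  pm <- label_patches(raster, connectivity = connectivity)
  pq <- .patch_quantities(pm)
  np <- nrow(pq)

  # total edge: differing 4-adjacencies, boundary excluded
  S <- .adjacency_single(g)
  te <- (sum(S) - sum(diag(S))) * cs
  ed <- te / A_ha
  lpi <- 100 * max(pq$area_ha) / A_ha
  pd <- np / A_ha * 100

  am <- function(x, w) sum(x * w) / sum(w)
  psd <- function(x) if (length(x) <= 1) 0 else sqrt(mean((x - mean(x))^2))
  flag_sd <- np <= 1

  d3 <- function(x) {
    c(am(x, pq$area_ha), median(x), psd(x))
  }

  enn <- pq$enn
  flag_enn <- all(is.na(enn))
  diag_m <- sqrt(nrow(g)^2 + ncol(g)^2) * cs
  if (flag_enn) {
    enn3 <- c(diag_m, diag_m, 0)
  } else {
    x <- enn[!is.na(enn)]
    w <- pq$area_ha[!is.na(enn)]
    enn3 <- c(am(x, w), median(x), psd(x))
  }

  # perimeter-area fractal dimension: 2 x OLS slope of ln(perim) on ln(area)
  flag_pafrac <- FALSE
  la <- log(pq$n_cells * cs^2)
  lp <- log(pq$perim_m)
  if (np < 2 || psd(la) < 1e-12) {
    pafrac <- 1
    flag_pafrac <- TRUE
  } else {
    pafrac <- 2 * sum((la - mean(la)) * (lp - mean(lp))) /
      sum((la - mean(la))^2)
  }

  agg <- aggregation_metrics(raster)
  div <- diversity_metrics(raster)

  vals <- c(
    comp,
    np = np, pd = pd, lpi = lpi, te = te, ed = ed,
    setNames(d3(pq$area_ha), c("area_am", "area_md", "area_sd")),
    setNames(d3(pq$gyrate), c("gyrate_am", "gyrate_md", "gyrate_sd")),
    setNames(d3(pq$shape), c("shape_am", "shape_md", "shape_sd")),
    setNames(d3(pq$frac), c("frac_am", "frac_md", "frac_sd")),
    setNames(d3(pq$para), c("para_am", "para_md", "para_sd")),
    setNames(d3(pq$circle), c("circle_am", "circle_md", "circle_sd")),
    setNames(d3(pq$contig), c("contig_am", "contig_md", "contig_sd")),
    pafrac = pafrac,
    setNames(enn3, c("enn_am", "enn_md", "enn_sd")),
    contag = agg$contag, pladj = agg$pladj, iji = agg$iji,
    pr = div$pr, shdi = div$shdi, sidi = div$sidi, shei = div$shei,
    siei = div$siei, ai = agg$ai
  )
  stopifnot(identical(names(vals), metric_registry()$name))
  out <- tibble::as_tibble(as.list(vals))
  out$flag_enn_imputed <- flag_enn
  out$flag_contag_imputed <- agg$flag_contag_imputed
  out$flag_iji_imputed <- agg$flag_iji_imputed
  out$flag_sd_single_patch <- flag_sd
  out$flag_pafrac_imputed <- flag_pafrac
  out$flag_pafrac_low_confidence <- np < 10
  out
}

#' Compute metric vectors for a set of landscapes
#'
#' @param rasters A named list of [landscape_raster()] objects (names become
#'   `landscape_id`).
#' @param connectivity Patch neighborhood rule.
#' @return A tibble, one row per raster: `landscape_id` plus the 50 metric
#'   columns and flags.
#' @export
compute_metric_table <- function(rasters, connectivity = 8) {
  if (is.null(names(rasters))) {
    names(rasters) <- sprintf("landscape_%03d", seq_along(rasters))
  }
  purrr::map_dfr(rasters, compute_metric_vector,
    connectivity = connectivity, .id = "landscape_id"
  )
}
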
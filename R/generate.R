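#' Configuration for the synthetic landscape generator
#'
#' Describes one synthetic habitat tile: target class composition, a
#' fragmentation control, linear road corridors, and water bodies. Target
#' proportions must be non-negative and sum to 1 (within 1e-9); roads and
#' water bodies are painted after composition and are allowed to displace
#' other classes.
#'
#' @param target_proportions Named numeric vector (class names from
#'   [habitat_classes()]) of target landscape fractions, summing to 1.
#' @param fragmentation Real in (0, 1\]: larger values seed more growth nuclei
#'   and yield more, smaller patches.
#' @param n_roads,road_width_cells Number and width (cells) of linear road
#'   corridors spanning the tile.
#' @param n_water_bodies Number of compact water bodies painted over the
#'   composition.
#' @param n_rows,n_cols Raster dimensions (default 216 x 216).
#' @param cell_size_m Cell edge length in meters (default 30).
#' @param seed Integer seed; identical config + seed gives identical rasters.
#' @return An object of class `landscape_config`.
#' @export
#' @examples
#' cfg <- landscape_config(c(grassland = 0.6, crop = 0.4), seed = 1)
landscape_config <- function(target_proportions,
                             fragmentation = 0.3,
                             n_roads = 0, road_width_cells = 1,
                             n_water_bodies = 0,
                             n_rows = 216, n_cols = 216,
                             cell_size_m = 30, seed = 1) {
  hc <- habitat_classes()
  if (is.null(names(target_proportions)) ||
    !all(names(target_proportions) %in% hc$name)) {
    stop("`target_proportions` must be named with habitat class names",
      call. = FALSE
    )
  }
  if (any(target_proportions < 0)) {
    stop("target proportions must be non-negative", call. = FALSE)
  }
  if (abs(sum(target_proportions) - 1) > 1e-9) {
    stop("target proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (fragmentation <= 0 || fragmentation > 1) {
    stop("`fragmentation` must be in (0, 1]", call. = FALSE)
  }
  if (n_roads < 0) stop("`n_roads` must be >= 0", call. = FALSE)
  if (road_width_cells < 1) {
    stop("`road_width_cells` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      target_proportions = target_proportions,
      fragmentation = fragmentation,
      n_roads = as.integer(n_roads),
      road_width_cells = as.integer(road_width_cells),
      n_water_bodies = as.integer(n_water_bodies),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size_m = cell_size_m, seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

# 4-neighbor offsets used by the region-growing generator
.nbr4 <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  out <- c(
    if (r > 1L) idx - 1L, if (r < nr) idx + 1L,
    if (c > 1L) idx - nr, if (c < nc) idx + nr
  )
  out
}

#' Generate a synthetic habitat raster
#'
#' Emulates reclassified land-cover tiles with a seeded-nuclei region-growing
#' scheme (a modified-random-clusters style neutral landscape model): class
#' quotas are fixed from the target proportions, nuclei are scattered in
#' numbers controlled by `fragmentation`, and classes grow cell-by-cell from
#' random frontier cells until quotas are exhausted. Realized proportions
#' match targets to within rounding before roads and water are painted (the
#' post-condition tolerance is 0.05 absolute per class). Road corridors and
#' water bodies, if requested, overwrite the composition. The call is fully
#' deterministic given the config (which carries its seed).
#'
#' @param config A [landscape_config()].
#' @return A [landscape_raster()].
#' @export
#' @examples
#' r <- generate_landscape(landscape_config(
#'   c(grassland = 0.5, crop = 0.5),
#'   n_rows = 32, n_cols = 32, seed = 7
#' ))
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows
  nc <- config$n_cols
  if (nr < 9 || nc < 9) {
    stop("grid dimensions must be at least 9 x 9", call. = FALSE)
  }
  hc <- habitat_classes()
  n_cells <- nr * nc
  props <- config$target_proportions
  props <- props[props > 0]

  # integer quotas by largest remainder
  raw <- props * n_cells
  quota <- floor(raw)
  short <- n_cells - sum(quota)
  if (short > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(short)]
    quota[extra] <- quota[extra] + 1
  }
  quota <- quota[quota > 0]
  classes <- names(quota)
  codes <- hc$code[match(classes, hc$name)]
  k <- length(classes)

  out <- withr::with_seed(config$seed, {
    assigned <- integer(n_cells) # 0 = unassigned, else 1..k
    remaining <- as.numeric(quota)

    # nuclei: total count scales with fragmentation^2, split by quota share
    total_nuclei <- max(k, ceiling(config$fragmentation^2 * n_cells / 2))
    n_nuc <- pmax(1L, round(total_nuclei * remaining / n_cells))
    frontiers <- vector("list", k)
    nuc_cells <- sample.int(n_cells, min(sum(n_nuc), n_cells))
    pos <- 1L
    for (i in seq_len(k)) {
      take <- min(n_nuc[i], remaining[i])
      cells <- nuc_cells[pos:(pos + take - 1L)]
      pos <- pos + take
      cells <- cells[assigned[cells] == 0L]
      assigned[cells] <- i
      remaining[i] <- remaining[i] - length(cells)
      frontiers[[i]] <- cells
    }

    while (sum(remaining) > 0) {
      i <- if (k == 1L) 1L else sample.int(k, 1L, prob = pmax(remaining, 0))
      if (remaining[i] <= 0) next
      fr <- frontiers[[i]]
      grown <- FALSE
      while (length(fr) > 0) {
        j <- if (length(fr) == 1L) 1L else sample.int(length(fr), 1L)
        cand <- .nbr4(fr[j], nr, nc)
        cand <- cand[assigned[cand] == 0L]
        if (length(cand) == 0L) {
          fr <- fr[-j]
          next
        }
        new_cell <- if (length(cand) == 1L) cand else {
          cand[sample.int(length(cand), 1L)]
        }
        assigned[new_cell] <- i
        remaining[i] <- remaining[i] - 1
        fr <- c(fr, new_cell)
        grown <- TRUE
        break
      }
      if (!grown) {
        # class enclosed: seed a fresh nucleus in unassigned space
        free <- which(assigned == 0L)
        new_cell <- if (length(free) == 1L) free else {
          free[sample.int(length(free), 1L)]
        }
        assigned[new_cell] <- i
        remaining[i] <- remaining[i] - 1
        fr <- c(fr, new_cell)
      }
      frontiers[[i]] <- fr
    }

    grid <- matrix(codes[assigned], nr, nc)
    raster <- landscape_raster(grid, cell_size_m = config$cell_size_m)
    if (config$n_water_bodies > 0) {
      raster <- add_water_bodies(raster, config$n_water_bodies)
    }
    if (config$n_roads > 0) {
      raster <- add_roads(raster, config$n_roads, config$road_width_cells)
    }
    raster
  })

  water_prop <- mean(out$grid == .code_water)
  if (water_prop >= 0.5) {
    stop(sprintf(
      "generated landscape is %.0f%% open water; pipeline rasters must be more than half terrestrial",
      100 * water_prop
    ), call. = FALSE)
  }
  out
}

#' Paint linear road corridors onto a raster
#'
#' Each road is an axis-aligned or diagonal straight polyline of the given
#' width spanning one full raster dimension; road cells overwrite whatever
#' class was present. With `n_roads = 0` the raster is returned unchanged.
#'
#' @param raster A [landscape_raster()].
#' @param n_roads Number of roads (>= 0).
#' @param width Road width in cells (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [generate_landscape()]).
#' @return A [landscape_raster()] with road cells set to the road class.
#' @export
add_roads <- function(raster, n_roads, width = 1, seed = NULL) {
  stopifnot(inherits(raster, "landscape_raster"))
  if (width < 1) stop("road width must be >= 1 cell", call. = FALSE)
  if (n_roads < 0) stop("`n_roads` must be >= 0", call. = FALSE)
  if (n_roads == 0) {
    return(raster)
  }
  run <- function() {
    g <- raster$grid
    nr <- nrow(g)
    nc <- ncol(g)
    for (k in seq_len(n_roads)) {
      orient <- sample(c("h", "v", "d"), 1L)
      if (orient == "h") {
        r0 <- sample.int(max(nr - width + 1L, 1L), 1L)
        g[r0:min(r0 + width - 1L, nr), ] <- .code_road
      } else if (orient == "v") {
        c0 <- sample.int(max(nc - width + 1L, 1L), 1L)
        g[, c0:min(c0 + width - 1L, nc)] <- .code_road
      } else {
        # diagonal spanning the column range, thickened vertically;
        # consecutive steps share a row or column, so the strip is
        # connected under the 8-neighbor labeling rule
        up <- sample(c(TRUE, FALSE), 1L)
        off <- sample.int(nr, 1L) - ifelse(up, 1L, nr)
        for (cc in seq_len(nc)) {
          rr <- if (up) off + cc else off + nr + 1L - cc
          rows <- rr:(rr + width - 1L)
          rows <- rows[rows >= 1L & rows <= nr]
          if (length(rows)) g[rows, cc] <- .code_road
        }
      }
    }
    landscape_raster(g, raster$cell_size_m)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Paint compact water bodies onto a raster
#'
#' Adds `n` roughly circular open-water patches at random centers with radii
#' drawn between 2 cells and ~1/8 of the shorter raster side, overwriting the
#' underlying classes.
#'
#' @inheritParams add_roads
#' @param n Number of water bodies.
#' @return A [landscape_raster()].
#' @export
add_water_bodies <- function(raster, n, seed = NULL) {
  stopifnot(inherits(raster, "landscape_raster"))
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  if (n == 0) {
    return(raster)
  }
  run <- function() {
    g <- raster$grid
    nr <- nrow(g)
    nc <- ncol(g)
    rows <- row(g)
    cols <- col(g)
    rmax <- max(2, floor(min(nr, nc) / 8))
    for (k in seq_len(n)) {
      cr <- sample.int(nr, 1L)
      cc <- sample.int(nc, 1L)
      rad <- runif(1, 2, rmax)
      g[(rows - cr)^2 + (cols - cc)^2 <= rad^2] <- .code_water
    }
    landscape_raster(g, raster$cell_size_m)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
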
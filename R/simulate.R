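#' Initialize an invasion
#'
#' Places the founding population — 50 second-year (adult) plants in each of
#' the 9 cells of a 3 x 3 block at the landscape center — on an empty state.
#' For even side lengths the block is centered on the cell at index
#' `floor((n + 1) / 2)` along each axis.
#'
#' @param raster A [landscape_raster()], at least 3 x 3.
#' @param founders Adults per founder cell (default 50).
#' @return An `invasion_state`: list with integer matrices `adults` and
#'   `juveniles` and the current `year` (0).
#' @export
#' @examples
#' st <- initialize_invasion(landscape_raster(matrix(1L, 9, 9)))
#' sum(st$adults) # 450
initialize_invasion <- function(raster, founders = 50) {
  stopifnot(inherits(raster, "landscape_raster"))
  nr <- nrow(raster$grid)
  nc <- ncol(raster$grid)
  if (nr < 3 || nc < 3) {
    stop("raster must be at least 3 x 3 to hold the founder block",
      call. = FALSE
    )
  }
  adults <- matrix(0L, nr, nc)
  cr <- floor((nr + 1) / 2)
  cc <- floor((nc + 1) / 2)
  adults[(cr - 1):(cr + 1), (cc - 1):(cc + 1)] <- as.integer(founders)
  structure(
    list(adults = adults, juveniles = matrix(0L, nr, nc), year = 0L),
    class = "invasion_state"
  )
}

#' @export
print.invasion_state <- function(x, ...) {
  cat(sprintf(
    "<invasion_state> year %d: %d adults in %d cells, %d juveniles\n",
    x$year, sum(x$adults), sum(x$adults > 0), sum(x$juveniles)
  ))
  invisible(x)
}

# road-network structures for corridor transport: per-road-cell graph
# distances (8-neighbor steps within connected road components) and, for each
# road cell, the nearest non-road cell (ties at radius 1 broken in the order
# N, E, S, W, NE, SE, SW, NW; farther ties row-major)
.road_network <- function(raster) {
  g <- raster$grid
  nr <- nrow(g)
  nc <- ncol(g)
  road <- which(g == .code_road)
  road_id <- matrix(0L, nr, nc)
  if (length(road) == 0) {
    return(list(
      road_id = road_id,
      dist = matrix(0L, 0, 0),
      exit = integer(0)
    ))
  }
  road_id[road] <- seq_along(road)
  rr <- (road - 1L) %% nr + 1L
  cc <- (road - 1L) %/% nr + 1L

  # 8-neighbor road subgraph
  n_road <- length(road)
  el <- list()
  key <- function(r, c) (c - 1L) * nr + r
  offs <- list(
    c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L)
  )
  for (d in offs) {
    r2 <- rr + d[1]
    c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- road_id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep)) {
      el[[length(el) + 1L]] <- cbind(which(ok)[keep], nb[keep])
    }
  }
  gr <- igraph::make_empty_graph(n_road, directed = FALSE)
  el <- do.call(rbind, el)
  if (!is.null(el) && nrow(el) > 0) {
    gr <- igraph::add_edges(gr, as.vector(t(el)))
  }
  D <- igraph::distances(gr)
  D[!is.finite(D)] <- -1
  storage.mode(D) <- "integer"

  # nearest non-road cell per road cell
  ord1 <- rbind(
    c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L),
    c(-1L, 1L), c(1L, 1L), c(1L, -1L), c(-1L, -1L)
  )
  exit <- integer(n_road)
  any_nonroad <- any(g != .code_road)
  for (i in seq_len(n_road)) {
    if (!any_nonroad) {
      exit[i] <- 0L
      next
    }
    found <- 0L
    rad <- 1L
    while (found == 0L) {
      if (rad == 1L) {
        for (j in seq_len(8L)) {
          r2 <- rr[i] + ord1[j, 1]
          c2 <- cc[i] + ord1[j, 2]
          if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            g[r2, c2] != .code_road) {
            found <- key(r2, c2)
            break
          }
        }
      } else {
        best <- Inf
        r_lo <- max(1L, rr[i] - rad)
        r_hi <- min(nr, rr[i] + rad)
        c_lo <- max(1L, cc[i] - rad)
        c_hi <- min(nc, cc[i] + rad)
        for (c2 in c_lo:c_hi) {
          for (r2 in r_lo:r_hi) {
            if (g[r2, c2] == .code_road) next
            d2 <- (r2 - rr[i])^2 + (c2 - cc[i])^2
            if (d2 < best) {
              best <- d2
              found <- key(r2, c2)
            }
          }
        }
      }
      rad <- rad + max(1L, rad)
      if (rad > max(nr, nc) * 2L && found == 0L) break
    }
    exit[i] <- found
  }
  list(road_id = road_id, dist = D, exit = exit)
}

#' Advance an invasion by one year
#'
#' Applies, in order: maturation of juveniles to adults; stochastic logistic
#' local growth (expected increment `r_i * growth_mult * N * (1 - N/K_i)`,
#' realized by Bernoulli rounding of the fractional part); seed production
#' (`fecundity` per adult) with log-normal dispersal scaled by
#' `dispersal_mult`; corridor transport of road-landing seeds along the
#' connected road network with probability `corridor_usage`; establishment of
#' seeds in unoccupied suitable cells with probability
#' `establishment_freq * r_i / r_grassland` (zero on roads, water, and
#' unsuitable land); and carrying-capacity truncation. The year advances by
#' one.
#'
#' @param state An `invasion_state`.
#' @param raster The [landscape_raster()] the state lives on.
#' @param params [habitat_params()].
#' @param traits A one-row trait tibble from [trait_set()].
#' @param kernel A [dispersal_kernel()].
#' @param road_network Optional precomputed road structures (internal reuse);
#'   computed from the raster when `NULL`.
#' @param kill_barrier_adults If `TRUE`, plants sitting on barrier habitat
#'   (possible only for founders) are removed this year.
#' @return The updated `invasion_state`.
#' @export
step_year <- function(state, raster, params = habitat_params(),
                      traits = trait_set(), kernel = dispersal_kernel(),
                      road_network = NULL, kill_barrier_adults = FALSE) {
  stopifnot(
    inherits(state, "invasion_state"), inherits(raster, "landscape_raster"),
    inherits(params, "habitat_params")
  )
  if (!all(dim(state$adults) == dim(raster$grid))) {
    stop("state and raster dimensions disagree", call. = FALSE)
  }
  if (any(state$adults < 0) || any(state$juveniles < 0)) {
    stop("corrupt state: negative counts", call. = FALSE)
  }
  if (is.null(road_network)) road_network <- .road_network(raster)
  out <- sim_step_cpp(
    state$adults, state$juveniles, raster$grid,
    r_eff = unname(params$r * traits$growth_mult),
    K = unname(params$k),
    rel_estab = unname(params$rel_estab),
    fecundity = params$fecundity,
    estab_freq = traits$establishment_freq,
    corridor_usage = traits$corridor_usage,
    meanlog = kernel$meanlog + log(traits$dispersal_mult),
    sdlog = kernel$sdlog,
    cell_size = raster$cell_size_m,
    road_id = road_network$road_id,
    road_dist = road_network$dist,
    road_exit = road_network$exit,
    kill_barrier_adults = kill_barrier_adults
  )
  structure(
    list(adults = out$adults, juveniles = out$juveniles,
         year = state$year + 1L),
    class = "invasion_state"
  )
}

#' Run a full invasion simulation
#'
#' Initializes the founder block and advances the state year by year,
#' recording the adult population total and the number of occupied cells
#' (cells with at least one adult) after every year. The trajectory has
#' `years + 1` rows (year 0 through `years`). Identical inputs and seed give
#' an identical trajectory.
#'
#' @inheritParams step_year
#' @param years Simulation horizon in years (default 100). Horizons below 31
#'   still run, but the 30-year transient metrics are computed over the
#'   available years and flagged.
#' @param seed Optional integer seed.
#' @param founders_on_unsuitable_die If `TRUE` (default), founders placed on
#'   barrier habitat die after `founder_lifespan` years.
#' @param founder_lifespan Years founders survive on barrier habitat.
#' @return A list of class `invasion_run`: `trajectory` (tibble with `year`,
#'   `population`, `occupied`, `total_cells`) and `summary` (the
#'   [summarize_trajectory()] tibble).
#' @export
#' @examples
#' r <- landscape_raster(matrix(1L, 16, 16))
#' run <- run_simulation(r, years = 35, seed = 1)
#' run$summary
run_simulation <- function(raster, params = habitat_params(),
                           traits = trait_set(),
                           kernel = dispersal_kernel(), years = 100,
                           seed = NULL,
                           founders_on_unsuitable_die = TRUE,
                           founder_lifespan = 5) {
  stopifnot(inherits(raster, "landscape_raster"), years >= 1)
  if (years < 31) {
    warning("horizon below 31 years: transient metrics use available years",
      call. = FALSE
    )
  }
  run <- function() {
    state <- initialize_invasion(raster)
    rn <- .road_network(raster)
    n_cells <- length(raster$grid)
    pop <- integer(years + 1)
    occ <- integer(years + 1)
    pop[1] <- sum(state$adults)
    occ[1] <- sum(state$adults > 0)
    for (t in seq_len(years)) {
      kill <- founders_on_unsuitable_die && (state$year + 1L) >= founder_lifespan
      state <- step_year(state, raster, params, traits, kernel,
        road_network = rn, kill_barrier_adults = kill
      )
      pop[t + 1] <- sum(state$adults)
      occ[t + 1] <- sum(state$adults > 0)
    }
    traj <- tibble::tibble(
      year = 0:years, population = pop, occupied = occ,
      total_cells = n_cells
    )
    structure(
      list(
        trajectory = traj,
        summary = summarize_trajectory(traj),
        final_state = state
      ),
      class = "invasion_run"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.invasion_run <- function(x, ...) {
  cat("<invasion_run>\n")
  print(x$summary)
  invisible(x)
}

#' Summarize an invasion trajectory into the four response metrics
#'
#' Computes the two transient metrics — the mean yearly landscape population
#' growth rate and the mean yearly increment of occupied-cell proportion,
#' both over the first 30 year-to-year transitions — and the two long-term
#' metrics: final occupied proportion and final mean adults per cell. Growth
#' ratios are undefined in years with zero population; those years are
#' skipped and counted in `skipped_years`.
#'
#' @param trajectory A tibble with columns `year`, `population`, `occupied`,
#'   `total_cells` (as produced by [run_simulation()]).
#' @param transient_years Number of initial transitions to average (30).
#' @return A one-row tibble: `expansion_rate`, `growth_rate`, `final_extent`,
#'   `final_population`, `skipped_years`, `transient_years`.
#' @export
#' @examples
#' traj <- tibble::tibble(
#'   year = 0:31, population = 450, occupied = 9, total_cells = 100
#' )
#' summarize_trajectory(traj)
summarize_trajectory <- function(trajectory, transient_years = 30) {
  need <- c("year", "population", "occupied", "total_cells")
  if (!all(need %in% names(trajectory))) {
    stop("trajectory must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(trajectory) < 2) {
    stop("trajectory must span at least one year", call. = FALSE)
  }
  n_cells <- trajectory$total_cells[1]
  n_trans <- min(transient_years, nrow(trajectory) - 1)
  N <- trajectory$population
  occ <- trajectory$occupied

  idx <- seq_len(n_trans)
  defined <- N[idx] > 0
  ratios <- N[idx + 1][defined] / N[idx][defined]
  growth <- if (length(ratios)) mean(ratios) else NA_real_
  expansion <- mean((occ[idx + 1] - occ[idx]) / n_cells)

  last <- nrow(trajectory)
  tibble::tibble(
    expansion_rate = expansion,
    growth_rate = growth,
    final_extent = occ[last] / n_cells,
    final_population = N[last] / n_cells,
    skipped_years = sum(!defined),
    transient_years = n_trans
  )
}

#' Simulate a grid of invasions
#'
#' Runs [run_simulation()] for every (landscape, trait combination) pair and
#' collects the four response metrics into a long tibble keyed by
#' `landscape_id` and `combo_id`. Per-job seeds are derived from `master_seed`
#' by a counter scheme (see [job_seed()]), so any subset of jobs reruns
#' identically.
#'
#' @param rasters Named list of [landscape_raster()] objects.
#' @param trait_grid A tibble from [build_trait_grid()] (or any subset with a
#'   `combo_id` column).
#' @inheritParams run_simulation
#' @param master_seed Integer master seed for per-job seeds.
#' @return A tibble: one row per job with ids, trait levels, the four
#'   responses, and `skipped_years`.
#' @export
simulate_invasions <- function(rasters, trait_grid,
                               params = habitat_params(),
                               kernel = dispersal_kernel(), years = 100,
                               master_seed = 1) {
  if (is.null(names(rasters))) {
    names(rasters) <- sprintf("landscape_%03d", seq_along(rasters))
  }
  jobs <- tidyr::expand_grid(
    landscape_id = names(rasters),
    combo_id = trait_grid$combo_id
  )
  jobs$job <- seq_len(nrow(jobs))
  purrr::pmap_dfr(jobs, function(landscape_id, combo_id, job) {
    traits <- trait_grid[trait_grid$combo_id == combo_id, ]
    run <- run_simulation(
      rasters[[landscape_id]],
      params = params, traits = traits, kernel = kernel,
      years = years, seed = job_seed(master_seed, job)
    )
    dplyr::bind_cols(
      tibble::tibble(landscape_id = landscape_id, combo_id = combo_id),
      traits[, c(
        "dispersal_mult", "growth_mult", "establishment_freq",
        "corridor_usage"
      )],
      run$summary[, c(
        "expansion_rate", "growth_rate", "final_extent",
        "final_population", "skipped_years"
      )]
    )
  })
}
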
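#' Habitat class registry
#'
#' The eleven land-cover categories used throughout the package, in the fixed
#' registry order that also defines the first eleven (composition) entries of
#' the landscape-metric vector. Codes 0--10 are a fixed bijection with the
#' class names; rasters may only contain these codes.
#'
#' @return A tibble with columns `code` (integer 0--10), `name` (snake-case
#'   identifier), `label` (human-readable), and `suitable` (logical; whether
#'   the invader can establish and grow there). Roads, open water, and
#'   unsuitable/developed land are barriers: they never hold plants.
#' @export
#' @examples
#' habitat_classes()
habitat_classes <- function() {
  tibble::tibble(
    code = 0:10,
    name = c(
      "unsuitable", "grassland", "deciduous_forest", "coniferous_forest",
      "mixed_forest", "pasture", "crop", "road", "wetland", "water",
      "shrubland"
    ),
    label = c(
      "Unsuitable", "Grassland", "Deciduous forest", "Coniferous forest",
      "Mixed forest", "Pastureland", "Cultivated cropland", "Road",
      "Wetland (riparian)", "Open water", "Shrubland"
    ),
    suitable = c(
      FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE
    )
  )
}

# fixed codes for the barrier classes
.code_unsuitable <- 0L
.code_grassland <- 1L
.code_road <- 7L
.code_water <- 9L

.barrier_codes <- function() c(.code_unsuitable, .code_road, .code_water)

#' Habitat-specific demographic parameters
#'
#' Per-class expansion rates and carrying capacities for the annual invasion
#' model, plus per-adult fecundity. Expansion rate `r` is the local logistic
#' growth rate of an established population in that class and, scaled
#' relative to grassland, also sets the establishment probability of seeds
#' arriving there. Grassland is the best habitat: its rate is maximal among
#' suitable classes and is never reduced. Roads, water, and unsuitable land
#' have `r = 0` and `K = 0` (absolute barriers).
#'
#' Defaults: `r` of 0.5/yr in grassland, other suitable classes scaled in
#' (0, 1] of that; `K` of 100 adults/cell in grassland, scaled by
#' `r_i / r_grassland` elsewhere; 200 seeds per adult per year. These were
#' chosen once so that, across the invader trait grid, outcomes span failure
#' through landscape-scale infestation.
#'
#' @param r Named numeric vector (names as in [habitat_classes()]) of per-class
#'   expansion rates per year. Barrier classes must be 0; grassland must be
#'   positive and maximal among suitable classes.
#' @param k Named numeric vector of carrying capacities (adults per cell), or
#'   `NULL` to scale `k_grassland` by `r_i / r_grassland`.
#' @param k_grassland Grassland carrying capacity used when `k` is `NULL`.
#' @param fecundity Seeds produced per adult per year.
#' @return An object of class `habitat_params`.
#' @export
#' @examples
#' p <- habitat_params()
#' p$r[["grassland"]]
habitat_params <- function(r = NULL, k = NULL, k_grassland = 100,
                           fecundity = 200) {
  hc <- habitat_classes()
  if (is.null(r)) {
    r <- c(
      unsuitable = 0, grassland = 0.5, deciduous_forest = 0.35,
      coniferous_forest = 0.25, mixed_forest = 0.3, pasture = 0.4,
      crop = 0.05, road = 0, wetland = 0.15, water = 0, shrubland = 0.3
    )
  }
  if (!all(hc$name %in% names(r))) {
    stop("`r` must be named with all 11 habitat class names", call. = FALSE)
  }
  r <- r[hc$name]
  if (any(r < 0)) stop("expansion rates must be >= 0", call. = FALSE)
  barriers <- hc$name[!hc$suitable]
  if (any(r[barriers] != 0)) {
    stop("barrier classes (road, water, unsuitable) must have r = 0",
      call. = FALSE
    )
  }
  if (r[["grassland"]] <= 0) {
    stop("grassland expansion rate must be positive", call. = FALSE)
  }
  if (any(r > r[["grassland"]])) {
    stop("grassland must have the maximal expansion rate", call. = FALSE)
  }
  if (is.null(k)) {
    k <- k_grassland * r / r[["grassland"]]
  } else {
    if (!all(hc$name %in% names(k))) {
      stop("`k` must be named with all 11 habitat class names", call. = FALSE)
    }
    k <- k[hc$name]
  }
  if (any(k < 0)) stop("carrying capacities must be >= 0", call. = FALSE)
  if (fecundity < 0) stop("fecundity must be >= 0", call. = FALSE)
  structure(
    list(
      r = r, k = k, fecundity = fecundity,
      rel_estab = r / r[["grassland"]]
    ),
    class = "habitat_params"
  )
}

#' @export
print.habitat_params <- function(x, ...) {
  cat("<habitat_params>\n")
  print(tibble::tibble(
    class = names(x$r), r = unname(x$r), k = unname(x$k),
    rel_establishment = unname(x$rel_estab)
  ))
  cat("fecundity:", x$fecundity, "seeds/adult/yr\n")
  invisible(x)
}

#' Invader trait set
#'
#' One scenario of the four invasiveness traits: multipliers on mean dispersal
#' distance and on habitat expansion rates, the frequency with which
#' accessible (colonizable) sites arise per arriving seed, and the proportion
#' of seeds landing on a road that travel along the road network.
#'
#' @param dispersal_mult Multiplier on the dispersal kernel's median distance.
#' @param growth_mult Multiplier on all habitat expansion rates.
#' @param establishment_freq Per-seed probability scale of establishment in an
#'   unoccupied suitable cell (further scaled by relative habitat quality).
#' @param corridor_usage Probability in \[0, 1\] that a seed landing on a road
#'   is transported along the connected road network.
#' @return A one-row tibble with the four trait columns.
#' @export
#' @examples
#' trait_set(dispersal_mult = 2, corridor_usage = 0)
trait_set <- function(dispersal_mult = 1, growth_mult = 1,
                      establishment_freq = 0.025, corridor_usage = 0.5) {
  stopifnot(
    dispersal_mult > 0, growth_mult >= 0,
    establishment_freq >= 0, establishment_freq <= 1,
    corridor_usage >= 0, corridor_usage <= 1
  )
  tibble::tibble(
    dispersal_mult = dispersal_mult, growth_mult = growth_mult,
    establishment_freq = establishment_freq, corridor_usage = corridor_usage
  )
}

#' Factorial grid of invader trait combinations
#'
#' Cartesian product of the four trait level sets used in the full factorial
#' design: dispersal and growth multipliers \{0.33, 0.5, 1, 1.5, 2\},
#' establishment frequencies \{0.005, 0.01, 0.025, 0.05\}, and corridor usage
#' \{0, 0.25, 0.5, 0.75, 1\} — 5 x 5 x 4 x 5 = 500 combinations, in
#' deterministic lexicographic order over the printed level orders.
#'
#' @param dispersal_levels,growth_levels,establishment_levels,corridor_levels
#'   Optional restricted level sets for reduced designs.
#' @return A tibble with `combo_id` and the four trait columns.
#' @export
#' @examples
#' nrow(build_trait_grid()) # 500
build_trait_grid <- function(dispersal_levels = c(0.33, 0.5, 1, 1.5, 2),
                             growth_levels = c(0.33, 0.5, 1, 1.5, 2),
                             establishment_levels = c(0.005, 0.01, 0.025, 0.05),
                             corridor_levels = c(0, 0.25, 0.5, 0.75, 1)) {
  grid <- tidyr::expand_grid(
    dispersal_mult = dispersal_levels,
    growth_mult = growth_levels,
    establishment_freq = establishment_levels,
    corridor_usage = corridor_levels
  )
  dplyr::mutate(grid,
    combo_id = sprintf("combo_%03d", dplyr::row_number()),
    .before = 1
  )
}

#' Log-normal dispersal kernel
#'
#' Seed displacement distances are log-normal; directions are uniform on
#' \[0, 2*pi). The kernel is parameterized by its median distance in meters
#' (the log-scale mean is `log(median_m)`). The trait-level dispersal
#' multiplier scales the median (and hence the mean displacement)
#' multiplicatively.
#'
#' @param median_m Median dispersal distance in meters.
#' @param log_sd Standard deviation on the log scale.
#' @return An object of class `dispersal_kernel`.
#' @export
dispersal_kernel <- function(median_m = 60, log_sd = 1) {
  stopifnot(median_m > 0, log_sd > 0)
  structure(
    list(meanlog = log(median_m), sdlog = log_sd, median_m = median_m),
    class = "dispersal_kernel"
  )
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf(
    "<dispersal_kernel> log-normal, median %.1f m, log-sd %.2f\n",
    x$median_m, x$sdlog
  ))
  invisible(x)
}
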
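test_that("initialization places the founder block at the center", {
  st <- initialize_invasion(landscape_raster(matrix(1L, 216, 216)))
  expect_identical(sum(st$adults), 450L)
  expect_identical(sum(st$adults > 0), 9L)
  expect_identical(st$year, 0L)

  st3 <- initialize_invasion(landscape_raster(matrix(1L, 3, 3)))
  expect_true(all(st3$adults == 50L))

  st10 <- initialize_invasion(landscape_raster(matrix(1L, 10, 10)))
  expect_identical(sum(st10$adults > 0), 9L)
  occ <- which(st10$adults > 0, arr.ind = TRUE)
  expect_identical(sort(unique(occ[, 1])), 4:6) # centered on floor((n+1)/2)

  expect_error(
    initialize_invasion(landscape_raster(matrix(1L, 2, 3))),
    "3 x 3"
  )
})

test_that("null dynamics leave the state unchanged except the year", {
  r <- landscape_raster(matrix(1L, 16, 16)) # K holds the founder density
  st <- initialize_invasion(r)
  p0 <- habitat_params(fecundity = 0)
  st2 <- withr::with_seed(1, step_year(
    st, r,
    params = p0, traits = trait_set(growth_mult = 0)
  ))
  expect_identical(st2$adults, st$adults)
  expect_identical(sum(st2$juveniles), 0L)
  expect_identical(st2$year, 1L)
})

test_that("zero establishment freezes the occupied set at the founders", {
  r <- landscape_raster(matrix(1L, 20, 20))
  run <- suppressWarnings(run_simulation(
    r,
    traits = trait_set(establishment_freq = 0), years = 25, seed = 2
  ))
  expect_true(all(run$trajectory$occupied == 9))
  expect_equal(run$summary$final_extent, 9 / 400)
})

test_that("trajectories have years + 1 rows and are seed-deterministic", {
  r <- landscape_raster(matrix(1L, 12, 12))
  run <- run_simulation(r, years = 100, seed = 3,
    traits = trait_set(establishment_freq = 0.005)
  )
  expect_identical(nrow(run$trajectory), 101L)
  run2 <- run_simulation(r, years = 100, seed = 3,
    traits = trait_set(establishment_freq = 0.005)
  )
  expect_identical(run$trajectory, run2$trajectory)
  expect_warning(run_simulation(r, years = 20, seed = 1), "31 years")
})

test_that("founders on barrier habitat die out and extent reaches zero", {
  r <- landscape_raster(matrix(0L, 15, 15))
  run <- suppressWarnings(run_simulation(r, years = 31, seed = 4))
  expect_equal(run$summary$final_extent, 0)
  expect_equal(run$summary$final_population, 0)
  # founders persist for the documented lifespan, then die
  expect_true(all(run$trajectory$population[1:4] == 450))
  expect_true(all(run$trajectory$population[6:31] == 0))
})

test_that("barrier classes never hold plants and K bounds suitable cells", {
  r <- mixed_raster(24)
  run <- suppressWarnings(run_simulation(
    r,
    traits = trait_set(
      dispersal_mult = 2, establishment_freq = 0.05, corridor_usage = 0.5
    ),
    years = 40, seed = 5
  ))
  fs <- run$final_state
  barrier <- r$grid %in% invadescape:::.barrier_codes()
  expect_true(all(fs$adults[barrier] == 0))
  expect_true(all(fs$juveniles[barrier] == 0))
  k <- habitat_params()$k
  expect_true(all(fs$adults <= k[r$grid + 1L] + 1)) # +1 for this year's recruit
  expect_true(all(fs$adults >= 0) && all(fs$juveniles >= 0))
})

test_that("growth-rate averaging skips undefined years and reports them", {
  traj <- tibble::tibble(
    year = 0:31, population = 450, occupied = 9, total_cells = 100
  )
  s <- summarize_trajectory(traj)
  expect_equal(s$growth_rate, 1)
  expect_equal(s$expansion_rate, 0)
  expect_identical(s$skipped_years, 0L)

  # occupancy grows one cell per year on a 100-cell landscape
  traj2 <- tibble::tibble(
    year = 0:31, population = 100 + 0:31, occupied = 9 + 0:31,
    total_cells = 100
  )
  expect_equal(summarize_trajectory(traj2)$expansion_rate, 0.01)

  # extinction at year 10
  pop <- c(rep(100, 10), rep(0, 22))
  traj3 <- tibble::tibble(
    year = 0:31, population = pop, occupied = ifelse(pop > 0, 5, 0),
    total_cells = 100
  )
  s3 <- summarize_trajectory(traj3)
  expect_equal(s3$final_extent, 0)
  expect_equal(s3$final_population, 0)
  expect_identical(s3$skipped_years, 20L) # transitions from years 10..29

  expect_error(summarize_trajectory(traj3[1, ]), "at least one year")
  expect_error(summarize_trajectory(tibble::tibble(year = 1)), "columns")
})

test_that("the factorial trait grid reproduces the printed design", {
  grid <- build_trait_grid()
  expect_identical(nrow(grid), 500L)
  expect_identical(nrow(dplyr::distinct(grid[, -1])), 500L)
  expect_setequal(unique(grid$dispersal_mult), c(0.33, 0.5, 1, 1.5, 2))
  expect_setequal(unique(grid$establishment_freq),
    c(0.005, 0.01, 0.025, 0.05)
  )
  one <- build_trait_grid(1, 1, 0.01, 0.5)
  expect_identical(nrow(one), 1L)
})

test_that("corridor transport moves seeds to habitat reachable only by road", {
  # a grassland island at the landscape center, a road running the full
  # width one row below it, and a remote grassland row hugging the road's
  # north side at its far end (road deposits resolve north-first); the
  # matrix is unsuitable, so the remote row is reachable by long road
  # transport or only a rare direct tail flight
  g <- matrix(0L, 9, 80)
  g[4:6, 38:42] <- 1L # island around the center (5, 40)
  g[7, ] <- 7L # road
  g[6, 1:12] <- 1L # remote row alongside the road's far end
  r <- landscape_raster(g)
  remote <- row(g) == 6 & col(g) <= 12

  reached <- function(usage, seed) {
    run <- suppressWarnings(run_simulation(
      r,
      traits = trait_set(corridor_usage = usage, establishment_freq = 0.05),
      years = 10, seed = seed
    ))
    sum(run$final_state$adults[remote] > 0)
  }
  withr::with_seed(7, {
    seeds <- sample.int(1e6, 200)
  })
  with_corridor <- mean(sapply(seeds, function(s) reached(1, s)))
  without <- mean(sapply(seeds, function(s) reached(0, s)))
  expect_gt(with_corridor, without)
})

test_that("responses increase statistically with the relevant traits", {
  r <- mixed_raster(24)
  reps <- 30
  mean_resp <- function(tr) {
    out <- sapply(seq_len(reps), function(s) {
      run <- suppressWarnings(run_simulation(
        r,
        traits = tr, years = 31, seed = 1000 + s
      ))
      c(run$summary$final_population, run$summary$final_extent,
        run$summary$expansion_rate)
    })
    rowMeans(out)
  }
  lo_g <- mean_resp(trait_set(growth_mult = 0.5))
  hi_g <- mean_resp(trait_set(growth_mult = 2))
  expect_gte(hi_g[1], lo_g[1]) # final population rises with growth

  lo_d <- mean_resp(trait_set(dispersal_mult = 0.5))
  hi_d <- mean_resp(trait_set(dispersal_mult = 2))
  expect_gte(hi_d[2], lo_d[2]) # final extent rises with dispersal
})

test_that("corrupt states and mismatched rasters are rejected", {
  r <- mixed_raster(16)
  st <- initialize_invasion(r)
  st$adults[1, 1] <- -1L
  expect_error(step_year(st, r), "negative")
  st2 <- initialize_invasion(mixed_raster(12))
  expect_error(step_year(st2, r), "dimensions")
})
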
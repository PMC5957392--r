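#' Deterministic per-job seeds
#'
#' Counter-based scheme deriving one 32-bit seed per job from the master
#' seed, so any subset of a job grid can be rerun identically: seed =
#' `(master * 1000003 + stream * 33331 + index * 7919) mod 2147483629`.
#' Streams separate the pipeline stages (landscape generation, simulation,
#' stage-1 and stage-2 regressions).
#'
#' @param master_seed Integer master seed.
#' @param index Job counter (any non-negative integer).
#' @param stream Stage stream id (default 0).
#' @return An integer seed below 2^31.
#' @export
job_seed <- function(master_seed, index, stream = 0) {
  as.integer(
    (as.double(master_seed) * 1000003 + stream * 33331 + index * 7919) %%
      2147483629
  )
}

#' Configure a full experiment
#'
#' Bundles every setting of the generate / simulate / metrics / lasso /
#' interaction pipeline. Two presets: `"smoke"` — 5 synthetic 64 x 64
#' landscapes spanning 5% to 80% grassland, 8 trait combinations, 40 years,
#' an 8-point shrinkage grid, and reduced MCMC — and `"paper"` — the
#' full-scale design: 1000 landscapes of 216 x 216 cells, the complete
#' 500-combination trait grid, 100 years, a 900/100 train/holdout split, 24
#' shrinkage rates, and 10,000-iteration chains.
#'
#' @param preset `"smoke"` or `"paper"`.
#' @param master_seed Integer master seed for all derived seeds.
#' @param n_landscapes,years Optional overrides.
#' @param trait_grid Optional trait grid override (tibble with `combo_id`).
#' @param taus,mcmc,holdout_frac,params,kernel Optional overrides.
#' @param landscape_configs Optional list of [landscape_config()] overriding
#'   the preset generator settings.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("smoke", "paper"), master_seed = 1,
                              n_landscapes = NULL, years = NULL,
                              trait_grid = NULL, taus = NULL, mcmc = NULL,
                              holdout_frac = NULL, params = NULL,
                              kernel = NULL, landscape_configs = NULL) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_landscapes <- n_landscapes %||% 1000L
    years <- years %||% 100L
    trait_grid <- trait_grid %||% build_trait_grid()
    taus <- taus %||% tau_grid_default()
    mcmc <- mcmc %||% mcmc_control(preset = "paper")
    holdout_frac <- holdout_frac %||% 0.1
    dim <- 216L
  } else {
    n_landscapes <- n_landscapes %||% 5L
    years <- years %||% 40L
    trait_grid <- trait_grid %||% build_trait_grid(
      dispersal_levels = c(0.5, 2),
      growth_levels = c(0.5, 2),
      establishment_levels = c(0.005, 0.025),
      corridor_levels = 0.5
    )
    taus <- taus %||% tau_grid_default(n = 8)
    mcmc <- mcmc %||% mcmc_control(preset = "reduced")
    holdout_frac <- holdout_frac %||% 0.2
    dim <- 64L
  }
  if (is.null(landscape_configs)) {
    landscape_configs <- default_landscape_configs(
      n_landscapes,
      n_rows = dim, n_cols = dim, master_seed = master_seed
    )
  }
  if (length(landscape_configs) != n_landscapes) {
    stop("`landscape_configs` must have one entry per landscape",
      call. = FALSE
    )
  }
  if (nrow(trait_grid) == 0) {
    stop("the trait grid is empty; nothing to simulate", call. = FALSE)
  }
  structure(
    list(
      preset = preset, master_seed = as.integer(master_seed),
      n_landscapes = as.integer(n_landscapes), years = as.integer(years),
      trait_grid = trait_grid, taus = taus, mcmc = mcmc,
      holdout_frac = holdout_frac,
      params = params %||% habitat_params(),
      kernel = kernel %||% dispersal_kernel(),
      landscape_configs = landscape_configs
    ),
    class = "experiment_config"
  )
}

#' Preset landscape generator settings for an experiment
#'
#' Builds `n` [landscape_config()]s spanning a gradient of grassland
#' abundance (5% to 80%), fragmentation (0.1 to 0.6), and road density (0 to
#' 2 corridors), with the non-grassland remainder split among cropland,
#' deciduous forest, pasture, water, and unsuitable land. This spread of
#' composition and structure is what gives the stage-1 regressions leverage.
#'
#' @param n Number of landscapes.
#' @param n_rows,n_cols Raster dimensions.
#' @param master_seed Master seed (landscape i uses stream-1 seed i).
#' @return A list of [landscape_config()].
#' @export
default_landscape_configs <- function(n, n_rows = 64, n_cols = 64,
                                      master_seed = 1) {
  grass <- seq(0.05, 0.8, length.out = n)
  # fragmentation and roads deliberately out of phase with the grassland
  # gradient so structure metrics are not proxies for composition
  frag <- rep(c(0.4, 0.1, 0.6, 0.25, 0.5), length.out = n)
  roads <- rep(c(1L, 0L, 2L, 1L, 0L), length.out = n)
  # the barrier remainder is split between unsuitable land and open water in
  # varying ratios, so no single class is a linear copy of the grassland
  # gradient; a small fixed share of secondary suitable habitat is kept
  unsuit_share <- rep(c(0.8, 0.55, 0.65, 0.45, 0.7), length.out = n)
  lapply(seq_len(n), function(i) {
    barrier <- max(0, 1 - grass[i] - 0.2)
    landscape_config(
      target_proportions = c(
        grassland = grass[i],
        crop = 0.10,
        deciduous_forest = 0.05,
        pasture = 0.05,
        unsuitable = unsuit_share[i] * barrier,
        water = (1 - unsuit_share[i]) * barrier
      ),
      fragmentation = frag[i],
      n_roads = roads[i], road_width_cells = 1,
      n_rows = n_rows, n_cols = n_cols,
      seed = job_seed(master_seed, i, stream = 1)
    )
  })
}

#' Enumerate the simulation jobs of an experiment
#'
#' One job per (landscape, trait combination) pair, each with its
#' deterministic seed. The full-scale preset enumerates 1000 x 500 = 500,000
#' jobs. Re-planning with the same master seed reproduces identical seeds.
#'
#' @param config An [experiment_config()].
#' @return A tibble with `job_id`, `landscape_id`, `combo_id`, `seed`.
#' @export
#' @examples
#' nrow(plan_experiment(experiment_config("smoke"))) # 5 * 8 = 40
plan_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  jobs <- tidyr::expand_grid(
    landscape_id = sprintf("landscape_%04d", seq_len(config$n_landscapes)),
    combo_id = config$trait_grid$combo_id
  )
  dplyr::mutate(jobs,
    job_id = dplyr::row_number(),
    seed = job_seed(config$master_seed, .data$job_id, stream = 2),
    .before = 1
  )
}

#' Run a full experiment
#'
#' Executes the pipeline end to end: generates the landscapes, computes the
#' 50-metric table, simulates every (landscape, trait combination) job,
#' fits the stage-1 Bayesian lasso (with shrinkage selection over the
#' configured grid) for every combination and response metric, and fits the
#' stage-2 trait-interaction model for every (response, landscape metric)
#' pair. All randomness derives from the master seed, so a rerun with an
#' identical config is identical.
#'
#' @param config An [experiment_config()].
#' @param outdir Optional output directory for CSV/asc serialization.
#' @param force Overwrite a non-empty `outdir`.
#' @param job_budget Warn when jobs x years exceeds this desk-scale budget.
#' @param progress Print per-stage progress messages.
#' @return A list of class `invasion_experiment`: `landscapes` (list of
#'   rasters), `metrics`, `responses`, `stage1` (long coefficient table),
#'   `stage1_meta` (per-fit shrinkage selection and convergence),
#'   `interactions` (stage-2 long table), and `manifest`.
#' @export
run_experiment <- function(config, outdir = NULL, force = FALSE,
                           job_budget = 1e6, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  jobs <- plan_experiment(config)
  if (nrow(jobs) * config$years > job_budget) {
    warning(sprintf(
      "%d jobs x %d years exceeds the desk-scale budget (%g); consider a reduced design",
      nrow(jobs), config$years, job_budget
    ), call. = FALSE)
  }
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
      stop("`outdir` exists and is not empty; use force = TRUE",
        call. = FALSE
      )
    }
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }

  say("generating %d landscapes", config$n_landscapes)
  landscapes <- lapply(config$landscape_configs, generate_landscape)
  names(landscapes) <- sprintf(
    "landscape_%04d", seq_len(config$n_landscapes)
  )

  say("computing landscape metrics")
  metrics <- compute_metric_table(landscapes)

  say("simulating %d invasion jobs", nrow(jobs))
  responses <- purrr::pmap_dfr(
    jobs,
    function(job_id, landscape_id, combo_id, seed) {
      traits <- config$trait_grid[config$trait_grid$combo_id == combo_id, ]
      run <- suppressWarnings(run_simulation(
        landscapes[[landscape_id]],
        params = config$params, traits = traits, kernel = config$kernel,
        years = config$years, seed = seed
      ))
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
    }
  )

  say("stage 1: shrinkage-selected lasso per (combination, response)")
  reg <- metric_registry()
  x <- as.matrix(metrics[, reg$name])
  rownames(x) <- metrics$landscape_id
  n_land <- nrow(x)
  n_val <- max(1L, round(config$holdout_frac * n_land))
  holdout_ids <- withr::with_seed(
    job_seed(config$master_seed, 0, stream = 3),
    sort(sample.int(n_land, n_val))
  )
  resp_names <- c(
    "expansion_rate", "growth_rate", "final_extent", "final_population"
  )
  combos <- config$trait_grid$combo_id
  stage1_rows <- list()
  meta_rows <- list()
  counter <- 0L
  for (combo in combos) {
    for (resp in resp_names) {
      counter <- counter + 1L
      sub <- responses[responses$combo_id == combo, ]
      y <- sub[[resp]][match(metrics$landscape_id, sub$landscape_id)]
      design <- suppressWarnings(
        lasso_design(x, y, holdout_ids = holdout_ids)
      )
      sel <- suppressMessages(select_tau(
        design,
        taus = config$taus, control = config$mcmc,
        seed = job_seed(config$master_seed, counter * 100L, stream = 3)
      ))
      td <- tidy(sel$fit)
      td <- td[!td$term %in% c("(Intercept)", "sigma"), ]
      full <- tibble::tibble(
        combo_id = combo, response = resp, metric = reg$name,
        estimate = 0, conf.low = 0, conf.high = 0, dropped = TRUE
      )
      idx <- match(td$term, full$metric)
      full$estimate[idx] <- td$estimate
      full$conf.low[idx] <- td$conf.low
      full$conf.high[idx] <- td$conf.high
      full$dropped[idx] <- FALSE
      stage1_rows[[counter]] <- full
      meta_rows[[counter]] <- tibble::tibble(
        combo_id = combo, response = resp, tau_star = sel$tau_star,
        boundary = sel$boundary, score = max(sel$curve$score),
        max_rhat = max(sel$fit$rhat, na.rm = TRUE),
        converged = sel$fit$converged
      )
    }
  }
  stage1 <- dplyr::bind_rows(stage1_rows)
  stage1_meta <- dplyr::bind_rows(meta_rows)

  say("stage 2: trait-interaction model per (response, metric)")
  traits_by_combo <- config$trait_grid
  if (nrow(traits_by_combo) < 8) {
    rlang::inform(
      "fewer than 8 trait combinations: stage 2 skipped explicitly"
    )
    interactions <- tibble::tibble(
      response = character(), metric = character(), position = integer(),
      trait = character(), estimate = numeric(), conf.low = numeric(),
      conf.high = numeric(), significant = logical()
    )
    fit_rows <- tibble::tibble(fit = list())
    return(finish_experiment(
      landscapes, metrics, responses, stage1, stage1_meta, interactions,
      fit_rows, config, outdir
    ))
  }
  fit_rows <- tidyr::expand_grid(response = resp_names, metric = reg$name)
  counter2 <- 0L
  fit_rows$fit <- purrr::pmap(fit_rows, function(response, metric) {
    counter2 <<- counter2 + 1L
    bh <- stage1[stage1$response == response & stage1$metric == metric, ]
    dat <- dplyr::left_join(
      traits_by_combo, bh[, c("combo_id", "estimate")],
      by = "combo_id"
    )
    dat$beta_hat <- dat$estimate
    suppressMessages(fit_interaction_model(
      dat,
      control = config$mcmc,
      seed = job_seed(config$master_seed, counter2, stream = 4)
    ))
  })
  interactions <- interaction_table(fit_rows)
  finish_experiment(
    landscapes, metrics, responses, stage1, stage1_meta, interactions,
    fit_rows, config, outdir
  )
}

finish_experiment <- function(landscapes, metrics, responses, stage1,
                              stage1_meta, interactions, fit_rows, config,
                              outdir) {
  manifest <- tibble::tibble(
    stage = c("landscapes", "metrics", "simulations", "stage1", "stage2"),
    n_items = c(
      length(landscapes), nrow(metrics), nrow(responses),
      nrow(stage1_meta), nrow(fit_rows)
    ),
    seed_stream = 1:5 - 1L,
    master_seed = config$master_seed
  )
  out <- structure(
    list(
      landscapes = landscapes, metrics = metrics, responses = responses,
      stage1 = stage1, stage1_meta = stage1_meta,
      interactions = interactions, manifest = manifest, config = config
    ),
    class = "invasion_experiment"
  )
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' @export
print.invasion_experiment <- function(x, ...) {
  cat("<invasion_experiment>\n")
  print(x$manifest)
  invisible(x)
}

#' Serialize experiment outputs to a directory
#'
#' Writes the metric, response, stage-1, interaction, and manifest tables as
#' CSV and each landscape as an ESRI ASCII grid.
#'
#' @param experiment An `invasion_experiment`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  wr(experiment$metrics, "metrics.csv")
  wr(experiment$responses, "responses.csv")
  wr(experiment$stage1, "stage1_coefficients.csv")
  wr(experiment$stage1_meta, "stage1_meta.csv")
  wr(experiment$interactions, "interactions.csv")
  wr(experiment$manifest, "manifest.csv")
  for (id in names(experiment$landscapes)) {
    write_ascii_grid(
      experiment$landscapes[[id]], file.path(outdir, paste0(id, ".asc"))
    )
  }
  invisible(outdir)
}
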
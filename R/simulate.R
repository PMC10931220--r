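#' Configuration for a synthetic live-trapping study
#'
#' Defines the design and biology of a virtual multi-year CMR study of a
#' small-mammal community: 24 one-hectare plots, a 7 x 8 trap grid per plot
#' checked twice a day for 4 consecutive days, in spring, summer and autumn
#' of each of 5 years. Per species, plot occupancy is drawn from a
#' symmetric Dirichlet whose concentration `occupancy_alpha` acts as an
#' evenness dial mapping directly to expected spatial niche breadth;
#' individuals persist across sessions with probability `survival`
#' (optionally a different `winter_survival` across the year boundary, 0
#' emulating obligate hibernators), and are detected per trap check with
#' probability `p_capture`.
#'
#' @param n_plots Number of plots.
#' @param grid_rows,grid_cols Trap grid dimensions per plot.
#' @param n_days Consecutive trapping days per session.
#' @param years Vector of study years.
#' @param seasons Trapped seasons in chronological order.
#' @param species Species codes.
#' @param abundance Named expected total abundance per species per season
#'   (summed over all plots).
#' @param occupancy_alpha Named Dirichlet concentration per species.
#' @param p_capture Per-check detection probability.
#' @param survival Between-session survival probability within a year.
#' @param winter_survival Survival across the winter gap (defaults to
#'   `survival`).
#' @param effective_area_ha Effective trapped area per plot (ha).
#' @param buffer_session Add one trailing session after the last study
#'   year so the bracketing term of MNKA is informed at the study end.
#' @param env_links Named list: for each linked factor acronym, a named
#'   coefficient vector over species codes linking plot-level factor values
#'   to species density.
#' @param env_noise_sd Gaussian noise sd added to each latent plot-level
#'   factor value.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plots = 24, grid_rows = 7, grid_cols = 8,
                       n_days = 4, years = 2017:2021,
                       seasons = c("spring", "summer", "autumn"),
                       species = c("SZ", "WZ", "MZ", "ZW"),
                       abundance = c(SZ = 60, WZ = 40, MZ = 30, ZW = 90),
                       occupancy_alpha = c(SZ = 3, WZ = 3, MZ = 0.8, ZW = 8),
                       p_capture = 0.25, survival = 0.5,
                       winter_survival = NULL, effective_area_ha = 1,
                       buffer_session = FALSE,
                       env_links = list(AH.S = c(ZW = 0.4)),
                       env_noise_sd = 1) {
  if (p_capture < 0 || p_capture > 1) abort("`p_capture` must be in [0, 1]")
  if (survival < 0 || survival > 1) abort("`survival` must be in [0, 1]")
  if (any(occupancy_alpha <= 0)) abort("`occupancy_alpha` must be positive")
  if (any(abundance < 0)) abort("`abundance` must be non-negative")
  if (is.null(winter_survival)) winter_survival <- survival
  structure(
    list(
      n_plots = n_plots, grid_rows = grid_rows, grid_cols = grid_cols,
      n_days = n_days, years = years, seasons = seasons, species = species,
      abundance = abundance, occupancy_alpha = occupancy_alpha,
      p_capture = p_capture, survival = survival,
      winter_survival = winter_survival,
      effective_area_ha = effective_area_ha,
      buffer_session = buffer_session,
      env_links = env_links, env_noise_sd = env_noise_sd
    ),
    class = "sim_config"
  )
}

#' Total trapping effort of a design
#'
#' Trap-days = traps per plot x plots x days per session x sessions:
#' the default design gives 56 x 24 x 4 x 3 x 5 = 80,640 cage-days.
#'
#' @param config A [sim_config()].
#' @return Integer number of cage-days.
#' @export
trap_effort <- function(config) {
  config$grid_rows * config$grid_cols * config$n_plots * config$n_days *
    length(config$seasons) * length(config$years)
}

rdirichlet1 <- function(alpha, k) {
  g <- rgamma(k, shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a capture-mark-recapture study
#'
#' Generates a long-format capture-record table with known latent truth.
#' For each species and year, plot occupancy weights are drawn from a
#' symmetric Dirichlet; each season the target per-plot abundance is
#' allocated multinomially, survivors from the previous session are kept
#' with the configured survival probability (individuals are plot-faithful)
#' and the shortfall is filled with newly recruited, newly tagged
#' individuals. Every alive individual is then exposed to `n_days` x 2
#' trap checks with independent per-check detection.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the records exactly.
#'
#' @return A list with `captures` (tibble in the capture-record schema) and
#'   `truth` (list: `abundance` tibble of true alive counts per species,
#'   plot and session; `occupancy` tibble of the Dirichlet weights and
#'   their exact breadth per species and year; the `config`; total
#'   `trap_days`).
#' @export
simulate_study <- function(config, seed = 1L) {
  set.seed(seed)
  sessions <- tidyr::expand_grid(
    year = config$years, season = factor(config$seasons,
                                         levels = config$seasons)
  )
  sessions <- dplyr::arrange(sessions, .data$year, .data$season)
  if (config$buffer_session) {
    sessions <- dplyr::bind_rows(sessions, tibble::tibble(
      year = max(config$years) + 1L,
      season = factor(config$seasons[1], levels = config$seasons)
    ))
  }
  plots <- sprintf("P%02d", seq_len(config$n_plots))

  occupancy <- tidyr::expand_grid(species = config$species,
                                  year = unique(sessions$year))
  occupancy$weights <- purrr::map(occupancy$species, function(sp) {
    rdirichlet1(config$occupancy_alpha[[sp]], config$n_plots)
  })
  occupancy$breadth_true <- purrr::map_dbl(
    occupancy$weights, ~ breadth_index(.x)
  )

  next_id <- setNames(rep(1L, length(config$species)), config$species)
  # alive[[species]][[plot]] = character vector of ids
  alive <- lapply(config$species, function(sp) {
    setNames(vector("list", config$n_plots), plots)
  })
  names(alive) <- config$species

  rec_list <- list()
  truth_list <- list()
  prev_year <- NULL
  for (s in seq_len(nrow(sessions))) {
    yr <- sessions$year[s]
    sn <- as.character(sessions$season[s])
    surv_p <- if (!is.null(prev_year) && yr != prev_year) {
      config$winter_survival
    } else {
      config$survival
    }
    for (sp in config$species) {
      w <- occupancy$weights[occupancy$species == sp &
                               occupancy$year == yr][[1]]
      n_total <- rpois(1, config$abundance[[sp]])
      target <- as.vector(stats::rmultinom(1, n_total, w))
      for (j in seq_len(config$n_plots)) {
        prev <- alive[[sp]][[plots[j]]]
        survivors <- if (s > 1 && length(prev) > 0) {
          prev[stats::runif(length(prev)) < surv_p]
        } else {
          character(0)
        }
        shortfall <- max(0L, target[j] - length(survivors))
        recruits <- character(0)
        if (shortfall > 0) {
          recruits <- sprintf("%s-%06d", sp,
                              seq(next_id[[sp]], length.out = shortfall))
          next_id[[sp]] <- next_id[[sp]] + shortfall
        }
        now <- c(survivors, recruits)
        alive[[sp]][[plots[j]]] <- now
        truth_list[[length(truth_list) + 1]] <- tibble::tibble(
          species = sp, plot_id = plots[j], year = yr, season = sn,
          n_true = length(now)
        )
        if (length(now) == 0) next
        n_checks <- config$n_days * 2L
        caught <- matrix(
          stats::runif(length(now) * n_checks) < config$p_capture,
          nrow = length(now)
        )
        hits <- which(caught, arr.ind = TRUE)
        if (nrow(hits) == 0) next
        rec_list[[length(rec_list) + 1]] <- tibble::tibble(
          year = yr, season = sn, plot_id = plots[j],
          day = (hits[, "col"] - 1L) %/% 2L + 1L,
          check = ifelse(hits[, "col"] %% 2L == 1L, "morning", "afternoon"),
          station_row = sample(0:(config$grid_rows - 1L), nrow(hits),
                               replace = TRUE),
          station_col = sample(0:(config$grid_cols - 1L), nrow(hits),
                               replace = TRUE),
          species = sp, individual_id = now[hits[, "row"]]
        )
      }
    }
    prev_year <- yr
  }

  captures <- if (length(rec_list) > 0) {
    dplyr::bind_rows(rec_list)
  } else {
    tibble::tibble(
      year = integer(), season = character(), plot_id = character(),
      day = integer(), check = character(), station_row = integer(),
      station_col = integer(), species = character(),
      individual_id = character()
    )
  }
  truth <- list(
    abundance = dplyr::bind_rows(truth_list),
    occupancy = occupancy,
    config = config,
    trap_days = trap_effort(config)
  )
  list(captures = captures, truth = truth)
}

# Default latent plot-level baselines for the continuous habitat factors
# emitted by simulate_environment (units as in the factor table).
ENV_BASELINES <- c(
  AH.S = 40, AH.G = 10, Den.S = 20, Den.G = 50, TC.S = 15,
  TB.S = 30, TB.G = 20,
  HSL1 = 5, HSL2 = 7, HSL3 = 9, HSL4 = 11,
  YD1 = 10, YD2 = 14, YD3 = 18, YD4 = 22
)

#' Simulate the environmental data bundle for a study
#'
#' Generates shrub quadrat, herb quadrat, soil and monthly meteorology
#' tables for the plots and sessions of a simulated study. Each linked
#' factor's latent plot-level value is baseline + sum(coefficient x true
#' species density) + Gaussian noise; unlinked continuous factors are
#' baseline + noise. Raw records are constructed so that plot-level
#' aggregation (see [assemble_factor_table()]) recovers the latent value
#' exactly for the continuous factors (heights, soil, biomass); count-based
#' factors (densities, diversity indices) are emergent from the generated
#' counts.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element returned by [simulate_study()].
#' @param seed Integer seed.
#'
#' @return A list with `shrub`, `herb`, `soil`, `meteo` tibbles and
#'   `latent` (the per-plot latent factor values, for recovery tests).
#' @export
simulate_environment <- function(config, truth, seed = 1L) {
  set.seed(seed)
  dens <- tidyr::pivot_wider(
    truth$abundance, names_from = "species", values_from = "n_true",
    values_fill = 0
  )
  dens <- dens[dens$year %in% config$years, ]
  n_cells <- nrow(dens)

  latent <- dens[, c("plot_id", "year", "season")]
  for (f in names(ENV_BASELINES)) {
    val <- rep(ENV_BASELINES[[f]], n_cells)
    link <- config$env_links[[f]]
    if (!is.null(link)) {
      for (sp in names(link)) {
        val <- val + link[[sp]] *
          dens[[sp]] / config$effective_area_ha
      }
    }
    val <- val + rnorm(n_cells, 0, config$env_noise_sd)
    latent[[f]] <- pmax(val, 0.01)
  }

  shrub_species <- c("Nitraria", "Reaumuria")
  herb_species <- c("Stipa", "Allium", "Cleistogenes")
  shrub <- tidyr::expand_grid(
    latent[, c("plot_id", "year", "season")],
    quadrat_id = paste0("SQ", 1:3),
    species = shrub_species
  )
  shrub <- dplyr::left_join(shrub, latent, by = c("plot_id", "year", "season"))
  ns <- length(shrub_species)
  shrub <- dplyr::mutate(
    shrub,
    quadrat_area = 100,
    count = rpois(dplyr::n(), .data$Den.S / ns),
    height_large = .data$AH.S,
    height_medium = .data$AH.S,
    height_small = .data$AH.S,
    # per-species canopy radius chosen so summed coverage tracks TC.S
    canopy_radius = 100 * sqrt(
      .data$TC.S / ns / (3.14 * pmax(.data$count, 0.5))
    ),
    branch_fraction = 0.3,
    # per-species dry weight chosen so summed biomass tracks TB.S
    dry_weight = .data$TB.S / ns * 100 / (0.3 * pmax(.data$count, 0.5))
  )
  shrub <- shrub[, c("plot_id", "season", "year", "quadrat_id",
                     "quadrat_area", "species", "count", "height_large",
                     "height_medium", "height_small", "canopy_radius",
                     "branch_fraction", "dry_weight")]

  herb <- tidyr::expand_grid(
    latent[, c("plot_id", "year", "season")],
    quadrat_id = paste0("HQ", 1:3),
    species = herb_species
  )
  herb <- dplyr::left_join(herb, latent, by = c("plot_id", "year", "season"))
  nh <- length(herb_species)
  herb <- dplyr::mutate(
    herb,
    quadrat_area = 1,
    height = .data$AH.G,
    count = rpois(dplyr::n(), .data$Den.G / nh),
    dry_weight = .data$TB.G / nh
  )
  herb <- herb[, c("plot_id", "season", "year", "quadrat_id",
                   "quadrat_area", "species", "height", "count",
                   "dry_weight")]

  soil <- tidyr::expand_grid(
    latent[, c("plot_id", "year", "season")],
    layer = 1:4
  )
  soil <- dplyr::left_join(soil, latent, by = c("plot_id", "year", "season"))
  soil$moisture_pct <- purrr::map2_dbl(
    seq_len(nrow(soil)), soil$layer,
    function(i, l) soil[[paste0("HSL", l)]][i]
  )
  soil$hardness <- purrr::map2_dbl(
    seq_len(nrow(soil)), soil$layer,
    function(i, l) soil[[paste0("YD", l)]][i]
  )
  soil <- soil[, c("plot_id", "season", "year", "layer", "moisture_pct",
                   "hardness")]

  meteo <- tidyr::expand_grid(year = config$years, month = 1:12)
  meteo <- dplyr::mutate(
    meteo,
    WD = 8 + 14 * sin((.data$month - 4) / 12 * 2 * pi) +
      rnorm(dplyr::n(), 0, 1.5),
    SD = 40 + 10 * sin((.data$month - 7) / 12 * 2 * pi) +
      rnorm(dplyr::n(), 0, 3),
    RZ = 260 + 40 * sin((.data$month - 6) / 12 * 2 * pi) +
      rnorm(dplyr::n(), 0, 10)
  )

  list(shrub = shrub, herb = herb, soil = soil, meteo = meteo,
       latent = latent)
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper: [simulate_study()] plus [simulate_environment()].
#'
#' @inheritParams simulate_study
#' @return A list with `captures`, `shrub`, `herb`, `soil`, `meteo`,
#'   `truth`, `latent`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  study <- simulate_study(config, seed)
  env <- simulate_environment(config, study$truth, seed + 1L)
  c(list(captures = study$captures, truth = study$truth), env)
}
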
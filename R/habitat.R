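#' Average shrub height over the three height classes
#'
#' AH = (LH + MH + SH)/3, the mean of the large, medium and small height
#' classes recorded for each shrub species in a quadrat (cm). Missing
#' classes are excluded from the mean when `na.rm = TRUE`.
#'
#' @param LH,MH,SH Heights (cm) of the large, medium and small class.
#' @param na.rm Drop missing classes instead of propagating `NA`.
#' @return Mean height in cm.
#' @export
average_height <- function(LH, MH, SH, na.rm = FALSE) {
  h <- cbind(LH, MH, SH)
  if (any(h < 0, na.rm = TRUE)) abort("heights must be non-negative")
  rowMeans(h, na.rm = na.rm)
}

#' Shrub density on a 100 m2 basis
#'
#' Den = IN / 100 m2: the individual count normalized to the standard shrub
#' quadrat area.
#'
#' @param count Number of individuals (IN).
#' @param area_m2 Area actually surveyed, in m2 (default 100).
#' @return Individuals per 100 m2.
#' @export
shrub_density <- function(count, area_m2 = 100) {
  if (any(area_m2 <= 0)) abort("`area_m2` must be positive")
  if (any(count < 0)) abort("`count` must be non-negative")
  count / area_m2 * 100
}

#' Per-species shrub coverage
#'
#' C = (3.14 x SR^2 x Den) / 100 m2, expressed as a percentage of ground
#' covered. The canopy radius SR is recorded in cm and converted to metres
#' internally; the constant 3.14 is used verbatim rather than `pi`.
#'
#' @param SR_cm Canopy radius in cm.
#' @param Den Density in individuals per 100 m2.
#' @return Coverage in percent.
#' @export
species_coverage <- function(SR_cm, Den) {
  if (any(SR_cm < 0)) abort("`SR_cm` must be non-negative")
  # (3.14 * SR_m^2 * Den) / 100 m2 as a fraction, times 100 for percent:
  # the two factors of 100 cancel.
  3.14 * (SR_cm / 100)^2 * Den
}

#' Total shrub coverage of a quadrat
#'
#' TC.S = sum of the per-species coverages. Overlapping canopies can push
#' the total above 100 percent; that is reported as-is with a warning.
#'
#' @param per_species_C Vector of per-species coverages (percent).
#' @return Total coverage in percent.
#' @export
total_coverage <- function(per_species_C) {
  if (any(per_species_C < 0)) abort("coverages must be non-negative")
  tc <- sum(per_species_C)
  if (tc > 100) warn("total coverage exceeds 100% (overlapping canopies)")
  tc
}

#' Shrub biomass per unit area
#'
#' TB = (P x DW x Den) / 100 in g/m2, where P is the sampled fraction of
#' current-year branches, DW the dry weight (g) per individual and Den the
#' density per 100 m2.
#'
#' @param P Sampling proportion in \[0, 1\].
#' @param DW Dry weight in g.
#' @param Den Density per 100 m2.
#' @return Biomass in g/m2.
#' @export
shrub_biomass <- function(P, DW, Den) {
  if (any(P < 0 | P > 1)) abort("`P` must be within [0, 1]")
  if (any(DW < 0) || any(Den < 0)) abort("`DW` and `Den` must be non-negative")
  P * DW * Den / 100
}

#' Shannon, Gini-Simpson and Pielou diversity of a community
#'
#' Standard forms: Shannon H = -sum p ln p; Gini-Simpson D = 1 - sum p^2;
#' Pielou evenness E = H / ln S with S the number of species present
#' (undefined, `NaN`, for a single species).
#'
#' @param abundances Non-negative abundance vector with positive sum.
#' @return A one-row tibble with columns `shannon`, `simpson`, `pielou`.
#' @export
diversity_indices <- function(abundances) {
  if (any(abundances < 0)) abort("abundances must be non-negative")
  total <- sum(abundances)
  if (total == 0) abort("all-zero abundance vector")
  p <- abundances[abundances > 0] / total
  s <- length(p)
  h <- -sum(p * log(p))
  tibble::tibble(
    shannon = h,
    simpson = 1 - sum(p^2),
    pielou = if (s > 1) h / log(s) else NaN
  )
}

# ---- plot-level aggregation --------------------------------------------

aggregate_shrub <- function(shrub) {
  shrub <- tibble::as_tibble(shrub)
  shrub$season <- as_season(shrub$season)
  per_rec <- dplyr::mutate(
    shrub,
    AH = average_height(.data$height_large, .data$height_medium,
                        .data$height_small, na.rm = TRUE),
    Den = shrub_density(.data$count, .data$quadrat_area),
    C = species_coverage(.data$canopy_radius, .data$Den),
    TB = shrub_biomass(.data$branch_fraction, .data$dry_weight, .data$Den)
  )
  per_quadrat <- dplyr::summarise(
    dplyr::group_by(per_rec, .data$plot_id, .data$season, .data$year,
                    .data$quadrat_id),
    AH.S = mean(.data$AH),
    Den.S = sum(.data$Den),
    TC.S = sum(.data$C),
    TB.S = sum(.data$TB),
    .groups = "drop"
  )
  means <- dplyr::summarise(
    dplyr::group_by(per_quadrat, .data$plot_id, .data$season, .data$year),
    dplyr::across(c("AH.S", "Den.S", "TC.S", "TB.S"), mean),
    .groups = "drop"
  )
  div <- dplyr::summarise(
    dplyr::group_by(shrub, .data$plot_id, .data$season, .data$year),
    {
      counts <- tapply(.data$count, .data$species, sum)
      if (sum(counts) == 0) {
        tibble::tibble(D.S = NA_real_, E.S = NA_real_, H.S = NA_real_)
      } else {
        d <- diversity_indices(counts)
        tibble::tibble(D.S = d$simpson, E.S = d$pielou, H.S = d$shannon)
      }
    },
    .groups = "drop"
  )
  dplyr::left_join(means, div, by = c("plot_id", "season", "year"))
}

aggregate_herb <- function(herb) {
  herb <- tibble::as_tibble(herb)
  herb$season <- as_season(herb$season)
  per_quadrat <- dplyr::summarise(
    dplyr::group_by(herb, .data$plot_id, .data$season, .data$year,
                    .data$quadrat_id),
    AH.G = mean(.data$height),
    Den.G = sum(.data$count) / .data$quadrat_area[1],
    TB.G = sum(.data$dry_weight),
    .groups = "drop"
  )
  means <- dplyr::summarise(
    dplyr::group_by(per_quadrat, .data$plot_id, .data$season, .data$year),
    dplyr::across(c("AH.G", "Den.G", "TB.G"), mean),
    .groups = "drop"
  )
  div <- dplyr::summarise(
    dplyr::group_by(herb, .data$plot_id, .data$season, .data$year),
    {
      counts <- tapply(.data$count, .data$species, sum)
      if (sum(counts) == 0) {
        tibble::tibble(D.G = NA_real_, E.G = NA_real_, H.G = NA_real_)
      } else {
        d <- diversity_indices(counts)
        tibble::tibble(D.G = d$simpson, E.G = d$pielou, H.G = d$shannon)
      }
    },
    .groups = "drop"
  )
  dplyr::left_join(means, div, by = c("plot_id", "season", "year"))
}

aggregate_soil <- function(soil) {
  soil <- tibble::as_tibble(soil)
  soil$season <- as_season(soil$season)
  layer_means <- dplyr::summarise(
    dplyr::group_by(soil, .data$plot_id, .data$season, .data$year,
                    .data$layer),
    moisture = mean(.data$moisture_pct),
    hardness = mean(.data$hardness),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    layer_means,
    names_from = "layer",
    values_from = c("moisture", "hardness"),
    names_glue = "{.value}{layer}"
  )
  names(wide) <- sub("^moisture", "HSL", names(wide))
  names(wide) <- sub("^hardness", "YD", names(wide))
  expected <- c(paste0("HSL", 1:4), paste0("YD", 1:4))
  absent <- setdiff(expected, names(wide))
  if (length(absent) > 0) {
    warn(paste0("missing soil layer column(s): ", paste(absent, collapse = ", ")))
    for (col in absent) wide[[col]] <- NA_real_
  }
  wide[, c("plot_id", "season", "year", expected)]
}

aggregate_rodents <- function(rodent_mnka) {
  per_sp <- tidyr::pivot_wider(
    rodent_mnka[, c("plot_id", "season", "year", "species", "mnka")],
    names_from = "species", values_from = "mnka", values_fill = 0,
    names_sort = TRUE
  )
  div <- dplyr::summarise(
    dplyr::group_by(rodent_mnka, .data$plot_id, .data$season, .data$year),
    {
      counts <- tapply(.data$mnka, .data$species, sum)
      if (sum(counts) == 0) {
        tibble::tibble(D.R = NA_real_, E.R = NA_real_, H.R = NA_real_)
      } else {
        d <- diversity_indices(counts)
        tibble::tibble(D.R = d$simpson, E.R = d$pielou, H.R = d$shannon)
      }
    },
    .groups = "drop"
  )
  dplyr::left_join(div, per_sp, by = c("plot_id", "season", "year"))
}

#' Assemble the plot-by-factor habitat table
#'
#' Joins all environmental data sources into one row per (plot, season,
#' year) with the 31 analysis factors as columns: 7 biotic (rodent
#' Simpson/Pielou/Shannon indices D.R, E.R, H.R and per-species population
#' sizes) and 24 abiotic (shrub and grass structure and diversity, four
#' soil moisture and four soil hardness layers, and the three monthly
#' meteorological variables WD, SD, RZ joined via the trapping month of
#' each season). Quadrat replicates are averaged per plot; missing cells
#' are flagged `NA` with a warning, never imputed.
#'
#' @param shrub Shrub quadrat table: `plot_id`, `season`, `year`,
#'   `quadrat_id`, `quadrat_area` (m2), `species`, `count`, `height_large`,
#'   `height_medium`, `height_small` (cm), `canopy_radius` (cm),
#'   `branch_fraction`, `dry_weight` (g).
#' @param herb Herb quadrat table: `plot_id`, `season`, `year`,
#'   `quadrat_id`, `quadrat_area`, `species`, `height`, `count`,
#'   `dry_weight`.
#' @param soil Soil table: `plot_id`, `season`, `year`, `layer` (1-4),
#'   `moisture_pct`, `hardness`.
#' @param meteo Monthly meteorology: `year`, `month`, `WD` (mean
#'   temperature), `SD` (mean relative humidity), `RZ` (sunshine duration).
#' @param rodent_mnka Output of [mnka_table()].
#' @param season_months Named map from season to trapping month for the
#'   meteorological join.
#'
#' @return A tibble keyed by `plot_id`, `season`, `year` with the factor
#'   columns described above.
#' @export
assemble_factor_table <- function(shrub, herb, soil, meteo, rodent_mnka,
                                  season_months = SEASON_MONTHS) {
  rod <- aggregate_rodents(rodent_mnka)
  sh <- aggregate_shrub(shrub)
  hb <- aggregate_herb(herb)
  so <- aggregate_soil(soil)

  out <- dplyr::full_join(rod, sh, by = c("plot_id", "season", "year"))
  out <- dplyr::full_join(out, hb, by = c("plot_id", "season", "year"))
  out <- dplyr::full_join(out, so, by = c("plot_id", "season", "year"))

  months_needed <- unname(season_months[as.character(out$season)])
  meteo <- tibble::as_tibble(meteo)
  key <- paste(out$year, months_needed)
  mkey <- paste(meteo$year, meteo$month)
  unmatched <- unique(key[!key %in% mkey])
  if (length(unmatched) > 0) {
    abort(paste0(
      "no meteorological record for year-month: ",
      paste(unmatched, collapse = "; ")
    ))
  }
  idx <- match(key, mkey)
  out$WD <- meteo$WD[idx]
  out$SD <- meteo$SD[idx]
  out$RZ <- meteo$RZ[idx]

  factor_cols <- setdiff(names(out), c("plot_id", "season", "year"))
  n_missing <- sum(is.na(out[factor_cols]))
  if (n_missing > 0) {
    warn(paste0(n_missing, " missing factor cell(s) flagged NA (not imputed)"))
  }
  dplyr::arrange(out, .data$year, .data$season, .data$plot_id)
}
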
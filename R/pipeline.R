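#' Run the full niche-analysis pipeline
#'
#' Orchestrates every stage end-to-end and writes the complete report
#' bundle to `outdir`: per-session MNKA abundance and density, per-year
#' spatial niche breadth and overlap with seasonal mean +/- se summaries,
#' the assembled plot-by-factor habitat table, per-species shadow-feature
#' importance screens pooled and VIF-filtered, and the Hellinger-RDA with
#' global permutation test and forward selection. Inputs are either a
#' named list of data frames (`captures`, and optionally `shrub`, `herb`,
#' `soil`, `meteo`) or, when `data` is `NULL`, a fresh simulated bundle.
#' If the environmental tables are absent, only the capture-based stages
#' run and a notice is logged.
#'
#' @param data Named list of input tables, or `NULL` to simulate with
#'   `config`.
#' @param config A [sim_config()] used when simulating.
#' @param outdir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param seed Integer seed covering every stochastic stage.
#' @param vif_threshold Multicollinearity threshold (default 10).
#' @param alpha Forward-selection admission level (default 0.05).
#' @param n_permutations Permutations for the RDA tests (default 999).
#' @param n_trees Trees per importance screen (default 500).
#'
#' @return Invisibly, a list with every intermediate result (`mnka`,
#'   `breadth`, `breadth_summary`, `overlap`, `overlap_summary`,
#'   `factor_table`, `screens`, `vif_report`, `rda`, `permutation`,
#'   `forward`, `manifest`).
#' @export
run_pipeline <- function(data = NULL, config = sim_config(), outdir = NULL,
                         seed = 1L, vif_threshold = 10, alpha = 0.05,
                         n_permutations = 999, n_trees = 500) {
  if (is.null(data)) {
    data <- simulate_dataset(config, seed)
  }
  if (is.null(data$captures)) abort("input bundle must contain `captures`")
  have_env <- all(c("shrub", "herb", "soil", "meteo") %in% names(data))

  area <- if (!is.null(config$effective_area_ha)) config$effective_area_ha else 1
  mnka_tbl <- mnka_table(data$captures, effective_area_ha = area)
  breadth <- niche_breadth(mnka_tbl)
  breadth_summary <- summarize_by_season(breadth, "breadth")
  overlap <- niche_overlap(mnka_tbl)
  overlap_summary <- summarize_by_season(overlap, "overlap")

  factor_table <- NULL
  screens <- NULL
  vif_report <- NULL
  rda <- NULL
  perm <- NULL
  forward <- NULL
  if (have_env) {
    factor_table <- assemble_factor_table(
      data$shrub, data$herb, data$soil, data$meteo, mnka_tbl
    )
    # response block: per-(plot, season, year) species use (MNKA counts),
    # Hellinger-transformed; factor block: complete-case, standardized
    use_wide <- tidyr::pivot_wider(
      mnka_tbl[, c("plot_id", "season", "year", "species", "mnka")],
      names_from = "species", values_from = "mnka", values_fill = 0,
      names_prefix = "use_"
    )
    joined <- dplyr::inner_join(
      use_wide, factor_table, by = c("plot_id", "season", "year")
    )
    sp_cols <- setdiff(names(use_wide), c("plot_id", "season", "year"))
    fac_cols <- setdiff(names(factor_table), c("plot_id", "season", "year"))
    joined <- joined[stats::complete.cases(joined[, c(sp_cols, fac_cols)]), ]
    joined <- joined[rowSums(joined[, sp_cols]) > 0, ]

    # per-species breadth screens, pooled, then VIF-filtered
    breadth_wide <- tidyr::pivot_wider(
      breadth, names_from = "species", values_from = "breadth",
      names_prefix = "breadth_"
    )
    fac_year <- dplyr::summarise(
      dplyr::group_by(factor_table, .data$season, .data$year),
      dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
    screen_df <- dplyr::inner_join(breadth_wide, fac_year,
                                   by = c("season", "year"))
    species_codes <- unique(breadth$species)
    all_fac <- setdiff(names(fac_year), c("season", "year"))
    screens <- purrr::map(setNames(species_codes, species_codes), function(sp) {
      resp <- paste0("breadth_", sp)
      df <- screen_df[stats::complete.cases(screen_df[, c(resp, all_fac)]), ]
      if (nrow(df) < 10) return(NULL)
      importance_screen(df, response = resp, factors = all_fac,
                        n_trees = n_trees, seed = seed)
    })
    screens <- purrr::compact(screens)
    pooled <- unique(unlist(purrr::map(screens, "high_set")))
    if (length(pooled) < 2) pooled <- all_fac

    Xpool <- joined[, intersect(pooled, fac_cols), drop = FALSE]
    if (ncol(Xpool) < 2) Xpool <- joined[, fac_cols, drop = FALSE]
    keep <- vapply(Xpool, function(x) sd(x) > 0, logical(1))
    Xpool <- Xpool[, keep, drop = FALSE]
    vif_report <- vif_filter(Xpool, threshold = vif_threshold)

    Y <- hellinger(as.matrix(joined[, sp_cols]))
    X <- scale(as.matrix(joined[, vif_report$retained, drop = FALSE]))
    rda <- rda_fit(Y, X)
    perm <- permutation_test(Y, X, n_permutations = n_permutations,
                             seed = seed)
    forward <- forward_select(Y, X, alpha = alpha,
                              n_permutations = n_permutations, seed = seed)
  } else {
    rlang::inform(
      "environmental tables absent: habitat, screening and ordination stages skipped"
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nichetrap")),
    seed = seed,
    vif_threshold = vif_threshold,
    alpha = alpha,
    n_permutations = n_permutations,
    n_captures = nrow(data$captures),
    stages_run = c("mnka", "niche",
                   if (have_env) c("habitat", "screening", "ordination")),
    config_hash = rlang::hash(list(config, seed, vif_threshold, alpha,
                                   n_permutations, n_trees))
  )

  result <- list(
    mnka = mnka_tbl, breadth = breadth, breadth_summary = breadth_summary,
    overlap = overlap, overlap_summary = overlap_summary,
    factor_table = factor_table, screens = screens,
    vif_report = vif_report, rda = rda, permutation = perm,
    forward = forward, manifest = manifest
  )
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_csv(x, file.path(outdir, f))
  w(result$mnka, "mnka.csv")
  w(result$breadth, "niche_breadth.csv")
  w(result$breadth_summary, "niche_breadth_summary.csv")
  w(result$overlap, "niche_overlap.csv")
  w(result$overlap_summary, "niche_overlap_summary.csv")
  if (!is.null(result$factor_table)) w(result$factor_table, "factor_table.csv")
  if (!is.null(result$screens)) {
    jsonlite::write_json(
      purrr::map(result$screens, function(s) {
        list(response = s$response,
             importances = as.list(setNames(s$importance$importance,
                                            s$importance$factor)),
             shadow_mean = s$shadow_mean, shadow_max = s$shadow_max,
             high_set = s$high_set, very_high_set = s$very_high_set,
             seed = s$seed, n_trees = s$n_trees)
      }),
      file.path(outdir, "screening_report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(result$vif_report)) {
    jsonlite::write_json(
      list(retained = result$vif_report$retained,
           removed = result$vif_report$removed,
           final_vifs = as.list(result$vif_report$final_vifs)),
      file.path(outdir, "vif_report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(result$rda)) {
    jsonlite::write_json(
      list(
        canonical_eigenvalues = as.list(result$rda$canonical_eigenvalues),
        residual_eigenvalues = result$rda$residual_eigenvalues,
        proportion_explained = as.list(result$rda$proportion_explained),
        cumulative_first_two = result$rda$cumulative_first_two,
        r2 = result$rda$r2, adjusted_r2 = result$rda$adjusted_r2,
        permutation = list(pseudo_F = result$permutation$pseudo_F,
                           p_value = result$permutation$p_value,
                           n_permutations = result$permutation$n_permutations,
                           seed = result$permutation$seed)
      ),
      file.path(outdir, "rda_result.json"), auto_unbox = TRUE, digits = NA
    )
    # forward-selection table in the printed-report layout: per factor the
    # biplot scores on the first two axes, then the selection columns
    fw <- result$forward
    full_bip <- result$rda$biplot_scores
    tab <- tibble::tibble(
      factor = rownames(full_bip),
      RDA1 = full_bip[, 1],
      RDA2 = if (ncol(full_bip) >= 2) full_bip[, 2] else NA_real_
    )
    tab <- dplyr::left_join(tab, fw$steps[, c("factor", "r2", "pseudo_F",
                                              "p_value")],
                            by = "factor")
    w(tab, "forward_selection.csv")
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
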
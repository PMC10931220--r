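#' RDA triplot
#'
#' Sites as points, response variables as labelled segments, factors as
#' arrows scaled to their correlation with the first two canonical axes.
#'
#' @param object A `niche_rda` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.niche_rda <- function(object, ...) {
  if (ncol(object$site_scores) < 2) {
    abort("need at least two canonical axes to plot")
  }
  sites <- tibble::as_tibble(object$site_scores[, 1:2])
  names(sites) <- c("RDA1", "RDA2")
  spp <- tibble::as_tibble(object$species_scores[, 1:2], rownames = "label")
  names(spp) <- c("label", "RDA1", "RDA2")
  fac <- tibble::as_tibble(object$biplot_scores[, 1:2], rownames = "label")
  names(fac) <- c("label", "RDA1", "RDA2")
  r <- max(abs(sites$RDA1), abs(sites$RDA2))
  fac$RDA1 <- fac$RDA1 * r
  fac$RDA2 <- fac$RDA2 * r
  pct <- 100 * object$proportion_explained[1:2]
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$RDA1, y = .data$RDA2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(colour = "grey40", alpha = 0.6, size = 1) +
    ggplot2::geom_segment(
      data = fac,
      ggplot2::aes(x = 0, y = 0, xend = .data$RDA1, yend = .data$RDA2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(data = fac, ggplot2::aes(label = .data$label),
                       colour = "steelblue", vjust = -0.5, size = 3) +
    ggplot2::geom_text(data = spp, ggplot2::aes(label = .data$label),
                       colour = "firebrick", fontface = "italic", size = 3.2) +
    ggplot2::labs(
      x = sprintf("RDA1 (%.1f%% of total variance)", pct[1]),
      y = sprintf("RDA2 (%.1f%% of total variance)", pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' Importance histogram with shadow thresholds
#'
#' Factor importances sorted as a horizontal bar chart with the shadow
#' Mean and MAX reference lines: bars beyond MAX mark very-high
#' contribution, beyond Mean high contribution.
#'
#' @param object An `importance_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_screen <- function(object, ...) {
  df <- dplyr::arrange(object$importance, .data$importance)
  df$factor <- factor(df$factor, levels = df$factor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$factor,
                                   fill = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$shadow_mean, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$shadow_max, linetype = 1) +
    ggplot2::scale_fill_manual(values = c(
      "very high" = "firebrick", "high" = "orange", "none" = "grey70"
    )) +
    ggplot2::labs(
      x = "permutation importance", y = NULL,
      title = paste("Factor screen:", object$response),
      caption = "dashed line = shadow Mean, solid line = shadow MAX"
    ) +
    ggplot2::theme_minimal()
}

#' Seasonal abundance trends from an MNKA table
#'
#' Community MNKA per species and session (summed over plots), in
#' chronological session order.
#'
#' @param mnka_tbl Output of [mnka_table()].
#' @return A ggplot object.
#' @export
plot_mnka_trend <- function(mnka_tbl) {
  totals <- dplyr::summarise(
    dplyr::group_by(mnka_tbl, .data$year, .data$season, .data$species),
    mnka = sum(.data$mnka), .groups = "drop"
  )
  totals$session <- paste(totals$year, totals$season)
  totals$session <- factor(
    totals$session,
    levels = unique(totals$session[order(session_rank(totals$year,
                                                      totals$season))])
  )
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$session, y = .data$mnka,
                                       colour = .data$species,
                                       group = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "MNKA (all plots)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
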
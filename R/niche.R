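#' Shannon-Wiener spatial niche breadth
#'
#' Normalized Shannon entropy of a species' use across resource levels
#' (survey plots):
#' \deqn{B_i = \frac{1}{\log r}\left[\log N_i -
#'   \frac{1}{N_i}\sum_j N_{ij}\log N_{ij}\right],\qquad N_i=\sum_j N_{ij}}
#' which equals \eqn{H/\log r} with \eqn{H=-\sum_j p_j \log p_j},
#' \eqn{p_j = N_{ij}/N_i}. The index is 0 when a single plot is used and 1
#' when use is uniform across all r plots; the logarithm base cancels, the
#' conventional base 10 is the default. Zero-use plots contribute nothing.
#'
#' @param use Non-negative numeric vector of use values, one per plot
#'   (length r >= 2).
#' @param base Logarithm base (default 10).
#'
#' @return A value in \[0, 1\]; `NaN` (with a warning) for an all-zero row.
#' @export
breadth_index <- function(use, base = 10) {
  if (length(use) < 2) abort("breadth needs at least 2 resource levels (log r = 0)")
  if (any(use < 0)) abort("use values must be non-negative")
  n_total <- sum(use)
  if (n_total == 0) {
    warn("all-zero use vector: breadth undefined, returning NaN")
    return(NaN)
  }
  pos <- use[use > 0]
  num <- log(n_total, base) - sum(pos * log(pos, base)) / n_total
  num / log(length(use), base)
}

#' Colwell-Futuyma spatial niche overlap between two species
#'
#' \deqn{O_{ik} = 1 - \tfrac12 \sum_j \left|N_{ij}/N_i - N_{kj}/N_k\right|}
#' i.e. one minus half the L1 distance between the two species' plot-use
#' proportion vectors (also known as Schoener's index). Ranges from 0
#' (disjoint plot use) to 1 (identical proportional use); invariant to
#' positive rescaling of either vector.
#'
#' @param use_i,use_k Non-negative use vectors of equal length.
#'
#' @return A value in \[0, 1\]; `NaN` (with a warning) when either vector
#'   sums to zero.
#' @export
overlap_index <- function(use_i, use_k) {
  if (length(use_i) != length(use_k)) abort("use vectors must have equal length")
  if (any(use_i < 0) || any(use_k < 0)) abort("use values must be non-negative")
  si <- sum(use_i)
  sk <- sum(use_k)
  if (si == 0 || sk == 0) {
    warn("zero-sum use vector: overlap undefined, returning NaN")
    return(NaN)
  }
  1 - 0.5 * sum(abs(use_i / si - use_k / sk))
}

#' Pairwise niche overlap matrix
#'
#' @param use A species-by-plots matrix of non-negative use values, with
#'   species as rownames.
#' @return A symmetric species-by-species matrix of overlap indices with
#'   unit diagonal for species with positive total use.
#' @export
overlap_matrix <- function(use) {
  use <- as.matrix(use)
  if (nrow(use) < 2) abort("need at least 2 species")
  s <- nrow(use)
  out <- matrix(NA_real_, s, s, dimnames = list(rownames(use), rownames(use)))
  for (i in seq_len(s)) {
    for (k in seq_len(i)) {
      o <- suppressWarnings(overlap_index(use[i, ], use[k, ]))
      out[i, k] <- o
      out[k, i] <- o
    }
  }
  out
}

# Species x plot use matrix (N_ij) for one (year, season), from the MNKA
# table. Plots never used by a species carry 0.
use_matrix_one <- function(mnka_tbl) {
  wide <- tidyr::pivot_wider(
    mnka_tbl[, c("species", "plot_id", "mnka")],
    names_from = "plot_id", values_from = "mnka", values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$species
  m
}

#' Spatial niche breadth per species, season and year
#'
#' Treats each survey plot as one resource level and the per-plot MNKA count
#' for the (year, season) as the use value N_ij. Species absent everywhere
#' in a season-year get `NaN` and are excluded from downstream summaries.
#'
#' @param mnka_tbl Output of [mnka_table()] (columns `year`, `season`,
#'   `plot_id`, `species`, `mnka`).
#' @param base Logarithm base for the breadth index (default 10; the result
#'   is base-invariant).
#'
#' @return A tibble with columns `species`, `season`, `year`, `breadth`.
#' @export
niche_breadth <- function(mnka_tbl, base = 10) {
  grouped <- dplyr::group_by(mnka_tbl, .data$species, .data$season, .data$year)
  out <- dplyr::summarise(
    grouped,
    breadth = suppressWarnings(breadth_index(.data$mnka, base = base)),
    .groups = "drop"
  )
  n_absent <- sum(is.nan(out$breadth))
  if (n_absent > 0) {
    rlang::inform(paste0(
      n_absent, " species-season-year combination(s) with zero captures: ",
      "breadth undefined (NaN)"
    ))
  }
  out[, c("species", "season", "year", "breadth")]
}

#' Pairwise spatial niche overlap per season and year
#'
#' @inheritParams niche_breadth
#' @return A tibble with columns `species_a`, `species_b`, `season`, `year`,
#'   `overlap`, one row per unordered species pair.
#' @export
niche_overlap <- function(mnka_tbl) {
  groups <- dplyr::group_by(mnka_tbl, .data$season, .data$year)
  out <- dplyr::group_modify(groups, function(g, key) {
    m <- use_matrix_one(g)
    if (nrow(m) < 2) {
      return(tibble::tibble(species_a = character(), species_b = character(),
                            overlap = double()))
    }
    om <- overlap_matrix(m)
    pairs <- which(lower.tri(om), arr.ind = TRUE)
    tibble::tibble(
      species_a = rownames(om)[pairs[, "col"]],
      species_b = rownames(om)[pairs[, "row"]],
      overlap = om[pairs]
    )
  })
  out <- dplyr::ungroup(out)
  out[, c("species_a", "species_b", "season", "year", "overlap")]
}

#' Summarize per-year index values as mean and standard error
#'
#' Collapses per-year niche index values to the mean +/- se form of a
#' seasonal summary table: the arithmetic mean across years and the standard
#' error of that mean (sample sd / sqrt(n)); a single year yields se = 0.
#' `NaN` values (species absent in a season-year) are dropped with a notice.
#'
#' @param tbl A tibble holding one index value per year, e.g. the output of
#'   [niche_breadth()] or [niche_overlap()].
#' @param value Name of the value column to summarize (default `"breadth"`).
#'
#' @return A tibble grouped by all columns except `year` and the value
#'   column, with `mean`, `se` and `n_years`.
#' @export
summarize_by_season <- function(tbl, value = "breadth") {
  if (!value %in% names(tbl)) abort(paste0("no column `", value, "`"))
  if (nrow(tbl) == 0) abort("empty input")
  dropped <- sum(is.na(tbl[[value]]))
  if (dropped > 0) {
    rlang::inform(paste0(dropped, " undefined value(s) dropped from summary"))
    tbl <- tbl[!is.na(tbl[[value]]), , drop = FALSE]
  }
  if (nrow(tbl) == 0) abort("no defined values to summarize")
  keys <- setdiff(names(tbl), c("year", value))
  grouped <- dplyr::group_by(tbl, dplyr::across(dplyr::all_of(keys)))
  dplyr::summarise(
    grouped,
    mean = mean(.data[[value]]),
    se = ifelse(dplyr::n() > 1, sd(.data[[value]]) / sqrt(dplyr::n()), 0),
    n_years = dplyr::n(),
    .groups = "drop"
  )
}
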
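# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's own code paths.

# Random capture-record table over a small design.
random_records <- function(n = 200, n_plots = 3, n_species = 2,
                           years = 2017:2018,
                           seasons = c("spring", "summer", "autumn"),
                           n_individuals = 25) {
  tibble::tibble(
    year = sample(years, n, replace = TRUE),
    season = sample(seasons, n, replace = TRUE),
    plot_id = sample(sprintf("P%02d", seq_len(n_plots)), n, replace = TRUE),
    day = sample(1:4, n, replace = TRUE),
    check = sample(c("morning", "afternoon"), n, replace = TRUE),
    station_row = sample(0:6, n, replace = TRUE),
    station_col = sample(0:7, n, replace = TRUE),
    individual_id = sample(sprintf("ID%03d", seq_len(n_individuals)), n,
                           replace = TRUE),
    species = NA_character_
  ) |>
    dplyr::mutate(
      # species fixed per individual so the id-species pairing is consistent
      species = sprintf("SP%d", (match(individual_id,
                                       sort(unique(individual_id))) %%
                                   n_species) + 1L)
    )
}

# Set-based oracle: for each (species, plot), each individual's set of
# session indices (over the full chronological session list of the table).
oracle_capture_sets <- function(records) {
  season_rank <- c(spring = 1, summer = 2, autumn = 3)
  sess <- unique(records[, c("year", "season")])
  sess <- sess[order(sess$year, season_rank[as.character(sess$season)]), ]
  sess_key <- paste(sess$year, sess$season)
  out <- list()
  for (grp in split(records, paste(records$species, records$plot_id))) {
    sets <- lapply(split(grp, grp$individual_id), function(g) {
      sort(unique(match(paste(g$year, g$season), sess_key)))
    })
    out[[paste(grp$species[1], grp$plot_id[1])]] <-
      list(sets = sets, n_sessions = length(sess_key))
  }
  out
}

# Per-individual enumeration of MNKA at session t.
oracle_mnka <- function(sets, t) {
  a <- sum(vapply(sets, function(s) t %in% s, logical(1)))
  b <- sum(vapply(sets, function(s) {
    !(t %in% s) && any(s < t) && any(s > t)
  }, logical(1)))
  a + b
}

# Direct Shannon-entropy breadth: H / log r, any base (base cancels).
oracle_breadth <- function(use) {
  p <- use[use > 0] / sum(use)
  h <- -sum(p * log(p))
  h / log(length(use))
}

# Direct evaluation of the proportional-overlap formula.
oracle_overlap <- function(x, y) {
  1 - 0.5 * sum(abs(x / sum(x) - y / sum(y)))
}

# Explicit-projection RDA oracle: hat matrix by normal equations, full
# eigendecomposition of the fitted and residual covariance.
oracle_rda_eigen <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  Yhat <- H %*% Yc
  canonical <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)$values
  residual <- eigen(crossprod(Yc - Yhat) / (n - 1), symmetric = TRUE)$values
  list(
    canonical = canonical[canonical > 1e-12],
    residual = residual[residual > 1e-12],
    total = sum(Yc^2) / (n - 1)
  )
}
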
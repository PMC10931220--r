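small_cfg <- function(...) {
  sim_config(n_plots = 4, years = 2017:2018,
             abundance = c(SZ = 20, WZ = 15, MZ = 10, ZW = 25), ...)
}

test_that("the default design totals the published trapping effort", {
  expect_equal(trap_effort(sim_config()), 56 * 24 * 4 * 3 * 5)
  expect_equal(trap_effort(sim_config()), 80640)
})

test_that("simulation is reproducible to the byte under a fixed seed", {
  a <- simulate_dataset(small_cfg(), seed = 5)
  b <- simulate_dataset(small_cfg(), seed = 5)
  expect_identical(a$captures, b$captures)
  expect_identical(a$shrub, b$shrub)
  expect_identical(a$meteo, b$meteo)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  readr::write_csv(a$captures, f1)
  readr::write_csv(b$captures, f2)
  expect_identical(readLines(f1), readLines(f2))
  c2 <- simulate_dataset(small_cfg(), seed = 6)
  expect_false(identical(a$captures, c2$captures))
})

test_that("records conform to the capture schema and ids are species-unique", {
  d <- simulate_study(small_cfg(), seed = 1)
  expect_silent(validate_captures(d$captures))
  expect_true(all(d$captures$day %in% 1:4))
  sp_of_id <- tapply(d$captures$species, d$captures$individual_id,
                     function(s) length(unique(s)))
  expect_true(all(sp_of_id == 1))
})

test_that("perfect detection and survival make MNKA equal truth", {
  cfg <- small_cfg(p_capture = 1, survival = 1)
  d <- simulate_study(cfg, seed = 2)
  mt <- mnka_table(d$captures, plots = sprintf("P%02d", 1:4))
  joined <- dplyr::inner_join(
    mt, d$truth$abundance,
    by = c("year", "season" = "season", "plot_id", "species")
  )
  expect_gt(nrow(joined), 0)
  expect_equal(joined$mnka, joined$n_true)
})

test_that("truth stores the exact breadth of the occupancy draw", {
  d <- simulate_study(small_cfg(), seed = 3)
  occ <- d$truth$occupancy
  for (i in seq_len(nrow(occ))) {
    expect_equal(occ$breadth_true[i], breadth_index(occ$weights[[i]]),
                 tolerance = 1e-14)
  }
})

test_that("MNKA shows the endpoint bias of a constant-N study", {
  # constant population, constant capture rate, full survival: the mean
  # MNKA series over many replicate studies peaks at interior sessions
  set.seed(4)
  n_sessions <- 7
  n_ind <- 20
  reps <- 500
  series <- matrix(0, reps, n_sessions)
  for (r in seq_len(reps)) {
    p <- runif(1, 0.3, 0.7)
    m <- matrix(runif(n_ind * n_sessions) < p, n_ind)
    keep <- rowSums(m) > 0
    sets <- apply(m[keep, , drop = FALSE], 1, which, simplify = FALSE)
    h <- local({
      sessions <- tibble::tibble(year = 2000 + seq_len(n_sessions),
                                 season = factor("spring"))
      nichetrap:::new_capture_history(
        "S", "P",
        matrix(m[keep, ], ncol = n_sessions,
               dimnames = list(sprintf("I%02d", which(keep)), NULL)),
        sessions
      )
    })
    series[r, ] <- mnka_series(h)
  }
  avg <- colMeans(series)
  interior <- avg[2:(n_sessions - 1)]
  expect_true(all(interior > avg[1]))
  expect_true(all(interior > avg[n_sessions]))
  # and the bias is negative: MNKA never exceeds the true N
  expect_true(all(series <= n_ind))
})

test_that("unlinked environments carry no density signal", {
  cfg <- small_cfg(env_links = list())
  study <- simulate_study(cfg, seed = 5)
  env <- simulate_environment(cfg, study$truth, seed = 6)
  dens <- tidyr::pivot_wider(study$truth$abundance, names_from = "species",
                             values_from = "n_true", values_fill = 0)
  joined <- dplyr::inner_join(env$latent, dens,
                              by = c("plot_id", "year", "season"))
  r <- cor(joined$AH.S, joined$ZW)
  expect_lt(abs(r), 0.15)
})

test_that("with zero noise a linked factor is an exact affine map of density", {
  cfg <- small_cfg(env_links = list(AH.S = c(ZW = 0.4)), env_noise_sd = 0)
  study <- simulate_study(cfg, seed = 7)
  env <- simulate_environment(cfg, study$truth, seed = 8)
  dens <- tidyr::pivot_wider(study$truth$abundance, names_from = "species",
                             values_from = "n_true", values_fill = 0)
  joined <- dplyr::inner_join(env$latent, dens,
                              by = c("plot_id", "year", "season"))
  expect_equal(joined$AH.S, 40 + 0.4 * joined$ZW, tolerance = 1e-12)
  # and the raw quadrat tables aggregate back to that exact value
  ft <- suppressWarnings(assemble_factor_table(
    env$shrub, env$herb, env$soil, env$meteo,
    mnka_table(study$captures, plots = sprintf("P%02d", 1:4))
  ))
  chk <- dplyr::inner_join(
    dplyr::mutate(ft[, c("plot_id", "season", "year", "AH.S")],
                  season = as.character(season)),
    joined,
    by = c("plot_id", "year", "season")
  )
  expect_equal(chk$AH.S.x, chk$AH.S.y, tolerance = 1e-10)
})

test_that("occupancy evenness regimes separate cleanly in estimated breadth", {
  set.seed(9)
  n_pairs <- 100
  even <- replicate(n_pairs, {
    w <- rgamma(24, 5); breadth_index(w / sum(w))
  })
  concentrated <- replicate(n_pairs, {
    w <- rgamma(24, 0.3); breadth_index(w / sum(w))
  })
  # AUC of separating the two regimes by breadth alone
  auc <- mean(outer(even, concentrated, ">")) +
    0.5 * mean(outer(even, concentrated, "=="))
  expect_gte(auc, 0.95)
})

test_that("a trailing buffer session informs the final study year", {
  cfg <- small_cfg(buffer_session = TRUE, survival = 1, p_capture = 0.6)
  d <- simulate_study(cfg, seed = 10)
  expect_true(max(d$captures$year) == 2019)
})
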
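make_record <- function(year = 2017, season = "spring", plot = "P01",
                        day = 1, check = "morning", row = 0, col = 0,
                        species = "SP1", id = "ID001") {
  tibble::tibble(
    year = year, season = season, plot_id = plot, day = day, check = check,
    station_row = row, station_col = col, species = species,
    individual_id = id
  )
}

test_that("capture validation rejects malformed records", {
  ok <- make_record()
  expect_silent(validate_captures(ok))
  expect_error(validate_captures(make_record(day = 5)), "day")
  expect_error(validate_captures(make_record(row = 7)), "grid")
  expect_error(validate_captures(make_record(col = -1)), "grid")
  expect_error(validate_captures(make_record(season = "winter")), "season")
  expect_error(validate_captures(ok[, -1]), "missing column")
  clash <- dplyr::bind_rows(make_record(species = "SP1"),
                            make_record(day = 2, species = "SP2"))
  expect_error(validate_captures(clash), "ID001")
})

test_that("empty input yields an empty history table", {
  h <- build_capture_histories(make_record()[0, ])
  expect_equal(nrow(h), 0)
})

test_that("within-session recaptures collapse to a single presence cell", {
  rec <- dplyr::bind_rows(
    make_record(day = 1, check = "morning"),
    make_record(day = 3, check = "afternoon")
  )
  h <- build_capture_histories(rec)$history[[1]]
  expect_equal(dim(h$matrix), c(1, 1))
  expect_true(h$matrix[1, 1])
})

test_that("species absent from a session still get an all-false column", {
  rec <- dplyr::bind_rows(
    make_record(season = "spring"),
    make_record(season = "autumn", id = "ID002"),
    make_record(season = "summer", species = "SP2", id = "ID003")
  )
  tbl <- build_capture_histories(rec)
  h1 <- tbl$history[[which(tbl$species == "SP1")]]
  expect_equal(ncol(h1$matrix), 3)
  expect_equal(unname(colSums(h1$matrix)), c(1, 0, 1))
})

test_that("histories match the set-based oracle on randomized records", {
  set.seed(42)
  for (rep in 1:3) {
    rec <- random_records(200)
    tbl <- build_capture_histories(rec)
    oracle <- oracle_capture_sets(rec)
    expect_equal(nrow(tbl), length(oracle))
    for (i in seq_len(nrow(tbl))) {
      h <- tbl$history[[i]]
      o <- oracle[[paste(tbl$species[i], tbl$plot_id[i])]]
      expect_equal(ncol(h$matrix), o$n_sessions)
      got <- lapply(rownames(h$matrix),
                    function(id) unname(which(h$matrix[id, ])))
      names(got) <- rownames(h$matrix)
      expect_equal(got[order(names(got))],
                   lapply(o$sets, as.integer)[order(names(o$sets))])
    }
  }
})

test_that("history building is invariant to record order", {
  set.seed(11)
  rec <- random_records(150)
  a <- build_capture_histories(rec)
  b <- build_capture_histories(rec[sample(nrow(rec)), ])
  expect_equal(a, b)
})

fabricate_history <- function(m) {
  sessions <- tibble::tibble(year = 2000 + seq_len(ncol(m)),
                             season = factor("spring"))
  nichetrap:::new_capture_history(
    "SP1", "P01",
    matrix(m, nrow = nrow(m),
           dimnames = list(sprintf("ID%02d", seq_len(nrow(m))),
                           paste(sessions$year, sessions$season))),
    sessions
  )
}

test_that("mnka counts caught plus bracketed individuals", {
  # 3 caught at session 2; 1 caught at sessions 1 and 3 only -> 3 + 1
  m <- rbind(
    c(FALSE, TRUE, FALSE),
    c(FALSE, TRUE, FALSE),
    c(FALSE, TRUE, FALSE),
    c(TRUE, FALSE, TRUE)
  )
  h <- fabricate_history(m)
  expect_equal(mnka(h, 2), 4L)
  expect_equal(mnka(h, 1), 1L)
  expect_equal(mnka(h, 3), 1L)
  expect_error(mnka(h, 4), "session")
  expect_error(mnka(h, 0), "session")
})

test_that("empty session with no bracketing captures gives zero", {
  h <- fabricate_history(rbind(c(TRUE, FALSE, FALSE)))
  expect_equal(mnka(h, 2), 0L)
  expect_equal(mnka(h, 3), 0L)
})

test_that("mnka_series fills the gap between bracketing captures", {
  always <- fabricate_history(matrix(TRUE, 1, 5))
  expect_equal(unname(mnka_series(always)), rep(1L, 5))
  ends <- fabricate_history(matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE), 1))
  expect_equal(unname(mnka_series(ends)), rep(1L, 5))
})

test_that("mnka equals the exhaustive per-individual oracle on random histories", {
  set.seed(99)
  for (rep in 1:50) {
    n_ind <- sample(1:12, 1)
    n_sess <- sample(3:8, 1)
    m <- matrix(runif(n_ind * n_sess) < 0.35, n_ind, n_sess)
    m[rowSums(m) == 0, sample(n_sess, 1)] <- TRUE # every row caught once
    h <- fabricate_history(m)
    sets <- apply(m, 1, which, simplify = FALSE)
    for (t in seq_len(n_sess)) {
      expect_equal(mnka(h, t), oracle_mnka(sets, t))
    }
  }
})

test_that("adding a capture never decreases any session's MNKA", {
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(runif(6 * 6) < 0.3, 6, 6)
    m[rowSums(m) == 0, 1] <- TRUE
    before <- unname(mnka_series(fabricate_history(m)))
    free <- which(!m)
    m[free[sample(length(free), 1)]] <- TRUE
    after <- unname(mnka_series(fabricate_history(m)))
    expect_true(all(after >= before))
  }
})

test_that("mnka_table completes the species-plot-session grid with zeros", {
  rec <- dplyr::bind_rows(
    make_record(season = "spring", plot = "P01"),
    make_record(season = "summer", plot = "P02", species = "SP2", id = "ID09")
  )
  tbl <- mnka_table(rec)
  expect_equal(nrow(tbl), 2 * 2 * 2) # 2 sessions x 2 plots x 2 species
  expect_equal(sum(tbl$mnka), 2)
  expect_equal(tbl$density_per_ha, tbl$mnka / 1)
})

test_that("density and the log10(n+1) transform behave as defined", {
  expect_equal(density_per_ha(0), 0)
  expect_equal(density_per_ha(9, 1), 9)
  expect_equal(density_per_ha(56, 1), 56)
  expect_equal(density_per_ha(27, 0.945), 27 / 0.945)
  expect_error(density_per_ha(3, 0), "positive")
  expect_equal(log10p1(0), 0)
  expect_equal(log10p1(9), 1)
  expect_error(log10p1(-1), "non-negative")
})
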
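test_that("hellinger rows have unit sum of squares", {
  expect_equal(unname(hellinger(rbind(c(1, 1, 1, 1)))[1, ]), rep(0.5, 4))
  expect_equal(unname(hellinger(rbind(c(4, 0, 0)))[1, ]), c(1, 0, 0))
  set.seed(1)
  Y <- matrix(rgamma(20 * 6, 1), 20)
  H <- hellinger(Y)
  expect_equal(rowSums(H^2), rep(1, 20), tolerance = 1e-12)
  expect_error(hellinger(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(hellinger(rbind(c(-1, 2))), "non-negative")
})

test_that("hellinger matches the standard community-transform oracle", {
  skip_if_not_installed("vegan")
  set.seed(2)
  Y <- matrix(rpois(15 * 5, 4) + 1, 15)
  expect_equal(c(unname(hellinger(Y))),
               c(unname(as.matrix(vegan::decostand(Y, "hellinger")))),
               tolerance = 1e-12)
})

test_that("a noise-free linear response gives a perfect RDA fit", {
  set.seed(3)
  X <- matrix(rnorm(30 * 2), 30)
  Y <- X %*% matrix(rnorm(2 * 3), 2)
  fit <- rda_fit(Y, X)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(sum(fit$residual_eigenvalues), 1e-16)
})

test_that("a response orthogonal to the factors explains nothing", {
  set.seed(4)
  n <- 40
  X <- scale(matrix(rnorm(n * 2), n), scale = FALSE)
  noise <- matrix(rnorm(n * 3), n)
  # project the noise off the factor space
  Y <- noise - X %*% solve(crossprod(X)) %*% crossprod(X, noise)
  fit <- rda_fit(Y, X)
  expect_lt(fit$r2, 1e-10)
})

test_that("rda eigenvalues match the brute-force projection oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:25, 1)
    p <- sample(2:4, 1)
    m <- sample(2:3, 1)
    Y <- matrix(rnorm(n * p), n)
    X <- matrix(rnorm(n * m), n)
    fit <- rda_fit(Y, X)
    oracle <- oracle_rda_eigen(Y, X)
    can <- fit$canonical_eigenvalues[fit$canonical_eigenvalues > 1e-12]
    expect_lt(max(abs(unname(can) - oracle$canonical[seq_along(can)])), 1e-8)
    res <- fit$residual_eigenvalues[fit$residual_eigenvalues > 1e-12]
    expect_lt(max(abs(res - oracle$residual[seq_along(res)])), 1e-8)
    # variance conservation
    expect_equal(
      sum(fit$canonical_eigenvalues) + sum(fit$residual_eigenvalues),
      oracle$total, tolerance = 1e-8
    )
    expect_lte(fit$adjusted_r2, fit$r2)
    expect_true(fit$cumulative_first_two >= 0 &&
                  fit$cumulative_first_two <= 1 + 1e-12)
    expect_true(sum(fit$proportion_explained) <= 1 + 1e-12)
  }
})

test_that("rda agrees with the vegan reference on a fixed instance", {
  skip_if_not_installed("vegan")
  set.seed(6)
  Y <- matrix(rnorm(20 * 4), 20)
  X <- as.data.frame(matrix(rnorm(20 * 3), 20))
  fit <- rda_fit(Y, X)
  vfit <- vegan::rda(Y ~ ., data = X)
  expect_equal(unname(fit$canonical_eigenvalues),
               unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$r2, unname(vegan::RsquareAdj(vfit)$r.squared),
               tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, unname(vegan::RsquareAdj(vfit)$adj.r.squared),
               tolerance = 1e-10)
})

test_that("rda is invariant to factor column order and flags rank deficiency", {
  set.seed(7)
  Y <- matrix(rnorm(25 * 3), 25)
  X <- matrix(rnorm(25 * 3), 25, dimnames = list(NULL, c("a", "b", "c")))
  f1 <- rda_fit(Y, X)
  f2 <- rda_fit(Y, X[, c("c", "a", "b")])
  expect_equal(f1$canonical_eigenvalues, f2$canonical_eigenvalues,
               tolerance = 1e-10)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  Xbad <- cbind(X, d = X[, "a"])
  expect_error(rda_fit(Y, Xbad), "rank deficient")
  # site scores orthogonal
  ss <- f1$site_scores
  off <- crossprod(ss) - diag(diag(crossprod(ss)))
  expect_lt(max(abs(off)), 1e-8)
})

test_that("permutation test is deterministic under a fixed seed", {
  set.seed(8)
  Y <- matrix(rnorm(20 * 3), 20)
  X <- matrix(rnorm(20 * 2), 20)
  a <- permutation_test(Y, X, n_permutations = 99, seed = 42)
  b <- permutation_test(Y, X, n_permutations = 99, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$pseudo_F, b$pseudo_F)
  expect_true(a$p_value > 0 && a$p_value <= 1)
  expect_error(permutation_test(Y, X, n_permutations = 50), "99")
})

test_that("a strong signal drives the permutation p to its floor", {
  set.seed(9)
  n <- 50
  X <- matrix(rnorm(n * 2), n)
  Y <- X %*% matrix(c(1, 0.5, -0.5, 1, 0.3, 0.7), 2) +
    0.05 * matrix(rnorm(n * 3), n)
  pt <- permutation_test(Y, X, n_permutations = 199, seed = 1)
  expect_equal(pt$p_value, 1 / 200)
})

test_that("whenever forward selection admits anything, the signal leads", {
  # with a lone informative factor the scope rule of the double stopping
  # criterion can halt before any admission (the signal-only adjusted R2
  # often exceeds the noise-penalized full model's); but every nonempty
  # selection must start with the informative factor
  n_nonempty <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    X <- as.data.frame(matrix(rnorm(n * 10), n))
    names(X) <- c("signal", paste0("noise", 1:9))
    Y <- cbind(2 * X$signal, -1.5 * X$signal, X$signal) +
      0.5 * matrix(rnorm(n * 3), n)
    fs <- forward_select(Y, X, n_permutations = 99, seed = s)
    if (length(fs$selected) >= 1) {
      n_nonempty <- n_nonempty + 1
      expect_identical(fs$selected[1], "signal")
    }
  }
  expect_gt(n_nonempty, 0)
})

test_that("duplicated informative factors are never co-selected", {
  # a and b are exact duplicates; c carries independent signal so the
  # selection does not stop at the scope rule before reaching the pair
  set.seed(11)
  n <- 50
  x <- rnorm(n)
  z <- rnorm(n)
  X <- data.frame(a = x, b = x, c = z)
  Y <- cbind(2 * x + z, -x + 2 * z) + 0.3 * matrix(rnorm(n * 2), n)
  fs <- forward_select(Y, X, n_permutations = 99, seed = 1)
  expect_gte(length(fs$selected), 1)
  expect_equal(sum(c("a", "b") %in% fs$selected), 1)
})

test_that("the double stopping rule caps selection at the full-model adj R2", {
  set.seed(12)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 8), n))
  Y <- cbind(X$V1 + 0.5 * X$V2, X$V2) + 0.4 * matrix(rnorm(n * 2), n)
  fs <- forward_select(Y, X, n_permutations = 99, seed = 2)
  if (!is.null(fs$final)) {
    expect_lte(fs$final$adjusted_r2, fs$full_adjusted_r2 + 1e-10)
  }
  expect_equal(fs$steps$order, seq_len(nrow(fs$steps)))
  expect_true(all(fs$steps$p_value <= 0.05))
})

test_that("tidy and glance expose the fit summaries", {
  set.seed(13)
  Y <- matrix(rnorm(20 * 3), 20)
  X <- matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("a", "b")))
  fit <- rda_fit(Y, X)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$r2, fit$r2)
  fs <- forward_select(Y, X, n_permutations = 99, seed = 1)
  expect_s3_class(tidy(fs), "tbl_df")
  expect_s3_class(glance(fs), "tbl_df")
})
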
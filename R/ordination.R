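#' Hellinger transformation of a community matrix
#'
#' Row-wise square root of proportions: y'_ij = sqrt(y_ij / y_i+). Every
#' transformed row has unit sum of squares, which makes Euclidean-based
#' linear ordination (RDA/PCA) appropriate for abundance-like data.
#'
#' @param Y Non-negative numeric matrix or data frame (rows = samples).
#' @return A matrix of the same shape.
#' @export
hellinger <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) abort("Hellinger transformation needs non-negative data")
  rs <- rowSums(Y)
  zero <- which(rs == 0)
  if (length(zero) > 0) {
    abort(paste0(
      "all-zero row(s): ",
      paste(head(if (is.null(rownames(Y))) zero else rownames(Y)[zero], 5),
            collapse = ", ")
    ))
  }
  sqrt(sweep(Y, 1, rs, "/"))
}

# Centered response/factor matrices and the thin Q basis of the factor
# space, shared by rda_fit, permutation tests and forward selection.
rda_prepare <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (!is.numeric(X)) abort("factor matrix must be numeric")
  if (nrow(Y) != nrow(X)) abort("Y and X must have the same number of rows")
  n <- nrow(Y)
  m <- ncol(X)
  if (n <= m + 1) abort("need n > number of factors + 1")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  list(Yc = Yc, Xc = Xc, qx = qx, n = n, m = m)
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination from first principles: the response columns are
#' centered, fitted values from the multivariate least-squares regression
#' of Y on X (with intercept) are eigen-decomposed to give the canonical
#' axes, and the residuals give the unconstrained axes. R2 is the
#' proportion of total variance captured by the canonical axes; the
#' adjusted R2 uses Ezekiel's formula
#' 1 - (1 - R2)(n - 1)/(n - m - 1).
#'
#' Typically `Y` is the Hellinger-transformed species block (see
#' [hellinger()]) and `X` the standardized environmental factor block.
#'
#' @param Y Response matrix (rows = samples).
#' @param X Factor matrix or data frame of numeric columns.
#'
#' @return A `niche_rda` object with canonical and residual eigenvalues,
#'   per-axis explained proportions, R2 and adjusted R2, and site, species
#'   and biplot scores.
#' @export
rda_fit <- function(Y, X) {
  prep <- rda_prepare(Y, X)
  n <- prep$n
  m <- prep$m
  if (prep$qx$rank < m) {
    abort("factor matrix is rank deficient; remove collinear columns (see vif_filter)")
  }
  Q <- qr.Q(prep$qx)[, seq_len(prep$qx$rank), drop = FALSE]
  Yhat <- Q %*% crossprod(Q, prep$Yc)
  resid <- prep$Yc - Yhat

  n_can <- min(m, ncol(prep$Yc))
  sv_c <- svd(Yhat / sqrt(n - 1))
  can_ev <- sv_c$d[seq_len(n_can)]^2
  can_ev[can_ev < max(can_ev[1], .Machine$double.eps) * 1e-12] <- 0

  sv_r <- svd(resid / sqrt(n - 1))
  n_res <- min(n - 1 - prep$qx$rank, ncol(prep$Yc))
  res_ev <- sv_r$d[seq_len(max(n_res, 0))]^2
  res_ev <- res_ev[res_ev > 1e-14 * max(c(can_ev, res_ev, 1))]

  total <- sum(prep$Yc^2) / (n - 1)
  r2 <- sum(can_ev) / total
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - m - 1)

  axes <- seq_len(n_can)
  d <- sv_c$d[axes]
  site_scores <- sqrt(n - 1) * sv_c$u[, axes, drop = FALSE]
  species_scores <- sv_c$v[, axes, drop = FALSE] %*% diag(d, n_can)
  # correlations of the (centered) factors with the canonical site scores
  biplot_scores <- suppressWarnings(cor(prep$Xc, site_scores))
  biplot_scores[!is.finite(biplot_scores)] <- 0
  ax_names <- paste0("RDA", axes)
  colnames(site_scores) <- colnames(species_scores) <-
    colnames(biplot_scores) <- ax_names
  rownames(species_scores) <- colnames(Y)
  rownames(biplot_scores) <- colnames(X)

  prop <- can_ev / total
  structure(
    list(
      canonical_eigenvalues = setNames(can_ev, ax_names),
      residual_eigenvalues = res_ev,
      total_variance = total,
      proportion_explained = setNames(prop, ax_names),
      cumulative_first_two = sum(can_ev[seq_len(min(2, n_can))]) /
        max(sum(can_ev), .Machine$double.eps),
      r2 = r2,
      adjusted_r2 = adj_r2,
      site_scores = site_scores,
      species_scores = species_scores,
      biplot_scores = biplot_scores,
      n_samples = n,
      n_factors = m
    ),
    class = "niche_rda"
  )
}

#' @export
print.niche_rda <- function(x, ...) {
  cat("<niche_rda> ", x$n_samples, " samples, ", x$n_factors, " factors\n",
      sep = "")
  cat("  R2 =", signif(x$r2, 4), " adj R2 =", signif(x$adjusted_r2, 4), "\n")
  cat("  first two canonical axes:",
      sprintf("%.2f%%", 100 * x$cumulative_first_two),
      "of constrained variance\n")
  invisible(x)
}

#' @export
tidy.niche_rda <- function(x, ...) {
  tibble::tibble(
    axis = names(x$canonical_eigenvalues),
    eigenvalue = unname(x$canonical_eigenvalues),
    proportion_of_total = unname(x$proportion_explained),
    proportion_of_constrained =
      unname(x$canonical_eigenvalues) /
        max(sum(x$canonical_eigenvalues), .Machine$double.eps)
  )
}

#' @export
glance.niche_rda <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2,
    adjusted_r2 = x$adjusted_r2,
    total_variance = x$total_variance,
    n_samples = x$n_samples,
    n_factors = x$n_factors
  )
}

# Constrained sum of squares of (already centered) Y on the basis Q.
rda_ssc <- function(Q, Yc) {
  if (is.null(Q)) return(0)
  sum(crossprod(Q, Yc)^2)
}

# Pseudo-F for a model with q constrained dimensions.
pseudo_f <- function(ssc, sst, n, q) {
  (ssc / q) / ((sst - ssc) / (n - q - 1))
}

#' Permutation test of an RDA model
#'
#' Global significance test of the constrained model: the observed pseudo-F
#' (constrained mean square over residual mean square) is compared with the
#' distribution obtained by permuting the rows of the response matrix. The
#' p-value uses the add-one rule p = (1 + #\{F_perm >= F_obs\}) /
#' (1 + n_permutations), so it is never zero and its floor at 999
#' permutations is 0.001.
#'
#' @inheritParams rda_fit
#' @param n_permutations Number of row permutations (>= 99; default 999).
#' @param seed Integer seed for the permutations.
#'
#' @return A `rda_permutation` object: list with `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(Y, X, n_permutations = 999, seed = 1L) {
  if (n_permutations < 99) abort("use at least 99 permutations")
  prep <- rda_prepare(Y, X)
  n <- prep$n
  q <- prep$qx$rank
  Q <- qr.Q(prep$qx)[, seq_len(q), drop = FALSE]
  sst <- sum(prep$Yc^2)
  f_obs <- pseudo_f(rda_ssc(Q, prep$Yc), sst, n, q)
  set.seed(seed)
  n_ge <- 0L
  for (i in seq_len(n_permutations)) {
    Yp <- prep$Yc[sample(n), , drop = FALSE]
    if (pseudo_f(rda_ssc(Q, Yp), sst, n, q) >= f_obs) n_ge <- n_ge + 1L
  }
  structure(
    list(
      pseudo_F = f_obs,
      p_value = (1 + n_ge) / (1 + n_permutations),
      n_permutations = n_permutations,
      seed = seed
    ),
    class = "rda_permutation"
  )
}

#' @export
print.rda_permutation <- function(x, ...) {
  cat("<rda_permutation> F =", signif(x$pseudo_F, 5),
      " p =", signif(x$p_value, 4),
      " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Forward selection of environmental factors for RDA
#'
#' Greedy forward selection with the double stopping rule: at each step the
#' candidate factor giving the largest adjusted R2 of the extended model is
#' considered; selection stops if that adjusted R2 would exceed the
#' adjusted R2 of the full model (all candidates), otherwise the candidate
#' is admitted only if its conditional permutation test (reduced-model
#' permutation of the residuals from the already-selected factors) has
#' p <= alpha. Per-step unadjusted R2 contribution, pseudo-F and p are
#' reported in a forward-selection table.
#'
#' @inheritParams permutation_test
#' @param alpha Admission significance level (default 0.05).
#'
#' @return A `forward_selection` object: list with `steps` (tibble: order,
#'   factor, r2 contribution, cumulative adjusted R2, F, p), `selected`,
#'   `full_adjusted_r2`, and `final` (the `niche_rda` fit on the selected
#'   factors, or `NULL` for an empty selection).
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_permutations = 999,
                           seed = 1L) {
  X <- as.data.frame(X)
  prep <- rda_prepare(Y, as.matrix(X))
  n <- prep$n
  Yc <- prep$Yc
  Xc <- prep$Xc
  sst <- sum(Yc^2)
  p_cols <- ncol(Xc)

  adj <- function(ssc, q) {
    r2 <- ssc / sst
    1 - (1 - r2) * (n - 1) / (n - q - 1)
  }
  basis <- function(cols) {
    if (length(cols) == 0) return(NULL)
    qx <- qr(Xc[, cols, drop = FALSE])
    qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  }

  full_adj <- adj(rda_ssc(basis(seq_len(p_cols)), Yc), qr(Xc)$rank)

  set.seed(seed)
  selected <- integer(0)
  steps <- tibble::tibble(
    order = integer(), factor = character(), r2 = double(),
    adjusted_r2 = double(), pseudo_F = double(), p_value = double()
  )
  Q_sel <- NULL
  repeat {
    candidates <- setdiff(seq_len(p_cols), selected)
    if (length(candidates) == 0) break
    ssc_sel <- rda_ssc(Q_sel, Yc)
    cand_adj <- vapply(candidates, function(j) {
      adj(rda_ssc(basis(c(selected, j)), Yc), length(selected) + 1)
    }, numeric(1))
    best <- candidates[which.max(cand_adj)]
    best_adj <- max(cand_adj)
    # double stopping rule: the candidate model must improve on the current
    # model and must not climb past the full model's adjusted R2
    cur_adj <- if (length(selected) == 0) 0 else adj(ssc_sel, length(selected))
    if (best_adj <= cur_adj || best_adj > full_adj) break

    Q_new <- basis(c(selected, best))
    q_new <- length(selected) + 1
    ssc_new <- rda_ssc(Q_new, Yc)
    f_obs <- (ssc_new - ssc_sel) / ((sst - ssc_new) / (n - q_new - 1))

    # reduced-model permutation: shuffle residuals of Y given the
    # already-selected factors
    fitted_sel <- if (is.null(Q_sel)) 0 else Q_sel %*% crossprod(Q_sel, Yc)
    E <- Yc - fitted_sel
    n_ge <- 0L
    for (i in seq_len(n_permutations)) {
      Yp <- fitted_sel + E[sample(n), , drop = FALSE]
      ssc_new_p <- rda_ssc(Q_new, Yp)
      ssc_sel_p <- rda_ssc(Q_sel, Yp)
      f_p <- (ssc_new_p - ssc_sel_p) / ((sum(Yp^2) - ssc_new_p) / (n - q_new - 1))
      if (f_p >= f_obs) n_ge <- n_ge + 1L
    }
    p_val <- (1 + n_ge) / (1 + n_permutations)
    if (p_val > alpha) break

    selected <- c(selected, best)
    Q_sel <- Q_new
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      order = length(selected),
      factor = colnames(Xc)[best],
      r2 = (ssc_new - ssc_sel) / sst,
      adjusted_r2 = adj(ssc_new, q_new),
      pseudo_F = f_obs,
      p_value = p_val
    ))
  }

  final <- if (length(selected) > 0) {
    rda_fit(Y, X[, colnames(Xc)[selected], drop = FALSE])
  } else NULL
  structure(
    list(steps = steps, selected = colnames(Xc)[selected],
         full_adjusted_r2 = full_adj, final = final,
         alpha = alpha, n_permutations = n_permutations, seed = seed),
    class = "forward_selection"
  )
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("<forward_selection> ", length(x$selected), " factor(s) selected",
      " (full-model adj R2 = ", signif(x$full_adjusted_r2, 4), ")\n",
      sep = "")
  if (nrow(x$steps) > 0) print(x$steps)
  invisible(x)
}

#' @export
tidy.forward_selection <- function(x, ...) x$steps

#' @export
glance.forward_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    full_adjusted_r2 = x$full_adjusted_r2,
    final_adjusted_r2 = if (is.null(x$final)) NA_real_ else x$final$adjusted_r2,
    alpha = x$alpha,
    n_permutations = x$n_permutations
  )
}
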
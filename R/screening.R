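#' Screen environmental factors by shadow-feature importance
#'
#' Fits a seeded random-forest regression of the response on the candidate
#' factors augmented with shadow copies of each factor (the same column
#' with its rows permuted, which preserves the marginal distribution while
#' destroying any association with the response). Permutation importance is
#' computed for every column; the mean ("Mean") and maximum ("MAX") of the
#' shadow importances calibrate what importance an irrelevant factor can
#' reach by chance. Factors with importance above Mean are classed as
#' high-contribution, above MAX as very-high-contribution.
#'
#' Because real and shadow columns are exchangeable when the response is
#' pure noise, the chance that any irrelevant factor exceeds MAX is about
#' n_factors / (n_factors x (1 + shadow_copies)); the default of 19 shadow
#' copies per factor holds that family-wise rate near the conventional 5%.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (default: all
#'   other numeric columns).
#' @param n_trees Number of trees (default 500).
#' @param shadow_copies Independently permuted shadow copies per factor
#'   (default 19).
#' @param seed Integer seed; the screen is bit-reproducible for a fixed
#'   seed and input ordering.
#'
#' @return An `importance_screen` object: a list with `importance` (tibble
#'   of factor, importance, classification), `shadow_mean`, `shadow_max`,
#'   `high_set`, `very_high_set`, `response`, `seed`, `n_trees`.
#' @export
importance_screen <- function(data, response, factors = NULL,
                              n_trees = 500, shadow_copies = 19, seed = 1L) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) abort(paste0("no column `", response, "`"))
  if (is.null(factors)) {
    factors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       response)
  }
  X <- data[, factors, drop = FALSE]
  y <- data[[response]]
  if (anyNA(X) || anyNA(y)) abort("missing cells in response or factors")
  if (sd(y) == 0) abort("constant response: nothing to screen")
  if (nrow(X) < 10) abort("need at least 10 rows")
  if (nrow(X) < 2 * length(factors)) {
    warn("fewer rows than 2x factors: importance estimates will be noisy")
  }

  set.seed(seed)
  shadow_names <- as.vector(outer(factors, seq_len(shadow_copies),
                                  function(f, k) paste0("shadow", k, "_", f)))
  shadows <- as.data.frame(lapply(
    setNames(shadow_names, shadow_names),
    function(nm) X[[sub("^shadow[0-9]+_", "", nm)]][sample(nrow(X))]
  ))
  aug <- cbind(X, shadows)
  aug$..response.. <- y

  fit <- ranger::ranger(
    dependent.variable.name = "..response..", data = aug,
    num.trees = n_trees, importance = "permutation",
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  shadow_imp <- imp[shadow_names]
  real_imp <- imp[factors]
  shadow_mean <- mean(shadow_imp)
  shadow_max <- max(shadow_imp)

  structure(
    list(
      importance = tibble::tibble(
        factor = factors,
        importance = unname(real_imp),
        contribution = dplyr::case_when(
          real_imp > shadow_max ~ "very high",
          real_imp > shadow_mean ~ "high",
          TRUE ~ "none"
        )
      ),
      shadow_mean = shadow_mean,
      shadow_max = shadow_max,
      high_set = factors[real_imp > shadow_mean],
      very_high_set = factors[real_imp > shadow_max],
      response = response,
      seed = seed,
      n_trees = n_trees,
      shadow_copies = shadow_copies
    ),
    class = "importance_screen"
  )
}

#' @export
print.importance_screen <- function(x, ...) {
  cat("<importance_screen> response:", x$response, "\n")
  cat("  shadow Mean =", signif(x$shadow_mean, 4),
      " MAX =", signif(x$shadow_max, 4), "\n")
  cat("  high:", paste(x$high_set, collapse = ", "), "\n")
  cat("  very high:", paste(x$very_high_set, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.importance_screen <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$importance))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), with R2_j from the least-squares regression of
#' column j on all other columns plus an intercept. A perfectly collinear
#' column yields `Inf`, never an error. Invariant to affine rescaling of
#' the columns.
#'
#' @param data Data frame or matrix of numeric factor columns (at least 2
#'   columns, more rows than columns).
#' @return A named numeric vector of VIFs.
#' @export
vif <- function(data) {
  X <- as.matrix(data)
  if (!is.numeric(X)) abort("all columns must be numeric")
  if (ncol(X) < 2) abort("need at least 2 columns")
  if (nrow(X) <= ncol(X)) abort("need more rows than columns")
  vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) return(NA_real_) # constant column: VIF undefined
    Z <- cbind(1, X[, -j, drop = FALSE])
    res <- qr.resid(qr(Z), yj)
    r2 <- 1 - sum(res^2) / sst
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(colnames(X))
}

#' Iterative VIF filtering of a factor table
#'
#' Repeatedly drops the single highest-VIF column while any VIF meets the
#' threshold, recomputing VIFs after each removal. Ties on the maximum are
#' broken toward the later column. Terminates when all remaining VIFs are
#' below the threshold or one column is left.
#'
#' @inheritParams vif
#' @param threshold Multicollinearity threshold (default 10: VIF >= 10
#'   flags strong multicollinearity).
#'
#' @return A `vif_filter` object: list with `retained` (column names),
#'   `removed` (tibble of factor and the VIF at removal), `final_vifs`.
#' @export
vif_filter <- function(data, threshold = 10) {
  if (threshold <= 0) abort("`threshold` must be positive")
  X <- as.data.frame(data)
  removed <- tibble::tibble(factor = character(), vif_at_removal = double())
  repeat {
    if (ncol(X) < 2) break
    v <- vif(X)
    vmax <- max(v, na.rm = TRUE)
    if (vmax < threshold) break
    # ties broken toward the later column
    drop_j <- max(which(v == vmax))
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      factor = names(v)[drop_j], vif_at_removal = vmax
    ))
    X <- X[, -drop_j, drop = FALSE]
  }
  final <- if (ncol(X) >= 2) vif(X) else setNames(numeric(0), character(0))
  structure(
    list(retained = names(X), removed = removed, final_vifs = final,
         threshold = threshold),
    class = "vif_filter"
  )
}

#' @export
print.vif_filter <- function(x, ...) {
  cat("<vif_filter> threshold", x$threshold, "\n")
  cat("  retained:", length(x$retained), "factor(s)\n")
  if (nrow(x$removed) > 0) {
    cat("  removed:", paste(x$removed$factor, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.vif_filter <- function(x, ...) {
  tibble::tibble(
    factor = names(x$final_vifs),
    vif = unname(x$final_vifs)
  )
}
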
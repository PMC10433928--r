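#' LMG relative-importance decomposition of R-squared
#'
#' Decomposes the R-squared of a multiple linear regression into
#' non-negative shares, one per regressor: each regressor's share is its
#' incremental R-squared when added to the model, averaged over all \eqn{p!}
#' orderings in which the regressors can enter (equivalently, the Shapley
#' value of the R-squared game). Shares always sum exactly to the full-model
#' R-squared, and for mutually orthogonal regressors each share equals the
#' regressor's marginal R-squared.
#'
#' Implemented by exact enumeration: the R-squared of every regressor subset
#' is computed once (\eqn{2^p} fits), and increments are averaged with the
#' combinatorial weights \eqn{|S|!(p-|S|-1)!/p!} — identical to the literal
#' average over orderings. Exactness restricts `p` to at most 8 regressors.
#'
#' @param response Numeric response vector.
#' @param regressors Data frame or matrix of regressors (p columns, p <= 8).
#' @return Tibble of class `relimp_result`: `term`, `lmg_share`; the
#'   full-model R-squared is attached as attribute `r_squared` and reported
#'   by [glance()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] + 0.5 * x[, 2] + rnorm(20, 0, 0.3)
#' lmg(y, x)
#' @export
lmg <- function(response, regressors) {
  X <- as.matrix(regressors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (p < 1) abort("at least one regressor is required")
  if (p > 8) abort("exact LMG enumeration is limited to p <= 8 regressors")
  if (length(response) != nrow(X)) abort("response and regressors differ in length")
  keep <- complete.cases(response, X)
  y <- response[keep]; X <- X[keep, , drop = FALSE]
  if (nrow(X) < p + 2) abort("too few complete rows for the design")
  if (var(y) == 0) abort("response has zero variance: R-squared is undefined")
  if (qr(cbind(1, X))$rank < p + 1) {
    abort("regressor matrix is collinear to singularity")
  }

  r2_subset <- subset_r2(y, X)
  w <- vapply(0:(p - 1), function(k) {
    factorial(k) * factorial(p - k - 1) / factorial(p)
  }, numeric(1))

  shares <- numeric(p)
  subsets <- seq_len(2^p) - 1L # bitmask over regressors
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    without_j <- subsets[bitwAnd(subsets, bit_j) == 0L]
    sizes <- vapply(without_j, popcount, integer(1))
    shares[j] <- sum(w[sizes + 1] *
                       (r2_subset[as.character(without_j + bit_j)] -
                          r2_subset[as.character(without_j)]))
  }

  out <- tibble::tibble(term = colnames(X), lmg_share = shares)
  attr(out, "r_squared") <- unname(r2_subset[as.character(2^p - 1)])
  attr(out, "n") <- length(y)
  class(out) <- c("relimp_result", class(out))
  out
}

# R-squared of every regressor subset, keyed by bitmask (as character).
subset_r2 <- function(y, X) {
  p <- ncol(X)
  tss <- sum((y - mean(y))^2)
  masks <- seq_len(2^p) - 1L
  r2 <- setNames(numeric(length(masks)), as.character(masks))
  for (m in masks) {
    if (m == 0L) { r2[["0"]] <- 0; next }
    cols <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2[[as.character(m)]] <- 1 - sum(fit$residuals^2) / tss
  }
  r2
}

popcount <- function(m) {
  n <- 0L
  while (m > 0L) { n <- n + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  n
}

#' @rdname lmg
#' @param x A `relimp_result`.
#' @param ... Unused.
#' @export
glance.relimp_result <- function(x, ...) {
  tibble::tibble(r.squared = attr(x, "r_squared"), nobs = attr(x, "n"),
                 n_terms = nrow(x))
}

#' Bootstrap confidence intervals for LMG shares
#'
#' Case-resampling bootstrap of the LMG decomposition: rows of
#' (response, regressors) are resampled with replacement `n_boot` times and
#' the shares recomputed; percentile intervals at level `conf` are returned.
#' A resample with fewer than p + 2 distinct rows cannot support the design
#' and is redrawn (the count of redraws is recorded).
#'
#' @param response Numeric response vector.
#' @param regressors Data frame or matrix of regressors.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; the same seed reproduces the intervals exactly.
#' @param conf Confidence level for the percentile intervals.
#' @return Tibble: `term`, `lmg_share` (point estimate on the original
#'   data), `ci_lower`, `ci_upper`; attributes `n_boot` and `n_redrawn`.
#' @export
lmg_bootstrap <- function(response, regressors, n_boot = 1000, seed = 1,
                          conf = 0.95) {
  if (n_boot < 100) abort("`n_boot` must be at least 100")
  X <- as.matrix(regressors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  n <- nrow(X)
  point <- lmg(response, X)
  set.seed(seed)
  shares <- matrix(NA_real_, n_boot, p)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= p + 2 &&
          qr(cbind(1, X[idx, , drop = FALSE]))$rank == p + 1) break
      n_redrawn <- n_redrawn + 1L
    }
    shares[b, ] <- lmg(response[idx], X[idx, , drop = FALSE])$lmg_share
  }
  if (n_redrawn > 0) {
    inform(sprintf("%d degenerate resample(s) redrawn", n_redrawn))
  }
  alpha <- (1 - conf) / 2
  out <- tibble::tibble(
    term = point$term,
    lmg_share = point$lmg_share,
    ci_lower = apply(shares, 2, quantile, probs = alpha),
    ci_upper = apply(shares, 2, quantile, probs = 1 - alpha)
  )
  attr(out, "r_squared") <- attr(point, "r_squared")
  attr(out, "n_boot") <- n_boot
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("relimp_result", class(out))
  out
}
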
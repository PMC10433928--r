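#' Principal component analysis of a trait matrix
#'
#' Standardises each trait to zero mean and unit variance, eigendecomposes
#' the correlation matrix, and returns loadings, scores and variance
#' fractions with a deterministic sign convention (the largest-magnitude
#' loading of each component is made positive, ties broken by trait order).
#' Missing cells are an error — imputation is the caller's responsibility —
#' as is a constant trait column, which is named in the error.
#'
#' @param traits Data frame whose numeric columns are the traits (>= 2);
#'   non-numeric columns (identifiers) are carried through to the scores.
#' @return Object of class `trait_pca`: `loadings` (traits x components),
#'   `scores` (tibble with the identifier columns and `PC1..PCk`),
#'   `var_frac` (variance fraction per component), `center`, `scale`.
#' @export
trait_pca <- function(traits) {
  df <- tibble::as_tibble(traits)
  num <- vapply(df, is.numeric, logical(1))
  ids <- df[, !num, drop = FALSE]
  X <- as.matrix(df[, num, drop = FALSE])
  if (ncol(X) < 2) abort("need at least 2 numeric trait columns")
  if (anyNA(X)) abort("trait matrix contains missing cells; impute before calling")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant trait column(s): %s",
                  paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  V <- eg$vectors
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_len(ncol(V))) {
    lead <- which.max(abs(V[, k]))
    if (V[lead, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- Z %*% V
  structure(
    list(
      loadings = V,
      scores = dplyr::bind_cols(ids, tibble::as_tibble(scores)),
      var_frac = eg$values / sum(eg$values),
      eigenvalues = eg$values,
      center = ctr, scale = sds, traits = colnames(X)
    ),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("Trait PCA: %d traits, %d components\n",
              length(x$traits), length(x$var_frac)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", head(x$var_frac, 4)), collapse = " "),
      if (length(x$var_frac) > 4) "...\n" else "\n")
  invisible(x)
}

#' @rdname trait_pca
#' @param x A `trait_pca`.
#' @param ... Unused.
#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @rdname trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(
    n_traits = length(x$traits),
    var_frac_pc1 = x$var_frac[1],
    var_frac_pc2 = if (length(x$var_frac) > 1) x$var_frac[2] else NA_real_,
    cum_var_2 = sum(head(x$var_frac, 2))
  )
}

#' Regress a response on leading principal-component scores
#'
#' Ordinary least squares of a response (e.g. the sap-flux sensitivity to
#' log deficit) on the first `k` component scores of a [trait_pca()].
#'
#' @param response Numeric response, aligned with the score rows.
#' @param pca A `trait_pca`.
#' @param k Number of leading components (>= 1, <= available).
#' @return Object of class `pc_regression`: coefficient tibble (`term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`), `r_squared`, `n`, `k`.
#' @export
regress_on_pcs <- function(response, pca, k = 2) {
  stopifnot(inherits(pca, "trait_pca"))
  if (k < 1) abort("`k` must be at least 1")
  if (k > length(pca$var_frac)) abort("`k` exceeds the available components")
  S <- as.matrix(pca$scores[, paste0("PC", seq_len(k)), drop = FALSE])
  if (length(response) != nrow(S)) abort("response length does not match scores")
  fit <- lm(response ~ S)
  sm <- summary(fit)
  cf <- sm$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = c("(Intercept)", paste0("PC", seq_len(k))),
        estimate = cf[, 1], std.error = cf[, 2],
        statistic = cf[, 3], p.value = cf[, 4]
      ),
      r_squared = sm$r.squared, n = length(response), k = k, model = fit
    ),
    class = "pc_regression"
  )
}

#' @export
print.pc_regression <- function(x, ...) {
  cat(sprintf("Response ~ first %d PC scores  (n = %d, R2 = %.3f)\n",
              x$k, x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @rdname regress_on_pcs
#' @param x A `pc_regression`.
#' @param ... Unused.
#' @export
tidy.pc_regression <- function(x, ...) x$coefficients

#' @rdname regress_on_pcs
#' @export
glance.pc_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n, k = x$k)
}

#' Tukey-type multiple comparison among species
#'
#' One-way linear model followed by all pairwise comparisons with the
#' studentized-range (Tukey-Kramer) adjustment; p-values come from base R's
#' numerical integration of the range distribution. An optional variance-
#' stabilising pre-transformation (log or square root) is applied before
#' fitting and recorded in the output. Group means and standard errors are
#' reported on the (possibly transformed) analysis scale, together with a
#' compact letter display at level `alpha` (insert-and-absorb algorithm;
#' groups sharing a letter do not differ significantly).
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`; >= 2 groups with
#'   >= 2 values each.
#' @param transform `"none"`, `"log"` or `"sqrt"`.
#' @param alpha Significance level for the letter display.
#' @return Object of class `tukey_comparison`: `groups` tibble (`group`, `n`,
#'   `mean`, `se`, `letters`), `pairs` tibble (`group1`, `group2`, `diff`,
#'   `q`, `p_adj`), plus the transform and alpha used.
#' @export
tukey_compare <- function(values, groups, transform = c("none", "log", "sqrt"),
                          alpha = 0.05) {
  transform <- match.arg(transform)
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab < 2)) {
    abort(sprintf("group(s) with a single value: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  y <- switch(transform,
    none = values,
    log = { if (any(values <= 0)) abort("log transform needs positive values"); log(values) },
    sqrt = { if (any(values < 0)) abort("sqrt transform needs non-negative values"); sqrt(values) }
  )
  glev <- unique(groups)
  k <- length(glev)
  ni <- as.numeric(tab[glev])
  mi <- vapply(glev, function(g) mean(y[groups == g]), numeric(1))
  n <- length(y)
  df_err <- n - k
  mse <- sum((y - mi[groups])^2) / df_err

  pairs <- utils::combn(glev, 2)
  pair_tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se_pair <- sqrt(mse / 2 * (1 / tab[[g1]] + 1 / tab[[g2]]))
    q <- abs(mi[g1] - mi[g2]) / se_pair
    tibble::tibble(
      group1 = g1, group2 = g2,
      diff = unname(mi[g1] - mi[g2]), q = unname(q),
      p_adj = ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    )
  })

  group_tbl <- tibble::tibble(
    group = glev, n = ni, mean = unname(mi),
    se = sqrt(mse / ni),
    letters = cld_insert_absorb(glev, pair_tbl, alpha)
  )
  structure(
    list(groups = group_tbl, pairs = pair_tbl,
         transform = transform, alpha = alpha,
         mse = mse, df = df_err),
    class = "tukey_comparison"
  )
}

# Compact letter display by insert-and-absorb: start from one class holding
# every group; for each significantly different pair present together in a
# class, split the class in two (dropping one member from each copy); absorb
# classes contained in others. Letters follow class creation order; ties in
# membership keep the input group order.
cld_insert_absorb <- function(glev, pair_tbl, alpha) {
  classes <- list(glev)
  sig <- pair_tbl[pair_tbl$p_adj < alpha, , drop = FALSE]
  if (nrow(sig)) {
    for (j in seq_len(nrow(sig))) {
      g1 <- sig$group1[j]; g2 <- sig$group2[j]
      new_classes <- list()
      for (cl in classes) {
        if (g1 %in% cl && g2 %in% cl) {
          new_classes <- c(new_classes, list(setdiff(cl, g1)), list(setdiff(cl, g2)))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      # absorb: drop classes that are subsets of another
      keep <- rep(TRUE, length(new_classes))
      for (a in seq_along(new_classes)) {
        for (b in seq_along(new_classes)) {
          if (a != b && keep[a] &&
              all(new_classes[[a]] %in% new_classes[[b]]) &&
              (length(new_classes[[a]]) < length(new_classes[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      classes <- new_classes[keep]
    }
  }
  vapply(glev, function(g) {
    paste(letters[which(vapply(classes, function(cl) g %in% cl, logical(1)))],
          collapse = "")
  }, character(1))
}

#' @export
print.tukey_comparison <- function(x, ...) {
  cat(sprintf("Tukey multiple comparison (%s scale, alpha = %.2f)\n",
              x$transform, x$alpha))
  print(x$groups)
  invisible(x)
}

#' @rdname tukey_compare
#' @param x A `tukey_comparison`.
#' @param ... Unused.
#' @export
tidy.tukey_comparison <- function(x, ...) x$pairs

#' @rdname tukey_compare
#' @export
glance.tukey_comparison <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$groups), df = x$df, mse = x$mse,
                 transform = x$transform)
}

#' Model calibration quality from hydraulic traits
#'
#' Cross-species model for the strength of the conductance calibration:
#' regresses the per-tree R-squared of the conductance vs flux-to-deficit
#' relationship on the tree's Huber value and plant hydraulic conductance,
#' pooling all species. Reports coefficient tests, residual diagnostics
#' (Shapiro-Wilk normality, Breusch-Pagan heteroscedasticity, design
#' condition number), and the LMG relative-importance shares of the two
#' predictors with case-bootstrap confidence intervals.
#'
#' @param data Tibble with one row per tree.
#' @param response,hv,kplant Column names (strings) of the calibration
#'   R-squared, Huber value and plant conductance.
#' @param n_boot Bootstrap resamples for the share intervals.
#' @param seed Seed for the bootstrap.
#' @return Object of class `r2_trait_model`: coefficient tibble, `r_squared`,
#'   `p_value` (model F test), `diagnostics`, and `relimp` (shares with CIs).
#' @export
fit_r2_model <- function(data, response = "r_squared", hv = "hv_cm2_cm2",
                         kplant = "kplant_mol_m2_s_mpa",
                         n_boot = 1000, seed = 1) {
  check_columns(data, c(response, hv, kplant), "data")
  df <- tibble::as_tibble(data)[, c(response, hv, kplant)]
  names(df) <- c("y", "hv", "kplant")
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 6) abort("need at least 6 trees to fit the trait model")
  fit <- lm(y ~ hv + kplant, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  X <- as.matrix(df[, c("hv", "kplant")])
  colnames(X) <- c(hv, kplant)
  # a response with no variance (e.g. a noise-free campaign where every
  # calibration is perfect) has no R-squared to decompose
  rel <- tryCatch(
    lmg_bootstrap(df$y, X, n_boot = n_boot, seed = seed),
    error = function(e) {
      warn(sprintf("relative importance unavailable: %s", conditionMessage(e)))
      out <- tibble::tibble(term = colnames(X), lmg_share = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_)
      class(out) <- c("relimp_result", class(out))
      out
    }
  )
  # degenerate fits (e.g. an exactly reproduced response) break the residual
  # tests; report NA rather than failing the stage
  diagnostics <- tibble::tibble(
    shapiro_p = tryCatch(shapiro.test(fit$residuals)$p.value,
                         error = function(e) NA_real_),
    breusch_pagan_p = tryCatch(unname(lmtest::bptest(fit)$p.value),
                               error = function(e) NA_real_),
    condition_number = kappa(scale(X), exact = TRUE)
  )
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(sm$coefficients),
        estimate = sm$coefficients[, 1], std.error = sm$coefficients[, 2],
        statistic = sm$coefficients[, 3], p.value = sm$coefficients[, 4]
      ),
      r_squared = sm$r.squared,
      p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
      diagnostics = diagnostics,
      relimp = rel,
      n = nrow(df), model = fit
    ),
    class = "r2_trait_model"
  )
}

#' @export
print.r2_trait_model <- function(x, ...) {
  cat(sprintf("Calibration-quality trait model (n = %d, R2 = %.3f, p = %.3g)\n",
              x$n, x$r_squared, x$p_value))
  print(x$coefficients)
  cat("LMG shares with bootstrap CIs:\n")
  print(x$relimp)
  invisible(x)
}

#' @rdname fit_r2_model
#' @param x An `r2_trait_model`.
#' @param ... Unused.
#' @export
tidy.r2_trait_model <- function(x, ...) x$coefficients

#' @rdname fit_r2_model
#' @export
glance.r2_trait_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n),
    x$diagnostics
  )
}
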
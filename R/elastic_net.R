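#' Elastic net specification
#'
#' Bundles the tuning choices of the penalty-factor-weighted elastic net:
#' mixing parameter `alpha` (0.5 by default, the value used for all
#' expression models here), the descending `lambda_grid` (computed from
#' the data when `NULL`), the number of cross-validation folds used to
#' pick lambda, and per-variant `penalty_factors` (1 for every variant in
#' the plain family; `1 - PIP` in the fine-mapping-weighted family; 0
#' means a variant is never penalized).
#'
#' @param alpha Elastic net mixing parameter in `[0, 1]`.
#' @param lambda_grid Optional strictly descending positive grid.
#' @param n_cv_folds Folds for lambda selection (default 10).
#' @param penalty_factors Optional non-negative per-variant multipliers.
#' @return An `ElasticNetSpec` list.
#' @export
elastic_net_spec <- function(alpha = 0.5, lambda_grid = NULL,
                             n_cv_folds = 10, penalty_factors = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, n_cv_folds >= 2)
  if (!is.null(lambda_grid)) {
    stopifnot(all(lambda_grid > 0), !is.unsorted(rev(lambda_grid), strictly = TRUE))
  }
  if (!is.null(penalty_factors)) stopifnot(all(penalty_factors >= 0))
  structure(list(alpha = alpha, lambda_grid = lambda_grid,
                 n_cv_folds = n_cv_folds, penalty_factors = penalty_factors),
            class = "ElasticNetSpec")
}

# lambda_max: smallest lambda with the all-zero solution, honoring penalty
# factors (unpenalized variants excluded -- they never obey the threshold).
enet_lambda_grid <- function(Xs, yc, alpha, pf, n_lambda = 100,
                             lambda_min_ratio = 1e-3) {
  n <- length(yc)
  a <- max(alpha, 0.001) # ridge edge: glmnet-style floor for the grid only
  g <- abs(as.numeric(crossprod(Xs, yc)) / n)
  pen <- pf > 0
  lam_max <- if (any(pen)) max(g[pen] / (a * pf[pen])) else 1
  lam_max <- max(lam_max, .Machine$double.eps)
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = n_lambda))
}

#' Fit a penalty-factor-weighted elastic net
#'
#' Minimizes `(1/2n)||y - b0 - X beta||^2 +
#' lambda * sum_j f_j [alpha |beta_j| + (1-alpha) beta_j^2 / 2]`
#' by cyclic coordinate descent over a descending lambda grid with warm
#' starts. Columns of `X` are standardized internally and `y` is centered;
#' penalty factors are rescaled to mean 1 (so lambda grids are comparable
#' across genes), except that a factor of exactly 0 keeps its variant
#' unpenalized. Lambda is chosen to minimize the mean cross-validated
#' squared error over `spec$n_cv_folds` folds, then the model is refit on
#' the full data at that lambda. Coefficients are returned on the
#' original per-allele dosage scale.
#'
#' @param X Numeric design matrix (samples by variants).
#' @param y Numeric response.
#' @param spec An [elastic_net_spec()].
#' @param seed Integer seed controlling fold assignment.
#' @return List with `coefficients` (named, original scale), `intercept`,
#'   `lambda` (chosen), `lambda_grid`, `cv_error` (mean CV MSE per
#'   lambda), `alpha` and `penalty_factors` (as rescaled).
#' @export
fit_weighted_elastic_net <- function(X, y, spec = elastic_net_spec(), seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p == 0) stop("empty design: no variants to fit")
  stopifnot(length(y) == n)
  if (sd(y) < .Machine$double.eps) stop("degenerate input: y is constant")
  if (n < 2 * spec$n_cv_folds)
    stop("need at least 2 samples per cross-validation fold")

  pf <- spec$penalty_factors %||% rep(1, p)
  stopifnot(length(pf) == p, all(pf >= 0))
  if (sum(pf) > 0) pf <- pf * p / sum(pf) # mean-1 rescaling, zeros preserved

  sx <- std_cols(X)
  yc <- y - mean(y)
  lambda <- spec$lambda_grid %||% enet_lambda_grid(sx$X, yc, spec$alpha, pf)

  folds <- make_folds(n, spec$n_cv_folds, seed)
  cv_sse <- matrix(NA_real_, spec$n_cv_folds, length(lambda))
  for (k in seq_len(spec$n_cv_folds)) {
    tr <- folds != k
    sxt <- std_cols(X[tr, , drop = FALSE])
    ytr <- y[tr] - mean(y[tr])
    B <- cd_enet_path(sxt$X, ytr, lambda, spec$alpha, pf, 1e-7, 10000L)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, sxt$center, "-"),
                 2L, sxt$scale, "/")
    pred <- Xte %*% B + mean(y[tr])
    cv_sse[k, ] <- colSums((pred - y[!tr])^2)
  }
  cvm <- colSums(cv_sse) / n
  l_idx <- which.min(cvm)

  B <- cd_enet_path(sx$X, yc, lambda[seq_len(l_idx)], spec$alpha, pf,
                    1e-9, 100000L)
  beta_std <- B[, l_idx]
  beta <- beta_std / sx$scale
  names(beta) <- colnames(X)
  list(coefficients = beta,
       intercept = mean(y) - sum(beta * sx$center),
       lambda = lambda[l_idx],
       lambda_grid = lambda,
       cv_error = cvm,
       alpha = spec$alpha,
       penalty_factors = pf)
}

#' Nested cross-validated prediction performance
#'
#' Out-of-sample performance of a fitting procedure: for each outer fold
#' the trainer is fit on the complement (all tuning, including lambda
#' selection, happens inside the training portion), the held-out fold is
#' predicted, and the fold's Pearson correlation `r_i` (fold size `n_i`)
#' is recorded. Fold correlations are combined with the Fisher
#' transformation and Stouffer's method:
#' `z_i = atanh(r_i) * sqrt(n_i - 3)`, `Z = sum(z_i) / sqrt(k)`, and
#' `p_combined` is the one-sided upper-tail normal probability of `Z`
#' (predictive models are only useful when the correlation is positive).
#'
#' @param X,y Design and response.
#' @param trainer Function `(X, y, seed)` returning either a prediction
#'   function of a new design matrix, or a list with `coefficients` and
#'   `intercept`.
#' @param n_outer_folds Outer folds (default 10).
#' @param seed Integer seed for fold assignment (trainers get child seeds).
#' @return A `PerformanceEstimate`: list with `rho_avg` (mean fold
#'   correlation), `p_combined`, and `per_fold` data frame (`n`, `r`).
#' @export
nested_cv_performance <- function(X, y, trainer, n_outer_folds = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 2 * n_outer_folds) stop("need at least 2 samples per outer fold")
  folds <- make_folds(n, n_outer_folds, child_seed(seed, "outer"))
  r <- numeric(n_outer_folds)
  ni <- integer(n_outer_folds)
  for (k in seq_len(n_outer_folds)) {
    te <- folds == k
    fit <- trainer(X[!te, , drop = FALSE], y[!te], child_seed(seed, paste0("fold", k)))
    pred <- if (is.function(fit)) {
      fit(X[te, , drop = FALSE])
    } else {
      as.numeric(X[te, , drop = FALSE] %*% fit$coefficients + fit$intercept)
    }
    ni[k] <- sum(te)
    if (sd(pred) < .Machine$double.eps || sd(y[te]) < .Machine$double.eps) {
      warning("constant out-of-fold prediction in fold ", k, "; r set to 0")
      r[k] <- 0
    } else {
      r[k] <- cor(pred, y[te])
    }
  }
  combine_fold_correlations(r, ni)
}

#' Combine per-fold correlations (Fisher + Stouffer)
#'
#' The closed-form combination used by [nested_cv_performance()], exposed
#' so hand-specified fold correlations can be scored directly.
#'
#' @param r Per-fold Pearson correlations.
#' @param n Per-fold sample sizes (each > 3).
#' @return A `PerformanceEstimate` list (`rho_avg`, `p_combined`,
#'   `per_fold`).
#' @export
combine_fold_correlations <- function(r, n) {
  stopifnot(length(r) == length(n), all(n > 3))
  rc <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(rc) * sqrt(n - 3)
  Z <- sum(z) / sqrt(length(z))
  structure(list(rho_avg = mean(r),
                 p_combined = pnorm(Z, lower.tail = FALSE),
                 per_fold = data.frame(n = n, r = r)),
            class = "PerformanceEstimate")
}
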
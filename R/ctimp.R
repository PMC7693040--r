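#' Cross-tissue imputation model specification
#'
#' Tuning choices for the multi-tissue sparse group lasso: a lasso
#' penalty `lambda1` within each tissue and a group-lasso penalty
#' `lambda2` tying each variant's effects across tissues. When the
#' lambda grids are `NULL` a 5 x 5 log-spaced grid is derived from the
#' data and `(lambda1, lambda2)` chosen by fivefold cross-validated error
#' pooled across tissues.
#'
#' @param lambda1_grid,lambda2_grid Optional non-negative grids (a scalar
#'   fixes the value).
#' @param n_cv_folds Cross-validation folds (default 5).
#' @param tol Relative-objective convergence tolerance (default 1e-6).
#' @param max_iter Block-coordinate-descent iteration cap (default 1000).
#' @return A `CtimpSpec` list.
#' @export
ctimp_spec <- function(lambda1_grid = NULL, lambda2_grid = NULL,
                       n_cv_folds = 5, tol = 1e-6, max_iter = 1000) {
  if (!is.null(lambda1_grid)) stopifnot(all(lambda1_grid >= 0))
  if (!is.null(lambda2_grid)) stopifnot(all(lambda2_grid >= 0))
  structure(list(lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                 n_cv_folds = n_cv_folds, tol = tol, max_iter = max_iter),
            class = "CtimpSpec")
}

ctimp_standardize <- function(panels) {
  lapply(panels, function(pn) {
    sx <- std_cols(as.matrix(pn$X))
    list(X = sx$X, y = pn$y - mean(pn$y), center = sx$center,
         scale = sx$scale, ybar = mean(pn$y))
  })
}

ctimp_grids <- function(std, n_grid = 5, min_ratio = 0.01) {
  U <- vapply(std, function(s)
    abs(as.numeric(crossprod(s$X, s$y)) / length(s$y)),
    numeric(ncol(std[[1]]$X)))
  U <- matrix(U, ncol = length(std))
  l1max <- max(U)
  l2max <- max(sqrt(rowSums(U^2)))
  list(l1 = exp(seq(log(l1max), log(l1max * min_ratio), length.out = n_grid)),
       l2 = exp(seq(log(l2max), log(l2max * min_ratio), length.out = n_grid)))
}

#' Fit the cross-tissue sparse group lasso
#'
#' Minimizes `sum_t (1/2 n_t) ||y_t - X_t beta_t||^2 +
#' lambda1 sum_t ||beta_t||_1 + lambda2 sum_j ||beta_(j.)||_2`
#' by block coordinate descent with proximal updates over variants
#' (exact, since per-tissue columns are standardized internally).
#' `(lambda1, lambda2)` are selected on a 2-D grid by cross-validated
#' squared error pooled across tissues. Coefficients are returned on the
#' original dosage scale per tissue.
#'
#' @param panels List per tissue of lists with `X` (samples by shared
#'   variants) and `y`.
#' @param spec A [ctimp_spec()].
#' @param seed Integer seed for fold assignment.
#' @return List with `coefficients` (variants-by-tissues matrix, original
#'   scale), `intercepts`, `lambda1`, `lambda2`, `objective_trace`,
#'   `converged` and `cv_error` (grid matrix, when tuned).
#' @export
fit_ctimp <- function(panels, spec = ctimp_spec(), seed = 1) {
  stopifnot(length(panels) >= 1)
  p <- ncol(panels[[1]]$X)
  stopifnot(all(vapply(panels, function(z) ncol(z$X), 0L) == p))
  std <- ctimp_standardize(panels)

  g <- ctimp_grids(std)
  l1g <- spec$lambda1_grid %||% g$l1
  l2g <- spec$lambda2_grid %||% g$l2

  cvm <- NULL
  if (length(l1g) > 1 || length(l2g) > 1) {
    k <- spec$n_cv_folds
    folds <- lapply(seq_along(panels), function(t)
      make_folds(nrow(panels[[t]]$X), k, child_seed(seed, paste0("ct", t))))
    cvm <- matrix(0, length(l1g), length(l2g), dimnames = list(NULL, NULL))
    ntot <- sum(vapply(panels, function(z) nrow(z$X), 0L))
    for (f in seq_len(k)) {
      tr_std <- lapply(seq_along(panels), function(t) {
        tr <- folds[[t]] != f
        sx <- std_cols(as.matrix(panels[[t]]$X)[tr, , drop = FALSE])
        list(X = sx$X, y = panels[[t]]$y[tr] - mean(panels[[t]]$y[tr]),
             center = sx$center, scale = sx$scale,
             ybar = mean(panels[[t]]$y[tr]))
      })
      for (i in seq_along(l1g)) for (j in seq_along(l2g)) {
        fitb <- cd_ctimp(lapply(tr_std, `[[`, "X"), lapply(tr_std, `[[`, "y"),
                         l1g[i], l2g[j], spec$tol, spec$max_iter,
                         matrix(0, p, length(panels)))
        sse <- 0
        for (t in seq_along(panels)) {
          te <- folds[[t]] == f
          Xte <- sweep(sweep(as.matrix(panels[[t]]$X)[te, , drop = FALSE],
                             2L, tr_std[[t]]$center, "-"),
                       2L, tr_std[[t]]$scale, "/")
          pred <- as.numeric(Xte %*% fitb$beta[, t]) + tr_std[[t]]$ybar
          sse <- sse + sum((pred - panels[[t]]$y[te])^2)
        }
        cvm[i, j] <- cvm[i, j] + sse / ntot
      }
    }
    best <- which(cvm == min(cvm), arr.ind = TRUE)[1, ]
    l1 <- l1g[best[1]]; l2 <- l2g[best[2]]
  } else {
    l1 <- l1g[1]; l2 <- l2g[1]
  }

  fit <- cd_ctimp(lapply(std, `[[`, "X"), lapply(std, `[[`, "y"),
                  l1, l2, spec$tol, spec$max_iter,
                  matrix(0, p, length(panels)))
  if (!fit$converged)
    warning("cross-tissue fit did not converge in ", spec$max_iter,
            " iterations; returning best iterate")
  beta <- vapply(seq_along(panels), function(t)
    fit$beta[, t] / std[[t]]$scale, numeric(p))
  beta <- matrix(beta, nrow = p,
                 dimnames = list(colnames(panels[[1]]$X), names(panels)))
  intercepts <- vapply(seq_along(panels), function(t)
    std[[t]]$ybar - sum(beta[, t] * std[[t]]$center), 0)
  list(coefficients = beta, intercepts = intercepts,
       lambda1 = l1, lambda2 = l2,
       objective_trace = fit$objective_trace, converged = fit$converged,
       cv_error = cvm)
}

#' Train cross-tissue imputation models for one gene
#'
#' Fits the cross-tissue sparse group lasso over all tissues jointly,
#' then estimates each tissue's out-of-sample performance by nested
#' cross-validation (the whole joint fit, including the 2-D lambda
#' search, is repeated inside each outer training set) and applies the
#' same strict retention filters as the elastic net family (`rho > 0.1`,
#' `p < 0.05`, per tissue).
#'
#' @param panels List per tissue of lists with `X`, `y` and optionally
#'   `variants` (data frame `id`, `ref`, `alt` shared across tissues --
#'   taken from the first tissue).
#' @param spec A [ctimp_spec()].
#' @param gene Gene id.
#' @param performance Set `FALSE` to skip nested CV and retention.
#' @param seed Integer seed.
#' @return List per tissue of `PredictionModel` (family `CTIMP-M`) or
#'   `ModelRejection`.
#' @export
train_gene_ctimp <- function(panels, spec = ctimp_spec(), gene = "gene",
                             performance = TRUE, seed = 1) {
  k <- spec$n_cv_folds
  if (!any(vapply(panels, function(z) nrow(z$X) >= 2 * k, TRUE)))
    stop("need at least one tissue with 2 samples per fold")
  tissues <- names(panels) %||% sprintf("tissue%d", seq_along(panels))
  vmeta <- panels[[1]]$variants %||%
    data.frame(id = colnames(panels[[1]]$X) %||%
                 sprintf("v%d", seq_len(ncol(panels[[1]]$X))),
               ref = "A", alt = "G", stringsAsFactors = FALSE)

  fit <- fit_ctimp(panels, spec, seed = child_seed(seed, "tune"))

  perf <- vector("list", length(panels))
  if (isTRUE(performance)) {
    folds <- lapply(seq_along(panels), function(t)
      make_folds(nrow(panels[[t]]$X), k, child_seed(seed, paste0("outer", t))))
    rmat <- matrix(0, k, length(panels))
    nmat <- matrix(0L, k, length(panels))
    for (f in seq_len(k)) {
      tr_panels <- lapply(seq_along(panels), function(t) {
        tr <- folds[[t]] != f
        list(X = as.matrix(panels[[t]]$X)[tr, , drop = FALSE],
             y = panels[[t]]$y[tr])
      })
      f_fit <- fit_ctimp(tr_panels, spec, seed = child_seed(seed, paste0("in", f)))
      for (t in seq_along(panels)) {
        te <- folds[[t]] == f
        pred <- as.numeric(as.matrix(panels[[t]]$X)[te, , drop = FALSE] %*%
                             f_fit$coefficients[, t]) + f_fit$intercepts[t]
        nmat[f, t] <- sum(te)
        rmat[f, t] <- if (sd(pred) < .Machine$double.eps) {
          warning("constant out-of-fold prediction (tissue ", t,
                  ", fold ", f, "); r set to 0")
          0
        } else cor(pred, panels[[t]]$y[te])
      }
    }
    perf <- lapply(seq_along(panels), function(t)
      combine_fold_correlations(rmat[, t], nmat[, t]))
  }

  out <- lapply(seq_along(panels), function(t) {
    w <- data.frame(variant_id = vmeta$id, ref = vmeta$ref, alt = vmeta$alt,
                    weight = fit$coefficients[, t], stringsAsFactors = FALSE)
    if (all(w$weight == 0))
      return(model_rejection(gene, tissues[t], "CTIMP-M", "all_zero_weights"))
    if (isTRUE(performance) && !retained(perf[[t]]))
      return(model_rejection(gene, tissues[t], "CTIMP-M", "performance_filter"))
    prediction_model(gene, tissues[t], "CTIMP-M", w, perf[[t]])
  })
  names(out) <- tissues
  out
}
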
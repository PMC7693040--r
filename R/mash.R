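#' Canonical covariance prior components
#'
#' The mixture-of-covariances prior for cross-tissue effect sharing is
#' built from canonical T x T components: the zero matrix (null effects),
#' the identity (independent tissue-specific effects of equal scale), the
#' T singleton matrices (an effect in exactly one tissue), and the
#' all-ones equal-effects matrix (perfectly shared effects). Each
#' non-null component is crossed with a positive scale grid at fit time.
#' Duplicate matrices (which arise when `n_tissues = 1`) are removed.
#'
#' @param n_tissues Number of tissues (T >= 1).
#' @param scale_grid Optional strictly increasing positive scales; when
#'   `NULL`, [fit_mixture_em()] uses `c(0.1, 0.25, 0.5, 1, 2, 4)` times
#'   the median squared standard error of the panel.
#' @return A `CovariancePriorSet`: list with `components` (named list of
#'   T x T PSD matrices, the first labelled `null`) and `scale_grid`.
#' @export
canonical_covariances <- function(n_tissues, scale_grid = NULL) {
  stopifnot(n_tissues >= 1)
  if (!is.null(scale_grid))
    stopifnot(all(scale_grid > 0), !is.unsorted(scale_grid, strictly = TRUE))
  T <- n_tissues
  comps <- list(null = matrix(0, T, T), identity = diag(T))
  for (t in seq_len(T)) {
    U <- matrix(0, T, T); U[t, t] <- 1
    comps[[paste0("singleton_", t)]] <- U
  }
  comps$equal_effects <- matrix(1, T, T)
  sig <- vapply(comps, function(U) paste(U, collapse = ","), "")
  comps <- comps[!duplicated(sig)]
  structure(list(components = comps, scale_grid = scale_grid),
            class = "CovariancePriorSet")
}

# Expand (component x scale) pairs; the null enters once with scale 1.
expand_components <- function(priors, scale_grid) {
  out <- list(list(label = "null", U = priors$components$null, omega = 1))
  for (nm in setdiff(names(priors$components), "null"))
    for (w in scale_grid)
      out[[length(out) + 1L]] <- list(label = sprintf("%s:%g", nm, w),
                                      U = priors$components[[nm]], omega = w)
  out
}

# Per-row per-component Gaussian log-likelihoods, restricted to observed
# coordinates, with row-specific diagonal error covariance diag(shat^2).
component_logliks <- function(bhat, shat, comps) {
  R <- nrow(bhat)
  L <- matrix(-Inf, R, length(comps))
  for (r in seq_len(R)) {
    obs <- which(is.finite(bhat[r, ]) & is.finite(shat[r, ]))
    if (length(obs) == 0) { L[r, ] <- 0; next }
    b <- bhat[r, obs]
    s2 <- shat[r, obs]^2
    for (k in seq_along(comps)) {
      Sig <- comps[[k]]$omega * comps[[k]]$U[obs, obs, drop = FALSE]
      diag(Sig) <- diag(Sig) + s2
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) {
        ch <- tryCatch(chol(Sig + diag(1e-10, length(obs))),
                       error = function(e) NULL)
        if (is.null(ch)) next # component unusable for this row
      }
      v <- backsolve(ch, b, transpose = TRUE)
      L[r, k] <- -0.5 * length(obs) * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * sum(v^2)
    }
  }
  L
}

#' Fit mixture weights by expectation-maximization
#'
#' Empirical-Bayes step of the cross-tissue shrinkage model: with the
#' covariance components fixed, maximizes the marginal log-likelihood
#' `sum_rows log sum_k pi_k N(bhat_row; 0, omega_k U_k + S_row)` over the
#' mixture weights `pi` by EM, where `S_row = diag(shat_row^2)`. Missing
#' tissue entries (NA) are marginalized out of a row's likelihood.
#'
#' @param panel List with `bhat` and `shat` matrices (rows = gene-variant
#'   pairs, columns = tissues); NA marks missing entries.
#' @param priors A [canonical_covariances()] set.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @return A `MixtureFit`: list with `pi` (named weights, summing to 1),
#'   `loglik_trace` (non-decreasing), `components` (expanded
#'   component/scale pairs) and `scale_grid`.
#' @export
fit_mixture_em <- function(panel, priors, tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(priors, "CovariancePriorSet"))
  bhat <- as.matrix(panel$bhat); shat <- as.matrix(panel$shat)
  stopifnot(nrow(bhat) >= 1, all(dim(bhat) == dim(shat)))
  grid <- priors$scale_grid %||%
    (c(0.1, 0.25, 0.5, 1, 2, 4) * median(shat^2, na.rm = TRUE))
  comps <- expand_components(priors, grid)
  K <- length(comps)
  L <- component_logliks(bhat, shat, comps)

  pi_k <- rep(1 / K, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2L, log(pi_k), "+")
    m <- apply(lw, 1L, max)
    ll <- sum(m + log(rowSums(exp(lw - m))))
    trace <- c(trace, ll)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-12)) break
    resp <- exp(lw - m)
    resp <- resp / rowSums(resp)
    pi_k <- colMeans(resp)
    pi_k <- pmax(pi_k, 0); pi_k <- pi_k / sum(pi_k)
  }
  names(pi_k) <- vapply(comps, `[[`, "", "label")
  structure(list(pi = pi_k, loglik_trace = trace, components = comps,
                 scale_grid = grid),
            class = "MixtureFit")
}

#' Posterior mean effect under the fitted shrinkage mixture
#'
#' For one gene-variant row of cross-tissue marginal effects, returns the
#' posterior mean effect vector: the responsibility-weighted average over
#' mixture components of `omega U (omega U + S)^-1 bhat`, with
#' `S = diag(shat^2)`. These posterior means are the weights of the
#' shrinkage-based prediction-model family. Missing tissues are
#' marginalized; their entries are returned as `NA`.
#'
#' @param bhat_row,shat_row Length-T effect and standard-error vectors.
#' @param fit A `MixtureFit`.
#' @param priors The `CovariancePriorSet` passed to [fit_mixture_em()]
#'   (consistency-checked against `fit`).
#' @return Length-T numeric vector of posterior mean effects.
#' @export
posterior_mean <- function(bhat_row, shat_row, fit, priors) {
  stopifnot(inherits(fit, "MixtureFit"))
  Tt <- length(bhat_row)
  comps <- fit$components
  obs <- which(is.finite(bhat_row) & is.finite(shat_row))
  out <- rep(NA_real_, Tt)
  if (length(obs) == 0) return(out)
  b <- bhat_row[obs]; s2 <- shat_row[obs]^2
  L <- component_logliks(matrix(bhat_row, 1), matrix(shat_row, 1), comps)[1, ]
  lw <- L + log(fit$pi)
  lw[!is.finite(lw)] <- -Inf
  w <- exp(lw - max(lw)); w <- w / sum(w)
  mu <- rep(0, length(obs))
  for (k in seq_along(comps)) {
    if (w[k] == 0 || comps[[k]]$label == "null") next
    V <- comps[[k]]$omega * comps[[k]]$U[obs, obs, drop = FALSE]
    Sig <- V; diag(Sig) <- diag(Sig) + s2
    mu <- mu + w[k] * as.numeric(V %*% solve(Sig, b))
  }
  out[obs] <- mu
  out
}
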
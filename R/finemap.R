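#' Bayesian fine-mapping by exact model enumeration
#'
#' Computes per-variant posterior inclusion probabilities (PIPs) for the
#' effect of cis-variants on an expression phenotype by exact enumeration
#' of all variant subsets up to `max_model_size`. Each subset is scored by
#' its Bayes factor under a conjugate zero-mean normal effect prior on the
#' standardized scale, combined with an independent-inclusion model prior,
#' normalized over the enumerated model space, and marginalized to PIPs.
#' This reproduces, at desk scale, the interface of fine-mappers whose
#' per-variant PIPs and LD clusters drive the fine-mapping-informed model
#' families; externally computed PIP tables can also be supplied via
#' [read_pip_table()].
#'
#' @param X Genotype submatrix (samples by variants); columns are
#'   standardized internally.
#' @param y Expression vector; standardized internally.
#' @param max_model_size Largest subset size enumerated (default 2; sizes
#'   above 3 are rarely tractable).
#' @param prior_inclusion Prior inclusion probability per variant
#'   (default `1/ncol(X)`).
#' @param effect_prior_variance Prior effect variance on the standardized
#'   scale (default `0.16`, i.e. prior sd 0.4).
#' @param max_models Enumeration budget; exceeding it raises a capacity
#'   error advising pre-filtering (default 2e5).
#' @return A `FineMapResult`: list with `pip` (length-p vector in `[0,1]`),
#'   `clusters` (empty until [cluster_by_ld()]) and `model_posteriors`
#'   (data frame of enumerated subsets and posterior probabilities).
#' @export
enumerate_pips <- function(X, y, max_model_size = 2,
                           prior_inclusion = NULL,
                           effect_prior_variance = 0.16,
                           max_models = 2e5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > 3, p >= 1)
  if (is.null(prior_inclusion)) prior_inclusion <- 1 / p
  K <- min(max_model_size, p)
  n_models <- sum(vapply(0:K, function(k) choose(p, k), 0))
  if (n_models > max_models)
    stop("enumeration budget exceeded (", format(n_models), " models); ",
         "pre-filter variants before fine-mapping")

  Xs <- std_cols(X)$X
  ys <- y - mean(y)
  sy <- sqrt(sum(ys^2) / n)
  if (sy < .Machine$double.eps) stop("y has zero variance")
  ys <- ys / sy

  v <- effect_prior_variance
  XtX <- crossprod(Xs) / n       # unit diagonal (standardized)
  Xty <- as.numeric(crossprod(Xs, ys)) / n
  yty <- sum(ys^2) / n           # = 1

  # log BF of model gamma vs the null, y ~ N(0, sigma2 (I + n v Xg Xg'/n)):
  # with columns scaled to x'x = n, beta ~ N(0, v I) on that scale gives
  # marginal covariance I + v Xg Xg'; sigma2 = 1 after standardizing y.
  log_bf <- function(idx) {
    k <- length(idx)
    if (k == 0) return(0)
    A <- diag(k) + n * v * XtX[idx, idx, drop = FALSE]
    q <- as.numeric(crossprod(Xty[idx], solve(A, Xty[idx]))) # (X'y/n)' A^-1 (X'y/n)
    -0.5 * as.numeric(determinant(A, logarithm = TRUE)$modulus) + 0.5 * n^2 * v * q
  }

  pi0 <- prior_inclusion
  sets <- list(integer(0))
  for (k in 1:K) sets <- c(sets, combn_list(p, k))
  logw <- vapply(sets, function(s) {
    log_bf(s) + length(s) * log(pi0) + (p - length(s)) * log1p(-pi0)
  }, 0)
  logw <- logw - max(logw)
  w <- exp(logw); w <- w / sum(w)

  pip <- numeric(p)
  for (i in seq_along(sets)) for (j in sets[[i]]) pip[j] <- pip[j] + w[i]
  pip <- pmin(pmax(pip, 0), 1)
  names(pip) <- colnames(X)

  mp <- data.frame(
    model = vapply(sets, function(s) paste(s, collapse = ","), ""),
    size = vapply(sets, length, 0L),
    posterior = w, stringsAsFactors = FALSE
  )
  structure(list(pip = pip, clusters = list(), model_posteriors = mp),
            class = "FineMapResult")
}

# All size-k subsets of 1:p as a list of integer vectors.
combn_list <- function(p, k) {
  if (k > p) return(list())
  m <- utils::combn(p, k)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Group fine-mapped variants into LD clusters
#'
#' Greedy clustering of variants by linkage disequilibrium: repeatedly
#' seed a cluster with the highest-PIP unassigned variant having
#' `pip >= pip_min`, then absorb every unassigned variant whose squared
#' correlation with the seed is at least `r2_min`. Variants below
#' `pip_min` remain unclustered. Each cluster records its summed PIP and
#' its representative (the member with maximal PIP, ties broken by lowest
#' variant index).
#'
#' @param fm A `FineMapResult` from [enumerate_pips()].
#' @param R Variant correlation matrix matching `fm$pip`.
#' @param r2_min Squared-correlation threshold for co-clustering
#'   (default 0.5).
#' @param pip_min Minimum PIP for cluster seeding (default 0.01).
#' @return `fm` with `clusters` filled: list of lists with `members`,
#'   `cluster_pip`, `representative`, `representative_pip`.
#' @export
cluster_by_ld <- function(fm, R, r2_min = 0.5, pip_min = 0.01) {
  stopifnot(inherits(fm, "FineMapResult"))
  p <- length(fm$pip)
  stopifnot(nrow(R) == p, ncol(R) == p)
  if (!(r2_min > 0 && r2_min <= 1)) stop("r2_min must be in (0, 1]")
  if (pip_min < 0 || pip_min >= 1) stop("pip_min must be in [0, 1)")

  pip <- fm$pip
  unassigned <- rep(TRUE, p)
  clusters <- list()
  repeat {
    cand <- which(unassigned & pip >= pip_min)
    if (length(cand) == 0) break
    seed <- cand[order(-pip[cand], cand)][1]
    members <- which(unassigned & (R[seed, ]^2 >= r2_min))
    members <- sort(unique(c(seed, members)))
    unassigned[members] <- FALSE
    rep_idx <- members[order(-pip[members], members)][1]
    clusters[[length(clusters) + 1L]] <- list(
      members = members,
      cluster_pip = sum(pip[members]),
      representative = rep_idx,
      representative_pip = unname(pip[rep_idx])
    )
  }
  fm$clusters <- clusters
  fm
}

#' Select the top variant per LD cluster
#'
#' Keeps one representative per fine-mapping cluster -- the member with
#' the highest PIP (lowest index on ties) -- restricted to representatives
#' with `pip > pip_min` (strict). These are the variants fed, with their
#' PIPs, into the fine-mapping-weighted elastic net and the
#' shrinkage-based model family; dropping within-cluster redundancy averts
#' collinear explanatory variables.
#'
#' @param fm A `FineMapResult` with clusters populated.
#' @param pip_min Strict lower PIP bound for a representative to be kept
#'   (default 0.01).
#' @return Data frame with columns `variant` (index) and `pip`; zero rows
#'   when no cluster representative clears the threshold (no model
#'   trainable for this gene).
#' @export
select_representatives <- function(fm, pip_min = 0.01) {
  stopifnot(inherits(fm, "FineMapResult"))
  if (length(fm$clusters) == 0)
    return(data.frame(variant = integer(0), pip = numeric(0)))
  out <- do.call(rbind, lapply(fm$clusters, function(cl)
    data.frame(variant = cl$representative, pip = cl$representative_pip)))
  out <- out[out$pip > pip_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}
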
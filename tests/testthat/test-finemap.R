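# Independent brute-force oracle: scores every subset by the explicit
# n-dimensional marginal Gaussian density N(y; 0, I + v X_g X_g') (full
# n x n covariance), the opposite factorization from the implementation.
brute_force_pips <- function(X, y, K, prior_inclusion, v) {
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X, center = TRUE, scale = FALSE)
  Xs <- sweep(Xs, 2L, sqrt(colSums(Xs^2) / n), "/")
  ys <- (y - mean(y)) / sqrt(sum((y - mean(y))^2) / n)
  log_dens <- function(idx) {
    Sig <- diag(n)
    if (length(idx) > 0)
      Sig <- Sig + v * Xs[, idx, drop = FALSE] %*% t(Xs[, idx, drop = FALSE])
    ch <- chol(Sig)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, ys, transpose = TRUE)^2)
  }
  sets <- list(integer(0))
  for (k in 1:K) {
    cmb <- combn(p, k)
    sets <- c(sets, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  lw <- vapply(sets, function(s)
    log_dens(s) + length(s) * log(prior_inclusion) +
      (p - length(s)) * log(1 - prior_inclusion), 0)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  pip <- numeric(p)
  for (i in seq_along(sets)) pip[sets[[i]]] <- pip[sets[[i]]] + w[i]
  pip
}

test_that("enumerated PIPs match the brute-force posterior to 1e-9", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    y <- 0.5 * X[, 3] + rnorm(n)
    fm <- enumerate_pips(X, y, max_model_size = 2, prior_inclusion = 0.05)
    oracle <- brute_force_pips(X, y, K = 2, prior_inclusion = 0.05, v = 0.16)
    expect_equal(unname(fm$pip), oracle, tolerance = 1e-9)
  }
})

test_that("a strong single eQTL among noise variants gets PIP above 0.95", {
  set.seed(1)
  n <- 300; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 4] + rnorm(n) # per-variant R^2 = 0.5
  fm <- enumerate_pips(X, y, max_model_size = 2)
  expect_gt(fm$pip[4], 0.95)
  expect_true(all(fm$pip >= 0 & fm$pip <= 1))
})

test_that("duplicated signal columns share PIP symmetrically", {
  set.seed(2)
  n <- 200
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  noise <- matrix(rnorm(n * 4), n, 4)
  Xdup <- cbind(x, x, noise)
  Xsingle <- cbind(x, noise)
  fm_dup <- enumerate_pips(Xdup, y, max_model_size = 2, prior_inclusion = 0.1)
  expect_equal(unname(fm_dup$pip[1]), unname(fm_dup$pip[2]), tolerance = 1e-9)
  # with single-variant models the duplicated pair splits the signal's
  # posterior mass exactly: the pair's PIPs sum to the deduplicated PIP
  fm_dup1 <- enumerate_pips(Xdup, y, max_model_size = 1, prior_inclusion = 0.1)
  fm_single1 <- enumerate_pips(Xsingle, y, max_model_size = 1, prior_inclusion = 0.1)
  expect_equal(unname(fm_dup1$pip[1]), unname(fm_dup1$pip[2]), tolerance = 1e-9)
  expect_equal(unname(fm_dup1$pip[1] + fm_dup1$pip[2]),
               unname(fm_single1$pip[1]), tolerance = 0.02)
})

test_that("null phenotypes give mean PIP near the prior inclusion mass", {
  set.seed(3)
  n <- 100; p <- 8
  pips <- replicate(500, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    mean(enumerate_pips(X, y, max_model_size = 1, prior_inclusion = 0.01)$pip)
  })
  expect_lt(abs(mean(pips) - 0.01), 0.01)
})

test_that("PIP is monotone in marginal association for orthogonal designs", {
  n <- 400; p <- 4
  set.seed(4)
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n) # orthogonal columns
  eps <- rnorm(n)
  pips <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(b) {
    y <- b * X[, 2] + eps
    enumerate_pips(X, y, max_model_size = 2)$pip[2]
  }, 0)
  expect_true(all(diff(pips) >= -1e-12))
})

test_that("enumeration capacity errors ask for pre-filtering", {
  X <- matrix(rnorm(50 * 30), 50, 30)
  expect_error(enumerate_pips(X, rnorm(50), max_model_size = 3,
                              max_models = 100), "pre-filter")
})

test_that("LD clustering follows the greedy absorb rule", {
  fm <- structure(list(pip = c(0.4, 0.4), clusters = list()),
                  class = "FineMapResult")
  R <- matrix(c(1, 1, 1, 1), 2) # perfect LD
  fm <- cluster_by_ld(fm, R)
  expect_length(fm$clusters, 1)
  expect_equal(fm$clusters[[1]]$members, c(1L, 2L))
  expect_equal(fm$clusters[[1]]$cluster_pip, 0.8)

  fm2 <- structure(list(pip = c(0.6, 0.6), clusters = list()),
                   class = "FineMapResult")
  fm2 <- cluster_by_ld(fm2, diag(2))
  expect_length(fm2$clusters, 2)
  expect_equal(lengths(lapply(fm2$clusters, `[[`, "members")), c(1L, 1L))

  # chain A-B r2 .8, B-C r2 .8, A-C r2 .1: A seeds and absorbs B; C alone
  R3 <- matrix(1, 3, 3)
  R3[1, 2] <- R3[2, 1] <- sqrt(0.8)
  R3[2, 3] <- R3[3, 2] <- sqrt(0.8)
  R3[1, 3] <- R3[3, 1] <- sqrt(0.1)
  fm3 <- structure(list(pip = c(0.5, 0.4, 0.3), clusters = list()),
                   class = "FineMapResult")
  fm3 <- cluster_by_ld(fm3, R3, r2_min = 0.5)
  expect_length(fm3$clusters, 2)
  expect_equal(fm3$clusters[[1]]$members, c(1L, 2L))
  expect_equal(fm3$clusters[[2]]$members, 3L)
})

test_that("cluster PIP equals the sum of member PIPs and clustering partitions", {
  set.seed(5)
  n <- 150; p <- 12
  G <- simulate_genotypes(n, p, block_size = 4, within_block_corr = 0.9,
                          maf_low = 0.2, maf_high = 0.5, seed = 5)
  y <- G$dosages[, 2] * 0.6 + G$dosages[, 9] * 0.5 + rnorm(n)
  fm <- enumerate_pips(G$dosages, y, max_model_size = 2)
  R <- cor(G$dosages)
  fm <- cluster_by_ld(fm, R, r2_min = 0.5, pip_min = 0.01)
  all_members <- unlist(lapply(fm$clusters, `[[`, "members"))
  expect_false(any(duplicated(all_members))) # disjoint
  expect_true(all(which(fm$pip >= 0.01) %in% all_members)) # covers
  for (cl in fm$clusters) {
    expect_equal(cl$cluster_pip, sum(fm$pip[cl$members]), tolerance = 1e-9)
    expect_equal(cl$representative_pip, max(fm$pip[cl$members]), tolerance = 1e-12)
  }
})

test_that("representative selection keeps the top variant per cluster, strictly above threshold", {
  fm <- structure(list(
    pip = c(A = 0.6, B = 0.3, C = 0.008),
    clusters = list(list(members = 1:2, cluster_pip = 0.9,
                         representative = 1L, representative_pip = 0.6),
                    list(members = 3L, cluster_pip = 0.008,
                         representative = 3L, representative_pip = 0.008))),
    class = "FineMapResult")
  reps <- select_representatives(fm, pip_min = 0.01)
  expect_equal(reps$variant, 1L)
  expect_equal(reps$pip, 0.6)

  # strict threshold: everything at or below 0.01 drops out
  fm$clusters[[1]]$representative_pip <- 0.01
  expect_equal(nrow(select_representatives(fm, 0.01)), 0)

  # tie within a cluster: lowest index wins
  fm2 <- structure(list(pip = c(0.4, 0.4), clusters = list()),
                   class = "FineMapResult")
  fm2 <- cluster_by_ld(fm2, matrix(1, 2, 2))
  expect_equal(fm2$clusters[[1]]$representative, 1L)
})
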
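test_that("cis window boundaries are closed and MAF/whitelist filters strict", {
  variants <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    pos = c(5e6 - 1e6, 5e6 - 1e6 - 1, 5e6, 6e6 + 1e6, 6e6 + 1e6 + 1),
    maf = c(0.2, 0.2, 0.2, 0.2, 0.2), stringsAsFactors = FALSE)
  idx <- cis_variant_filter(variants, gene_start = 5e6, gene_end = 6e6)
  expect_equal(variants$id[idx], c("a", "c", "d")) # closed boundaries

  variants$maf <- c(0.01, 0.0100001, 0.2, 0.009, 0.5)
  idx2 <- cis_variant_filter(variants, maf_min = 0.01)
  expect_equal(variants$id[idx2], c("b", "c", "e")) # maf == 0.01 excluded

  idx3 <- cis_variant_filter(variants, maf_min = 0,
                             panel_whitelist = c("a", "d"))
  expect_equal(variants$id[idx3], c("a", "d"))
})

test_that("a heritable gene is retained, with consistent model metadata", {
  pan <- make_gene_panel(n_samples = 400, n_genes = 1, variants_per_gene = 10,
                         h2 = 0.6, n_causal = 2, seed = 21)
  m <- train_gene_en(pan$G, pan$sim$panel[[1]]$expr[, 1],
                     c(pan$annotations[[1]], tissue = "tissue1"),
                     config = list(maf_min = 0), seed = 21)
  expect_s3_class(m, "PredictionModel")
  expect_identical(m$family, "EN-M")
  expect_gt(m$performance$rho_avg, 0.1)
  expect_lt(m$performance$p_combined, 0.05)
  expect_identical(m$n_snps, nrow(m$weights))
  expect_true(all(m$weights$weight != 0))
})

test_that("null genes are retained at no more than the nominal joint rate", {
  pan <- make_gene_panel(n_samples = 120, n_genes = 200, variants_per_gene = 8,
                         h2 = 0, seed = 22)
  kept <- 0L
  for (g in seq_len(200)) {
    m <- suppressWarnings(
      train_gene_en(pan$G, pan$sim$panel[[1]]$expr[, g],
                    pan$annotations[[g]], config = list(maf_min = 0),
                    seed = 300 + g))
    if (inherits(m, "PredictionModel")) kept <- kept + 1L
  }
  # joint requirement rho > .1 AND p < .05 is conservative under the null
  expect_lte(kept / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("retention inequalities are strict", {
  perf <- combine_fold_correlations(rep(0.1, 10), rep(40, 10))
  perf$rho_avg <- 0.1 # exactly at the boundary
  expect_false(finetwas:::retained(perf))
  perf2 <- list(rho_avg = 0.2, p_combined = 0.05)
  expect_false(finetwas:::retained(perf2))
  perf3 <- list(rho_avg = 0.2, p_combined = 0.049)
  expect_true(finetwas:::retained(perf3))
})

test_that("empty cis sets and rejections carry reason codes", {
  pan <- make_gene_panel(n_samples = 60, n_genes = 1, seed = 23)
  r <- train_gene_en(pan$G, pan$sim$panel[[1]]$expr[, 1],
                     list(gene = "g"), config = list(maf_min = 0.6))
  expect_s3_class(r, "ModelRejection")
  expect_identical(r$reason, "empty_cis_set")
})

test_that("fine-mapping penalty factors follow 1 - PIP and zero factors go unpenalized", {
  pan <- make_gene_panel(n_samples = 300, n_genes = 1, variants_per_gene = 8,
                         h2 = 0.5, n_causal = 1, seed = 24)
  y <- pan$sim$panel[[1]]$expr[, 1]
  fm <- finemap_gene(pan$G, y, pan$annotations[[1]], maf_min = 0)
  reps <- select_representatives(fm)
  expect_gt(nrow(reps), 0)
  m <- train_gene_dapgw(pan$G, y, fm, c(pan$annotations[[1]], tissue = "t"),
                        config = list(maf_min = 0), seed = 24)
  expect_s3_class(m, "PredictionModel")
  expect_identical(m$family, "DAPGW-M")
  # every model variant is a cluster representative
  rep_ids <- pan$G$variants$id[attr(fm, "cis_idx")[reps$variant]]
  expect_true(all(m$weights$variant_id %in% rep_ids))

  # a representative with PIP = 1 has penalty factor 0: always enters
  fm2 <- fm
  fm2$pip[] <- 0.001
  top <- fm$clusters[[1]]$representative
  fm2$pip[top] <- 1
  fm2$clusters <- list(list(members = top, cluster_pip = 1,
                            representative = top, representative_pip = 1))
  m2 <- train_gene_dapgw(pan$G, y, fm2, c(pan$annotations[[1]], tissue = "t"),
                         config = list(maf_min = 0, performance = FALSE),
                         seed = 24)
  expect_s3_class(m2, "PredictionModel")
  expect_identical(m2$weights$variant_id,
                   pan$G$variants$id[attr(fm, "cis_idx")[top]])
  expect_true(m2$weights$weight != 0)
})

test_that("the true causal representative is selected at least as often as a spurious one", {
  sel_causal <- 0L; sel_spurious <- 0L
  for (rep in 1:100) {
    set.seed(1000 + rep)
    n <- 150
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 0.35 * x1 + rnorm(n)
    G <- list(dosages = cbind(v1 = x1, v2 = x2),
              variants = data.frame(id = c("v1", "v2"), chrom = "1",
                                    pos = c(1000, 2000), ref = "A", alt = "G",
                                    maf = c(0.3, 0.3), stringsAsFactors = FALSE))
    fm <- structure(list(
      pip = c(0.9, 0.02),
      clusters = list(list(members = 1L, cluster_pip = 0.9,
                           representative = 1L, representative_pip = 0.9),
                      list(members = 2L, cluster_pip = 0.02,
                           representative = 2L, representative_pip = 0.02))),
      class = "FineMapResult")
    m <- train_gene_dapgw(G, y, fm, list(gene = "g", tissue = "t"),
                          config = list(maf_min = 0, performance = FALSE),
                          seed = rep)
    if (inherits(m, "PredictionModel")) {
      if ("v1" %in% m$weights$variant_id) sel_causal <- sel_causal + 1L
      if ("v2" %in% m$weights$variant_id) sel_spurious <- sel_spurious + 1L
    }
  }
  expect_gte(sel_causal, sel_spurious)
  expect_gt(sel_causal, 90) # the causal variant is nearly always kept
})

test_that("marginal eQTL scan matches closed forms and is calibrated", {
  set.seed(31)
  n <- 50
  x <- rnorm(n)
  expect_equal(marginal_eqtl_scan(matrix(x), 2 * x)$beta_hat, 2,
               tolerance = 1e-12)
  expect_lt(marginal_eqtl_scan(matrix(x), 2 * x)$se, 1e-10)

  X <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)
  sc <- marginal_eqtl_scan(X, y)
  for (j in 1:5) {
    expect_equal(sc$beta_hat[j], cov(X[, j], y) / var(X[, j]),
                 tolerance = 1e-10) # slope = cov(x, y) / var(x)
    lmfit <- summary(lm(y ~ X[, j]))$coefficients
    expect_equal(sc$beta_hat[j], lmfit[2, 1], tolerance = 1e-10)
    expect_equal(sc$se[j], lmfit[2, 2], tolerance = 1e-10)
  }

  # null calibration of z = beta/se over 10,000 variant-phenotype draws
  set.seed(32)
  z <- unlist(lapply(1:100, function(i) {
    Xn <- matrix(rnorm(60 * 100), 60, 100)
    s <- marginal_eqtl_scan(Xn, rnorm(60))
    s$beta_hat / s$se
  }))
  expect_lt(abs(mean(z)), 0.03)
  expect_lt(abs(var(z) - 1), 0.05)

  # zero-variance variant flagged
  sc2 <- marginal_eqtl_scan(cbind(rep(1, n), x), rnorm(n))
  expect_false(sc2$ok[1]); expect_true(sc2$ok[2])
})

test_that("shrinkage-family gene and variant gates follow the PIP rules", {
  fm <- structure(list(
    pip = c(0.05, 0.005, 0.5),
    clusters = list(list(members = 1L, cluster_pip = 0.05,
                         representative = 1L, representative_pip = 0.05))),
    class = "FineMapResult")
  bhat <- matrix(rnorm(6), 3, 2); shat <- matrix(1, 3, 2)
  priors <- canonical_covariances(2, scale_grid = c(0.5, 1))
  fit <- fit_mixture_em(list(bhat = bhat, shat = shat), priors)

  # max cluster PIP 0.05 <= 0.1: no model emitted
  r <- train_gene_mashr(fm, bhat, shat, fit, priors)
  expect_s3_class(r, "ModelRejection")
  expect_identical(r$reason, "no_cluster_above_pip")

  # gene gate passes but the 0.005-PIP variant stays excluded
  fm$clusters <- list(
    list(members = 1L, cluster_pip = 0.3, representative = 1L,
         representative_pip = 0.3),
    list(members = 2L, cluster_pip = 0.005, representative = 2L,
         representative_pip = 0.005))
  fm$pip <- c(0.3, 0.005, 0.5)
  models <- train_gene_mashr(fm, bhat, shat, fit, priors,
                             tissues = c("t1", "t2"))
  expect_length(models, 2)
  expect_identical(models$t1$weights$variant_id, "v1")

  # emitted weight equals the shrinkage posterior mean exactly
  pm <- posterior_mean(bhat[1, ], shat[1, ], fit, priors)
  expect_equal(models$t1$weights$weight, pm[1], tolerance = 1e-12)
  expect_equal(models$t2$weights$weight, pm[2], tolerance = 1e-12)
  expect_null(models$t1$performance)
  expect_identical(models$t1$family, "MASHR-M")
})
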
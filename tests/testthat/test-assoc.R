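panel_df <- function(ids, chrom = "1", pos = NULL, ref = "A", alt = "G") {
  data.frame(id = ids, chrom = chrom,
             pos = pos %||% seq_along(ids) * 1000,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("harmonization keeps, flips and drops variants by allele orientation", {
  panel <- panel_df(c("v1", "v2", "v3"), ref = c("A", "A", "A"),
                    alt = c("G", "G", "C"))
  gwas <- data.frame(
    variant_id = c("x1", "x2", "x3"),
    chromosome = "1", position = c(1000, 2000, 3000),
    effect_allele = c("G", "A", "G"), non_effect_allele = c("A", "G", "T"),
    zscore = c(2, 3, 4), stringsAsFactors = FALSE)
  h <- harmonize_sumstats(gwas, panel)
  expect_equal(h$variant_id, c("v1", "v2"))
  expect_equal(h$zscore, c(2, -3)) # same orientation kept, swapped flipped
  expect_equal(h$effect_allele, c("G", "G")) # aligned to panel alt
  log <- attr(h, "harmonization_log")
  expect_equal(unname(log["n_flipped"]), 1)
  expect_equal(unname(log["n_allele_mismatch"]), 1)
})

test_that("strand-ambiguous variants obey the drop flag", {
  panel <- panel_df("v1", ref = "A", alt = "T")
  gwas <- data.frame(variant_id = "x", chromosome = "1", position = 1000,
                     effect_allele = "T", non_effect_allele = "A",
                     zscore = 1.5, stringsAsFactors = FALSE)
  expect_equal(nrow(harmonize_sumstats(gwas, panel, drop_ambiguous = TRUE)), 0)
  kept <- harmonize_sumstats(gwas, panel, drop_ambiguous = FALSE)
  expect_equal(kept$zscore, 1.5)
})

test_that("beta/se inputs and duplicate panel positions are handled", {
  panel <- panel_df(c("v1", "v2"), pos = c(1000, 1000),
                    ref = c("A", "A"), alt = c("G", "C"))
  gwas <- data.frame(variant_id = "x", chromosome = "1", position = 1000,
                     effect_allele = "G", non_effect_allele = "A",
                     beta = 0.2, se = 0.1, stringsAsFactors = FALSE)
  expect_warning(h <- harmonize_sumstats(gwas, panel), "duplicated")
  expect_equal(nrow(h), 0) # conflicting duplicates all dropped

  panel2 <- panel_df("v1")
  h2 <- harmonize_sumstats(gwas, panel2)
  expect_equal(h2$zscore, 2) # z = beta / se
})

test_that("flipping every GWAS allele orientation leaves gene z-scores unchanged", {
  set.seed(1)
  G <- simulate_genotypes(500, 10, 5, 0.5, 0.2, 0.5, seed = 1)
  ld <- ld_reference(G)
  model <- toy_model(G$variants$id[c(2, 5, 8)], c(0.5, -0.3, 0.2))
  gwas <- data.frame(variant_id = G$variants$id, chromosome = G$variants$chrom,
                     position = G$variants$pos,
                     effect_allele = G$variants$alt,
                     non_effect_allele = G$variants$ref,
                     zscore = rnorm(10), stringsAsFactors = FALSE)
  flipped <- gwas
  flipped$effect_allele <- gwas$non_effect_allele
  flipped$non_effect_allele <- gwas$effect_allele
  flipped$zscore <- -gwas$zscore
  za <- spredixcan_z(model, harmonize_sumstats(gwas, G$variants), ld)
  zb <- spredixcan_z(model, harmonize_sumstats(flipped, G$variants), ld)
  expect_equal(za$zscore, zb$zscore, tolerance = 1e-12)
})

test_that("BLUP imputation honors the copy and no-information limits", {
  expect_equal(impute_missing_z(2.5, matrix(1), matrix(1), ridge = 0), 2.5)
  expect_equal(impute_missing_z(c(1, -2), diag(2), matrix(0, 1, 2)), 0)
  # ill-conditioned without ridge
  R_tt <- matrix(c(1, 1, 1, 1), 2)
  expect_error(impute_missing_z(c(1, 1), R_tt, matrix(c(1, 1), 1), ridge = 0),
               "ridge")
  expect_silent(impute_missing_z(c(1, 1), R_tt, matrix(c(1, 1), 1), ridge = 0.1))
})

test_that("masked variants are recovered accurately within high-LD blocks", {
  set.seed(2)
  n_blocks <- 30; p <- 20
  truth <- c(); imputed <- c()
  for (b in seq_len(n_blocks)) {
    R <- ar1_cor(p, 0.9)
    z <- simulate_gwas_z(R, rep(0, p), seed = 100 + b)
    mask <- seq(2, p, by = 4)
    zi <- impute_missing_z(z[-mask], R[-mask, -mask], R[mask, -mask, drop = FALSE],
                           ridge = 0.1)
    truth <- c(truth, z[mask]); imputed <- c(imputed, zi)
  }
  expect_gte(cor(truth, imputed), 0.9)
})

test_that("panel imputation never alters observed entries and tracks provenance", {
  set.seed(3)
  p <- 15
  R <- ar1_cor(p, 0.8)
  z <- simulate_gwas_z(R, rep(0, p), seed = 4)
  zm <- z; zm[c(3, 7)] <- NA
  out <- impute_gwas_panel(zm, R, ridge = 0.1)
  expect_equal(out$z[-c(3, 7)], z[-c(3, 7)], tolerance = 1e-15)
  expect_equal(out$provenance[c(3, 7)], c("imputed", "imputed"))
  expect_true(all(is.finite(out$z)))
})

test_that("the summary statistic collapses correctly in closed-form cases", {
  # single-variant model: z_g = sign(w) * z_l
  G <- simulate_genotypes(400, 2, 2, 0, 0.3, 0.4, seed = 5)
  ld <- ld_reference(G)
  gwas <- data.frame(variant_id = G$variants$id, chromosome = "1",
                     position = G$variants$pos,
                     effect_allele = G$variants$alt,
                     non_effect_allele = G$variants$ref,
                     zscore = c(2.2, -1.3), provenance = "observed",
                     stringsAsFactors = FALSE)
  m1 <- toy_model(G$variants$id[1], -0.7)
  expect_equal(spredixcan_z(m1, gwas, ld)$zscore, -2.2, tolerance = 1e-12)

  # two uncorrelated variants, equal weights, equal variances: (z1+z2)/sqrt(2)
  ld2 <- ld
  v <- mean(diag(ld$Gamma))
  ld2$Gamma <- diag(v, 2); ld2$sigma <- rep(sqrt(v), 2); ld2$R <- diag(2)
  m2 <- toy_model(G$variants$id, c(0.4, 0.4))
  expect_equal(spredixcan_z(m2, gwas, ld2)$zscore, (2.2 - 1.3) / sqrt(2),
               tolerance = 1e-12)
})

test_that("summary-based and individual-level associations agree on a simulated cohort", {
  pan <- make_gene_panel(n_samples = 2200, n_genes = 8, variants_per_gene = 8,
                         within_block_corr = 0.5, h2 = 0.4, n_causal = 2,
                         seed = 6)
  train_rows <- 1:400; gwas_rows <- 401:2200
  models <- list()
  for (g in seq_len(8)) {
    m <- train_gene_en(pan$G, pan$sim$panel[[1]]$expr[train_rows, g],
                       c(pan$annotations[[g]], tissue = "t1"),
                       config = list(maf_min = 0, performance = FALSE),
                       sample_idx = train_rows, seed = 10 + g)
    if (inherits(m, "PredictionModel")) models[[length(models) + 1]] <- m
  }
  expect_gte(length(models), 6)
  Gg <- list(dosages = pan$G$dosages[gwas_rows, , drop = FALSE],
             variants = pan$G$variants, sample_ids = pan$G$sample_ids[gwas_rows])
  set.seed(7)
  # phenotype driven by two genes' causal variants plus noise
  y <- as.numeric(
    Gg$dosages[, pan$sim$truth[[1]]$causal, drop = FALSE] %*%
      pan$sim$truth[[1]]$effects[, 1] * 0.6 +
    Gg$dosages[, pan$sim$truth[[4]]$causal, drop = FALSE] %*%
      pan$sim$truth[[4]]$effects[, 1] * 0.6 + rnorm(length(gwas_rows)))
  sc <- marginal_eqtl_scan(Gg$dosages, y)
  gwas <- data.frame(variant_id = pan$G$variants$id,
                     chromosome = pan$G$variants$chrom,
                     position = pan$G$variants$pos,
                     effect_allele = pan$G$variants$alt,
                     non_effect_allele = pan$G$variants$ref,
                     zscore = sc$beta_hat / sc$se, stringsAsFactors = FALSE)
  ldref <- ld_reference(Gg)
  zs <- vapply(models, function(m) spredixcan_z(m, gwas, ldref)$zscore, 0)
  zi <- vapply(models, function(m) predixcan_individual(m, Gg, y)$zscore, 0)
  expect_gte(cor(zs, zi), 0.99)
  expect_true(all(abs(zs - zi) < 0.5))
})

test_that("individual-level association matches closed-form regression and flags degenerate input", {
  G <- simulate_genotypes(300, 3, 3, 0.2, 0.2, 0.5, seed = 8)
  m <- toy_model(G$variants$id, c(0.5, 0.2, -0.1))
  set.seed(9)
  y <- rnorm(300)
  a <- predixcan_individual(m, G, y)
  pred <- as.numeric(G$dosages %*% m$weights$weight)
  lmfit <- summary(lm(y ~ pred))$coefficients
  expect_equal(a$zscore, lmfit[2, 1] / lmfit[2, 2], tolerance = 1e-10)

  # perfect association
  b <- predixcan_individual(m, G, pred)
  expect_lt(b$pvalue, 1e-10)

  # zero-variance prediction errors out
  m0 <- toy_model(G$variants$id[1], 1)
  G0 <- G; G0$dosages[, 1] <- 1
  expect_error(predixcan_individual(m0, G0, y), "zero-variance")

  # missing model variants contribute zero, with a logged count
  m2 <- toy_model(c(G$variants$id[1], "absent_variant"), c(0.5, 9))
  a2 <- predixcan_individual(m2, G, y)
  expect_equal(attr(a2, "n_missing_variants"), 1L)
  expect_equal(a2$fraction_model_snps_present, 0.5)
})

test_that("Bonferroni thresholds are per trait and strict", {
  assocs <- data.frame(
    trait = c(rep("A", 100), rep("B", 20)),
    pvalue = c(5e-4, rep(0.01, 99), 0.05 / 20, rep(0.5, 19)),
    stringsAsFactors = FALSE)
  fl <- bonferroni_flags(assocs, alpha = 0.05)
  expect_equal(fl$bonferroni_threshold[1], 5e-4)
  expect_false(fl$significant[1]) # p exactly at threshold: not significant
  expect_equal(fl$bonferroni_threshold[101], 0.05 / 20)
  expect_false(fl$significant[101])
  assocs2 <- data.frame(trait = c("A", "A", "B"), pvalue = c(0.02, 0.5, 0.01))
  fl2 <- bonferroni_flags(assocs2)
  expect_equal(fl2$significant, c(TRUE, FALSE, TRUE)) # 0.05/2 and 0.05/1
})
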
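#' Cis-window variant filter
#'
#' Retains variants within 1 MB upstream of the gene's transcription start
#' and 1 MB downstream of its transcription end (closed boundaries), with
#' MAF strictly above `maf_min`, and -- when a whitelist of robust variant
#' ids (HapMap-like) is supplied -- present in that whitelist.
#'
#' @param variants Data frame with at least `pos`, `maf` and `id` columns.
#' @param gene_start,gene_end 1-based transcription start/end
#'   (`gene_start <= gene_end`). `NULL` disables the positional filter
#'   (all variants deemed cis, as in positionless toy panels).
#' @param maf_min Strict lower MAF bound (default 0.01).
#' @param panel_whitelist Optional character vector of allowed ids.
#' @return Integer indices of retained variants.
#' @export
cis_variant_filter <- function(variants, gene_start = NULL, gene_end = NULL,
                               maf_min = 0.01, panel_whitelist = NULL) {
  keep <- variants$maf > maf_min
  if (!is.null(gene_start)) {
    stopifnot(gene_start <= gene_end)
    keep <- keep & variants$pos >= gene_start - 1e6 & variants$pos <= gene_end + 1e6
  }
  if (!is.null(panel_whitelist)) keep <- keep & variants$id %in% panel_whitelist
  which(keep)
}

prediction_model <- function(gene, tissue, family, weights, performance = NULL) {
  weights <- weights[weights$weight != 0, , drop = FALSE]
  rownames(weights) <- NULL
  structure(list(gene = gene, tissue = tissue, family = family,
                 weights = weights, performance = performance,
                 n_snps = nrow(weights)),
            class = "PredictionModel")
}

model_rejection <- function(gene, tissue, family, reason) {
  structure(list(gene = gene, tissue = tissue, family = family,
                 reason = reason),
            class = "ModelRejection")
}

#' @export
print.PredictionModel <- function(x, ...) {
  cat(sprintf("<PredictionModel %s | %s | %s | %d SNPs", x$family, x$gene,
              x$tissue, x$n_snps))
  if (!is.null(x$performance))
    cat(sprintf(" | rho=%.3f p=%.3g", x$performance$rho_avg,
                x$performance$p_combined))
  cat(">\n")
  invisible(x)
}

retained <- function(perf, rho_min = 0.1, p_max = 0.05) {
  perf$rho_avg > rho_min && perf$p_combined < p_max # both strict
}

#' Train an elastic net expression model for one gene
#'
#' The baseline family: cis variants (whitelist applied when given, MAF >
#' `maf_min` strict) enter a weighted elastic net with unit penalty
#' factors and `alpha = 0.5`; lambda is chosen by 10-fold cross-validated
#' error. Prediction performance is estimated by nested cross-validation
#' and the model is retained only when the mean out-of-fold Pearson
#' correlation exceeds 0.1 and the combined correlation-test p-value is
#' below 0.05 (both strict).
#'
#' @param G A `GenotypeMatrix` (or list with `dosages` and `variants`).
#' @param y Expression vector aligned to `rows of G$dosages` (or to
#'   `sample_idx` when given).
#' @param annotation Optional list with `gene` id, `tissue`, `start`,
#'   `end` (positions enable the 1 MB window filter) and `cis_idx`
#'   (explicit candidate variant indices -- the cis design of synthetic
#'   panels whose genes share one positional axis; the MAF and whitelist
#'   filters still apply on top).
#' @param config List of overrides: `alpha`, `n_cv_folds`, `maf_min`,
#'   `whitelist`, `rho_min`, `p_max`, `n_outer_folds`, `performance`
#'   (set `FALSE` to skip nested CV and retention).
#' @param sample_idx Optional row indices of `G$dosages` matching `y`.
#' @param seed Integer seed.
#' @return A `PredictionModel`, or a `ModelRejection` with a reason code.
#' @export
train_gene_en <- function(G, y, annotation = list(), config = list(),
                          sample_idx = NULL, seed = 1) {
  cfg <- modifyList(list(alpha = 0.5, n_cv_folds = 10, maf_min = 0.01,
                         whitelist = NULL, rho_min = 0.1, p_max = 0.05,
                         n_outer_folds = 10, performance = TRUE), config)
  gene <- annotation$gene %||% "gene"
  tissue <- annotation$tissue %||% "tissue"
  idx <- cis_design_idx(G, annotation, cfg$maf_min, cfg$whitelist)
  if (length(idx) == 0)
    return(model_rejection(gene, tissue, "EN-M", "empty_cis_set"))
  X <- G$dosages[sample_idx %||% seq_len(nrow(G$dosages)), idx, drop = FALSE]
  train_penalized(X, y, G$variants[idx, , drop = FALSE], gene, tissue,
                  "EN-M", rep(1, length(idx)), cfg, seed)
}

#' Train a fine-mapping-weighted elastic net model for one gene
#'
#' The fine-mapping-informed family: the design is restricted to LD-cluster
#' representatives with PIP > 0.01 (no whitelist restriction), and each
#' variant's elastic net penalty is multiplied by `1 - PIP`, so variants
#' with high posterior causal probability are penalized less (a PIP of 1
#' leaves a variant unpenalized). Fitting, performance estimation and
#' retention are otherwise identical to [train_gene_en()].
#'
#' @inheritParams train_gene_en
#' @param fm A `FineMapResult` computed on the gene's cis design -- the
#'   MAF-filtered cis variants of `G` (see [finemap_gene()]).
#' @return A `PredictionModel` (family `DAPGW-M`) or a `ModelRejection`.
#' @export
train_gene_dapgw <- function(G, y, fm, annotation = list(), config = list(),
                             sample_idx = NULL, seed = 1) {
  cfg <- modifyList(list(alpha = 0.5, n_cv_folds = 10, maf_min = 0.01,
                         pip_min = 0.01, rho_min = 0.1, p_max = 0.05,
                         n_outer_folds = 10, performance = TRUE), config)
  gene <- annotation$gene %||% "gene"
  tissue <- annotation$tissue %||% "tissue"
  idx <- cis_design_idx(G, annotation, cfg$maf_min, NULL)
  if (length(fm$pip) != length(idx))
    stop("fm was not computed on this gene's cis design (",
         length(fm$pip), " PIPs vs ", length(idx), " cis variants)")
  reps <- select_representatives(fm, cfg$pip_min)
  if (nrow(reps) == 0)
    return(model_rejection(gene, tissue, "DAPGW-M", "no_representatives"))
  sel <- idx[reps$variant]
  X <- G$dosages[sample_idx %||% seq_len(nrow(G$dosages)), sel, drop = FALSE]
  train_penalized(X, y, G$variants[sel, , drop = FALSE], gene, tissue,
                  "DAPGW-M", 1 - reps$pip, cfg, seed)
}

# Candidate cis design for a gene: explicit indices when given, then the
# positional window / MAF / whitelist filters.
cis_design_idx <- function(G, annotation, maf_min, whitelist) {
  base <- annotation$cis_idx %||% seq_len(nrow(G$variants))
  sub <- G$variants[base, , drop = FALSE]
  base[cis_variant_filter(sub, annotation$start, annotation$end,
                          maf_min, whitelist)]
}

# Shared EN/DAPGW fitting + nested-CV + retention pipeline.
train_penalized <- function(X, y, vmeta, gene, tissue, family, pf, cfg, seed) {
  keep <- apply(X, 2L, sd) > .Machine$double.eps
  if (!any(keep)) return(model_rejection(gene, tissue, family, "constant_design"))
  X <- X[, keep, drop = FALSE]; vmeta <- vmeta[keep, , drop = FALSE]
  pf <- pf[keep]
  spec <- elastic_net_spec(alpha = cfg$alpha, n_cv_folds = cfg$n_cv_folds,
                           penalty_factors = pf)
  fit <- fit_weighted_elastic_net(X, y, spec, seed = child_seed(seed, "lambda"))
  perf <- NULL
  if (isTRUE(cfg$performance)) {
    trainer <- function(Xtr, ytr, s)
      fit_weighted_elastic_net(Xtr, ytr, spec, seed = s)
    perf <- nested_cv_performance(X, y, trainer,
                                  n_outer_folds = cfg$n_outer_folds, seed = seed)
    if (!retained(perf, cfg$rho_min, cfg$p_max))
      return(model_rejection(gene, tissue, family, "performance_filter"))
  }
  w <- data.frame(variant_id = vmeta$id, ref = vmeta$ref, alt = vmeta$alt,
                  weight = unname(fit$coefficients), stringsAsFactors = FALSE)
  if (all(w$weight == 0))
    return(model_rejection(gene, tissue, family, "all_zero_weights"))
  prediction_model(gene, tissue, family, w, perf)
}

#' Fine-map one gene's cis region
#'
#' Convenience wrapper: applies the cis/MAF filter used by the
#' fine-mapping-informed families (no whitelist), enumerates PIPs on that
#' design, and clusters by LD. The returned result is aligned to the cis
#' design expected by [train_gene_dapgw()] and [train_gene_mashr()].
#'
#' @inheritParams train_gene_en
#' @param max_model_size,prior_inclusion,effect_prior_variance See
#'   [enumerate_pips()].
#' @param r2_min,pip_min See [cluster_by_ld()].
#' @return A `FineMapResult` with clusters populated; the attribute
#'   `cis_idx` holds the design's variant indices into `G$variants`.
#' @export
finemap_gene <- function(G, y, annotation = list(), maf_min = 0.01,
                         sample_idx = NULL,
                         max_model_size = 2, prior_inclusion = NULL,
                         effect_prior_variance = 0.16,
                         r2_min = 0.5, pip_min = 0.01) {
  idx <- cis_design_idx(G, annotation, maf_min, NULL)
  if (length(idx) == 0) stop("no cis variants pass the MAF filter")
  rows <- sample_idx %||% seq_len(nrow(G$dosages))
  X <- G$dosages[rows, idx, drop = FALSE]
  fm <- enumerate_pips(X, y, max_model_size = max_model_size,
                       prior_inclusion = prior_inclusion,
                       effect_prior_variance = effect_prior_variance)
  R <- suppressWarnings(cor(X))
  R[!is.finite(R)] <- 0; diag(R) <- 1
  fm <- cluster_by_ld(fm, R, r2_min = r2_min, pip_min = pip_min)
  attr(fm, "cis_idx") <- idx
  fm
}

#' Marginal eQTL scan
#'
#' Simple linear regression (with intercept) of expression on each
#' variant's dosage separately: the per-variant marginal effect sizes and
#' standard errors that feed the cross-tissue shrinkage family.
#'
#' @param X Dosage matrix (samples by variants).
#' @param y Expression vector.
#' @return Data frame with `beta_hat`, `se` and logical `ok` (`FALSE` for
#'   zero-variance variants, which must be excluded downstream).
#' @export
marginal_eqtl_scan <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 3)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, "-")
  sxx <- colSums(Xc^2)
  ok <- sxx > .Machine$double.eps * n
  yc <- y - mean(y)
  beta <- ifelse(ok, as.numeric(crossprod(Xc, yc)) / sxx, NA_real_)
  rss <- sum(yc^2) - beta^2 * sxx
  rss <- pmax(rss, 0)
  se <- ifelse(ok, sqrt(rss / (n - 2) / sxx), NA_real_)
  data.frame(beta_hat = beta, se = se, ok = ok,
             row.names = colnames(X) %||% NULL)
}

#' Cross-tissue shrinkage expression models for one gene
#'
#' The shrinkage-based family: a gene is retained only when fine-mapping
#' supports it -- its maximal LD-cluster PIP must exceed
#' `cluster_pip_min` (default 0.1). The model's variants are the cluster
#' representatives with PIP > `pip_min` (default 0.01), and each tissue's
#' weights are the posterior mean effects from the fitted
#' mixture-of-covariances shrinkage model (see [fit_mixture_em()]) applied
#' to the variants' marginal effects across tissues. No cross-validated
#' performance estimate exists for this family.
#'
#' @param fm A `FineMapResult` for the gene's cis design, clusters filled.
#' @param bhat,shat Matrices (design variants by tissues) of marginal
#'   effects and standard errors for this gene.
#' @param fit A `MixtureFit` from [fit_mixture_em()].
#' @param priors The `CovariancePriorSet` used for `fit`.
#' @param gene Gene id.
#' @param tissues Tissue names (default from `colnames(bhat)`).
#' @param variants Data frame (`id`, `ref`, `alt`) aligned to the design.
#' @param cluster_pip_min,pip_min Strict gene and variant gates.
#' @return List of `PredictionModel` (family `MASHR-M`, one per tissue),
#'   or a single `ModelRejection` when the gene gate fails.
#' @export
train_gene_mashr <- function(fm, bhat, shat, fit, priors, gene = "gene",
                             tissues = NULL, variants = NULL,
                             cluster_pip_min = 0.1, pip_min = 0.01) {
  stopifnot(inherits(fm, "FineMapResult"))
  bhat <- as.matrix(bhat); shat <- as.matrix(shat)
  tissues <- tissues %||% colnames(bhat) %||% sprintf("tissue%d", seq_len(ncol(bhat)))
  max_cpip <- if (length(fm$clusters)) max(vapply(fm$clusters, `[[`, 0, "cluster_pip")) else 0
  if (!(max_cpip > cluster_pip_min))
    return(model_rejection(gene, NA_character_, "MASHR-M", "no_cluster_above_pip"))
  reps <- select_representatives(fm, pip_min)
  if (nrow(reps) == 0)
    return(model_rejection(gene, NA_character_, "MASHR-M", "no_representatives"))
  if (is.null(variants))
    variants <- data.frame(id = sprintf("v%d", seq_len(nrow(bhat))),
                           ref = "A", alt = "G", stringsAsFactors = FALSE)
  pm <- t(vapply(reps$variant, function(r)
    posterior_mean(bhat[r, ], shat[r, ], fit, priors), numeric(ncol(bhat))))
  models <- lapply(seq_along(tissues), function(t) {
    w <- data.frame(variant_id = variants$id[reps$variant],
                    ref = variants$ref[reps$variant],
                    alt = variants$alt[reps$variant],
                    weight = pm[, t], stringsAsFactors = FALSE)
    prediction_model(gene, tissues[t], "MASHR-M", w, performance = NULL)
  })
  names(models) <- tissues
  models
}
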
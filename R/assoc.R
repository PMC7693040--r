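#' Harmonize GWAS summary statistics to a variant panel
#'
#' Matches GWAS variants to the model panel on `(chrom, pos)` and aligns
#' effect alleles (case-insensitively): when the GWAS effect allele is the
#' panel's alt allele the z-score is kept as is; when the orientation is
#' swapped (effect allele equals the panel ref) the z-score's sign is
#' flipped and the alleles swapped; any other allele pair is dropped.
#' Strand-ambiguous A/T and C/G variants are dropped when
#' `drop_ambiguous` is set. Duplicate panel positions with conflicting
#' alleles are all dropped with a warning. Every decision is counted in
#' the `"harmonization_log"` attribute.
#'
#' @param gwas Data frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `non_effect_allele` and `zscore` (or
#'   `beta` and `se`, from which `zscore = beta / se`).
#' @param panel Data frame of panel variants (`id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param drop_ambiguous Drop strand-ambiguous A/T, C/G pairs (default
#'   `TRUE`).
#' @return Data frame aligned to matched panel variants: `variant_id`
#'   (panel id), `chromosome`, `position`, `effect_allele` (panel alt),
#'   `non_effect_allele` (panel ref), `zscore`, `provenance`
#'   (`"observed"`).
#' @export
harmonize_sumstats <- function(gwas, panel, drop_ambiguous = TRUE) {
  if (!"zscore" %in% names(gwas)) {
    stopifnot(all(c("beta", "se") %in% names(gwas)))
    gwas$zscore <- gwas$beta / gwas$se
  }
  stopifnot(all(is.finite(gwas$zscore)))
  amb <- c("A_T", "T_A", "C_G", "G_C")
  ea <- toupper(gwas$effect_allele); nea <- toupper(gwas$non_effect_allele)
  n_in <- nrow(gwas)
  n_amb <- 0L
  if (drop_ambiguous) {
    bad <- paste(ea, nea, sep = "_") %in% amb
    n_amb <- sum(bad)
    gwas <- gwas[!bad, , drop = FALSE]
    ea <- ea[!bad]; nea <- nea[!bad]
  }
  gkey <- paste(gwas$chromosome, gwas$position)
  pkey <- paste(panel$chrom, panel$pos)
  dup <- pkey %in% pkey[duplicated(pkey)]
  if (any(dup)) warning(sum(dup), " panel variants at duplicated positions dropped")
  m <- match(gkey, ifelse(dup, NA, pkey))
  hit <- !is.na(m)
  pref <- toupper(panel$ref[m]); palt <- toupper(panel$alt[m])
  same <- hit & ea == palt & nea == pref
  swap <- hit & ea == pref & nea == palt
  z <- ifelse(swap, -gwas$zscore, gwas$zscore)
  keep <- same | swap
  out <- data.frame(
    variant_id = panel$id[m[keep]],
    chromosome = panel$chrom[m[keep]],
    position = panel$pos[m[keep]],
    effect_allele = panel$alt[m[keep]],
    non_effect_allele = panel$ref[m[keep]],
    zscore = z[keep],
    provenance = rep("observed", sum(keep)),
    stringsAsFactors = FALSE
  )
  attr(out, "harmonization_log") <- c(
    n_input = n_in, n_ambiguous_dropped = n_amb,
    n_position_matched = sum(hit), n_kept = sum(same, na.rm = TRUE),
    n_flipped = sum(swap, na.rm = TRUE),
    n_allele_mismatch = sum(hit & !keep, na.rm = TRUE)
  )
  out
}

#' Impute missing summary-statistic z-scores (BLUP)
#'
#' Best-linear-unbiased-prediction imputation of untyped variants'
#' z-scores under the multivariate-normal summary-statistic model:
#' `zhat_untyped = R_ut (R_tt + ridge I)^-1 z_typed`, where `R_tt` is the
#' LD correlation among typed variants and `R_ut` the untyped-by-typed
#' correlation. A perfectly correlated neighbor copies its z; an
#' uncorrelated variant imputes to 0.
#'
#' @param z_typed Observed z-scores.
#' @param R_tt Typed-by-typed correlation matrix.
#' @param R_ut Untyped-by-typed correlation matrix.
#' @param ridge Non-negative regularization added to `diag(R_tt)`
#'   (default 0.1, on the correlation scale).
#' @return Numeric vector of imputed z-scores (one per row of `R_ut`).
#' @export
impute_missing_z <- function(z_typed, R_tt, R_ut, ridge = 0.1) {
  R_ut <- matrix(R_ut, ncol = length(z_typed))
  stopifnot(nrow(R_tt) == length(z_typed), ncol(R_tt) == length(z_typed),
            ridge >= 0)
  A <- R_tt + diag(ridge, nrow(R_tt))
  if (ridge == 0 && rcond(A) < 1e-12)
    stop("R_tt is ill-conditioned; use ridge > 0")
  as.numeric(R_ut %*% solve(A, z_typed))
}

#' Impute a panel's missing z-scores blockwise
#'
#' Fills `NA` entries of a panel-aligned z-score vector by BLUP within LD
#' blocks (for tractability, and because cross-block LD is negligible by
#' construction of approximately independent regions). Observed entries
#' are never altered.
#'
#' @param z Panel-aligned z-scores with `NA` for missing variants.
#' @param R Panel LD correlation matrix.
#' @param blocks Integer block label per variant (`NULL` = one block).
#' @param ridge See [impute_missing_z()].
#' @return List with `z` (completed) and `provenance`
#'   (`"observed"`/`"imputed"`; variants in blocks with no typed variant
#'   stay `NA` with provenance `"unimputable"`).
#' @export
impute_gwas_panel <- function(z, R, blocks = NULL, ridge = 0.1) {
  p <- length(z)
  blocks <- blocks %||% rep(1L, p)
  stopifnot(nrow(R) == p, length(blocks) == p)
  prov <- ifelse(is.na(z), "imputed", "observed")
  for (b in unique(blocks)) {
    i <- which(blocks == b)
    u <- i[is.na(z[i])]
    t <- setdiff(i, u)
    if (length(u) == 0) next
    if (length(t) == 0) { prov[u] <- "unimputable"; next }
    z[u] <- impute_missing_z(z[t], R[t, t, drop = FALSE],
                             R[u, t, drop = FALSE], ridge)
  }
  list(z = z, provenance = prov)
}

#' LD reference from a genotype panel
#'
#' Dosage covariance matrix and standard deviations from a (training)
#' genotype panel, used by the summary-level gene association statistic
#' and, on the correlation scale, by summary-statistic imputation.
#'
#' @param G A `GenotypeMatrix`.
#' @param idx Optional variant indices to restrict to.
#' @return An `LdReference`: list with `variants`, `Gamma` (covariance,
#'   denominator n), `sigma` (sds) and `R` (correlation).
#' @export
ld_reference <- function(G, idx = NULL) {
  idx <- idx %||% seq_len(ncol(G$dosages))
  X <- G$dosages[, idx, drop = FALSE]
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  Gamma <- crossprod(Xc) / n
  sigma <- sqrt(diag(Gamma))
  R <- Gamma / outer(pmax(sigma, .Machine$double.eps),
                     pmax(sigma, .Machine$double.eps))
  diag(R) <- 1
  structure(list(variants = G$variants[idx, , drop = FALSE],
                 Gamma = Gamma, sigma = sigma, R = R),
            class = "LdReference")
}

#' Summary-statistics gene-level association
#'
#' Gene-level z-score from GWAS summary statistics, prediction weights
#' and an LD reference:
#' `z_g = sum_l w_l (sigma_l / sigma_g) z_l` with
#' `sigma_g^2 = sum_l sum_k w_l w_k Gamma_lk`, computed over the
#' intersection of the model's variants with the available (observed or
#' imputed) statistics. Missing model variants are dropped and the
#' statistic computed on the remainder; `fraction_model_snps_present`
#' reports the loss.
#'
#' @param model A `PredictionModel`.
#' @param gwas Harmonized summary statistics (see
#'   [harmonize_sumstats()]); rows with non-finite `zscore` are ignored.
#' @param ld An [ld_reference()] covering the model's variants.
#' @param trait Trait label carried into the output.
#' @return A `GeneAssociation` data frame row: `gene`, `tissue`, `trait`,
#'   `zscore`, `pvalue`, `n_snps_used`, `n_snps_in_model`,
#'   `fraction_model_snps_present`, `status`.
#' @export
spredixcan_z <- function(model, gwas, ld, trait = "trait") {
  stopifnot(inherits(model, "PredictionModel"))
  res <- data.frame(gene = model$gene, tissue = model$tissue, trait = trait,
                    zscore = NA_real_, pvalue = NA_real_,
                    n_snps_used = 0L, n_snps_in_model = model$n_snps,
                    fraction_model_snps_present = 0,
                    status = "ok", stringsAsFactors = FALSE)
  gw <- gwas[is.finite(gwas$zscore), , drop = FALSE]
  mi <- match(model$weights$variant_id, gw$variant_id)
  use <- which(!is.na(mi))
  if (length(use) == 0) { res$status <- "no_snps_in_gwas"; return(res) }
  li <- match(model$weights$variant_id[use], ld$variants$id)
  if (anyNA(li)) stop("LD reference does not cover all model variants")
  w <- model$weights$weight[use]
  zl <- gw$zscore[mi[use]]
  Gam <- ld$Gamma[li, li, drop = FALSE]
  sg2 <- as.numeric(t(w) %*% Gam %*% w)
  res$n_snps_used <- length(use)
  res$fraction_model_snps_present <- length(use) / model$n_snps
  if (sg2 <= 0) { res$status <- "nonpositive_variance"; return(res) }
  zg <- sum(w * ld$sigma[li] * zl) / sqrt(sg2)
  res$zscore <- zg
  res$pvalue <- 2 * pnorm(-abs(zg))
  res
}

#' Individual-level predicted-expression association
#'
#' The individual-level oracle for the summary statistic: predicted
#' expression is the weighted dosage sum `sum_l w_l dosage_l` (model
#' variants missing from the genotypes contribute 0, with a count in the
#' `"n_missing_variants"` attribute), and the association z-score comes
#' from simple linear regression of the phenotype on the prediction.
#'
#' @param model A `PredictionModel`.
#' @param G A `GenotypeMatrix`.
#' @param phenotype Numeric vector aligned to rows of `G$dosages`.
#' @param trait Trait label.
#' @return A `GeneAssociation` data frame row (as [spredixcan_z()]).
#' @export
predixcan_individual <- function(model, G, phenotype, trait = "trait") {
  stopifnot(inherits(model, "PredictionModel"),
            length(phenotype) == nrow(G$dosages))
  mi <- match(model$weights$variant_id, G$variants$id)
  present <- !is.na(mi)
  pred <- as.numeric(G$dosages[, mi[present], drop = FALSE] %*%
                       model$weights$weight[present])
  if (sd(pred) < .Machine$double.eps)
    stop("zero-variance predicted expression; association undefined")
  sc <- marginal_eqtl_scan(matrix(pred, ncol = 1), phenotype)
  z <- sc$beta_hat / sc$se
  out <- data.frame(gene = model$gene, tissue = model$tissue, trait = trait,
                    zscore = z, pvalue = 2 * pnorm(-abs(z)),
                    n_snps_used = sum(present),
                    n_snps_in_model = model$n_snps,
                    fraction_model_snps_present = mean(present),
                    status = "ok", stringsAsFactors = FALSE)
  attr(out, "n_missing_variants") <- sum(!present)
  out
}

#' Per-trait Bonferroni significance flags
#'
#' Within each trait, the significance threshold is `alpha` divided by
#' the number of gene-tissue associations computed for that trait; an
#' association is flagged iff its p-value is strictly below the
#' threshold.
#'
#' @param assocs Data frame of `GeneAssociation` rows (needs `trait` and
#'   `pvalue`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `assocs` with logical `significant` and numeric
#'   `bonferroni_threshold` columns added.
#' @export
bonferroni_flags <- function(assocs, alpha = 0.05) {
  if (nrow(assocs) == 0) {
    assocs$significant <- logical(0)
    assocs$bonferroni_threshold <- numeric(0)
    return(assocs)
  }
  n_by_trait <- table(assocs$trait)
  thr <- alpha / as.numeric(n_by_trait[assocs$trait])
  assocs$bonferroni_threshold <- thr
  assocs$significant <- !is.na(assocs$pvalue) & assocs$pvalue < thr
  assocs
}
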
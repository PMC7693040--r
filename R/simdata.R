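#' Simulate LD-structured genotype dosages
#'
#' Generates a sample-by-variant dosage matrix with block LD structure.
#' Variants are partitioned into contiguous blocks; within a block the
#' latent (haplotype-level) Gaussian correlation decays as
#' `within_block_corr^|i - j|`, and blocks are mutually independent. Each
#' haplotype is obtained by thresholding its latent Gaussian at the normal
#' quantile of the variant's minor allele frequency (MAF), and the two
#' haplotypes are summed, which preserves the target MAF and the sign of
#' the latent correlation. Per-variant MAFs are drawn uniformly from
#' `[maf_low, maf_high]`.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of variants.
#' @param block_size Number of variants per LD block (last block may be
#'   shorter). Must not exceed `n_variants`.
#' @param within_block_corr Latent correlation between adjacent variants in
#'   a block, in `[0, 1)`.
#' @param maf_low,maf_high Bounds for the per-variant MAF draw,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `GenotypeMatrix`: list with `dosages` (matrix, values in
#'   `[0, 2]`), `variants` (data frame with `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`) and `sample_ids`.
#' @examples
#' g <- simulate_genotypes(100, 20, block_size = 5, within_block_corr = 0.8,
#'                         maf_low = 0.1, maf_high = 0.4, seed = 1)
#' range(g$dosages)
#' @export
simulate_genotypes <- function(n_samples, n_variants, block_size,
                               within_block_corr = 0,
                               maf_low = 0.05, maf_high = 0.5, seed = 1) {
  if (n_samples < 1 || n_variants < 1 || block_size < 1)
    stop("n_samples, n_variants and block_size must be positive")
  if (block_size > n_variants) stop("block_size must not exceed n_variants")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop("within_block_corr must be in [0, 1)")

  set.seed(child_seed(seed, "genotypes"))
  maf <- runif(n_variants, maf_low, maf_high)
  thr <- qnorm(maf)
  block <- rep(seq_len(ceiling(n_variants / block_size)),
               each = block_size)[seq_len(n_variants)]
  rho <- within_block_corr

  # AR(1) latent recursion per haplotype: corr decays exactly as rho^|i-j|
  latent <- function() {
    Z <- matrix(0, n_samples, n_variants)
    for (j in seq_len(n_variants)) {
      e <- rnorm(n_samples)
      if (j > 1L && block[j] == block[j - 1L] && rho > 0)
        Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * e
      else
        Z[, j] <- e
    }
    Z
  }
  H1 <- sweep(latent(), 2L, thr, `<`) * 1L
  H2 <- sweep(latent(), 2L, thr, `<`) * 1L
  dos <- H1 + H2

  pos <- seq_len(n_variants) * 1000L
  variants <- data.frame(
    id = sprintf("1_%d_A_G", pos), chrom = "1", pos = pos,
    ref = "A", alt = "G", maf = maf, block = block,
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  dimnames(dos) <- list(sample_ids, variants$id)
  structure(list(dosages = dos, variants = variants, sample_ids = sample_ids),
            class = "GenotypeMatrix")
}

#' Simulate multi-tissue expression with sparse shared cis-eQTLs
#'
#' For each gene, `n_causal` causal variants are drawn within the gene's
#' cis-window (by default all variants; supply `cis_windows` to restrict).
#' Each causal variant's per-tissue effect vector is multivariate normal
#' with unit variances and pairwise correlation `sharing_corr`, emulating
#' eQTL sharing across tissues. Per tissue, effects are rescaled so the
#' genetic fraction of expression variance equals `h2` (noise variance 1).
#' Tissues observe nested donor subsets drawn from one donor pool,
#' emulating an overlapping-donor design.
#'
#' @param G A `GenotypeMatrix`.
#' @param n_genes,n_tissues Number of genes and tissues.
#' @param n_causal Causal variants per gene (>= 1 when `h2 > 0`).
#' @param sharing_corr Cross-tissue effect correlation in `[0, 1]`.
#' @param h2 Cis-heritability in `[0, 1]`; a scalar, or a length-`n_genes`
#'   vector for panels mixing eGenes with no-eQTL genes.
#' @param tissue_sample_fractions Fractions (in `(0, 1]`) of the donor pool
#'   observed by each tissue; recycled to `n_tissues`.
#' @param cis_windows Optional list (length `n_genes`) of variant index
#'   vectors defining each gene's cis-window.
#' @param seed Integer seed.
#' @return A list with `panel` (per tissue: `expr` samples-by-genes matrix,
#'   `sample_ids`, `sample_idx`) and `truth` (per gene: `causal` indices,
#'   `effects` matrix `n_causal` x `n_tissues`, `h2`, `sharing_corr`).
#' @export
simulate_multitissue_expression <- function(G, n_genes, n_tissues,
                                            n_causal = 1,
                                            sharing_corr = 0.8,
                                            h2 = 0.3,
                                            tissue_sample_fractions = 1,
                                            cis_windows = NULL,
                                            seed = 1) {
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]")
  h2 <- rep_len(h2, n_genes)
  if (any(h2 > 0) && n_causal < 1) stop("n_causal must be >= 1 when h2 > 0")
  fr <- rep_len(tissue_sample_fractions, n_tissues)
  if (any(fr <= 0 | fr > 1)) stop("tissue_sample_fractions must be in (0, 1]")
  if (sharing_corr < 0 || sharing_corr > 1) stop("sharing_corr must be in [0, 1]")

  set.seed(child_seed(seed, "expression"))
  n <- nrow(G$dosages)
  p <- ncol(G$dosages)
  if (is.null(cis_windows)) cis_windows <- rep(list(seq_len(p)), n_genes)
  stopifnot(length(cis_windows) == n_genes)

  # effect sharing: equicorrelated MVN via shared + specific components
  draw_effects <- function(k) {
    shared <- matrix(rnorm(k), k, n_tissues)
    own <- matrix(rnorm(k * n_tissues), k, n_tissues)
    sqrt(sharing_corr) * shared + sqrt(1 - sharing_corr) * own
  }

  donor_perm <- sample(n)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  truth <- vector("list", n_genes)
  names(truth) <- genes
  for (g in seq_len(n_genes)) {
    win <- cis_windows[[g]]
    causal <- sort(sample(win, min(n_causal, length(win))))
    eff <- draw_effects(length(causal))
    if (h2[g] == 0) eff[] <- 0
    truth[[g]] <- list(causal = causal, effects = eff, h2 = h2[g],
                       sharing_corr = sharing_corr)
  }

  panel <- vector("list", n_tissues)
  names(panel) <- sprintf("tissue%d", seq_len(n_tissues))
  for (t in seq_len(n_tissues)) {
    idx <- sort(donor_perm[seq_len(max(2L, round(fr[t] * n)))])
    expr <- matrix(0, length(idx), n_genes,
                   dimnames = list(G$sample_ids[idx], genes))
    for (g in seq_len(n_genes)) {
      tr <- truth[[g]]
      gv <- as.numeric(G$dosages[, tr$causal, drop = FALSE] %*% tr$effects[, t])
      if (h2[g] > 0) {
        v <- var(gv)
        scl <- if (v > 0) sqrt((h2[g] / (1 - h2[g])) / v) else 0
        gv <- gv * scl
        truth[[g]]$scale <- c(truth[[g]]$scale, scl)
      } else gv <- rep(0, n)
      expr[, g] <- gv[idx] + rnorm(length(idx))
    }
    panel[[t]] <- list(expr = expr, sample_ids = G$sample_ids[idx],
                       sample_idx = idx)
  }
  # store per-tissue scaled effects on the dosage scale
  for (g in seq_len(n_genes)) {
    scl <- truth[[g]]$scale
    if (h2[g] > 0 && !is.null(scl))
      truth[[g]]$effects <- sweep(truth[[g]]$effects, 2L, scl, `*`)
    truth[[g]]$scale <- NULL
  }
  list(panel = panel, truth = truth, genes = genes)
}

#' Simulate GWAS summary-statistic z-scores under an LD structure
#'
#' Draws `z = R %*% causal_ncp + e` with `e ~ MVN(0, R)`: the standard
#' summary-level model in which marginal z-scores of null variants in LD
#' with a causal variant inherit `r` times its non-centrality.
#'
#' @param R Variant correlation matrix (symmetric PSD, unit diagonal).
#' @param causal_ncp Vector of per-variant non-centrality parameters
#'   (0 for null variants); length must match `nrow(R)`.
#' @param seed Integer seed.
#' @return Numeric vector of z-scores.
#' @export
simulate_gwas_z <- function(R, causal_ncp, seed = 1) {
  p <- nrow(R)
  stopifnot(ncol(R) == p, length(causal_ncp) == p)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    for (j in c(1e-8, 1e-6, 1e-4)) {
      ch <- tryCatch(chol(R + diag(j, p)), error = function(e) NULL)
      if (!is.null(ch)) break
    }
    if (is.null(ch)) stop("R is not positive semi-definite (jitter failed)")
  }
  set.seed(child_seed(seed, "gwas_z"))
  as.numeric(R %*% causal_ncp + t(ch) %*% rnorm(p))
}

#' Sample-size-tiered latent covariate factor count
#'
#' Number of latent expression-covariate factors (PEER-style) assigned to a
#' tissue as a step function of its RNA-seq sample size: 15 factors below
#' 150 samples, 30 for 150-249, 45 for 250-349, and 60 at 350 or more.
#'
#' @param n Sample count (positive integer).
#' @return Factor count: 15, 30, 45 or 60.
#' @examples
#' peer_factor_count(120) # 15
#' peer_factor_count(188) # 30
#' peer_factor_count(602) # 60
#' @export
peer_factor_count <- function(n) {
  if (any(n < 1)) stop("n must be positive")
  ifelse(n < 150, 15L, ifelse(n < 250, 30L, ifelse(n < 350, 45L, 60L)))
}
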
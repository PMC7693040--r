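#' Prioritize candidate genes for a trait
#'
#' A gene is a "prioritized" detection for a trait when it is both
#' significant and colocalized: Bonferroni-significant in at least one
#' tissue and with regional colocalization probability rcp > 0.5 (strict)
#' in at least one tissue. Each gene counts once regardless of how many
#' tissues support it. Genes with no rcp row are treated as rcp = 0 (no
#' colocalization evidence).
#'
#' @param assocs Data frame with `gene`, `tissue`, `trait`, `pvalue` and
#'   a logical `significant` column (see [bonferroni_flags()]).
#' @param coloc Data frame with `gene`, `tissue`, `trait`, `rcp`.
#' @param trait Trait to evaluate.
#' @param rcp_min Strict colocalization threshold (default 0.5).
#' @return Character vector of unique prioritized gene ids.
#' @export
prioritize_genes <- function(assocs, coloc, trait, rcp_min = 0.5) {
  a <- assocs[assocs$trait == trait, , drop = FALSE]
  cc <- coloc[coloc$trait == trait & coloc$rcp > rcp_min, , drop = FALSE]
  sig_genes <- unique(a$gene[a$significant])
  coloc_genes <- unique(cc$gene)
  sort(intersect(sig_genes, coloc_genes))
}

#' Restrict gene-trait pairs to the vicinity of GWAS loci
#'
#' Silver-standard benchmarking only considers gene-trait pairs near the
#' trait's GWAS signals: a pair is retained iff the gene's approximately
#' independent LD region (half-open `[start, end)`, matched on the gene's
#' position) contains at least one genome-wide signal for that trait.
#' Retained pairs are labelled positive iff they appear in the silver
#' standard.
#'
#' @param pairs Data frame with `gene` and `trait`.
#' @param gene_pos Data frame with `gene`, `chrom`, `pos` (e.g. the TSS).
#' @param regions Data frame of LD regions: `chrom`, `start`, `end`
#'   (half-open, 1-based starts).
#' @param gwas_loci Data frame of significant GWAS variants: `trait`,
#'   `chrom`, `pos`.
#' @param silver Data frame of positive pairs: `gene`, `trait`.
#' @return Subset of `pairs` with an added logical `label` column; genes
#'   with no region are excluded (with a warning).
#' @export
vicinity_filter <- function(pairs, gene_pos, regions, gwas_loci, silver) {
  region_of <- function(chrom, pos) {
    hit <- which(regions$chrom == chrom & regions$start <= pos &
                   pos < regions$end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  gp <- gene_pos[match(pairs$gene, gene_pos$gene), , drop = FALSE]
  greg <- mapply(region_of, gp$chrom, gp$pos)
  if (anyNA(greg)) {
    warning(sum(is.na(greg)), " gene-trait pairs dropped: gene has no LD region")
    pairs <- pairs[!is.na(greg), , drop = FALSE]
    greg <- greg[!is.na(greg)]
  }
  lreg <- mapply(region_of, gwas_loci$chrom, gwas_loci$pos)
  keep <- mapply(function(r, tr)
    any(lreg == r & gwas_loci$trait == tr, na.rm = TRUE),
    greg, pairs$trait)
  out <- pairs[keep, , drop = FALSE]
  out$label <- paste(out$gene, out$trait) %in% paste(silver$gene, silver$trait)
  rownames(out) <- NULL
  out
}

#' Per gene-trait association score
#'
#' Aggregates a gene's tissue-level associations for a trait into one
#' score for causal-gene ranking: the maximum over tissues of the
#' absolute z-score (default), or the score of the best p-value tissue
#' (`aggregate = "best_p"`, identical ranking when p-values are
#' two-sided normal tails of z).
#'
#' @param assocs Data frame with `gene`, `trait`, `zscore` (and `pvalue`
#'   for `"best_p"`); rows with missing z are ignored.
#' @param aggregate `"max"` or `"best_p"`.
#' @return Data frame with `gene`, `trait`, `score`.
#' @export
gene_trait_score <- function(assocs, aggregate = c("max", "best_p")) {
  aggregate <- match.arg(aggregate)
  a <- assocs[is.finite(assocs$zscore), , drop = FALSE]
  key <- interaction(a$gene, a$trait, drop = TRUE)
  score <- if (aggregate == "max") {
    tapply(abs(a$zscore), key, max)
  } else {
    tapply(seq_len(nrow(a)), key, function(i) abs(a$zscore[i[which.min(a$pvalue[i])]]))
  }
  first <- match(levels(key), key)
  data.frame(gene = a$gene[first], trait = a$trait[first],
             score = as.numeric(score), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Trapezoidal ROC/PR computation with tie grouping: thresholds at unique
# score values (descending), each group entering at once.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  P <- sum(labels); N <- sum(!labels)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  prec <- tp[last] / (tp[last] + fp[last])
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = tp[last] / P, precision = prec))
}

trapezoid_auc <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' ROC and precision-recall AUC with bootstrap standard errors
#'
#' ROC from descending-score thresholds with ties grouped; the area under
#' the curve by the standard trapezoidal approach (numerically identical
#' to the Mann-Whitney pair-counting statistic, with ties worth one
#' half). The PR curve reports precision at each threshold. Standard
#' errors come from resampling the labelled pairs with replacement
#' `n_boot` times; the SE is the standard deviation of the bootstrap
#' AUCs.
#'
#' @param scores Numeric association scores (higher = more confident).
#' @param labels Logical (or 0/1) truth labels; both classes required.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An `AucEstimate`: list with `auc`, `se`, `pr_auc`, `pr_se`,
#'   `n_boot`, `roc` and `pr` curve data frames, and `boot_auc` (the
#'   bootstrap draws, reused for paired family comparison).
#' @export
roc_pr_auc <- function(scores, labels, n_boot = 2000, seed = 1) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("AUC undefined: both classes must be present")
  pts <- roc_points(scores, labels)
  auc <- trapezoid_auc(pts$roc$fpr, pts$roc$tpr)
  pr_auc <- trapezoid_auc(c(0, pts$pr$recall),
                          c(pts$pr$precision[1], pts$pr$precision))
  idx <- bootstrap_indices(length(scores), n_boot, seed)
  ba <- vapply(idx, function(i) {
    l <- labels[i]
    if (!any(l) || all(l)) return(NA_real_)
    p <- roc_points(scores[i], l)
    trapezoid_auc(p$roc$fpr, p$roc$tpr)
  }, 0)
  bp <- vapply(idx, function(i) {
    l <- labels[i]
    if (!any(l) || all(l)) return(NA_real_)
    p <- roc_points(scores[i], l)
    trapezoid_auc(c(0, p$pr$recall), c(p$pr$precision[1], p$pr$precision))
  }, 0)
  structure(list(auc = auc, se = sd(ba, na.rm = TRUE),
                 pr_auc = pr_auc, pr_se = sd(bp, na.rm = TRUE),
                 n_boot = n_boot, roc = pts$roc, pr = pts$pr,
                 boot_auc = ba, seed = seed),
            class = "AucEstimate")
}

bootstrap_indices <- function(n, n_boot, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, "bootstrap"))
  lapply(seq_len(n_boot), function(b) sample.int(n, replace = TRUE))
}

#' Compare two model families' AUCs with a paired bootstrap
#'
#' Difference in ROC AUC between two families scored on the same labelled
#' gene-trait pairs, with the standard error of the difference from a
#' paired bootstrap: the same resample indices are applied to both score
#' vectors, so shared sampling noise cancels.
#'
#' @param scores_a,scores_b Score vectors aligned to `labels`.
#' @param labels Truth labels (same pairs for both families).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return List with `auc_a`, `auc_b`, `difference` (a minus b) and `se`.
#' @export
compare_families <- function(scores_a, scores_b, labels, n_boot = 2000,
                             seed = 1) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("score vectors and labels must align on the same pairs")
  pa <- roc_points(scores_a, labels); pb <- roc_points(scores_b, labels)
  auc_a <- trapezoid_auc(pa$roc$fpr, pa$roc$tpr)
  auc_b <- trapezoid_auc(pb$roc$fpr, pb$roc$tpr)
  idx <- bootstrap_indices(length(labels), n_boot, seed)
  d <- vapply(idx, function(i) {
    l <- labels[i]
    if (!any(l) || all(l)) return(NA_real_)
    qa <- roc_points(scores_a[i], l); qb <- roc_points(scores_b[i], l)
    trapezoid_auc(qa$roc$fpr, qa$roc$tpr) - trapezoid_auc(qb$roc$fpr, qb$roc$tpr)
  }, 0)
  list(auc_a = auc_a, auc_b = auc_b, difference = auc_a - auc_b,
       se = sd(d, na.rm = TRUE), n_boot = n_boot)
}
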
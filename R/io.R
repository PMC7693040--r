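#' Write / read a plain-text dosage matrix
#'
#' Tab-separated dosage format: a header row of sample ids, then one row
#' per variant: `id`, `chrom`, `pos`, `ref`, `alt`, `maf`, followed by
#' per-sample dosages.
#'
#' @param G A `GenotypeMatrix`.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `GenotypeMatrix` (reader).
#' @export
write_dosage_file <- function(G, path) {
  hdr <- c("id", "chrom", "pos", "ref", "alt", "maf", G$sample_ids)
  body <- cbind(G$variants[, c("id", "chrom", "pos", "ref", "alt", "maf")],
                as.data.frame(t(G$dosages)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_file
#' @export
read_dosage_file <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "maf")
  variants <- d[, meta_cols]
  variants$chrom <- as.character(variants$chrom)
  dos <- t(as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE]))
  sample_ids <- rownames(dos)
  dimnames(dos) <- list(sample_ids, variants$id)
  structure(list(dosages = dos, variants = variants, sample_ids = sample_ids),
            class = "GenotypeMatrix")
}

#' Write / read a per-tissue expression TSV (genes x samples)
#'
#' @param expr Samples-by-genes matrix (transposed on disk: one row per
#'   gene, columns are samples, first column `gene`).
#' @param path File path.
#' @export
write_expression_tsv <- function(expr, path) {
  d <- data.frame(gene = colnames(expr), t(expr), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(m) <- d$gene
  m
}

#' Write the simulation truth table
#'
#' TSV with one row per gene-tissue-causal-variant: `gene`, `tissue`,
#' `variant_id`, `effect`, `h2`.
#'
#' @param sim Output of [simulate_multitissue_expression()].
#' @param G The `GenotypeMatrix` the simulation used.
#' @param path File path.
#' @export
write_truth_tsv <- function(sim, G, path) {
  rows <- do.call(rbind, lapply(names(sim$truth), function(g) {
    tr <- sim$truth[[g]]
    do.call(rbind, lapply(seq_len(ncol(tr$effects)), function(t)
      data.frame(gene = g, tissue = names(sim$panel)[t],
                 variant_id = G$variants$id[tr$causal],
                 effect = tr$effects[, t], h2 = tr$h2,
                 stringsAsFactors = FALSE)))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a fine-mapping PIP table
#'
#' TSV with columns `gene`, `variant_id`, `pip`, `cluster_id`,
#' `cluster_pip` -- the interchange format for externally computed
#' fine-mapping results (unclustered variants get `cluster_id` NA).
#'
#' @param fm A `FineMapResult`.
#' @param gene Gene id.
#' @param variant_ids Ids aligned to `fm$pip`.
#' @param path File path.
#' @export
write_pip_table <- function(fm, gene, variant_ids, path) {
  p <- length(fm$pip)
  cid <- rep(NA_integer_, p)
  cpip <- rep(NA_real_, p)
  for (i in seq_along(fm$clusters)) {
    cid[fm$clusters[[i]]$members] <- i
    cpip[fm$clusters[[i]]$members] <- fm$clusters[[i]]$cluster_pip
  }
  d <- data.frame(gene = gene, variant_id = variant_ids, pip = unname(fm$pip),
                  cluster_id = cid, cluster_pip = cpip,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pip_table
#' @param variant_ids_order Ids defining the design order on read; rows
#'   are matched by `variant_id`.
#' @export
read_pip_table <- function(path, gene = NULL, variant_ids_order = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(gene)) d <- d[d$gene == gene, , drop = FALSE]
  if (!is.null(variant_ids_order))
    d <- d[match(variant_ids_order, d$variant_id), , drop = FALSE]
  pip <- d$pip
  names(pip) <- d$variant_id
  clusters <- list()
  for (ci in sort(unique(d$cluster_id[!is.na(d$cluster_id)]))) {
    members <- which(!is.na(d$cluster_id) & d$cluster_id == ci)
    rep_idx <- members[order(-pip[members], members)][1]
    clusters[[length(clusters) + 1L]] <- list(
      members = members, cluster_pip = d$cluster_pip[members[1]],
      representative = rep_idx, representative_pip = unname(pip[rep_idx]))
  }
  structure(list(pip = pip, clusters = clusters, model_posteriors = NULL),
            class = "FineMapResult")
}

#' Write / read GWAS summary statistics
#'
#' The TSV dialect with exact column names `variant_id`, `chromosome`,
#' `position`, `effect_allele`, `non_effect_allele`, `zscore` and
#' optionally `beta`, `se`.
#'
#' @param gwas Data frame in the dialect above.
#' @param path File path.
#' @export
write_gwas_tsv <- function(gwas, path) {
  lead <- c("variant_id", "chromosome", "position", "effect_allele",
            "non_effect_allele", "zscore")
  stopifnot(all(setdiff(lead, "zscore") %in% names(gwas)))
  cols <- c(intersect(lead, names(gwas)),
            intersect(c("beta", "se"), names(gwas)))
  write.table(gwas[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "non_effect_allele")
  if (!all(need %in% names(d)))
    stop("missing GWAS columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!"zscore" %in% names(d)) {
    if (!all(c("beta", "se") %in% names(d)))
      stop("need either zscore or beta+se columns")
    d$zscore <- d$beta / d$se
  }
  d$chromosome <- as.character(d$chromosome)
  d
}

#' Write / read a prediction model store
#'
#' Two TSV files mirroring the predictdb relational convention: `weights`
#' (`gene`, `varID`, `ref_allele`, `eff_allele`, `weight`) and `extra`
#' (`gene`, `n_snps_in_model`, `pred_perf_rho`, `pred_perf_pval`,
#' `family`).
#'
#' @param models List of `PredictionModel` (rejections are skipped).
#' @param prefix Output path prefix; writes `<prefix>_weights.tsv` and
#'   `<prefix>_extra.tsv`.
#' @return Named vector of the two paths (writer); list of
#'   `PredictionModel` (reader).
#' @export
write_model_store <- function(models, prefix) {
  models <- Filter(function(m) inherits(m, "PredictionModel"), models)
  weights <- do.call(rbind, lapply(models, function(m)
    data.frame(gene = m$gene, varID = m$weights$variant_id,
               ref_allele = m$weights$ref, eff_allele = m$weights$alt,
               weight = m$weights$weight, tissue = m$tissue,
               stringsAsFactors = FALSE)))
  extra <- do.call(rbind, lapply(models, function(m)
    data.frame(gene = m$gene, n_snps_in_model = m$n_snps,
               pred_perf_rho = m$performance$rho_avg %||% NA_real_,
               pred_perf_pval = m$performance$p_combined %||% NA_real_,
               family = m$family, tissue = m$tissue,
               stringsAsFactors = FALSE)))
  pw <- paste0(prefix, "_weights.tsv")
  pe <- paste0(prefix, "_extra.tsv")
  write.table(weights, pw, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(extra, pe, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(weights = pw, extra = pe))
}

#' @rdname write_model_store
#' @export
read_model_store <- function(prefix) {
  w <- read.delim(paste0(prefix, "_weights.tsv"), stringsAsFactors = FALSE)
  e <- read.delim(paste0(prefix, "_extra.tsv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(e)), function(i) {
    sel <- w$gene == e$gene[i] & w$tissue == e$tissue[i]
    perf <- if (is.finite(e$pred_perf_rho[i]))
      structure(list(rho_avg = e$pred_perf_rho[i],
                     p_combined = e$pred_perf_pval[i], per_fold = NULL),
                class = "PerformanceEstimate") else NULL
    prediction_model(e$gene[i], e$tissue[i], e$family[i],
                     data.frame(variant_id = w$varID[sel],
                                ref = w$ref_allele[sel],
                                alt = w$eff_allele[sel],
                                weight = w$weight[sel],
                                stringsAsFactors = FALSE),
                     perf)
  })
}

#' Read pipeline configuration
#'
#' YAML configuration with per-family blocks (thresholds, grids, seeds),
#' merged over the package defaults.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @return Nested named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    en = list(alpha = 0.5, n_cv_folds = 10, maf_min = 0.01,
              rho_min = 0.1, p_max = 0.05, n_outer_folds = 10),
    dapgw = list(alpha = 0.5, n_cv_folds = 10, maf_min = 0.01,
                 pip_min = 0.01, rho_min = 0.1, p_max = 0.05,
                 n_outer_folds = 10),
    ctimp = list(n_cv_folds = 5, tol = 1e-6, max_iter = 1000,
                 rho_min = 0.1, p_max = 0.05),
    mashr = list(cluster_pip_min = 0.1, pip_min = 0.01),
    finemap = list(max_model_size = 2, effect_prior_variance = 0.16,
                   r2_min = 0.5, pip_min = 0.01),
    assoc = list(ridge = 0.1, drop_ambiguous = TRUE, alpha = 0.05),
    evaluate = list(n_boot = 2000, rcp_min = 0.5, aggregate = "max"),
    seed = 1
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  modifyList(defaults, user)
}

#' Write an evaluation report as JSON
#'
#' Per-family AUC/SE, curve points and per-trait prioritized-gene counts.
#'
#' @param aucs Named list of `AucEstimate` per family.
#' @param prioritized Optional named list (per trait) of prioritized gene
#'   vectors.
#' @param path Output JSON file.
#' @export
write_evaluation_report <- function(aucs, prioritized = NULL, path) {
  rep <- list(
    families = lapply(aucs, function(a) list(
      auc = a$auc, se = a$se, pr_auc = a$pr_auc, pr_se = a$pr_se,
      n_boot = a$n_boot, roc = a$roc, pr = a$pr)),
    prioritized_gene_counts = if (!is.null(prioritized))
      lapply(prioritized, length) else NULL,
    prioritized_genes = prioritized
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read silver-standard, LD-region and colocalization tables
#'
#' `read_silver_standard()`: TSV with `gene`, `trait`.
#' `read_ld_regions()`: BED-like TSV with `chrom`, `start`, `end`
#' (half-open intervals, 1-based starts).
#' `read_rcp_table()`: TSV with `gene`, `tissue`, `trait`, `rcp` in
#' `[0, 1]`.
#'
#' @param path File path.
#' @name silver_io
#' @export
read_silver_standard <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "trait") %in% names(d)))
  d
}

#' @rdname silver_io
#' @export
read_ld_regions <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  d$chrom <- as.character(d$chrom)
  stopifnot(all(d$start < d$end))
  d
}

#' @rdname silver_io
#' @export
read_rcp_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "tissue", "trait", "rcp") %in% names(d)),
            all(d$rcp >= 0 & d$rcp <= 1))
  d
}

#' Write / read a cross-tissue effect panel
#'
#' Long-format TSV (`gene`, `variant_id`, `tissue`, `beta_hat`, `se`)
#' for the marginal-effect panels consumed by [fit_mixture_em()]; the
#' reader reshapes to the `bhat`/`shat` matrix pair (rows are
#' gene-variant pairs, columns tissues, NA where unobserved).
#'
#' @param panel List with `bhat` and `shat` matrices; rownames
#'   "gene:variant_id", colnames tissues (or supplied via arguments).
#' @param path File path.
#' @export
write_effect_panel <- function(panel, path) {
  bh <- as.matrix(panel$bhat); sh <- as.matrix(panel$shat)
  rn <- rownames(bh) %||% sprintf("gene:%d", seq_len(nrow(bh)))
  cn <- colnames(bh) %||% sprintf("tissue%d", seq_len(ncol(bh)))
  gene <- sub(":.*$", "", rn)
  variant <- sub("^[^:]*:", "", rn)
  rows <- do.call(rbind, lapply(seq_len(ncol(bh)), function(t)
    data.frame(gene = gene, variant_id = variant, tissue = cn[t],
               beta_hat = bh[, t], se = sh[, t], stringsAsFactors = FALSE)))
  rows <- rows[is.finite(rows$beta_hat), , drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_panel
#' @export
read_effect_panel <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "variant_id", "tissue", "beta_hat", "se") %in%
                  names(d)))
  key <- paste(d$gene, d$variant_id, sep = ":")
  rows <- unique(key)
  tissues <- sort(unique(d$tissue))
  bh <- matrix(NA_real_, length(rows), length(tissues),
               dimnames = list(rows, tissues))
  sh <- bh
  i <- cbind(match(key, rows), match(d$tissue, tissues))
  bh[i] <- d$beta_hat
  sh[i] <- d$se
  list(bhat = bh, shat = sh)
}

#' Write a shrinkage-mixture fit summary as JSON
#'
#' Component labels, scales, fitted mixture weights and the final
#' marginal log-likelihood of a [fit_mixture_em()] result.
#'
#' @param fit A `MixtureFit`.
#' @param path Output JSON file.
#' @export
write_mixture_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "MixtureFit"))
  out <- list(
    components = lapply(fit$components, function(cp)
      list(label = cp$label, omega = cp$omega)),
    scale_grid = fit$scale_grid,
    pi = as.list(fit$pi),
    loglik = fit$loglik_trace[length(fit$loglik_trace)],
    n_iterations = length(fit$loglik_trace)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Maps the `DS` FORMAT field to dosages when present, otherwise counts
#' alternate alleles in `GT`. MAF is computed empirically from the
#' dosages (folded at 0.5). Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A `GenotypeMatrix`.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosage requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-variant VCF
  if (any(colnames(v@gt) == "FORMAT") &&
      any(grepl("DS", v@gt[, "FORMAT"]))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dos <- t(ds) # samples x variants
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  variants <- data.frame(
    id = sprintf("%s_%s_%s_%s", fix[, "CHROM"], fix[, "POS"],
                 fix[, "REF"], fix[, "ALT"]),
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], maf = unname(maf),
    stringsAsFactors = FALSE)
  dimnames(dos) <- list(rownames(dos), variants$id)
  structure(list(dosages = dos, variants = variants,
                 sample_ids = rownames(dos)),
            class = "GenotypeMatrix")
}
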
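# Shared fixture builders (all generated in code; no files).

# A multi-gene panel where each gene's cis design is one LD block and its
# true eQTL variants sit inside that block. Returns genotypes, expression,
# truth, and per-gene annotations carrying the block as cis_idx.
make_gene_panel <- function(n_samples, n_genes, variants_per_gene = 10,
                            genes_per_block = 1, within_block_corr = 0.6,
                            n_tissues = 1, n_causal = 1, sharing_corr = 0.9,
                            h2 = 0.4, tissue_sample_fractions = 1, seed = 1,
                            maf_low = 0.1, maf_high = 0.5) {
  n_variants <- n_genes * variants_per_gene
  block_size <- variants_per_gene * genes_per_block
  G <- simulate_genotypes(n_samples, n_variants, block_size = block_size,
                          within_block_corr = within_block_corr,
                          maf_low = maf_low, maf_high = maf_high, seed = seed)
  # gene g's causal variants are drawn from its own tenth of the block,
  # but its cis design (candidate variants) is the whole block
  own <- lapply(seq_len(n_genes), function(g)
    ((g - 1) * variants_per_gene + 1):(g * variants_per_gene))
  sim <- simulate_multitissue_expression(
    G, n_genes, n_tissues, n_causal = n_causal, sharing_corr = sharing_corr,
    h2 = h2, tissue_sample_fractions = tissue_sample_fractions,
    cis_windows = own, seed = seed + 1)
  blocks <- split(seq_len(n_variants),
                  rep(seq_len(ceiling(n_variants / block_size)),
                      each = block_size)[seq_len(n_variants)])
  annotations <- lapply(seq_len(n_genes), function(g) {
    blk <- blocks[[ceiling(g / genes_per_block)]]
    list(gene = sim$genes[g], cis_idx = blk)
  })
  list(G = G, sim = sim, annotations = annotations, own = own)
}

# Minimal hand-built PredictionModel for association tests.
toy_model <- function(variant_ids, weights, ref = "A", alt = "G",
                      gene = "GENE", tissue = "tissue1", family = "EN-M") {
  finetwas:::prediction_model(
    gene, tissue, family,
    data.frame(variant_id = variant_ids, ref = ref, alt = alt,
               weight = weights, stringsAsFactors = FALSE))
}

# AR(1) correlation matrix.
ar1_cor <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), "-"))
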
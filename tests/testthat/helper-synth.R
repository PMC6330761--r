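# compact study configurations used across the suite

small_sample_sizes <- function() {
  c(MCL = 40, BL = 30, DLBCL = 60, FL = 50, BPLL = 20, CLL = 50,
    HCL = 20, MALT = 40, SMZL = 30, MM = 50,
    NBC = 7, CB = 8, CC = 7, MBC = 8, BMPC = 7)
}

small_config <- function(seed = 1, ...) {
  synth_config(seed = seed, n_genes = 60, n_probes = 150,
               sample_sizes = small_sample_sizes(), ...)
}

# minimal panel-only corpus over the five trial entities, for ratio tests
ratio_config <- function(seed = 1, n_per_entity = 40, ...) {
  ss <- setNames(rep(n_per_entity, 5), c("CLL", "MCL", "FL", "DLBCL", "MM"))
  synth_config(seed = seed, n_genes = 25, n_probes = 25,
               probes_per_gene = 1L, sample_sizes = ss, ...)
}

# gene-level view of a panel-only corpus: with one probe per gene the
# probe rows are the gene rows up to fidelity mixing
gene_level <- function(d) {
  m <- d$expr
  rownames(m) <- d$probe_map$gene
  m
}
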
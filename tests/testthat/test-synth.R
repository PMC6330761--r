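test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$ann, d2$ann)
  expect_identical(d1$truth$latent, d2$truth$latent)
  c1 <- generate_cellline_panel(cfg)
  c2 <- generate_cellline_panel(cfg)
  expect_identical(c1$gep, c2$gep)
  d3 <- generate_dataset(small_config(seed = 12))
  expect_false(identical(d1$expr, d3$expr))
})

test_that("dimensions follow the configuration", {
  ss <- setNames(rep(20L, 10), malignant_entities())
  cfg <- synth_config(seed = 3, n_genes = 40, n_probes = 90,
                      sample_sizes = ss)
  d <- generate_dataset(cfg)
  expect_equal(ncol(d$expr), 200)
  expect_equal(nrow(d$expr), 90)
  expect_equal(nrow(d$probe_map), 90)
  expect_setequal(colnames(d$expr), d$ann$sample_id)
  expect_true(all(c("entity", "tissue", "subtype", "status", "series") %in%
                    names(d$ann)))
  expect_true(all(d$ann$tissue %in% c("PB", "LN", "BM", "SPL")))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(sample_sizes = integer(0)), "entity list")
  expect_error(synth_config(n_genes = 100, n_probes = 50,
                            probes_per_gene = 2L), "exceeds n_probes")
  expect_error(synth_config(tissue_mix = {
    mx <- default_tissue_mix(); mx["CLL", ] <- c(0.5, 0.5, 0.5, 0); mx
  }), "sum to 1")
  expect_error(synth_config(fidelity_overrides = list(BCL2 = 1.5)),
               "fidelity")
  cfg <- small_config()
  cfg$n_celllines <- 2L
  expect_error(generate_cellline_panel(cfg), "n_celllines")
})

test_that("a planted +2 log2 entity effect is recovered by group medians", {
  eff <- default_entity_effects()
  eff["BCL2", ] <- 0
  eff["BCL2", "CLL"] <- 2
  hits <- 0L
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(seed = 1000 + s, n_genes = 25, n_probes = 25,
                        probes_per_gene = 1L,
                        sample_sizes = c(CLL = 50, MBC = 50),
                        entity_effects = eff, batch_sd = 0,
                        noise_sd = 0.5,
                        fidelity_overrides = list(BCL2 = 1))
    d <- generate_dataset(cfg)
    m <- gene_level(d)
    dd <- median(m["BCL2", d$ann$entity == "CLL"]) -
      median(m["BCL2", d$ann$entity == "MBC"])
    if (abs(dd - 2) <= 0.3) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.92 * n_seeds))
})

test_that("transformed FL/MALT samples carry the aggressive DLBCL-like profile", {
  cfg <- small_config(seed = 5, transformed_fraction = 0.4)
  d <- generate_dataset(cfg)
  fl <- d$ann$entity == "FL"
  expect_true(any(d$ann$status[fl] == "aggressive"))
  expect_true(any(d$ann$status[fl] == "indolent"))
  # transformed FL sits closer to DLBCL than to indolent FL in family space
  lat <- d$truth$latent[bcl2_family_genes(), ]
  prof <- function(sel) rowMeans(lat[, sel, drop = FALSE])
  tr <- prof(fl & d$ann$status == "aggressive")
  ind <- prof(fl & d$ann$status == "indolent")
  dl <- prof(d$ann$entity == "DLBCL")
  expect_lt(sqrt(sum((tr - dl)^2)), sqrt(sum((tr - ind)^2)))
})

test_that("venetoclax ORR table carries the published trial values", {
  orr <- default_orr_table()
  expect_equal(unname(orr["CLL"]), 79)
  expect_equal(unname(orr["MCL"]), 75)
  expect_equal(unname(orr["FL"]), 38)
  expect_equal(unname(orr["DLBCL"]), 18)
  expect_equal(unname(orr["MM"]), 21)
  expect_true(all(orr >= 0 & orr <= 100))
  expect_false("HCL" %in% names(orr))
})

test_that("implied ORR is monotone in the entity-level planted ratio median", {
  d <- generate_dataset(small_config(seed = 21))
  tr <- d$truth
  scores <- ratio_score(tr$latent, tr$planted_ratio)
  ents <- names(tr$implied_orr)
  expect_gte(length(ents), 5)
  med <- vapply(ents, function(e)
    median(scores[d$ann$entity == e]), numeric(1))
  ord <- order(med)
  expect_true(all(diff(tr$implied_orr[ord]) >= 0))
})

test_that("cell-line panel pairs probe-level GEP with gene-level RNA-seq", {
  cfg <- small_config(seed = 9, fidelity_overrides = list(BCL2 = 1))
  cl <- generate_cellline_panel(cfg)
  expect_equal(ncol(cl$gep), 19)
  expect_equal(ncol(cl$rnaseq), 19)
  # a fidelity-1 probe reproduces its gene's RNA-seq values exactly
  pr <- cl$probe_map$probe_id[cl$probe_map$gene == "BCL2"][1]
  expect_equal(cor(cl$gep[pr, ], cl$rnaseq["BCL2", ]), 1)
})

test_that("higher-fidelity probes track RNA-seq better", {
  hits <- 0L
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(seed = 3000 + s, n_genes = 25, n_probes = 50,
                        probes_per_gene = 2L,
                        sample_sizes = c(CLL = 10, MM = 10),
                        fidelity_overrides = list(BCL2 = c(0.9, 0.1)))
    cl <- generate_cellline_panel(cfg)
    pr <- cl$probe_map$probe_id[cl$probe_map$gene == "BCL2"]
    r <- vapply(pr, function(p)
      cor(cl$gep[p, ], cl$rnaseq["BCL2", ]), numeric(1))
    if (r[1] > r[2]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
})
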
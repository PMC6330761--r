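test_that("ratio scores are sums of log2 values over numerator and denominator", {
  m <- rbind(BCL2 = c(8, 5), BCL2L11 = c(6, 5), BAX = c(7, 5),
             BCL2L1 = c(7, 5))
  colnames(m) <- c("s1", "s2")
  spec <- ratio_spec(c("BCL2", "BCL2L11", "BAX"), "BCL2L1")
  sc <- ratio_score(m, spec)
  expect_equal(unname(sc["s1"]), 3.0)       # (8+6+7)/7
  expect_equal(unname(sc["s2"]), 3.0)       # (v+v+v)/v
  # linear-scale option un-logs before summing
  lin <- ratio_score(m, spec, linear = TRUE)
  expect_equal(unname(lin["s1"]), (2^8 + 2^6 + 2^7) / 2^7)
  expect_error(ratio_score(m[1:3, ], spec), "absent")
  m_bad <- m; m_bad["BCL2L1", 1] <- -7
  expect_error(ratio_score(m_bad, spec), "non-positive")
})

test_that("ratio specs are constrained to their gene pools", {
  sp <- ratio_spec(c("BCL2", "BCL2L11", "BAX"), "BCL2L1")
  expect_s3_class(sp, "ratio_spec")
  expect_error(ratio_spec(character(0), "BCL2L1"), "non-empty")
  expect_error(ratio_spec("MCL1", "BCL2L1"), "efficacy")
  expect_error(ratio_spec("BCL2", "BAX"), "resistance")
})

test_that("candidate enumeration covers all subset pairs exactly once", {
  cands <- enumerate_ratio_specs()
  expect_length(cands, 49)
  keys <- vapply(cands, format, character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(format(ratio_spec(efficacy_genes(), "BCL2L1")) %in% keys)
  expect_length(enumerate_ratio_specs("BCL2", "MCL1"), 1)
  expect_error(enumerate_ratio_specs(character(0), "MCL1"), "non-empty")
})

test_that("scores are invariant to common scaling of the ratio genes", {
  set.seed(101)
  m <- matrix(runif(24, 5, 9), nrow = 4,
              dimnames = list(c("BCL2", "BCL2L11", "BAX", "BCL2L1"),
                              paste0("s", 1:6)))
  spec <- ratio_spec(c("BCL2", "BCL2L11", "BAX"), "BCL2L1")
  expect_equal(ratio_score(3 * m, spec), ratio_score(m, spec),
               tolerance = 1e-12)
})

test_that("entity medians exactly linear in ORR give r = 1 for the planted spec", {
  ents <- c("CLL", "MCL", "FL", "DLBCL", "MM")
  ratio_by_entity <- c(4.4, 4.0, 3.2, 2.6, 2.8)
  orr <- setNames(10 + 20 * ratio_by_entity, ents)
  # constant samples per entity: BCL2L1 fixed at 7, numerator sum chosen
  # to hit the target ratio exactly
  ann <- data.frame(sample_id = paste0("s", 1:10),
                    entity = rep(ents, each = 2))
  # only the full numerator over BCL2L1 is exactly linear in ORR: the
  # per-gene perturbations delta/eps cancel in the three-gene sum
  delta <- c(0.3, -0.2, 0.5, -0.4, 0.1)
  eps <- c(-0.2, 0.4, 0.1, -0.3, 0.2)
  m <- rbind(BCL2 = rep(7 * ratio_by_entity - 14 - delta, each = 2),
             BCL2L11 = rep(7 + delta + eps, each = 2),
             BAX = rep(7 - eps, each = 2), BCL2L1 = 7,
             MCL1 = rep(c(8, 7, 9, 6, 7), each = 2),
             BCL2A1 = rep(c(6, 8, 7, 9, 6), each = 2))
  colnames(m) <- ann$sample_id
  rk <- rank_ratio_candidates(m, ann, orr,
                              summary = "median-per-entity")
  planted <- ratio_spec(efficacy_genes(), "BCL2L1")
  expect_equal(spec_rank(rk, planted), 1)
  expect_equal(rk$r[1], 1, tolerance = 1e-9)
  expect_equal(rk$n[1], 5)
  expect_error(rank_ratio_candidates(m, ann, orr[1:2]), "3 entities")
})

test_that("the planted ratio is recovered from linked synthetic data", {
  planted <- ratio_spec(efficacy_genes(), "BCL2L1")
  hits <- 0L
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    d <- generate_dataset(ratio_config(seed = 4000 + s))
    # recovery is judged at the level the link is planted: entity medians
    # of the gene-level matrix
    rk <- rank_ratio_candidates(d$truth$latent, d$ann, d$truth$implied_orr,
                                summary = "median-per-entity")
    if (spec_rank(rk, planted) == 1) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.85 * n_seeds))
})

test_that("entities without trial ORR are scored but not correlated", {
  d <- generate_dataset(small_config(seed = 105))
  m <- d$truth$latent
  orr <- default_orr_table()
  rk <- rank_ratio_candidates(m, d$ann, orr)
  with_orr <- sum(d$ann$entity %in% names(orr))
  expect_true(all(rk$n == with_orr))
  sc <- ratio_score(m, ratio_spec(efficacy_genes(), "BCL2L1"))
  expect_length(sc, ncol(m))            # every sample scored, HCL included
  # BPLL and HCL carry high ratios, BL a low one
  med <- tapply(sc, d$ann$entity, median)
  expect_gt(med["BPLL"], med["BL"])
  expect_gt(med["HCL"], med["BL"])
})

test_that("ratio contrasts by tissue and subtype recover planted structure", {
  sc <- setNames(c(1, 1, 1, 2, 2, 2), paste0("s", 1:6))
  ann <- data.frame(sample_id = paste0("s", 1:6),
                    tissue = rep(c("PB", "LN"), each = 3))
  same <- compare_ratio_by_group(setNames(rep(1, 6), paste0("s", 1:6)),
                                 ann, "tissue")
  expect_equal(same$stars, "ns")
  expect_error(compare_ratio_by_group(sc, data.frame(
    sample_id = paste0("s", 1:6), tissue = "PB"), "tissue"), "2 groups")

  # planted niche effect: LN ratio below PB ratio in MCL
  lower <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    ss <- c(MCL = 60)
    cfg <- synth_config(seed = 5000 + s, n_genes = 25, n_probes = 25,
                        probes_per_gene = 1L, sample_sizes = ss)
    d <- generate_dataset(cfg)
    sc <- ratio_score(gene_level(d), cfg$planted_ratio)
    res <- compare_ratio_by_group(sc, d$ann, "tissue")
    row <- res[1, ]
    ln_med <- ifelse(row$group_a == "LN", row$median_a, row$median_b)
    pb_med <- ifelse(row$group_a == "PB", row$median_a, row$median_b)
    if (ln_med < pb_med && row$p < 0.05) lower <- lower + 1L
  }
  expect_gte(lower, ceiling(0.8 * n_seeds))

  # the CCND1 MM subgroup carries the highest ratio among MM subtypes
  top <- 0L
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(seed = 6000 + s, n_genes = 25, n_probes = 25,
                        probes_per_gene = 1L, sample_sizes = c(MM = 160))
    d <- generate_dataset(cfg)
    sc <- ratio_score(gene_level(d), cfg$planted_ratio)
    med <- tapply(sc, d$ann$subtype, median)
    if (names(which.max(med)) == "CCND1") top <- top + 1L
  }
  expect_gte(top, ceiling(0.8 * n_seeds))
})
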
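#' @name synth
#' @title Synthetic multi-series BCL2-family expression corpus
#'
#' @description
#' The generator emulates the structure of a pooled microarray compendium of
#' mature B-cell malignancies: ten malignant entities plus their normal
#' B-cell counterparts, several series (batches) per entity, tissue of
#' origin (PB/LN/BM/SPL), molecular subtypes, indolent/aggressive status,
#' multi-probe genes of heterogeneous fidelity, matched cell-line RNA-seq,
#' and a planted monotone link between a chosen expression ratio and
#' entity-level venetoclax overall response rate (ORR).
#'
#' The latent model for gene g in sample s is
#' \deqn{x_{gs} = \mu_g + \beta_{g,entity(s)} + \gamma_{g,tissue(s)} +
#'   b_{series(s)} + \epsilon, \quad \epsilon \sim N(0, \sigma^2)}
#' on the log2 scale, and a probe p of gene g reports
#' \deqn{y_{ps} = f_p x_{gs} + (1 - f_p)(\mu_g + \eta_{ps})}
#' with fidelity \eqn{f_p \in [0,1]} and independent noise \eqn{\eta}.
NULL

#' The twelve BCL2-family genes of the analysis panel
#'
#' Anti-apoptotic members (BCL2, BCL2L1, MCL1, BCL2L2, BCL2A1), BH3-only
#' pro-apoptotics (BIK, PMAIP1, BMF, BID, BCL2L11) and effectors (BAX, BAK1).
#'
#' @return Character vector of gene symbols.
#' @export
bcl2_family_genes <- function() {
  c("BCL2", "BCL2L1", "MCL1", "BCL2L2", "BCL2A1",
    "BIK", "PMAIP1", "BMF", "BID", "BCL2L11", "BAX", "BAK1")
}

#' Venetoclax efficacy and resistance gene pools
#'
#' Efficacy pool: genes whose expression favours venetoclax-induced
#' apoptosis (BCL2, BCL2L11, BAX). Resistance pool: anti-apoptotic members
#' known to buffer venetoclax (MCL1, BCL2L1, BCL2A1).
#'
#' @return Character vector of gene symbols.
#' @export
efficacy_genes <- function() c("BCL2", "BCL2L11", "BAX")

#' @rdname efficacy_genes
#' @export
resistance_genes <- function() c("MCL1", "BCL2L1", "BCL2A1")

#' Anchoring genes used for post-normalization quality control
#' @return Character vector of marker gene symbols.
#' @export
anchor_genes <- function() {
  c("CD27", "CCND1", "SOX11", "MKI67", "BCL6",
    "MME", "CD200", "ITGAE", "CD38", "SDC1")
}

#' Malignant entities and their normal B-cell counterparts
#'
#' The counterpart assignment follows cell-of-origin: MCL is a pre-germinal
#' center neoplasm (naive B cells, NBC), BL/DLBCL derive from centroblasts
#' (CB), FL from centrocytes (CC), the post-GC leukemias/lymphomas from
#' memory B cells (MBC) and MM from bone-marrow plasma cells (BMPC). The
#' mapping is a plain named vector so it can be overridden in the config.
#'
#' @return Named character vector, entity -> counterpart label.
#' @export
default_counterpart_map <- function() {
  c(MCL = "NBC", BL = "CB", DLBCL = "CB", FL = "CC", CLL = "MBC",
    BPLL = "MBC", HCL = "MBC", MALT = "MBC", SMZL = "MBC", MM = "BMPC")
}

malignant_entities <- function() names(default_counterpart_map())
normal_entities <- function() unique(unname(default_counterpart_map()))

#' Venetoclax-monotherapy overall response rates by entity
#'
#' Trial ORR (percent) for the entities with published venetoclax
#' monotherapy data: high in CLL and MCL (79 and 75), intermediate in FL
#' (38), low in DLBCL and MM (18 and 21). Entities without trial data
#' (BPLL, HCL, BL, MALT, SMZL) carry no value.
#'
#' @return Named numeric vector of percentages in \[0, 100\].
#' @export
default_orr_table <- function() {
  c(CLL = 79, MCL = 75, FL = 38, DLBCL = 18, MM = 21)
}

baseline_expression <- function() {
  c(BCL2 = 8, BCL2L1 = 7.5, MCL1 = 8.5, BCL2L2 = 7, BCL2A1 = 6.5,
    BIK = 6, PMAIP1 = 7, BMF = 6.5, BID = 7, BCL2L11 = 7, BAX = 7.5,
    BAK1 = 7.5, BAD = 6, HRK = 5.5, BBC3 = 6.5,
    CD27 = 5, CCND1 = 5, SOX11 = 4.5, MKI67 = 5, BCL6 = 5,
    MME = 4.5, CD200 = 5, ITGAE = 4.5, CD38 = 5, SDC1 = 4.5)
}

#' Default per-entity log2 expression shifts
#'
#' A genes-by-entities matrix of planted log2 shifts for the BCL2-family
#' panel and the anchoring genes, over the ten malignant entities and five
#' normal counterpart populations. The family profiles encode the main
#' biology the pipeline is meant to recover: anti-apoptotic genes up and
#' pro-apoptotics down in tumors versus normals, an efficacy/resistance
#' balance that decreases from CLL/MCL through FL to DLBCL/BL, and
#' distinctive per-entity signatures so entities are separable in the
#' 12-gene space. Anchor shifts (default +3 log2, the `anchor_effect`
#' argument, with secondary markers at two thirds of it) give the QC rules
#' signal.
#'
#' @param anchor_effect log2 shift planted for primary anchor markers.
#' @return Numeric matrix, rownames = genes, colnames = entities.
#' @export
default_entity_effects <- function(anchor_effect = 3) {
  ents <- c(malignant_entities(), normal_entities())
  genes <- c(bcl2_family_genes(), "BAD", "HRK", "BBC3", anchor_genes())
  eff <- matrix(0, nrow = length(genes), ncol = length(ents),
                dimnames = list(genes, ents))
  fam <- rbind(
    #          MCL    BL DLBCL    FL  BPLL   CLL   HCL  MALT  SMZL    MM
    BCL2    = c(1.8, -2.0,  0.2,  1.2,  2.2,  2.0,  1.0,  1.0,  1.5,  0.0),
    BCL2L1  = c(-1.0,  0.5,  1.5,  0.0, -1.5, -1.5, -0.5,  0.5, -0.5,  0.5),
    MCL1    = c(0.8, -0.5,  0.5, -0.5,  0.0,  0.0, -1.0,  1.5,  0.5,  1.2),
    BCL2L2  = c(0.0,  2.0, -0.5,  0.5, -0.5,  0.5,  2.0, -1.0,  1.0, -1.5),
    BCL2A1  = c(-0.5, -2.0,  1.0,  0.8,  0.5,  0.5,  2.5,  1.0,  1.5, -2.0),
    BIK     = c(1.5,  0.0, -0.5,  0.5, -1.0, -0.5, -2.0,  0.5,  0.0,  1.5),
    PMAIP1  = c(-0.5,  1.5,  0.5, -0.5,  1.5, -1.0,  1.0, -1.5,  0.5,  0.5),
    BMF     = c(0.5, -1.5, -1.0,  1.0,  1.0,  1.5,  0.5,  0.5, -1.5, -0.5),
    BID     = c(-0.5,  1.0,  0.8, -1.0,  0.5,  0.0, -0.5, -2.0,  0.5,  1.0),
    BCL2L11 = c(1.2, -0.5,  0.5, -0.3,  1.0,  1.5,  1.5, -0.5,  0.5, -0.2),
    BAX     = c(1.0,  0.5,  0.4,  0.1,  0.5,  0.8,  0.0, -0.3, -1.0,  0.0),
    BAK1    = c(0.0,  1.0,  0.5, -0.5, -1.0,  0.0,  0.5, -0.5,  0.5,  1.5))
  colnames(fam) <- malignant_entities()
  eff[rownames(fam), colnames(fam)] <- fam

  # normal counterparts: lower anti-apoptotic, higher BH3-only/effector tone
  nrm <- rbind(
    #          NBC    CB    CC   MBC  BMPC
    BCL2    = c(-0.5, -2.0, -1.5,  0.0, -1.0),
    BCL2A1  = c(-0.5,  0.0, -0.5, -0.5, -1.0),
    MCL1    = c(0.0,  0.0,  0.0,  0.0,  1.5),
    BCL2L11 = c(1.5,  1.0,  1.0,  1.5,  0.5),
    PMAIP1  = c(1.0,  1.5,  1.0,  1.0,  0.5),
    BMF     = c(1.0,  0.5,  1.5,  1.0,  0.5),
    BAX     = c(1.0,  1.0,  1.0,  1.0,  0.5),
    BID     = c(0.5,  0.5,  0.0,  0.5,  0.0))
  colnames(nrm) <- normal_entities()
  eff[rownames(nrm), colnames(nrm)] <- nrm

  a <- anchor_effect
  a2 <- anchor_effect * 2 / 3
  anch <- list(
    CCND1 = c(MCL = a), SOX11 = c(MCL = a),
    SDC1 = c(MM = a, BMPC = a), CD38 = c(MM = a, BMPC = a),
    CD27 = c(CLL = a, MBC = a),
    MKI67 = c(BL = a, DLBCL = a2, CB = a2),
    BCL6 = c(BL = a, DLBCL = a, FL = a, CB = a, CC = a),
    MME = c(BL = a, FL = a, CB = a, CC = a),
    CD200 = c(CLL = a, HCL = a), ITGAE = c(HCL = a))
  for (g in names(anch)) eff[g, names(anch[[g]])] <- anch[[g]]
  eff
}

#' Default tissue-of-origin log2 shifts
#'
#' Tumor-niche regulation relative to peripheral blood: the BH3-only genes
#' BCL2L11 and PMAIP1 are repressed in protective niches (strongest in
#' lymph node) while BCL2L1 is induced.
#'
#' @return Numeric matrix, rownames = genes, colnames = tissues
#'   (PB, LN, BM, SPL); genes not listed shift by 0.
#' @export
default_tissue_effects <- function() {
  te <- rbind(
    #           PB    LN    BM   SPL
    BCL2L11 = c(0, -1.2, -0.8, -0.8),
    PMAIP1  = c(0, -1.2, -0.8, -0.6),
    BCL2L1  = c(0,  1.0,  0.4,  0.3))
  colnames(te) <- c("PB", "LN", "BM", "SPL")
  te
}

#' Default per-entity tissue composition
#' @return Matrix of proportions (entities x PB/LN/BM/SPL), rows sum to 1.
#' @export
default_tissue_mix <- function() {
  mix <- rbind(
    MCL  = c(0.5, 0.5, 0.0, 0.0),
    BL   = c(0.0, 1.0, 0.0, 0.0),
    DLBCL = c(0.0, 1.0, 0.0, 0.0),
    FL   = c(0.3, 0.7, 0.0, 0.0),
    BPLL = c(1.0, 0.0, 0.0, 0.0),
    CLL  = c(0.7, 0.1, 0.2, 0.0),
    HCL  = c(0.6, 0.0, 0.4, 0.0),
    MALT = c(0.0, 1.0, 0.0, 0.0),
    SMZL = c(0.5, 0.0, 0.0, 0.5),
    MM   = c(0.0, 0.0, 1.0, 0.0),
    NBC  = c(1.0, 0.0, 0.0, 0.0),
    CB   = c(0.0, 1.0, 0.0, 0.0),
    CC   = c(0.0, 1.0, 0.0, 0.0),
    MBC  = c(1.0, 0.0, 0.0, 0.0),
    BMPC = c(0.0, 0.0, 1.0, 0.0))
  colnames(mix) <- c("PB", "LN", "BM", "SPL")
  mix
}

#' Default per-entity sample counts (full corpus, 1200 samples)
#'
#' Mirrors the make-up of a pooled public compendium: large DLBCL/MM/CLL
#' series, mid-size FL/MCL, small rare-entity series, and 37 normal B-cell
#' samples spanning naive B cells to bone-marrow plasma cells.
#'
#' @return Named integer vector.
#' @export
default_sample_sizes <- function() {
  c(MCL = 120, BL = 60, DLBCL = 220, FL = 160, BPLL = 30, CLL = 190,
    HCL = 38, MALT = 60, SMZL = 75, MM = 210,
    NBC = 7, CB = 8, CC = 7, MBC = 8, BMPC = 7)
}

# molecular subtype labels, proportions and gene-effect tweaks per entity
default_subtypes <- function() {
  list(
    MCL = list(labels = c("SOX11pos", "SOX11neg"), props = c(0.85, 0.15),
               tweaks = list(SOX11neg = c(SOX11 = -3, MCL1 = 0.7, BIK = -2))),
    DLBCL = list(labels = c("GCB", "ABC", "PMBL"), props = c(0.5, 0.4, 0.1),
                 tweaks = list(ABC = c(BCL2 = 1.0, BCL2L1 = -0.5),
                               PMBL = c(BCL2L1 = 0.5))),
    MM = list(labels = c("CCND1", "CCND3", "MAF", "MAFB", "MMSET",
                         "HY", "PR", "LB"),
              props = c(0.18, 0.05, 0.08, 0.04, 0.15, 0.25, 0.12, 0.13),
              tweaks = list(CCND1 = c(BCL2 = 1.5, BCL2L1 = -1.0),
                            MAF = c(BCL2L1 = 0.5),
                            MMSET = c(BCL2 = -0.5),
                            PR = c(BCL2L11 = -0.5))))
}

entity_status <- function() {
  c(MCL = "aggressive", BL = "aggressive", DLBCL = "aggressive",
    FL = "indolent", BPLL = "aggressive", CLL = "indolent",
    HCL = "indolent", MALT = "indolent", SMZL = "indolent",
    MM = "aggressive",
    NBC = "normal", CB = "normal", CC = "normal", MBC = "normal",
    BMPC = "normal")
}

#' Configuration of the synthetic corpus generator
#'
#' All structural knobs of [generate_dataset()] and
#' [generate_cellline_panel()] in one validated list. Defaults reproduce
#' the study conditions: a 1,200-sample / 5,000-probe corpus over 10
#' malignant entities and 5 normal counterpart populations, two series per
#' entity, the planted (BCL2+BCL2L11+BAX)/BCL2L1 ratio linked linearly to
#' entity-level ORR, and 19 matched cell lines.
#'
#' @param seed integer; fixes every random draw (same config + seed gives
#'   byte-identical output).
#' @param n_genes total gene count (panel + anchors + background genes).
#' @param n_probes total probe count; must be at least
#'   `min(probes_per_gene) * n_genes`.
#' @param probes_per_gene candidate probe counts per gene, sampled
#'   uniformly (default 1:4).
#' @param sample_sizes named integer vector, entity -> sample count.
#' @param series_per_entity number of series (batches) per entity.
#' @param tissue_mix entities-by-tissue proportion matrix (rows sum to 1).
#' @param entity_effects genes-by-entities log2 shift matrix; rows for
#'   genes absent from the matrix are taken as 0.
#' @param tissue_effects genes-by-tissue log2 shift matrix.
#' @param counterpart_map named vector, malignant entity -> normal
#'   counterpart label.
#' @param batch_sd sd (log2) of the per-series offset shared by all probes.
#' @param noise_sd sd (log2) of the per-sample biological/technical noise.
#' @param probe_noise_sd sd of the probe-specific off-target channel.
#' @param fidelity_range range of fidelities for secondary/background
#'   probes.
#' @param high_fidelity_range fidelity range of each panel gene's best
#'   probe.
#' @param zero_fidelity_genes genes all of whose probes are pure noise
#'   (off-target probe sets; BAD and HRK by default).
#' @param fidelity_overrides named list gene -> numeric vector of
#'   fidelities, recycled across the gene's probes.
#' @param subtypes per-entity subtype definitions (labels, proportions,
#'   gene tweaks); see `default_subtypes()`.
#' @param transformed_fraction fraction of FL and MALT samples drawn from
#'   the DLBCL-like family profile and labeled status = "aggressive".
#' @param planted_ratio a [ratio_spec()]; the ratio the ORR link is built
#'   on.
#' @param orr_link_intercept,orr_link_slope linear link from the
#'   entity-level median planted ratio to ORR percent, truncated to
#'   \[0, 100\].
#' @param orr_noise_sd sd of entity-level ORR measurement noise
#'   (percentage points) added around the link.
#' @param n_celllines number of matched GEP/RNA-seq cell lines.
#' @param cellline_sd sd of the per-line latent expression spread.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 2000L,
                         n_probes = 5000L,
                         probes_per_gene = 1:4,
                         sample_sizes = default_sample_sizes(),
                         series_per_entity = 2L,
                         tissue_mix = default_tissue_mix(),
                         entity_effects = default_entity_effects(),
                         tissue_effects = default_tissue_effects(),
                         counterpart_map = default_counterpart_map(),
                         batch_sd = 0.3,
                         noise_sd = 0.5,
                         probe_noise_sd = 1,
                         fidelity_range = c(0.55, 0.95),
                         high_fidelity_range = c(0.85, 0.95),
                         zero_fidelity_genes = c("BAD", "HRK"),
                         fidelity_overrides = list(),
                         subtypes = default_subtypes(),
                         transformed_fraction = 0.2,
                         planted_ratio = ratio_spec(efficacy_genes(), "BCL2L1"),
                         orr_link_intercept = -42,
                         orr_link_slope = 27,
                         orr_noise_sd = 0,
                         n_celllines = 19L,
                         cellline_sd = 1) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_probes = as.integer(n_probes),
              probes_per_gene = as.integer(probes_per_gene),
              sample_sizes = sample_sizes,
              series_per_entity = as.integer(series_per_entity),
              tissue_mix = tissue_mix, entity_effects = entity_effects,
              tissue_effects = tissue_effects,
              counterpart_map = counterpart_map,
              batch_sd = batch_sd, noise_sd = noise_sd,
              probe_noise_sd = probe_noise_sd,
              fidelity_range = fidelity_range,
              high_fidelity_range = high_fidelity_range,
              zero_fidelity_genes = zero_fidelity_genes,
              fidelity_overrides = fidelity_overrides,
              subtypes = subtypes,
              transformed_fraction = transformed_fraction,
              planted_ratio = planted_ratio,
              orr_link_intercept = orr_link_intercept,
              orr_link_slope = orr_link_slope,
              orr_noise_sd = orr_noise_sd,
              n_celllines = as.integer(n_celllines),
              cellline_sd = cellline_sd)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$sample_sizes) == 0L)
    stop("configuration error: entity list is empty")
  if (is.null(names(cfg$sample_sizes)) || any(names(cfg$sample_sizes) == ""))
    stop("configuration error: sample_sizes must be named by entity")
  if (any(cfg$sample_sizes < 0))
    stop("configuration error: negative sample count")
  if (any(cfg$probes_per_gene < 1L))
    stop("configuration error: probes_per_gene must be >= 1")
  if (min(cfg$probes_per_gene) * cfg$n_genes > cfg$n_probes)
    stop("configuration error: probes_per_gene * n_genes exceeds n_probes")
  if (cfg$n_genes < length(panel_genes()))
    stop("configuration error: n_genes smaller than the fixed gene panel")
  ents <- names(cfg$sample_sizes)
  missing_mix <- setdiff(ents, rownames(cfg$tissue_mix))
  if (length(missing_mix))
    stop("configuration error: no tissue mix for ", paste(missing_mix, collapse = ", "))
  rs <- rowSums(cfg$tissue_mix[ents, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-8))
    stop("configuration error: tissue proportions must sum to 1 per entity")
  if (length(cfg$fidelity_overrides)) {
    f <- unlist(cfg$fidelity_overrides)
    if (any(f < 0 | f > 1))
      stop("configuration error: fidelity must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$batch_sd < 0)
    stop("configuration error: negative sd")
  invisible(cfg)
}

panel_genes <- function() {
  c(bcl2_family_genes(), "BAD", "HRK", "BBC3", anchor_genes())
}

# draw per-gene probe counts and fit them exactly into the probe budget;
# background genes absorb the slack so panel genes keep their drawn counts
draw_probe_counts <- function(cfg, genes) {
  counts <- if (length(cfg$probes_per_gene) == 1L)
    rep(cfg$probes_per_gene, length(genes))
  else sample(cfg$probes_per_gene, length(genes), replace = TRUE)
  names(counts) <- genes
  bg <- setdiff(genes, panel_genes())
  excess <- sum(counts) - cfg$n_probes
  if (excess > 0) {
    for (g in sample(bg)) {
      if (excess <= 0) break
      drop <- min(counts[g] - min(cfg$probes_per_gene), excess)
      counts[g] <- counts[g] - drop
      excess <- excess - drop
    }
    if (excess > 0) for (g in sample(names(counts))) {
      if (excess <= 0) break
      drop <- min(counts[g] - 1L, excess)
      counts[g] <- counts[g] - drop
      excess <- excess - drop
    }
  } else if (excess < 0) {
    pool <- if (length(bg)) bg else genes
    extra <- sample(pool, -excess, replace = TRUE)
    tab <- table(extra)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

draw_fidelities <- function(cfg, map) {
  fid <- runif(nrow(map), cfg$fidelity_range[1], cfg$fidelity_range[2])
  names(fid) <- map$probe_id
  for (g in intersect(unique(map$gene), panel_genes())) {
    first <- which(map$gene == g)[1]
    fid[first] <- runif(1, cfg$high_fidelity_range[1],
                        cfg$high_fidelity_range[2])
  }
  fid[map$gene %in% cfg$zero_fidelity_genes] <- 0
  for (g in names(cfg$fidelity_overrides)) {
    idx <- which(map$gene == g)
    if (length(idx))
      fid[idx] <- rep_len(cfg$fidelity_overrides[[g]], length(idx))
  }
  fid
}

effect_for_gene <- function(effects, gene, entity) {
  if (gene %in% rownames(effects) && entity %in% colnames(effects))
    effects[gene, entity] else 0
}

# per-sample annotation table: entity, series, tissue, subtype, status
draw_annotation <- function(cfg) {
  ann <- do.call(rbind, lapply(names(cfg$sample_sizes), function(e) {
    n <- cfg$sample_sizes[[e]]
    if (n == 0L) return(NULL)
    tissues <- colnames(cfg$tissue_mix)
    tissue <- sample(tissues, n, replace = TRUE, prob = cfg$tissue_mix[e, ])
    series <- paste0(e, "_S",
                     sample(seq_len(cfg$series_per_entity), n, replace = TRUE))
    st <- cfg$subtypes[[e]]
    subtype <- if (!is.null(st))
      sample(st$labels, n, replace = TRUE, prob = st$props) else "NOS"
    status <- rep(entity_status()[[e]] %||% "indolent", n)
    if (e %in% c("FL", "MALT") && cfg$transformed_fraction > 0) {
      transformed <- runif(n) < cfg$transformed_fraction
      status[transformed] <- "aggressive"
      subtype <- ifelse(transformed, "transformed", "indolent")
    }
    data.frame(sample_id = sprintf("%s_%03d", e, seq_len(n)),
               entity = e, tissue = tissue, subtype = subtype,
               status = status, series = series,
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- ann$sample_id
  ann
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Generate a synthetic probe-level expression corpus
#'
#' Draws the full patient corpus described by a [synth_config()]: latent
#' gene-by-sample log2 expression built from gene baselines, planted
#' entity/tissue/subtype effects, per-series batch offsets and Gaussian
#' noise; then a probe-by-sample matrix where each probe mixes its gene's
#' latent signal with an independent noise channel according to the probe's
#' fidelity. Transformed FL/MALT samples are drawn from the DLBCL-like
#' BCL2-family profile but keep their own entity label (and anchors), with
#' status "aggressive". The implied entity-level ORR is computed by
#' applying the linear link to the entity medians of the planted ratio on
#' the latent matrix, truncated to \[0, 100\].
#'
#' @param cfg a [synth_config()].
#' @return List with elements `expr` (probe-by-sample log2 matrix), `ann`
#'   (sample annotation data.frame), `probe_map` (data.frame probe_id,
#'   gene) and `truth` (ground-truth list: `latent`, `fidelity`,
#'   `entity_effects`, `tissue_effects`, `batch_offsets`, `planted_ratio`,
#'   `implied_orr`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_synth_config(cfg)
  set.seed(cfg$seed)

  genes <- c(panel_genes(),
             sprintf("BG%04d", seq_len(cfg$n_genes - length(panel_genes()))))
  mu <- baseline_expression()[genes]
  names(mu) <- genes
  mu[is.na(mu)] <- runif(sum(is.na(mu)), 4, 10)

  counts <- draw_probe_counts(cfg, genes)
  map <- data.frame(
    probe_id = sprintf("ps%05d_at", seq_len(sum(counts))),
    gene = rep(names(counts), counts), stringsAsFactors = FALSE)
  fid <- draw_fidelities(cfg, map)

  ann <- draw_annotation(cfg)
  n <- nrow(ann)

  batch_levels <- unique(ann$series)
  batch <- rnorm(length(batch_levels), 0, cfg$batch_sd)
  names(batch) <- batch_levels

  eff <- cfg$entity_effects
  fam <- bcl2_family_genes()
  # per-sample effect column: entity profile, with the family block swapped
  # to the DLBCL profile for transformed FL/MALT, plus subtype tweaks
  sample_eff <- matrix(0, nrow = length(genes), ncol = n,
                       dimnames = list(genes, ann$sample_id))
  shared <- intersect(rownames(eff), genes)
  for (e in unique(ann$entity)) {
    idx <- which(ann$entity == e)
    if (e %in% colnames(eff))
      sample_eff[shared, idx] <- eff[shared, e]
    if (e %in% c("FL", "MALT") && "DLBCL" %in% colnames(eff)) {
      tr <- idx[ann$status[idx] == "aggressive"]
      if (length(tr))
        sample_eff[intersect(fam, shared), tr] <-
          eff[intersect(fam, shared), "DLBCL"]
    }
    st <- cfg$subtypes[[e]]
    if (!is.null(st) && length(st$tweaks)) {
      for (sub in names(st$tweaks)) {
        tw <- st$tweaks[[sub]]
        sidx <- idx[ann$subtype[idx] == sub]
        for (g in intersect(names(tw), genes))
          sample_eff[g, sidx] <- sample_eff[g, sidx] + tw[[g]]
      }
    }
  }

  te <- cfg$tissue_effects
  tissue_eff <- matrix(0, nrow = length(genes), ncol = n,
                       dimnames = list(genes, ann$sample_id))
  tg <- intersect(rownames(te), genes)
  if (length(tg))
    tissue_eff[tg, ] <- te[tg, ann$tissue, drop = FALSE]

  latent <- mu + sample_eff + tissue_eff +
    matrix(rnorm(length(genes) * n, 0, cfg$noise_sd), length(genes), n)
  latent <- sweep(latent, 2, batch[ann$series], `+`)
  dimnames(latent) <- list(genes, ann$sample_id)

  off_target <- mu[map$gene] +
    matrix(rnorm(nrow(map) * n, 0, cfg$probe_noise_sd), nrow(map), n)
  expr <- fid * latent[map$gene, , drop = FALSE] + (1 - fid) * off_target
  dimnames(expr) <- list(map$probe_id, ann$sample_id)

  implied <- implied_orr(latent, ann, cfg)

  truth <- list(latent = latent, fidelity = fid,
                entity_effects = eff, tissue_effects = te,
                batch_offsets = batch,
                planted_ratio = cfg$planted_ratio,
                implied_orr = implied, config = cfg)
  class(truth) <- "ground_truth"
  list(expr = expr, ann = ann, probe_map = map, truth = truth)
}

# linear ratio -> ORR link on entity medians of the planted ratio,
# truncated to [0, 100]; optional entity-level noise models trial-to-trial
# ORR variability
implied_orr <- function(latent, ann, cfg) {
  ents <- intersect(malignant_entities(), unique(ann$entity))
  if (!length(ents)) return(numeric(0))
  scores <- ratio_score(latent, cfg$planted_ratio)
  med <- vapply(ents, function(e)
    median(scores[ann$entity == e]), numeric(1))
  orr <- cfg$orr_link_intercept + cfg$orr_link_slope * med
  if (cfg$orr_noise_sd > 0)
    orr <- orr + rnorm(length(orr), 0, cfg$orr_noise_sd)
  setNames(pmin(100, pmax(0, orr)), ents)
}

#' Generate the matched cell-line GEP/RNA-seq panel
#'
#' Emulates the MM and MCL cell-line panel used to pick probes: a
#' gene-level matrix standing in for RNA-seq (the latent signal on a
#' log2(x+1)-like scale) and a probe-level microarray matrix over the same
#' lines, where each probe mixes latent signal and noise according to its
#' fidelity. Fidelities and the probe map are drawn exactly as in
#' [generate_dataset()] for the same config, so a probe's behaviour on the
#' cell lines is informative about its behaviour in the patient corpus.
#'
#' @param cfg a [synth_config()]; `n_celllines` must be >= 3.
#' @return List with `gep` (probe-by-line matrix), `rnaseq` (gene-by-line
#'   matrix), `probe_map` and `fidelity`.
#' @export
generate_cellline_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_celllines < 3)
    stop("configuration error: n_celllines must be >= 3")
  set.seed(cfg$seed)

  genes <- c(panel_genes(),
             sprintf("BG%04d", seq_len(cfg$n_genes - length(panel_genes()))))
  mu <- baseline_expression()[genes]
  names(mu) <- genes
  mu[is.na(mu)] <- runif(sum(is.na(mu)), 4, 10)
  counts <- draw_probe_counts(cfg, genes)
  map <- data.frame(
    probe_id = sprintf("ps%05d_at", seq_len(sum(counts))),
    gene = rep(names(counts), counts), stringsAsFactors = FALSE)
  fid <- draw_fidelities(cfg, map)

  nl <- cfg$n_celllines
  lines <- sprintf("CL%02d", seq_len(nl))
  line_entity <- rep_len(c("MM", "MCL"), nl)
  eff <- cfg$entity_effects
  shared <- intersect(rownames(eff), genes)
  ent_eff <- matrix(0, length(genes), nl, dimnames = list(genes, lines))
  for (e in unique(line_entity)) {
    if (e %in% colnames(eff))
      ent_eff[shared, line_entity == e] <- eff[shared, e]
  }
  latent <- mu + ent_eff +
    matrix(rnorm(length(genes) * nl, 0, cfg$cellline_sd), length(genes), nl) +
    matrix(rnorm(length(genes) * nl, 0, cfg$noise_sd), length(genes), nl)
  dimnames(latent) <- list(genes, lines)

  off_target <- mu[map$gene] +
    matrix(rnorm(nrow(map) * nl, 0, cfg$probe_noise_sd), nrow(map), nl)
  gep <- fid * latent[map$gene, , drop = FALSE] + (1 - fid) * off_target
  dimnames(gep) <- list(map$probe_id, lines)

  list(gep = gep, rnaseq = latent, probe_map = map, fidelity = fid)
}
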
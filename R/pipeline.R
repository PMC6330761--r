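#' Run the full analysis pipeline on a synthetic corpus
#'
#' Chains every stage on one generated dataset: simulate the corpus and
#' the matched cell-line panel, harmonize (outlier removal, quantile
#' normalization, anchor QC), select one probe per gene against the
#' cell-line RNA-seq, collapse to gene level, profile entities against
#' their normal counterparts, fit the PCA factor map, train the
#' random-forest entity classifier and score FL/MALT transformation, and
#' run the 49-candidate ratio search against the implied ORR.
#'
#' @param cfg a [synth_config()].
#' @param min_median_corr outlier threshold for [flag_outliers()].
#' @param min_r probe-selection threshold for [select_probes()].
#' @param n_trees forest size for [train_entity_classifier()].
#' @param orr ORR table used for the ratio search; default: the
#'   generator's implied ORR (use [default_orr_table()] for the published
#'   trial values).
#' @return List with the artefacts of every stage: `data`, `harmonized`,
#'   `selection`, `genes` (gene-level matrix), `de`, `pca`, `ellipses`,
#'   `classifier`, `transformation` (per evaluated entity), `ranking`,
#'   `scores`, `tissue_contrasts`.
#' @export
run_pipeline <- function(cfg, min_median_corr = 0.5, min_r = 0.5,
                         n_trees = 1000, orr = NULL) {
  data <- generate_dataset(cfg)
  cells <- generate_cellline_panel(cfg)

  harmonized <- harmonize(data$expr, data$ann,
                          min_median_corr = min_median_corr,
                          probe_map = data$probe_map)

  sel <- select_probes(cells$gep, cells$rnaseq, cells$probe_map,
                       min_r = min_r)
  genes <- collapse_to_genes(harmonized$expr, sel)
  ann <- harmonized$ann

  fam <- intersect(bcl2_family_genes(), rownames(genes))

  # entity vs normal counterpart, the Fig-1-style contrasts
  cmap <- cfg$counterpart_map
  contrasts <- list()
  for (e in intersect(names(cmap), unique(ann$entity))) {
    ctrl <- cmap[[e]]
    if (!ctrl %in% ann$entity) next
    contrasts[[paste0(e, "_vs_", ctrl)]] <-
      list(a = ann$sample_id[ann$entity == e],
           b = ann$sample_id[ann$entity == ctrl])
  }
  de <- compare_profiles(genes, ann, contrasts, genes = fam)

  model <- pca_fit(genes[fam, , drop = FALSE])
  ellipses <- group_ellipses(model, setNames(ann$entity, ann$sample_id))

  transformed <- ann$sample_id[ann$entity %in% c("FL", "MALT") &
                                 ann$status == "aggressive"]
  clf <- train_entity_classifier(genes, ann, genes = fam,
                                 n_trees = n_trees, seed = cfg$seed,
                                 exclude_samples = transformed)
  transformation <- list()
  for (e in intersect(c("FL", "MALT"), unique(ann$entity))) {
    ids <- ann$sample_id[ann$entity == e]
    if (length(unique(ann$status[ann$sample_id %in% ids])) < 2) next
    transformation[[e]] <- score_transformation(
      clf, genes[, ids, drop = FALSE], ann)
  }

  if (is.null(orr)) orr <- data$truth$implied_orr
  ranking <- rank_ratio_candidates(genes, ann, orr)
  scores <- ratio_score(genes, cfg$planted_ratio)
  mcl <- ann$sample_id[ann$entity == "MCL"]
  tissue_contrasts <- if (length(mcl) &&
                          length(unique(ann$tissue[ann$sample_id %in% mcl])) >= 2)
    compare_ratio_by_group(scores[mcl], ann, "tissue") else NULL

  list(data = data, harmonized = harmonized, selection = sel,
       genes = genes, de = de, pca = model, ellipses = ellipses,
       classifier = clf, transformation = transformation,
       ranking = ranking, scores = scores,
       tissue_contrasts = tissue_contrasts)
}
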
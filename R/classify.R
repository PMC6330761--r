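#' Train a random-forest entity classifier on BCL2-family expression
#'
#' An ensemble of 1,000 classification trees over the selected
#' BCL2-family genes (anchor and background genes are excluded from the
#' feature space): the question it answers is whether the 12-gene
#' apoptotic balance alone carries the identity of a B-cell malignancy.
#'
#' @param m gene-level matrix (genes x samples).
#' @param ann annotation data.frame with `sample_id` and `entity`.
#' @param genes feature genes (default: the BCL2-family panel genes
#'   present in `m`).
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed; fixes the forest so that repeated training
#'   gives identical predictions.
#' @param exclude_samples sample ids withheld from training (e.g. the
#'   transformed FL/MALT samples about to be scored).
#' @return An `entity_classifier` list: `forest`, `genes`, `n_trees`,
#'   `seed`, `oob_accuracy`, `training_samples`.
#' @export
train_entity_classifier <- function(m, ann,
                                    genes = intersect(bcl2_family_genes(),
                                                      rownames(m)),
                                    n_trees = 1000, seed = 1L,
                                    exclude_samples = character(0)) {
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  keep <- setdiff(colnames(m), exclude_samples)
  if (length(unique(ann$entity[ann$sample_id %in% keep])) < 2)
    stop("training set must contain at least 2 entities")
  x <- t(m[genes, keep, drop = FALSE])
  y <- factor(ann$entity[match(keep, ann$sample_id)])
  set.seed(seed)
  forest <- randomForest::randomForest(x, y, ntree = n_trees)
  out <- list(forest = forest, genes = genes, n_trees = n_trees,
              seed = seed,
              oob_accuracy = 1 - unname(forest$err.rate[n_trees, "OOB"]),
              training_samples = keep)
  class(out) <- "entity_classifier"
  out
}

#' Predict entities for new samples
#'
#' @param object an `entity_classifier`.
#' @param m gene-level matrix containing the classifier's feature genes.
#' @param ... unused.
#' @return Named character vector of predicted entities.
#' @export
predict.entity_classifier <- function(object, m, ...) {
  pr <- predict(object$forest, t(m[object$genes, , drop = FALSE]))
  setNames(as.character(pr), colnames(m))
}

#' Score histologic transformation by classifier re-labeling
#'
#' Applies a trained entity classifier to indolent and transformed
#' (aggressive) samples of an indolent lymphoma (FL or MALT) and asks
#' whether transformed samples are re-labeled as DLBCL. The association is
#' summarized by a 2x2 table of predicted-DLBCL against aggressive status,
#' its cross-product odds ratio, and the Fisher exact p-value. An
#' all-DLBCL (or no-DLBCL) prediction margin yields an infinite or NaN
#' odds ratio without error.
#'
#' @param clf an `entity_classifier`.
#' @param m gene-level matrix of the evaluated samples.
#' @param ann annotation with `sample_id` and `status` in
#'   {"indolent", "aggressive"}.
#' @param target predicted label counted as transformation (default
#'   "DLBCL").
#' @return A `classifier_report` list: `predictions`, `table` (2x2),
#'   `or`, `p`, `n_trees`, `seed`.
#' @export
score_transformation <- function(clf, m, ann, target = "DLBCL") {
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  if (!any(ann$status == "aggressive"))
    stop("no aggressive samples to evaluate")
  pred <- predict(clf, m)
  is_target <- pred == target
  is_aggr <- ann$status == "aggressive"
  tab <- matrix(c(sum(is_target & is_aggr), sum(is_target & !is_aggr),
                  sum(!is_target & is_aggr), sum(!is_target & !is_aggr)),
                2, 2, byrow = TRUE,
                dimnames = list(predicted = c(target, paste0("not_", target)),
                                status = c("aggressive", "indolent")))
  ft <- fisher_exact_test(tab)
  out <- list(predictions = pred, table = tab, or = ft$or, p = ft$p,
              n_trees = clf$n_trees, seed = clf$seed)
  class(out) <- "classifier_report"
  out
}
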
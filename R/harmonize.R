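#' Quantile-normalize a pooled expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the across-sample mean of order statistics, the standard
#' cross-study harmonization step for pooled array series. Ties within a
#' column receive the mean of the candidate quantile values (mean-of-ranks
#' convention). The computation is delegated to
#' \code{limma::normalizeQuantiles}; row and column labels are preserved.
#'
#' @param m numeric matrix, features x samples, all values finite.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2)
    stop("quantile normalization needs at least 2 samples")
  if (!all(is.finite(m)))
    stop("non-finite values in expression matrix")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Flag outlier samples by median pairwise correlation
#'
#' A sample is flagged when its median Spearman correlation with every
#' other sample falls below `min_median_corr`. Rank correlation makes the
#' rule scale-free, so it can run before or after normalization.
#'
#' @param m numeric matrix, features x samples (>= 3 samples).
#' @param min_median_corr threshold in \[-1, 1\]; default 0.5.
#' @return Character vector of flagged sample ids (possibly empty), with
#'   the criterion values as the `criterion` attribute.
#' @export
flag_outliers <- function(m, min_median_corr = 0.5) {
  m <- as.matrix(m)
  if (ncol(m) < 3)
    stop("outlier flagging needs at least 3 samples")
  if (!all(is.finite(m)))
    stop("non-finite values in expression matrix")
  rc <- cor(apply(m, 2, rank))
  diag(rc) <- NA
  med <- apply(rc, 2, median, na.rm = TRUE)
  flagged <- colnames(m)[med < min_median_corr]
  structure(flagged, criterion = med[med < min_median_corr])
}

#' Anchoring-gene quality control on a harmonized matrix
#'
#' After pooling heterogeneous series, marker ("anchoring") genes with
#' well-established entity specificity (e.g. CCND1 and SOX11 in MCL, SDC1
#' and CD38 in plasma-cell disease) must stand out in their entity
#' regardless of source series. Each rule `(gene, entity)` is checked by a
#' one-sided Wilcoxon rank-sum test of the gene's expression in the target
#' entity versus all other samples; the rule passes when p < `alpha` and
#' the median difference is positive.
#'
#' @param m gene-level expression matrix (genes x samples).
#' @param ann sample annotation data.frame with columns `sample_id`,
#'   `entity`; rows aligned to or matched against `colnames(m)`.
#' @param rules data.frame with columns `gene` and `entity`.
#' @param alpha significance level (default 0.05).
#' @return A `qc_report` list: `rules` (data.frame gene, entity, p,
#'   median_diff, pass, note) and `pass` (TRUE when every testable rule
#'   passed).
#' @export
anchor_qc <- function(m, ann, rules, alpha = 0.05) {
  m <- as.matrix(m)
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  res <- lapply(seq_len(nrow(rules)), function(i) {
    g <- rules$gene[i]; e <- rules$entity[i]
    if (!g %in% rownames(m))
      return(data.frame(gene = g, entity = e, p = NA_real_,
                        median_diff = NA_real_, pass = FALSE,
                        note = "gene absent from matrix"))
    inn <- ann$entity == e
    if (!any(inn) || all(inn))
      return(data.frame(gene = g, entity = e, p = NA_real_,
                        median_diff = NA_real_, pass = FALSE,
                        note = "entity absent or universal"))
    x <- m[g, inn]; y <- m[g, !inn]
    p <- suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value)
    md <- median(x) - median(y)
    data.frame(gene = g, entity = e, p = p, median_diff = md,
               pass = p < alpha && md > 0, note = "",
               stringsAsFactors = FALSE)
  })
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(), entity = character(), p = numeric(),
               median_diff = numeric(), pass = logical(), note = character())
  # rules that could not be tested (missing gene/entity) are reported as
  # error entries but do not sink the global verdict
  testable <- res$note == ""
  out <- list(rules = res, pass = all(res$pass[testable]))
  class(out) <- "qc_report"
  out
}

#' Default anchoring-gene QC rules
#' @return data.frame with columns `gene`, `entity`.
#' @export
default_anchor_rules <- function() {
  data.frame(
    gene = c("CCND1", "SOX11", "SDC1", "CD38", "CD27",
             "MKI67", "BCL6", "MME", "CD200", "ITGAE"),
    entity = c("MCL", "MCL", "MM", "MM", "CLL",
               "BL", "DLBCL", "FL", "CLL", "HCL"),
    stringsAsFactors = FALSE)
}

#' Harmonize a pooled probe-level corpus
#'
#' The pooled-normalization stage in one call: flag and drop outlier
#' samples, quantile-normalize the remaining columns, and (when `rules`
#' are supplied together with a probe map) run anchoring-gene QC on the
#' best-probe summary of the anchor genes.
#'
#' @param expr probe-level matrix (probes x samples).
#' @param ann sample annotation data.frame.
#' @param min_median_corr outlier threshold, see [flag_outliers()].
#' @param rules anchor QC rules or NULL to skip.
#' @param probe_map data.frame (probe_id, gene) needed for anchor QC.
#' @return List with `expr` (normalized, outliers removed), `ann`
#'   (filtered), `outliers` and `qc` (a `qc_report` or NULL).
#' @export
harmonize <- function(expr, ann, min_median_corr = 0.5,
                      rules = default_anchor_rules(), probe_map = NULL) {
  out <- flag_outliers(expr, min_median_corr)
  keep <- setdiff(colnames(expr), out)
  expr <- quantile_normalize(expr[, keep, drop = FALSE])
  ann <- ann[match(keep, ann$sample_id), , drop = FALSE]
  qc <- NULL
  if (!is.null(rules) && !is.null(probe_map)) {
    # summarise each anchor gene by its most corpus-correlated probe so QC
    # does not depend on the later RNA-seq-guided selection
    anchors <- intersect(unique(rules$gene), probe_map$gene)
    rowsel <- vapply(anchors, function(g) {
      probes <- probe_map$probe_id[probe_map$gene == g]
      probes <- intersect(probes, rownames(expr))
      if (!length(probes)) return(NA_character_)
      if (length(probes) == 1) return(probes)
      sub <- expr[probes, , drop = FALSE]
      med <- apply(sub, 2, median)
      probes[which.max(apply(sub, 1, cor, y = med))]
    }, character(1))
    rowsel <- rowsel[!is.na(rowsel)]
    gm <- expr[rowsel, , drop = FALSE]
    rownames(gm) <- names(rowsel)
    qc <- anchor_qc(gm, ann, rules)
  }
  list(expr = expr, ann = ann, outliers = out, qc = qc)
}
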
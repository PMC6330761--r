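#' Select one probe per gene by concordance with matched RNA-seq
#'
#' Microarray genes are often covered by several probe sets of unequal
#' quality. For each gene, every probe's expression across a shared panel
#' of cell lines is correlated with the gene's RNA-seq values; the probe
#' with the largest correlation is retained. A gene is excluded when its
#' best correlation falls below `min_r`, when the one-sided test of that
#' correlation is not significant at `alpha`, when the gene is missing
#' from the RNA-seq matrix, or when it is on the a-priori exclusion list
#' (e.g. BBC3, whose probes are confounded by microRNA
#' cross-hybridization).
#'
#' @param gep probe-level matrix (probes x cell lines).
#' @param rnaseq gene-level matrix (genes x cell lines), the concordance
#'   reference.
#' @param map data.frame (probe_id, gene) covering the rows of `gep`.
#' @param min_r minimum acceptable correlation of the best probe
#'   (default 0.5).
#' @param alpha level of the one-sided correlation test (default 0.05).
#' @param method "pearson" (default) or "spearman".
#' @param exclude genes excluded a priori regardless of correlation.
#' @return A `probe_selection` data.frame with columns `gene`, `probe`,
#'   `r`, `p`, `status` ("selected"/"excluded") and `reason`.
#' @export
select_probes <- function(gep, rnaseq, map, min_r = 0.5, alpha = 0.05,
                          method = c("pearson", "spearman"),
                          exclude = "BBC3") {
  method <- match.arg(method)
  shared <- intersect(colnames(gep), colnames(rnaseq))
  if (length(shared) < 3)
    stop("need at least 3 shared cell lines between GEP and RNA-seq")
  gep <- gep[, shared, drop = FALSE]
  rnaseq <- rnaseq[, shared, drop = FALSE]
  missing <- setdiff(rownames(gep), map$probe_id)
  if (length(missing))
    stop("probe map does not cover all GEP rows (e.g. ", missing[1], ")")

  genes <- sort(unique(map$gene[map$probe_id %in% rownames(gep)]))
  rows <- lapply(genes, function(g) {
    if (g %in% exclude)
      return(data.frame(gene = g, probe = NA_character_, r = NA_real_,
                        p = NA_real_, status = "excluded",
                        reason = "a priori exclusion"))
    if (!g %in% rownames(rnaseq))
      return(data.frame(gene = g, probe = NA_character_, r = NA_real_,
                        p = NA_real_, status = "excluded",
                        reason = "absent from RNA-seq"))
    probes <- sort(map$probe_id[map$gene == g])
    probes <- probes[probes %in% rownames(gep)]
    ref <- rnaseq[g, ]
    rs <- vapply(probes, function(p)
      suppressWarnings(cor(gep[p, ], ref, method = method)), numeric(1))
    rs[is.na(rs)] <- -Inf
    best <- probes[which.max(rs)]     # ties: first in lexicographic order
    r <- rs[best]
    pv <- if (is.finite(r))
      suppressWarnings(cor.test(gep[best, ], ref, method = method,
                                alternative = "greater", exact = FALSE)$p.value)
    else NA_real_
    if (!is.finite(r) || r < min_r || is.na(pv) || pv >= alpha)
      data.frame(gene = g, probe = best,
                 r = ifelse(is.finite(r), r, NA_real_), p = pv,
                 status = "excluded", reason = "no RNA-seq concordance")
    else
      data.frame(gene = g, probe = best, r = r, p = pv,
                 status = "selected", reason = "")
  })
  sel <- do.call(rbind, rows)
  rownames(sel) <- NULL
  class(sel) <- c("probe_selection", class(sel))
  sel
}

#' Collapse a probe-level matrix to gene level using a probe selection
#'
#' Each selected gene's row is copied verbatim from its chosen probe row;
#' excluded genes are absent from the output. No averaging is performed —
#' the analysis deliberately uses one validated probe per gene.
#'
#' @param gep probe-level matrix (probes x samples).
#' @param sel a `probe_selection` from [select_probes()].
#' @return Gene-level matrix (selected genes x samples).
#' @export
collapse_to_genes <- function(gep, sel) {
  keep <- sel[sel$status == "selected", , drop = FALSE]
  missing <- setdiff(keep$probe, rownames(gep))
  if (length(missing))
    stop("selection references probes absent from the matrix: ",
         paste(head(missing, 3), collapse = ", "))
  out <- gep[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  out
}
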
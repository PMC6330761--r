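#' Define a candidate sensitivity ratio
#'
#' A venetoclax-sensitivity ratio divides the summed expression of
#' efficacy genes by the summed expression of resistance genes. The
#' flagship ratio is (BCL2 + BCL2L11 + BAX) / BCL2L1. Members must come
#' from their respective pools and both sets must be non-empty.
#'
#' @param numerator non-empty subset of the efficacy pool.
#' @param denominator non-empty subset of the resistance pool.
#' @param efficacy_pool,resistance_pool allowed gene pools.
#' @return A `ratio_spec` list with elements `numerator`, `denominator`.
#' @export
ratio_spec <- function(numerator, denominator,
                       efficacy_pool = efficacy_genes(),
                       resistance_pool = resistance_genes()) {
  if (!length(numerator) || !length(denominator))
    stop("numerator and denominator must be non-empty")
  if (!all(numerator %in% efficacy_pool))
    stop("numerator genes must come from the efficacy pool")
  if (!all(denominator %in% resistance_pool))
    stop("denominator genes must come from the resistance pool")
  out <- list(numerator = sort(unique(numerator)),
              denominator = sort(unique(denominator)))
  class(out) <- "ratio_spec"
  out
}

#' @export
format.ratio_spec <- function(x, ...) {
  paste0("(", paste(x$numerator, collapse = "+"), ")/(",
         paste(x$denominator, collapse = "+"), ")")
}

#' @export
print.ratio_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Per-sample sensitivity ratio scores
#'
#' score(sample) = sum of numerator-gene values / sum of denominator-gene
#' values, computed directly on the matrix's normalized log2 scale (the
#' scale the ratio is defined on); `linear = TRUE` un-logs the values
#' (2^x) before summing.
#'
#' @param m gene-level matrix (genes x samples).
#' @param spec a [ratio_spec()].
#' @param linear compute on linear intensities instead of log2.
#' @return Named numeric vector of per-sample scores.
#' @export
ratio_score <- function(m, spec, linear = FALSE) {
  genes <- c(spec$numerator, spec$denominator)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  v <- if (linear) 2^m else m
  num <- colSums(v[spec$numerator, , drop = FALSE])
  den <- colSums(v[spec$denominator, , drop = FALSE])
  bad <- den <= 0
  if (any(bad))
    stop("non-positive denominator sum for sample(s): ",
         paste(head(colnames(m)[bad], 3), collapse = ", "))
  num / den
}

#' Enumerate all candidate efficacy/resistance ratios
#'
#' Every pairing of a non-empty subset of the efficacy pool with a
#' non-empty subset of the resistance pool, in a deterministic order
#' (numerators varying fastest, subsets ordered by size then
#' lexicographically). With the default 3 + 3 pools this yields
#' (2^3 - 1)^2 = 49 candidates.
#'
#' @param efficacy_pool,resistance_pool non-empty gene pools.
#' @return List of [ratio_spec()] objects.
#' @export
enumerate_ratio_specs <- function(efficacy_pool = efficacy_genes(),
                                  resistance_pool = resistance_genes()) {
  if (!length(efficacy_pool) || !length(resistance_pool))
    stop("gene pools must be non-empty")
  subsets <- function(pool) {
    idx <- unlist(lapply(seq_along(pool), function(k)
      utils::combn(sort(pool), k, simplify = FALSE)), recursive = FALSE)
    idx
  }
  out <- list()
  for (den in subsets(resistance_pool))
    for (num in subsets(efficacy_pool))
      out[[length(out) + 1L]] <- ratio_spec(num, den, efficacy_pool,
                                            resistance_pool)
  out
}

#' Rank candidate ratios by correlation with clinical response
#'
#' For each candidate ratio, per-sample scores are computed, summarized
#' (either each sample paired with its entity's ORR, or one median score
#' per entity), correlated with the ORR values, and the candidates are
#' ranked by decreasing correlation. Entities absent from the ORR table
#' are excluded from the correlation but still scored. Ties in r keep the
#' enumeration order.
#'
#' @param m gene-level matrix (genes x samples).
#' @param ann annotation with `sample_id` and `entity`.
#' @param orr named numeric vector, entity -> ORR percent.
#' @param candidates list of [ratio_spec()] (default: the 49-candidate
#'   enumeration).
#' @param summary "per-sample" (default; every sample carries its
#'   entity's ORR) or "median-per-entity".
#' @param method "pearson" (default) or "spearman".
#' @return A `ratio_ranking` data.frame: rank, numerator, denominator, r,
#'   p, n; sorted by decreasing r, with the spec list as the `specs`
#'   attribute (in ranked order).
#' @export
rank_ratio_candidates <- function(m, ann, orr,
                                  candidates = enumerate_ratio_specs(),
                                  summary = c("per-sample",
                                              "median-per-entity"),
                                  method = c("pearson", "spearman")) {
  summary <- match.arg(summary)
  method <- match.arg(method)
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  ents <- intersect(unique(ann$entity), names(orr)[!is.na(orr)])
  if (length(ents) < 3)
    stop("need at least 3 entities with ORR values")
  use <- ann$entity %in% ents
  rows <- lapply(candidates, function(spec) {
    sc <- ratio_score(m, spec)
    if (summary == "per-sample") {
      x <- sc[use]
      y <- orr[ann$entity[use]]
    } else {
      x <- vapply(ents, function(e)
        median(sc[ann$entity == e]), numeric(1))
      y <- orr[ents]
    }
    if (length(x) < 3) stop("fewer than 3 correlation points")
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    data.frame(numerator = paste(spec$numerator, collapse = "+"),
               denominator = paste(spec$denominator, collapse = "+"),
               r = unname(ct$estimate), p = ct$p.value, n = length(x))
  })
  res <- do.call(rbind, rows)
  ord <- order(-res$r)                # stable: ties keep enumeration order
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res <- res[, c("rank", "numerator", "denominator", "r", "p", "n")]
  attr(res, "specs") <- candidates[ord]
  class(res) <- c("ratio_ranking", class(res))
  res
}

#' Locate a spec inside a ranking
#'
#' @param ranking a `ratio_ranking`.
#' @param spec a [ratio_spec()].
#' @return Integer rank (1 = best correlation).
#' @export
spec_rank <- function(ranking, spec) {
  hit <- ranking$numerator == paste(spec$numerator, collapse = "+") &
    ranking$denominator == paste(spec$denominator, collapse = "+")
  if (!any(hit)) stop("spec not among ranked candidates")
  ranking$rank[hit]
}

#' Compare ratio scores between sample groups
#'
#' Pairwise Wilcoxon rank-sum comparisons of per-sample ratio scores
#' between the levels of a grouping (tissue, subtype or status), with the
#' figure star convention — the microenvironment and subgroup contrasts of
#' the ratio analysis.
#'
#' @param scores named per-sample scores from [ratio_score()].
#' @param ann annotation with `sample_id` and the grouping column.
#' @param grouping column name in `ann` ("tissue", "subtype", "status")
#'   or a vector aligned with `names(scores)`.
#' @return data.frame: group_a, group_b, median_a, median_b, n_a, n_b, U,
#'   p, stars.
#' @export
compare_ratio_by_group <- function(scores, ann, grouping = "tissue") {
  g <- if (length(grouping) == 1 && grouping %in% names(ann))
    ann[[grouping]][match(names(scores), ann$sample_id)]
  else as.character(grouping)
  levels <- unique(g[!is.na(g)])
  if (length(levels) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- scores[g == pr[1] & !is.na(g)]
    b <- scores[g == pr[2] & !is.na(g)]
    ts <- rank_sum_test(a, b)
    data.frame(group_a = pr[1], group_b = pr[2],
               median_a = median(a), median_b = median(b),
               n_a = length(a), n_b = length(b),
               U = ts$U, p = ts$p, stars = p_stars(ts$p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
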
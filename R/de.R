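#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-group nonparametric comparison used throughout the differential
#' profiling. The exact null distribution of the Mann-Whitney U statistic
#' is used when the pooled size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return List with `U` (Mann-Whitney U for `a` relative to `b`) and `p`
#'   (two-sided).
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- ht$p.value
  if (is.na(p)) p <- 1    # fully tied input: no evidence against the null
  list(U = unname(ht$statistic), p = min(1, p))
}

#' Kruskal-Wallis test for three or more groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom. A fully degenerate input (all values identical) returns
#' H = 0, p = 1 rather than an error.
#'
#' @param groups list of non-empty numeric vectors (>= 2 groups; the
#'   analysis convention uses it for >= 3).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis_test <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(x, g)
  list(H = unname(ht$statistic), p = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' The odds ratio is the sample cross-product (a d)/(b c) — infinite when
#' b c = 0 with a d > 0, NaN when both diagonals vanish — and the
#' two-sided p-value sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (the probability-mass definition).
#'
#' @param t 2x2 matrix of non-negative integer counts, not all zero;
#'   layout `rbind(c(a, b), c(c, d))`.
#' @return List with `or` and `p`.
#' @export
fisher_exact_test <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("table must be 2x2")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (sum(t) == 0) stop("all-zero table")
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  p <- fisher.test(t)$p.value
  list(or = unname(or), p = min(1, p))
}

#' Map a p-value to the figure star convention
#'
#' `ns` for p >= 0.05, then `*` < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

resolve_selector <- function(sel, ann) {
  if (is.function(sel)) return(ann$sample_id[sel(ann)])
  if (is.logical(sel)) return(ann$sample_id[sel])
  as.character(sel)
}

#' Per-gene nonparametric contrasts between sample groups
#'
#' For each contrast (two groups of samples) and each gene, runs
#' [rank_sum_test()] on the expression values and annotates the result
#' with group medians and the star code. Raw p-values are reported by
#' default, matching the figure convention of a flat alpha = 0.05;
#' Benjamini-Hochberg adjustment is available behind `adjust`.
#'
#' @param m gene-level matrix (genes x samples).
#' @param ann sample annotation data.frame with `sample_id`.
#' @param contrasts named list; each element a list with elements `a` and
#'   `b`, each a character vector of sample ids, a logical over `ann`
#'   rows, or a predicate `function(ann)`.
#' @param genes genes to test (default all rows of `m`).
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"`, adjustment is
#'   across genes within each contrast.
#' @return data.frame: contrast, gene, median_a, median_b, n_a, n_b, U, p,
#'   stars, note.
#' @export
compare_profiles <- function(m, ann, contrasts, genes = rownames(m),
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(names(contrasts)))
    names(contrasts) <- paste0("contrast", seq_along(contrasts))
  out <- lapply(names(contrasts), function(cn) {
    ct <- contrasts[[cn]]
    a <- intersect(resolve_selector(ct$a, ann), colnames(m))
    b <- intersect(resolve_selector(ct$b, ann), colnames(m))
    if (!length(a) || !length(b))
      return(data.frame(contrast = cn, gene = NA_character_,
                        median_a = NA_real_, median_b = NA_real_,
                        n_a = length(a), n_b = length(b), U = NA_real_,
                        p = NA_real_, stars = NA_character_,
                        note = "empty selector"))
    rows <- lapply(genes, function(g) {
      ts <- rank_sum_test(m[g, a], m[g, b])
      data.frame(contrast = cn, gene = g,
                 median_a = median(m[g, a]), median_b = median(m[g, b]),
                 n_a = length(a), n_b = length(b),
                 U = ts$U, p = ts$p, stars = NA_character_, note = "")
    })
    res <- do.call(rbind, rows)
    if (adjust == "BH") res$p <- p.adjust(res$p, "BH")
    res$stars <- p_stars(res$p)
    res
  })
  do.call(rbind, out)
}

#' @importFrom stats p.adjust
NULL

#' Group-median expression profiles
#'
#' The matrix behind the heat-map views: entry (gene, group) is the median
#' expression of the gene over the group's samples, optionally z-scored
#' within each gene row across groups.
#'
#' @param m gene-level matrix (genes x samples).
#' @param grouping named character vector or factor, sample -> group (or a
#'   vector aligned with `colnames(m)`).
#' @param z_score scale each gene row to mean 0 / sd 1 across groups.
#' @return genes x groups numeric matrix.
#' @export
median_profile <- function(m, grouping, z_score = FALSE) {
  if (!is.null(names(grouping))) grouping <- grouping[colnames(m)]
  grouping <- as.character(grouping)
  if (anyNA(grouping)) stop("grouping missing for some samples")
  groups <- unique(grouping)
  prof <- vapply(groups, function(g)
    apply(m[, grouping == g, drop = FALSE], 1, median), numeric(nrow(m)))
  prof <- matrix(prof, nrow = nrow(m), dimnames = list(rownames(m), groups))
  if (z_score) {
    mu <- rowMeans(prof)
    s <- apply(prof, 1, sd)
    prof <- (prof - mu) / ifelse(s == 0, 1, s)
  }
  prof
}
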
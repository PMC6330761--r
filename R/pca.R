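#' Principal component analysis of an expression matrix
#'
#' Correlation PCA (centered, unit-scaled variables) by default, the
#' convention of the factor-map methodology: samples are observations,
#' genes are variables. Components are ordered by decreasing variance and
#' the sign of each component is fixed so that its largest-magnitude
#' loading is positive, making the output deterministic.
#'
#' @param m gene-level matrix (genes x samples); >= 2 genes, >= 2 samples.
#' @param center,scale logical; defaults TRUE (correlation PCA).
#' @return A `pca_model` list: `scores` (samples x components), `loadings`
#'   (genes x components), `var_explained` (fractions summing to 1),
#'   `sdev`, `center`, `scale`.
#' @export
pca_fit <- function(m, center = TRUE, scale = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("PCA needs at least 2 genes and 2 samples")
  x <- t(m)
  if (scale) {
    v <- apply(x, 2, sd)
    if (any(v == 0))
      stop("zero-variance gene(s) with scale = TRUE: ",
           paste(head(colnames(x)[v == 0], 3), collapse = ", "))
  }
  fit <- prcomp(x, center = center, scale. = scale)
  flip <- apply(fit$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  out <- list(scores = scores, loadings = loadings,
              var_explained = fit$sdev^2 / sum(fit$sdev^2),
              sdev = fit$sdev,
              center = if (isTRUE(center)) fit$center else rep(0, ncol(x)),
              scale = if (isTRUE(scale)) fit$scale else rep(1, ncol(x)))
  class(out) <- "pca_model"
  out
}

#' Confidence ellipse of a group barycenter in score space
#'
#' The ellipse drawn around a group's mean position on the factor map is a
#' confidence region of the MEAN (not a data ellipse): with sample
#' covariance S of the group's n 2-D scores, the boundary is the set
#' \deqn{(x - \bar x)^T S^{-1} (x - \bar x) = \frac{2 (n - 1)}{n (n - 2)}
#'   F_{2, n-2}(level).}
#' Semi-axes and orientation come from the eigen-decomposition of S.
#'
#' @param scores n x 2 matrix of one group's scores (n >= 3).
#' @param level confidence level in (0, 1); default 0.95.
#' @param label optional group label stored in the result.
#' @return An `ellipse_spec` list: `label`, `center` (length 2),
#'   `semi_axes` (major, minor), `angle` (radians, orientation of the
#'   major axis), `level`, `n`.
#' @export
confidence_ellipse <- function(scores, level = 0.95, label = NA_character_) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  n <- nrow(scores)
  if (n < 3) stop("need at least 3 points for a confidence ellipse")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  s <- cov(scores)
  if (abs(det(s)) < 1e-12) stop("singular score covariance")
  r2 <- (2 * (n - 1)) / (n * (n - 2)) * qf(level, 2, n - 2)
  es <- eigen(s, symmetric = TRUE)
  out <- list(label = label, center = colMeans(scores),
              semi_axes = sqrt(pmax(es$values, 0) * r2),
              angle = atan2(es$vectors[2, 1], es$vectors[1, 1]),
              level = level, n = n)
  class(out) <- "ellipse_spec"
  out
}

#' Test whether a point lies inside a confidence ellipse
#'
#' @param es an `ellipse_spec` from [confidence_ellipse()].
#' @param point numeric length-2 coordinate.
#' @return TRUE when the point is inside or on the boundary.
#' @export
ellipse_contains <- function(es, point) {
  d <- as.numeric(point) - es$center
  rot <- matrix(c(cos(-es$angle), -sin(-es$angle),
                  sin(-es$angle), cos(-es$angle)), 2, 2, byrow = TRUE)
  u <- rot %*% d
  sum((u / es$semi_axes)^2) <= 1
}

#' Barycenter ellipses for every group on the first factor plane
#'
#' @param model a `pca_model`.
#' @param grouping named vector sample -> group (or aligned with the score
#'   rows).
#' @param level confidence level; default 0.95.
#' @param dims which two components to use (default 1:2).
#' @return Named list of `ellipse_spec`, one per group with >= 3 samples.
#' @export
group_ellipses <- function(model, grouping, level = 0.95, dims = 1:2) {
  sc <- model$scores[, dims, drop = FALSE]
  if (!is.null(names(grouping))) grouping <- grouping[rownames(sc)]
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  out <- list()
  for (g in groups) {
    pts <- sc[grouping == g, , drop = FALSE]
    if (nrow(pts) >= 3)
      out[[g]] <- confidence_ellipse(pts, level = level, label = g)
  }
  out
}

#' Variable correlation circle coordinates
#'
#' Each variable (gene) is placed at its Pearson correlations with the
#' first two component score vectors; all points fall inside the unit
#' disk, and variables perfectly represented by the plane sit on the
#' circle.
#'
#' @param model a `pca_model` fitted on `m`.
#' @param m the gene-level matrix the model was fitted on.
#' @param dims which two components (default 1:2).
#' @return data.frame: gene, r1, r2.
#' @export
variable_correlation_circle <- function(model, m, dims = 1:2) {
  m <- as.matrix(m)
  v <- apply(m, 1, sd)
  if (any(v == 0))
    stop("zero-variance variable(s): ",
         paste(head(rownames(m)[v == 0], 3), collapse = ", "))
  sc <- model$scores[colnames(m), dims, drop = FALSE]
  # a component with (numerically) zero variance carries no direction:
  # correlations with its round-off scores are meaningless, report 0
  ok <- model$sdev[dims] > 1e-8 * model$sdev[1]
  safe_cor <- function(x, s, keep) if (keep) cor(x, s) else 0
  data.frame(gene = rownames(m),
             r1 = apply(m, 1, safe_cor, s = sc[, 1], keep = ok[1]),
             r2 = apply(m, 1, safe_cor, s = sc[, 2], keep = ok[2]),
             stringsAsFactors = FALSE)
}
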
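test_that("pca_fit agrees with a direct eigendecomposition oracle", {
  set.seed(61)
  for (i in 1:10) {
    m <- matrix(rnorm(24), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    fit <- pca_fit(m)
    or <- oracle_pca(m)
    k <- length(fit$var_explained)
    expect_equal(fit$sdev^2, or$values[1:k], tolerance = 1e-8)
    for (j in 1:k) {
      if (or$values[j] < 1e-10) next
      expect_equal(abs(fit$loadings[, j]), abs(or$vectors[, j]),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(abs(fit$scores[, j]), abs(or$scores[, j]),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("explained variance fractions sum to 1 and scores are uncorrelated", {
  set.seed(62)
  m <- matrix(rnorm(200), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:25)))
  fit <- pca_fit(m)
  expect_equal(sum(fit$var_explained), 1, tolerance = 1e-9)
  cv <- cov(fit$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(fit$loadings))) {
    l <- fit$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
})

test_that("degenerate spectra behave as expected", {
  # rank-1: every sample is a multiple of one profile
  profile <- c(1, 2, 3, 4)
  m <- outer(profile, c(1, 2, 3, 5, 8))
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:5))
  fit <- pca_fit(m, center = TRUE, scale = FALSE)
  expect_equal(fit$var_explained[1], 1, tolerance = 1e-12)
  # two perfectly correlated variables under scaling
  x <- rnorm(10)
  m2 <- rbind(a = x, b = 2 * x + 1)
  colnames(m2) <- paste0("s", 1:10)
  fit2 <- pca_fit(m2)
  expect_equal(fit2$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(fit2$loadings[1, 1]), abs(fit2$loadings[2, 1]),
               tolerance = 1e-12)
  # zero-variance gene with scaling is an error naming the gene
  m3 <- rbind(flat = rep(1, 5), g = rnorm(5))
  colnames(m3) <- paste0("s", 1:5)
  expect_error(pca_fit(m3), "flat")
})

test_that("reconstruction from scores and loadings recovers the data", {
  set.seed(63)
  m <- matrix(rnorm(15), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  fit <- pca_fit(m)
  x <- fit$scores %*% t(fit$loadings)
  x <- sweep(x, 2, fit$scale, `*`)
  x <- sweep(x, 2, fit$center, `+`)
  expect_equal(t(x), m, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("confidence ellipse geometry follows the Hotelling form", {
  # circular covariance: points on the axes
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  es <- confidence_ellipse(pts, level = 0.95)
  expect_equal(es$semi_axes[1], es$semi_axes[2], tolerance = 1e-9)
  expect_equal(es$center, c(0, 0), ignore_attr = TRUE)
  # shrinking level shrinks the ellipse to the barycenter
  tiny <- confidence_ellipse(pts, level = 1e-8)
  expect_true(all(tiny$semi_axes < 1e-3 * es$semi_axes[1] + 1e-6))
  expect_true(ellipse_contains(es, c(0, 0)))
  expect_false(ellipse_contains(es, c(50, 50)))
  expect_error(confidence_ellipse(pts[1:2, ]), "3 points")
  degen <- cbind(1:5, 2 * (1:5))
  expect_error(confidence_ellipse(degen), "singular")
  expect_error(confidence_ellipse(pts, level = 1.2), "level")
})

test_that("quadrupling the group size roughly halves the ellipse axes", {
  set.seed(64)
  ratios <- replicate(40, {
    small <- cbind(rnorm(30), rnorm(30, sd = 2))
    big <- cbind(rnorm(120), rnorm(120, sd = 2))
    a1 <- confidence_ellipse(small)$semi_axes
    a2 <- confidence_ellipse(big)$semi_axes
    mean(a2 / a1)
  })
  expect_equal(mean(ratios), 0.5, tolerance = 0.15)
})

test_that("variable correlation circle lies in the unit disk", {
  set.seed(65)
  m <- matrix(rnorm(60), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  fit <- pca_fit(m)
  cc <- variable_correlation_circle(fit, m)
  expect_true(all(cc$r1^2 + cc$r2^2 <= 1 + 1e-9))
  # rank-1 data: every variable fully represented by PC1
  m1 <- outer(c(1, 2, 3), c(1, 3, 2, 5, 4))
  dimnames(m1) <- list(paste0("g", 1:3), paste0("s", 1:5))
  fit1 <- pca_fit(m1, scale = FALSE)
  cc1 <- variable_correlation_circle(fit1, m1)
  expect_equal(cc1$r1^2 + cc1$r2^2, rep(1, 3), tolerance = 1e-9)
  # hand-computed Pearson: cor([1,2,3], [1,2,4]) = 9 / sqrt(84)
  expect_equal(cor(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84), tolerance = 1e-12)
  expect_equal(round(cor(c(1, 2, 3), c(1, 2, 4)), 3), 0.982)
  mz <- rbind(flat = rep(2, 10), m[1:2, ])
  expect_error(variable_correlation_circle(fit, mz), "flat")
})

test_that("group ellipses cover barycenters of separated entities", {
  d <- generate_dataset(small_config(seed = 66))
  m <- d$truth$latent[bcl2_family_genes(), ]
  fit <- pca_fit(m)
  ells <- group_ellipses(fit, setNames(d$ann$entity, d$ann$sample_id))
  expect_true(all(vapply(ells, function(e) e$n >= 3, logical(1))))
  for (e in ells)
    expect_true(ellipse_contains(e, e$center))
})
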
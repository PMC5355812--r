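random_matrix <- function(n, k, seed) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("v", seq_len(k))))
}

test_that("PCA eigenvalues sum to the number of standardized variables and match an eigen oracle", {
  for (seed in 1:5) {
    m <- random_matrix(10, 4, seed)
    pca <- pca_scaled(m)
    expect_equal(sum(pca$eigenvalues), 4, tolerance = 1e-9)
    expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-12)
    oracle <- sort(eigen(cor(m), symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(pca$eigenvalues, oracle, tolerance = 1e-9)
  }
})

test_that("two perfectly correlated variables load everything on axis 1", {
  x <- seq(1, 10)
  m <- cbind(a = x, b = 3 * x + 2, c = -x)
  pca <- pca_scaled(m)
  expect_equal(pca$variance_fractions[1], 1, tolerance = 1e-12)
})

test_that("PCA scores reconstruct the standardized data through the loadings", {
  m <- random_matrix(12, 4, 9)
  pca <- pca_scaled(m)
  recon <- pca$scores %*% t(pca$loadings)
  std <- scale(m)
  expect_lt(max(abs(recon - std)), 1e-9)
  # loadings orthonormal per axis
  expect_equal(crossprod(pca$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA is invariant to variable order and affine rescaling, with a deterministic sign", {
  m <- random_matrix(15, 3, 31)
  p1 <- pca_scaled(m)
  p2 <- pca_scaled(m[, c(3, 1, 2)])
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-9)
  m3 <- m
  m3[, 2] <- 100 * m3[, 2] - 7
  p3 <- pca_scaled(m3)
  expect_equal(p1$eigenvalues, p3$eigenvalues, tolerance = 1e-9)
  expect_equal(p1$loadings, p3$loadings, tolerance = 1e-9)
  for (j in 1:3) {
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  }
  expect_error(pca_scaled(m[1:2, ]), "3 rows")
  expect_warning(pca_scaled(cbind(m, const = 1)), "constant")
})

test_that("identical rows carry no gradient: length 0 and a linear verdict", {
  m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  colnames(m) <- c("a", "b", "c")
  scr <- dca_gradient_length(m)
  expect_equal(scr$gradient_length_sd, 0)
  expect_equal(scr$verdict, "linear")
})

test_that("a shared linear gradient with small noise screens as linear (< 1.5 SD)", {
  set.seed(41)
  g <- seq(-1, 1, length.out = 30)
  m <- sapply(1:4, function(j) 5 + j * g + rnorm(30, 0, 0.1))
  colnames(m) <- paste0("v", 1:4)
  scr <- dca_gradient_length(m)
  expect_lt(scr$gradient_length_sd, 1.5)
  expect_equal(scr$verdict, "linear")
})

test_that("unimodal turnover along a long gradient screens as unimodal (> 2 SD)", {
  set.seed(43)
  g <- seq(0, 10, length.out = 60)
  optima <- seq(0, 10, length.out = 12)
  m <- sapply(optima, function(o) 20 * exp(-(g - o)^2 / (2 * 0.8^2)))
  m <- m + matrix(runif(length(m), 0, 0.05), nrow(m))
  colnames(m) <- paste0("sp", seq_along(optima))
  scr <- dca_gradient_length(m)
  expect_gt(scr$gradient_length_sd, 2)
  expect_equal(scr$verdict, "unimodal")
})

test_that("the DCA gradient length is invariant to row duplication", {
  set.seed(47)
  g <- seq(0, 4, length.out = 20)
  m <- sapply(seq(0, 4, length.out = 6),
              function(o) 10 * exp(-(g - o)^2 / 2) + 0.01)
  colnames(m) <- paste0("sp", 1:6)
  l1 <- dca_gradient_length(m)$gradient_length_sd
  l2 <- dca_gradient_length(m[rep(1:20, each = 2), ])$gradient_length_sd
  expect_equal(l1, l2, tolerance = 0.05)
})

test_that("OLS with adjusted R2 reproduces the closed-form anchors", {
  x <- 1:8
  fit <- regress_adjusted_r2(x, 2.5 * x - 1)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 2.5, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-8)

  # orthogonal residuals, n = 5: R2 = 0, adjusted R2 = -1/3
  x5 <- 1:5
  y5 <- (x5 - 3)^2 - 2          # cov(x, y) = 0 by symmetry
  fit0 <- regress_adjusted_r2(x5, y5)
  expect_equal(fit0$r_squared, 0, tolerance = 1e-12)
  expect_equal(fit0$adj_r_squared, -1 / 3, tolerance = 1e-12)
  expect_equal(fit0$n, 5)
  expect_error(regress_adjusted_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("trend test: strict decline, sign convention, degenerate input", {
  ages <- seq(0.5, 9.5, length.out = 30)
  # decline toward the present: higher values at older ages
  s <- proxy_series(ages, 0.4 + 0.05 * ages, name = "d30si")
  tr <- trend_test(s)
  expect_gt(tr$slope_per_kyr, 0)
  expect_lt(tr$p_value, 1e-10)
  expect_warning(tr0 <- trend_test(proxy_series(1:5, rep(2, 5), name = "x")),
                 "constant")
  expect_equal(tr0$slope_per_kyr, 0)
  expect_equal(tr0$p_value, 1)
  expect_error(trend_test(proxy_series(1:3, 1:3, name = "x")), "4 samples")
})

test_that("synthetic series with the observed decline geometry is detected with power", {
  # c. 0.9 to 0.4 permil over 9 kyr with 0.1 permil noise
  set.seed(53)
  hits <- 0L
  for (r in 1:100) {
    ages <- sort(runif(60, 0.2, 9.2))
    vals <- 0.4 + (0.5 / 9) * ages + rnorm(60, 0, 0.1)
    if (trend_test(proxy_series(ages, vals, name = "d30si"))$p_value < 0.001) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})
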
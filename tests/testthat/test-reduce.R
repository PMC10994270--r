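test_that("correlation-matrix PCA conserves trace and decorrelates scores", {
  set.seed(5)
  x <- matrix(rnorm(200 * 15), 200, 15)
  colnames(x) <- sprintf("F%02d", 1:15)
  pca <- fit_pca(x)
  expect_equal(sum(pca$eigenvalues), 15, tolerance = 1e-10)
  expect_false(is.unsorted(rev(pca$eigenvalues)))
  cc <- cor(pca$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # sign convention: the largest-|loading| entry of each component is positive
  expect_true(all(apply(pca$vectors, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(fit_pca(matrix(c(1, NA, 2, 3, 5, 6), 3)), "non-finite")
})

test_that("a planted common factor yields the analytic leading eigenvalue", {
  # 10 equicorrelated features with r = 0.9: lambda1 = 1 + 9 * 0.9 = 9.1
  set.seed(8)
  n <- 4000
  f <- rnorm(n)
  x <- sqrt(0.9) * matrix(f, n, 10) + sqrt(0.1) * matrix(rnorm(n * 10), n, 10)
  colnames(x) <- sprintf("F%02d", 1:10)
  lam1 <- fit_pca(x)$eigenvalues[1]
  se <- 9.1 * sqrt(2 / n)  # asymptotic SE of a sample eigenvalue
  expect_lt(abs(lam1 - 9.1), 4 * se)
})

test_that("component selection follows the kaiser, scree and fixed rules", {
  expect_equal(select_components(c(3.0, 1.2, 0.9, 0.5), "kaiser"), 2)
  expect_equal(select_components(rep(1, 6), "kaiser"), 0)  # strict inequality
  expect_equal(select_components(rep(1.5, 60), "fixed", k = 50), 50)
  expect_equal(select_components(c(3, 2), "fixed", k = 50), 2)  # capped
  # elbow by maximum second difference: computed by hand for this curve
  expect_equal(select_components(c(10, 6, 3, 2.8, 2.7, 2.6), "scree"), 3)
  expect_error(select_components(numeric(0)), "empty")
})

test_that("oblimin leaves perfect simple structure essentially fixed", {
  set.seed(31)
  Lt <- simple_structure(3, 4)
  r <- oblimin_rotate(Lt)
  aligned <- align_loadings(r$loadings, Lt)
  expect_false(is.null(aligned))
  expect_lt(max(abs(aligned - Lt)), 1e-6)
})

test_that("oblimin recovers simple structure mixed by a random rotation", {
  set.seed(32)
  Lt <- simple_structure(3, 5)
  M <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  r <- oblimin_rotate(Lt %*% M)
  aligned <- align_loadings(r$loadings, Lt)
  expect_false(is.null(aligned))
  expect_lt(max(abs(aligned - Lt)), 1e-6)
})

test_that("the factor correlation matrix is symmetric unit-diagonal PD", {
  set.seed(33)
  x <- matrix(rnorm(150 * 12), 150, 12) %*% matrix(rnorm(12 * 12, 0, .4), 12)
  x <- x + matrix(rnorm(150 * 12), 150, 12)
  colnames(x) <- sprintf("F%02d", 1:12)
  A <- fit_pca(x)$loadings[, 1:4]
  r <- oblimin_rotate(A)
  expect_equal(r$phi, t(r$phi), tolerance = 1e-12)
  expect_equal(unname(diag(r$phi)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(eigen(r$phi, symmetric = TRUE)$values > 0))
})

test_that("ten Berge scores reproduce phi exactly and honour orthogonality", {
  set.seed(34)
  x <- scale(matrix(rnorm(300 * 10), 300, 10) +
             0.8 * matrix(rnorm(300 * 2), 300, 2)[, c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)])
  pca <- fit_pca(unname(x + 0))
  A <- pca$loadings[, 1:2]
  rot <- oblimin_rotate(A)
  ts <- tenberge_scores(scale(x), rot$loadings, rot$phi)
  expect_equal(unname(cor(ts$scores)), unname(rot$phi), tolerance = 1e-8)
  expect_equal(unname(apply(ts$scores, 2, sd)), c(1, 1), tolerance = 1e-8)
  # orthogonal case phi = I
  ts0 <- tenberge_scores(scale(x), A, diag(2))
  expect_equal(unname(cor(ts0$scores)), diag(2), tolerance = 1e-8)
})

test_that("ten Berge scores match a brute-force matrix square-root oracle", {
  # 2-factor toy, 6 features with fixed loadings and factor correlation 0.4
  Lam <- matrix(c(0.8, 0.7, 0.6, 0.1, 0.0, 0.1,
                  0.0, 0.1, 0.1, 0.7, 0.8, 0.6), 6, 2)
  phi <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  set.seed(35)
  z <- matrix(rnorm(500 * 2), 500, 2) %*% chol(phi)
  x <- scale(z %*% t(Lam) + matrix(rnorm(500 * 6, 0, 0.5), 500, 6))
  got <- tenberge_scores(x, Lam, phi)$scores
  # independent construction via explicit spectral square roots
  msq <- function(S, pw) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(e$values^pw) %*% t(e$vectors)
  }
  R <- cor(x)
  L <- Lam %*% msq(phi, 0.5)
  C <- msq(R, -0.5) %*% L %*% msq(t(L) %*% solve(R) %*% L, -0.5)
  want <- x %*% msq(R, -0.5) %*% C %*% msq(phi, 0.5)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("rank-deficient feature correlation is refused with guidance", {
  x <- matrix(rnorm(60 * 3), 60, 3)
  x <- cbind(x, x[, 1] + x[, 2])
  expect_error(tenberge_scores(scale(x), matrix(0.5, 4, 2), diag(2)),
               "drop_degenerate")
})

test_that("reduce_profiles round-trips training data and new records", {
  scr <- small_screen(seed = 41)
  qc <- run_feature_qc(scr$table)
  red <- reduce_profiles(qc$wells, rule = "fixed", k = 6)
  expect_equal(red$k, 6)
  # transform(fit(X), X) reproduces the training scores exactly
  again <- predict(red, qc$wells)
  expect_equal(again, red$scores, tolerance = 1e-12)
  # held-out projection uses the training standardisation (no re-estimation)
  half <- qc$wells[1:100, ]
  red_half <- reduce_profiles(half, rule = "fixed", k = 4)
  rest <- predict(red_half, qc$wells[101:144, ])
  shifted <- qc$wells[101:144, ]
  shifted[, -(1:7)] <- shifted[, -(1:7)] + 100
  rest_shift <- predict(red_half, shifted)
  # a uniform shift moves scores by a constant, proving fixed centring
  d <- as.matrix(rest_shift[, -(1:7)]) - as.matrix(rest[, -(1:7)])
  expect_lt(max(abs(sweep(d, 2, d[1, ]))), 1e-8)
})

test_that("disabling rotation reduces to unit-variance PCA scores", {
  scr <- small_screen(seed = 41)
  qc <- run_feature_qc(scr$table)
  red <- reduce_profiles(qc$wells, rule = "fixed", k = 5, rotation = "none")
  pca <- fit_pca(qc$wells)
  sc <- as.matrix(red$scores[, -(1:7)])
  for (j in 1:5) {
    expect_equal(abs(cor(sc[, j], pca$scores[, j])), 1, tolerance = 1e-10)
    expect_equal(sd(sc[, j]), 1, tolerance = 1e-10)
  }
})

test_that("kaiser selection drives the pipeline when requested", {
  scr <- small_screen(seed = 43)
  qc <- run_feature_qc(scr$table)
  red <- reduce_profiles(qc$wells, rule = "kaiser")
  expect_equal(red$k, sum(red$eigenvalues > 1))
})
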
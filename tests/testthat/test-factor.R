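test_that("KMO is exactly 1/2 for any two correlated variables", {
  for (r in c(-0.9, -0.3, 0.2, 0.7)) {
    R <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(kmo_statistic(R), 0.5, tolerance = 1e-12)
  }
})

test_that("KMO matches the direct double-loop oracle", {
  expect_equal(kmo_statistic(block_corr_4()), kmo_oracle(block_corr_4()),
               tolerance = 1e-8)
  set.seed(17)
  for (p in c(4L, 6L, 8L)) {
    x <- matrix(rnorm(40 * p), 40, p)
    x[, 2] <- x[, 1] * 0.6 + x[, 2] * 0.8   # give it some structure
    R <- cor(x)
    expect_equal(kmo_statistic(R), kmo_oracle(R), tolerance = 1e-8)
  }
  expect_error(kmo_statistic(matrix(c(1, 1, 1, 1), 2, 2)), "singular")
})

test_that("Bartlett's sphericity matches closed forms and the det oracle", {
  expect_equal(bartlett_sphericity(diag(5), 100)$chi2, 0)
  expect_equal(bartlett_sphericity(diag(5), 100)$p_value, 1)
  # 3x3 equicorrelation rho = 0.5: det = (1-rho)^2 (1+2rho) = 0.5
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  b <- bartlett_sphericity(R, 100)
  expect_equal(b$chi2, -(100 - 1 - 11 / 6) * log(0.5), tolerance = 1e-12)
  expect_equal(b$df, 3)
  expect_equal(b$chi2, bartlett_oracle(R, 100), tolerance = 1e-10)
  # monotone in n
  expect_gt(bartlett_sphericity(R, 200)$chi2, b$chi2)
  set.seed(23)
  x <- matrix(rnorm(50 * 6), 50, 6)
  R6 <- cor(x)
  expect_equal(bartlett_sphericity(R6, 50)$chi2, bartlett_oracle(R6, 50),
               tolerance = 1e-8)
  expect_error(bartlett_sphericity(R, 2), "n > p")
})

test_that("correlation PCA reproduces closed-form spectra", {
  # two perfectly correlated variables -> eigenvalues (2, 0)
  x <- rnorm(30)
  z <- standardize_indicators(cbind(a = x, b = 2 * x + 3))
  p2 <- pca_correlation(z)
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-10)
  # equicorrelation: eigenvalues 1 + (p-1) rho, then 1 - rho
  for (rho in c(0.2, 0.6)) {
    R <- matrix(rho, 3, 3); diag(R) <- 1
    ev <- eigen(R, only.values = TRUE)$values  # sanity for the fixture
    expect_equal(sort(ev, decreasing = TRUE),
                 c(1 + 2 * rho, 1 - rho, 1 - rho), tolerance = 1e-12)
  }
})

test_that("PCA eigenvalues agree with the characteristic-polynomial oracle", {
  set.seed(29)
  x <- matrix(rnorm(60 * 6), 60, 6)
  x[, 4] <- 0.7 * x[, 1] + 0.5 * x[, 4]
  pc <- pca_correlation(standardize_indicators(x))
  expect_equal(pc$eigenvalues, charpoly_eigenvalues(cor(x)),
               tolerance = 1e-8)
  # structural invariants
  expect_equal(sum(pc$eigenvalues), 6, tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # loadings reproduce R: L L^T = R for full-rank PCA
  expect_equal(pc$loadings %*% t(pc$loadings), cor(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude element of each column positive
  for (j in 1:6) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("varimax leaves perfect simple structure unchanged", {
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  out <- varimax_rotate(L)
  expect_equal(varimax_criterion(out$loadings), varimax_criterion(L),
               tolerance = 1e-10)
  expect_equal(abs(out$rotmat), diag(2), tolerance = 1e-6)
  # k = 1: identity rotation
  one <- varimax_rotate(L[, 1, drop = FALSE])
  expect_identical(one$loadings, L[, 1, drop = FALSE])
  expect_error(varimax_rotate(L[, 0]), "no components")
})

test_that("varimax beats a fine planar grid search for k = 2", {
  set.seed(37)
  for (rep in 1:3) {
    L <- matrix(rnorm(12), 6, 2)
    out <- varimax_rotate(L)
    expect_gte(varimax_criterion(out$loadings) + 1e-10,
               varimax_grid_oracle(L))
  }
})

test_that("varimax is orthogonal and preserves communalities", {
  syn <- default_synthesis()
  pc <- pca_correlation(standardize_indicators(syn$table))
  L5 <- pc$loadings[, 1:5]
  out <- varimax_rotate(L5)
  expect_equal(t(out$rotmat) %*% out$rotmat, diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out$loadings, L5 %*% out$rotmat, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(out$loadings^2), rowSums(L5^2), tolerance = 1e-8)
  # total explained variance preserved (sum of top-k eigenvalues)
  expect_equal(sum(colSums(out$loadings^2)), sum(pc$eigenvalues[1:5]),
               tolerance = 1e-6)
})

test_that("parallel analysis retains nothing on pure noise", {
  set.seed(41)
  x <- matrix(rnorm(300 * 10), 300, 10)
  pa <- parallel_analysis(x, n_reps = 200L, seed = 1L)
  expect_equal(pa$k_retained, 0L)
  # adjusted eigenvalues hover near 1 under the null
  expect_lt(max(abs(pa$adjusted_eigenvalues - 1)), 0.3)
})

test_that("parallel analysis recovers two strong planted factors", {
  set.seed(43)
  n <- 300L; p <- 10L
  f <- matrix(rnorm(n * 2), n, 2)
  L <- matrix(0, p, 2)
  L[1:5, 1] <- 0.8; L[6:10, 2] <- 0.8
  x <- f %*% t(L) + matrix(rnorm(n * p, sd = 0.6), n, p)
  pa <- parallel_analysis(x, n_reps = 200L, seed = 1L)
  expect_equal(pa$k_retained, 2L)
})

test_that("parallel analysis is deterministic given data, reps and seed", {
  set.seed(47)
  x <- matrix(rnorm(100 * 5), 100, 5)
  a <- parallel_analysis(x, n_reps = 50L, seed = 9L)
  b <- parallel_analysis(x, n_reps = 50L, seed = 9L)
  expect_identical(a, b)
  c <- parallel_analysis(x, n_reps = 50L, seed = 10L)
  expect_false(identical(a$random_eigenvalue_means,
                         c$random_eigenvalue_means))
})

test_that("max-loading assignment follows absolute loadings with low-index ties", {
  L <- rbind(c(0.8, 0.1), c(-0.7, 0.6), c(0.5, 0.5), c(0.1, -0.9))
  rownames(L) <- paste0("v", 1:4)
  asg <- assign_to_subindices(L)
  expect_equal(unname(asg$component_of), c(1L, 1L, 1L, 2L))
  expect_equal(unname(asg$n_i), c(3L, 1L))
  expect_equal(sum(asg$n_i), 4L)
  expect_warning(assign_to_subindices(rbind(c(0.9, 0.1), c(0.8, 0.2))),
                 "no assigned indicators")
})

test_that("the full factor model recovers the generating structure", {
  syn <- default_synthesis()
  model <- fit_factor_model(standardize_indicators(syn$table),
                            n_reps = 200L, seed = 1L)
  expect_equal(model$k_retained, 5L)
  expect_gte(assignment_recovery(model$assignment$component_of,
                                 syn$truth$block_assignment), 0.95)
  expect_gt(model$suitability$kmo, 0.5)
  expect_lt(model$suitability$bartlett_p, 1e-10)
})
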
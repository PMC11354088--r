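test_that("North classification covers exactly the three northern regions", {
  expect_true(classify_north("North West"))
  expect_true(classify_north("North East"))
  expect_true(classify_north("Yorkshire and The Humber"))
  expect_false(classify_north("South East"))
  expect_false(classify_north("London"))
  expect_equal(sum(classify_north(english_regions)), 3L)
  expect_error(classify_north("The Shire"), "The Shire")
})

test_that("coastal classification uses a strict majority of population", {
  expect_false(classify_coastal(c(100, 100), c(TRUE, FALSE)))  # exactly half
  expect_true(classify_coastal(c(300, 100), c(TRUE, FALSE)))
  expect_true(classify_coastal(500, TRUE))
  expect_false(classify_coastal(500, FALSE))
  # invariant to uniform population scaling
  pops <- c(120, 80, 40); flags <- c(TRUE, FALSE, TRUE)
  expect_identical(classify_coastal(pops, flags),
                   classify_coastal(pops * 1000, flags))
  expect_error(classify_coastal(c(0, 0), c(TRUE, FALSE)), "zero")
})

test_that("pooled t-test matches the textbook formula", {
  cmp <- two_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, pooled_t_oracle(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(cmp$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  # identical constant groups: t = 0, p = 1, not an error
  same <- two_group_test(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # swapping groups negates t, keeps p
  sw <- two_group_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$statistic, -cmp$statistic)
  expect_equal(sw$p_value, cmp$p_value)
  # wider mean gap at equal spread is more significant
  far <- two_group_test(c(1, 2, 3), c(7, 8, 9))
  expect_lt(far$p_value, cmp$p_value)
  # Welch agrees with R's own implementation on unequal variances
  set.seed(59)
  a <- rnorm(12, sd = 1); b <- rnorm(20, mean = 1, sd = 3)
  w <- two_group_test(a, b, welch = TRUE)
  ref <- t.test(a, b)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("one-way ANOVA matches sums-of-squares arithmetic and t^2", {
  g <- list(a = c(1, 3, 5), b = c(2, 4, 9), c = c(8, 8, 10))
  out <- anova_oneway(g)
  expect_equal(out$statistic, anova_f_oracle(g), tolerance = 1e-12)
  expect_equal(out$df, c(2L, 6L))
  # two groups: F = t^2 of the pooled t-test
  t2 <- two_group_test(g$a, g$b)
  f2 <- anova_oneway(g[1:2])
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-10)
  # degenerate identical groups
  flat <- anova_oneway(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("F = t^2 holds on random two-group fixtures", {
  set.seed(61)
  for (rep in 1:5) {
    a <- rnorm(sample(5:15, 1)); b <- rnorm(sample(5:15, 1), mean = 0.5)
    expect_equal(anova_oneway(list(a, b))$statistic,
                 two_group_test(a, b)$statistic^2, tolerance = 1e-10)
  }
})

test_that("validation against a reference index behaves at the extremes", {
  ids <- paste0("A", 1:20)
  ref <- setNames(1:20, ids)
  dec <- setNames(rev(seq(10, 200, 10)), ids)   # strictly decreasing in rank
  v <- validate_against_reference(dec, ref)
  expect_equal(v$spearman_rho, -1)
  expect_equal(v$pearson_r, -1)
  # perfectly linear: zero residuals, no outliers
  lin <- setNames(3 + 2 * (1:20), ids)
  vl <- validate_against_reference(lin, ref)
  expect_lt(max(abs(vl$residuals)), 1e-10)
  expect_length(vl$top_positive, 0)
  expect_length(vl$top_negative, 0)
  expect_equal(unname(vl$slope), 2, tolerance = 1e-10)
  expect_error(validate_against_reference(setNames(rep(1, 20), ids), ref),
               "constant")
})

test_that("least-squares residuals sum to zero and are orthogonal to the regressor", {
  set.seed(67)
  ids <- paste0("A", 1:50)
  ref <- setNames(sample(50), ids)
  cri <- setNames(100 - 0.5 * ref + rnorm(50, sd = 5), ids)
  v <- validate_against_reference(cri, ref, n_outliers = 10L)
  expect_lt(abs(sum(v$residuals)), 1e-8)
  expect_lt(abs(sum(v$residuals * ref)), 1e-6)
  expect_length(v$top_positive, 10L)
  expect_true(all(v$residuals[v$top_positive] > 0))
  expect_true(all(v$residuals[v$top_negative] < 0))
})

test_that("sensitivity comparison matches the brute-force rank correlation", {
  syn <- default_synthesis()
  rk <- percentile_rank(syn$table)
  bric <- compute_bric_unweighted(rk, syn$table$registry)
  model <- fit_factor_model(standardize_indicators(syn$table),
                            n_reps = 100L, seed = 1L)
  w <- compute_indicator_weights(model$loadings_rotated, model$assignment)
  idx <- compute_cri(compute_subindices(rk, model$assignment, w),
                     model$pca$eigenvalues[1:model$k_retained])
  cmp <- sensitivity_compare(idx, bric, syn$table$areas)
  expect_equal(cmp$spearman_rho, spearman_oracle(idx$cri, bric$cri),
               tolerance = 1e-10)
  expect_gt(cmp$spearman_rho, 0.5)
  expect_equal(sum(cmp$region_ranks$n), 307L)
  # identical and reversed indices
  expect_equal(sensitivity_compare(idx, idx)$spearman_rho, 1)
  rev_idx <- idx
  rev_idx$cri <- -idx$cri
  expect_equal(sensitivity_compare(idx, rev_idx)$spearman_rho, -1)
})

test_that("geographic comparison report covers every area once", {
  syn <- default_synthesis()
  score <- setNames(syn$truth$latent_resilience, syn$table$areas$area_id)
  geo <- compare_geography(score, syn$table$areas)
  expect_named(geo, c("region", "north_south", "coastal_inland",
                      "urban_rural"))
  for (g in geo) {
    expect_equal(sum(g$group_stats$n), 307L)
    expect_gte(g$p_value, 0)
    expect_lte(g$p_value, 1)
  }
  expect_equal(geo$region$df[1], 8L)
})

test_that("map bins follow the documented z-score boundaries", {
  x <- c(0, 2.5, -2.5, 0.5, -0.5, 1.5)
  z <- (x - mean(x)) / sd(x)
  bins <- map_bins(x)
  expect_s3_class(bins, "factor")
  labels <- levels(bins)
  expect_equal(as.integer(bins), findInterval(z, c(-2, -1, 0, 1, 2)) + 1L)
  # mean value sits in [0, 1); far outliers hit the extreme bins
  y <- c(rep(10, 10), 10 + 25)
  expect_equal(as.character(map_bins(y)[1]), "-1 to 0 SD")
  expect_equal(as.character(map_bins(y)[11]), "> 2 SD")
  expect_error(map_bins(rep(3, 5)), "constant")
})

test_that("GeoJSON property attachment keys on area id", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(area_id = "A1"),
         geometry = NULL),
    list(type = "Feature", properties = list(area_id = "A2"),
         geometry = NULL)))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, null = "null")
  attach_geojson_property(path, c(A1 = 83.1, A2 = 76.0), property = "cri")
  back <- jsonlite::read_json(path)
  expect_equal(back$features[[1]]$properties$cri, 83.1)
  expect_equal(back$features[[2]]$properties$cri, 76.0)
})
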
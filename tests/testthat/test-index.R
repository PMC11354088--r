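make_assignment <- function(component_of) {
  k <- max(component_of)
  members <- lapply(seq_len(k), function(i) names(component_of)[component_of == i])
  names(members) <- paste0("SI", seq_len(k))
  structure(list(component_of = component_of, members = members,
                 n_i = lengths(members)),
            class = "cri_assignment")
}

test_that("indicator weights normalise squared loadings within sub-indices", {
  L <- rbind(c(0.7, 0), c(0.7, 0), c(0, 0.5))
  rownames(L) <- c("a", "b", "c")
  asg <- make_assignment(c(a = 1L, b = 1L, c = 2L))
  w <- compute_indicator_weights(L, asg)
  expect_equal(unname(w), c(0.5, 0.5, 1))
  L2 <- rbind(c(0.8, 0), c(0.4, 0))
  rownames(L2) <- c("a", "b")
  asg2 <- make_assignment(c(a = 1L, b = 1L))
  expect_equal(unname(compute_indicator_weights(L2, asg2)), c(0.8, 0.2))
  raw <- compute_indicator_weights(L2, asg2, "raw_squared_loading")
  expect_equal(unname(raw), c(0.64, 0.16))
  L0 <- rbind(c(0, 0.3), c(0.5, 0))
  rownames(L0) <- c("a", "b")
  expect_error(compute_indicator_weights(L0, make_assignment(c(a = 1L, b = 2L))),
               "zero total squared loading")
})

test_that("sub-index scores follow both aggregation modes", {
  asg1 <- make_assignment(c(a = 1L))
  ranks1 <- matrix(60, 1, 1, dimnames = list("A1", "a"))
  expect_equal(compute_subindices(ranks1, asg1, c(a = 1))[1, 1], 60)

  asg2 <- make_assignment(c(a = 1L, b = 1L))
  ranks2 <- matrix(c(40, 80), 1, 2, dimnames = list("A1", c("a", "b")))
  wm <- compute_subindices(ranks2, asg2, c(a = 0.5, b = 0.5),
                           mode = "weighted_mean")
  expect_equal(wm[1, 1], 60)
  # as-printed: weighted sum divided by member count
  ap <- compute_subindices(ranks2, asg2, c(a = 0.8, b = 0.2))
  expect_equal(ap[1, 1], (40 * 0.8 + 80 * 0.2) / 2)
  expect_error(compute_subindices(ranks2, asg2, c(a = 0.8)), "no weight")
})

test_that("composite assembly sums weighted sub-indices with contribution shares", {
  S <- matrix(c(10, 20), 1, 2, dimnames = list("A1", c("SI1", "SI2")))
  unit <- compute_cri(S, c(1, 1))
  expect_equal(unname(unit$cri), 30)
  res <- compute_cri(S, c(2, 0.5))
  expect_equal(unname(res$cri), 30)
  expect_equal(unname(res$contributions[1, ]), c(2 / 3, 1 / 3))
  zero <- compute_cri(matrix(0, 2, 2), c(1, 1))
  expect_equal(unname(zero$cri), c(0, 0))
  expect_true(all(is.na(zero$contributions)))
  expect_error(compute_cri(S, c(-1, 1)), "non-negative")
})

test_that("the unweighted BRIC variant takes per-domain means", {
  reg <- tiny_registry(12)   # two indicators per domain, round-robin
  ranks <- matrix(50, 4, 12, dimnames = list(paste0("A", 1:4), reg$id))
  bric <- compute_bric_unweighted(ranks, reg)
  expect_equal(unname(bric$cri), rep(300, 4))
  expect_true(all(bric$subindex_raw == 50))
  # one domain with ranks (20, 40) -> sub-index 30
  ranks2 <- ranks
  ranks2[1, reg$bric_domain == "social"] <- c(20, 40)
  expect_equal(compute_bric_unweighted(ranks2, reg)$subindex_raw[1, "social"],
               30)
  # bundled registry: domain sizes carried through as documented
  syn <- default_synthesis()
  rk <- percentile_rank(syn$table)
  full <- compute_bric_unweighted(rk, syn$table$registry)
  expect_equal(ncol(full$subindex_raw), 6L)
  expect_equal(unname(table(factor(syn$table$registry$bric_domain,
                                   levels = bric_domains))[bric_domains]),
               c(10L, 12L, 6L, 5L, 3L, 8L), ignore_attr = TRUE)
  reg_gap <- tiny_registry(4, domains = rep("social", 4))
  expect_error(compute_bric_unweighted(ranks[, 1:4][, , drop = FALSE] |>
                                         `colnames<-`(reg_gap$id), reg_gap),
               "no indicators")
})

test_that("contribution audit averages per-area shares to 100%", {
  S <- matrix(c(30, 10), 1, 2, dimnames = list("A1", c("SI1", "SI2")))
  res <- compute_cri(S, c(1, 1))
  expect_equal(unname(audit_contributions(res)), c(75, 25))
  S2 <- rbind(c(6, 4), c(4, 6))
  dimnames(S2) <- list(c("A1", "A2"), c("SI1", "SI2"))
  expect_equal(unname(audit_contributions(compute_cri(S2, c(1, 1)))),
               c(50, 50))
  syn <- default_synthesis()
  rk <- percentile_rank(syn$table)
  bric <- compute_bric_unweighted(rk, syn$table$registry)
  expect_equal(sum(audit_contributions(bric)), 100, tolerance = 1e-9)
})

test_that("the index is scale-equivariant and monotone in any rank", {
  set.seed(53)
  ranks <- matrix(runif(60, 0, 100), 10, 6,
                  dimnames = list(paste0("A", 1:10), paste0("x", 1:6)))
  asg <- make_assignment(setNames(rep(1:2, each = 3L), colnames(ranks)))
  w <- setNames(runif(6), colnames(ranks))
  for (i in 1:2) w[asg$component_of == i] <- w[asg$component_of == i] /
    sum(w[asg$component_of == i])
  base <- compute_cri(compute_subindices(ranks, asg, w), c(1.7, 0.4))
  scaled <- compute_cri(compute_subindices(ranks * 3, asg, w), c(1.7, 0.4))
  expect_equal(scaled$cri, 3 * base$cri, tolerance = 1e-10)
  expect_equal(scaled$subindex_raw, 3 * base$subindex_raw, tolerance = 1e-10)
  bumped <- ranks
  bumped[4, 2] <- bumped[4, 2] + 5
  res_b <- compute_cri(compute_subindices(bumped, asg, w), c(1.7, 0.4))
  expect_gte(res_b$cri[4], base$cri[4])
  expect_equal(res_b$cri[-4], base$cri[-4])
})

test_that("the two aggregation equations coincide under the BRIC configuration", {
  syn <- default_synthesis()
  reg <- syn$table$registry
  rk <- percentile_rank(syn$table)
  comp <- setNames(match(reg$bric_domain, bric_domains), reg$id)
  asg <- make_assignment(comp)
  w_equal <- setNames(numeric(nrow(reg)), reg$id)
  for (i in 1:6) w_equal[comp == i] <- 1 / sum(comp == i)
  sub <- compute_subindices(rk, asg, w_equal, mode = "weighted_mean")
  via_cri <- compute_cri(sub, rep(1, 6))
  bric <- compute_bric_unweighted(rk, reg)
  expect_equal(unname(via_cri$cri), unname(bric$cri), tolerance = 1e-10)
  expect_equal(unname(via_cri$subindex_raw), unname(bric$subindex_raw),
               tolerance = 1e-10)
})

test_that("index results round-trip through CSV", {
  syn <- default_synthesis()
  rk <- percentile_rank(syn$table)
  bric <- compute_bric_unweighted(rk, syn$table$registry)
  path <- tempfile(fileext = ".csv")
  write_index_result(bric, path)
  back <- read.csv(path)
  expect_equal(back$cri, unname(bric$cri), tolerance = 1e-10)
  expect_equal(nrow(back), 307L)
})
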
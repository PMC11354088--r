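# Independent slow oracles used to cross-check the implementation.
# These deliberately avoid the code paths (eigen, solve, cor, stats tests)
# that the functions under test rely on.

# determinant by recursive cofactor expansion (first row)
cofactor_det <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(A[1, 1])
  if (n == 2L) return(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  total <- 0
  for (j in seq_len(n)) {
    minor <- A[-1, -j, drop = FALSE]
    total <- total + (-1)^(1 + j) * A[1, j] * cofactor_det(minor)
  }
  total
}

# matrix inverse via adjugate / cofactor determinants
cofactor_inverse <- function(A) {
  n <- nrow(A)
  d <- cofactor_det(A)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      minor <- A[-i, -j, drop = FALSE]
      md <- if (nrow(minor) == 0L) 1 else cofactor_det(minor)
      C[i, j] <- (-1)^(i + j) * md
    }
  }
  t(C) / d
}

# characteristic polynomial coefficients by Faddeev-LeVerrier, roots by
# polyroot: an eigenvalue oracle independent of eigen()
charpoly_eigenvalues <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1L)       # coefs[k+1] multiplies lambda^k
  coefs[n + 1L] <- 1
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    M <- A %*% M + coefs[n - k + 2L] * diag(n)
    coefs[n - k + 1L] <- -sum(diag(A %*% M)) / k
  }
  roots <- polyroot(coefs)
  sort(Re(roots), decreasing = TRUE)
}

# KMO by literal double loops over the formula, partials from the
# adjugate-based inverse
kmo_oracle <- function(R) {
  S <- cofactor_inverse(R)
  p <- nrow(R)
  num <- 0; den_q <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      q <- -S[i, j] / sqrt(S[i, i] * S[j, j])
      num <- num + R[i, j]^2
      den_q <- den_q + q^2
    }
  }
  num / (num + den_q)
}

bartlett_oracle <- function(R, n) {
  p <- nrow(R)
  -(n - 1 - (2 * p + 5) / 6) * log(cofactor_det(R))
}

# best varimax criterion reachable by planar rotations on a 0.5 degree grid
# (k = 2 only)
varimax_grid_oracle <- function(L) {
  stopifnot(ncol(L) == 2L)
  best <- -Inf
  for (deg in seq(0, 359.5, by = 0.5)) {
    th <- deg * pi / 180
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    best <- max(best, varimax_criterion(L %*% Rm))
  }
  best
}

# rank by counting, Pearson on those ranks via explicit sums
spearman_oracle <- function(x, y) {
  count_rank <- function(v) {
    vapply(v, function(vi) {
      (sum(v < vi) + 1 + sum(v <= vi)) / 2
    }, numeric(1))
  }
  rx <- count_rank(x); ry <- count_rank(y)
  n <- length(x)
  sxy <- sum(rx * ry) - sum(rx) * sum(ry) / n
  sxx <- sum(rx^2) - sum(rx)^2 / n
  syy <- sum(ry^2) - sum(ry)^2 / n
  sxy / sqrt(sxx * syy)
}

pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  ss1 <- sum((a - m1)^2); ss2 <- sum((b - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

anova_f_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- sum(all_v) / length(all_v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    m <- sum(g) / length(g)
    ssb <- ssb + length(g) * (m - grand)^2
    ssw <- ssw + sum((g - m)^2)
  }
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# map estimated components to generating blocks by majority vote and score
# the fraction of indicators assigned to their generating block
assignment_recovery <- function(component_of, block_assignment) {
  k <- max(component_of)
  mapping <- integer(k)
  for (i in seq_len(k)) {
    members <- which(component_of == i)
    if (length(members) == 0L) next
    tab <- table(block_assignment[members])
    mapping[i] <- as.integer(names(tab)[which.max(tab)])
  }
  mean(mapping[component_of] == block_assignment)
}
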
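#' @title Factorability tests, PCA, rotation and retention
#' @description Suitability testing (Kaiser-Meyer-Olkin sampling adequacy,
#'   Bartlett's test of sphericity), principal components analysis of the
#'   correlation matrix, varimax rotation by iterative planar rotations,
#'   Horn's parallel analysis with the adjusted-eigenvalue (> 1) retention
#'   rule, and max-loading assignment of indicators to sub-indices.
#' @name factor_analysis
NULL

check_corr_matrix <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8) {
    stop("R must be a symmetric correlation matrix", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop("R must have a unit diagonal", call. = FALSE)
  }
  R
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the sum of squared off-diagonal correlations divided by that
#' sum plus the sum of squared off-diagonal anti-image partial correlations,
#' where the partials `q_ij = -s_ij / sqrt(s_ii s_jj)` come from the inverse
#' `S = R^-1`. Values near 1 indicate data well suited to factor methods;
#' below 0.5 is conventionally unacceptable.
#'
#' @param R correlation matrix (symmetric, unit diagonal, invertible).
#' @return The KMO statistic in \[0, 1\].
#' @export
kmo_statistic <- function(R) {
  R <- check_corr_matrix(R)
  S <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; remove collinear indicators or ",
         "add a ridge before computing KMO", call. = FALSE)
  })
  d <- 1 / sqrt(diag(S))
  Q <- -S * tcrossprod(d)        # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the correlation matrix is the identity, via
#' `chi2 = -(n - 1 - (2p + 5)/6) * log det R` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R correlation matrix (positive definite).
#' @param n sample size used to estimate `R`; must exceed the number of
#'   variables.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- check_corr_matrix(R)
  p <- nrow(R)
  stopifnot(n > p)
  detR <- det(R)
  if (detR <= 0) {
    stop("correlation matrix is not positive definite", call. = FALSE)
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Factorability report for a standardised matrix
#'
#' @param z a `cri_standardized` (or numeric matrix already standardised).
#' @return List with `kmo`, `bartlett_chi2`, `bartlett_df`, `bartlett_p`.
#' @export
suitability_tests <- function(z) {
  m <- if (inherits(z, "cri_standardized")) z$z_values else as.matrix(z)
  R <- stats::cor(m)
  b <- bartlett_sphericity(R, nrow(m))
  list(kmo = kmo_statistic(R), bartlett_chi2 = b$chi2,
       bartlett_df = b$df, bartlett_p = b$p_value)
}

#' Principal components of the correlation matrix
#'
#' Eigen-decomposition of the sample correlation matrix. Loadings are
#' eigenvectors scaled by the square root of their eigenvalues, ordered by
#' descending eigenvalue; each eigenvector's sign is fixed so its
#' largest-magnitude element is positive, making runs reproducible.
#'
#' @param z a `cri_standardized` or numeric matrix (no missing values).
#' @return A `cri_pca` list: `eigenvalues`, `variance_explained`,
#'   `loadings` (p x p unrotated), `rotation` (eigenvectors), `n`, `p`.
#' @export
pca_correlation <- function(z) {
  m <- if (inherits(z, "cri_standardized")) z$z_values else as.matrix(z)
  if (!all(is.finite(m))) stop("input contains non-finite values",
                               call. = FALSE)
  R <- stats::cor(m)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  loadings <- vecs %*% diag(sqrt(vals), nrow = length(vals))
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", seq_along(vals))
  structure(list(eigenvalues = vals,
                 variance_explained = vals / length(vals),
                 loadings = loadings, rotation = vecs,
                 n = nrow(m), p = ncol(m)),
            class = "cri_pca")
}

#' Varimax criterion
#'
#' Sum over components of the (population) variance of squared loadings,
#' the quantity varimax rotation maximises.
#'
#' @param loadings p x k loading matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- loadings^2
  p <- nrow(loadings)
  sum(colMeans(L2^2) - colMeans(L2)^2) * p
}

#' Varimax rotation
#'
#' Orthogonal rotation maximising the variance of squared loadings within
#' each component, by cycling over column pairs and applying the closed-form
#' optimal planar rotation until the largest angle in a sweep falls below
#' `tol`. Kaiser row-normalisation (rotating loadings scaled to unit
#' communality) is off by default.
#'
#' @param loadings p x k unrotated loading matrix.
#' @param normalize apply Kaiser row-normalisation during rotation?
#' @param tol convergence tolerance on the rotation angle (radians).
#' @param max_iter maximum number of sweeps over all column pairs.
#' @return List with `loadings` (rotated p x k) and `rotmat` (k x k
#'   orthogonal matrix such that `rotated = unrotated %*% rotmat`).
#' @export
varimax_rotate <- function(loadings, normalize = FALSE, tol = 1e-8,
                           max_iter = 1000L) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k == 0L) stop("no components to rotate", call. = FALSE)
  p <- nrow(L)
  rot <- diag(k)
  if (k == 1L) return(list(loadings = L, rotmat = rot))
  comm <- rep(1, p)
  if (normalize) {
    comm <- sqrt(rowSums(L^2))
    comm[comm == 0] <- 1
    L <- L / comm
  }
  for (iter in seq_len(max_iter)) {
    max_angle <- 0
    for (a in seq_len(k - 1L)) {
      for (b in seq((a + 1L), k)) {
        x <- L[, a]; y <- L[, b]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > max_angle) max_angle <- abs(phi)
        if (abs(phi) > .Machine$double.eps) {
          cs <- cos(phi); sn <- sin(phi)
          L[, a] <- cs * x + sn * y
          L[, b] <- -sn * x + cs * y
          ra <- rot[, a]; rb <- rot[, b]
          rot[, a] <- cs * ra + sn * rb
          rot[, b] <- -sn * ra + cs * rb
        }
      }
    }
    if (max_angle < tol) break
  }
  if (normalize) L <- L * comm
  dimnames(L) <- dimnames(loadings)
  list(loadings = L, rotmat = rot)
}

#' Horn's parallel analysis
#'
#' Compares the observed correlation-matrix eigenvalues with the mean
#' eigenvalues of `n_reps` independent standard-normal datasets of the same
#' dimensions. Adjusted eigenvalues are
#' `observed_j - (random_mean_j - 1)`; the number of components retained is
#' the longest initial run with adjusted eigenvalue strictly greater
#' than 1.
#'
#' @param z a `cri_standardized` or numeric matrix.
#' @param n_reps number of random replicate datasets (default 1000).
#' @param seed integer seed; the procedure is deterministic given
#'   `(data, n_reps, seed)`.
#' @param quantile `NULL` (default) for the mean random eigenvalue, or a
#'   probability (e.g. 0.95) to use that quantile instead.
#' @return List with `k_retained`, `random_eigenvalue_means`,
#'   `adjusted_eigenvalues`, `observed_eigenvalues`.
#' @export
parallel_analysis <- function(z, n_reps = 1000L, seed = 1L, quantile = NULL) {
  m <- if (inherits(z, "cri_standardized")) z$z_values else as.matrix(z)
  stopifnot(n_reps >= 1)
  n <- nrow(m); p <- ncol(m)
  observed <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  rand <- matrix(NA_real_, nrow = n_reps, ncol = p)
  for (r in seq_len(n_reps)) {
    x <- matrix(stats::rnorm(n * p), nrow = n)
    rand[r, ] <- eigen(stats::cor(x), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  ref <- if (is.null(quantile)) colMeans(rand) else
    apply(rand, 2, stats::quantile, probs = quantile)
  adjusted <- observed - (ref - 1)
  k <- match(FALSE, adjusted > 1, nomatch = p + 1L) - 1L
  list(k_retained = as.integer(k), random_eigenvalue_means = ref,
       adjusted_eigenvalues = adjusted, observed_eigenvalues = observed)
}

#' Assign indicators to sub-indices by maximum loading
#'
#' Each indicator joins the retained component on which it has the largest
#' absolute rotated loading; ties go to the lower component index. A warning
#' is raised if any component ends up with no members.
#'
#' @param loadings_rotated p x k rotated loading matrix.
#' @return A `cri_assignment` list: `component_of` (named integer vector),
#'   `members` (list of indicator ids per component), `n_i` (member counts).
#' @export
assign_to_subindices <- function(loadings_rotated) {
  L <- as.matrix(loadings_rotated)
  k <- ncol(L)
  stopifnot(k >= 1)
  ids <- rownames(L)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(nrow(L)))
  comp <- apply(abs(L), 1, which.max)
  names(comp) <- ids
  members <- lapply(seq_len(k), function(i) ids[comp == i])
  names(members) <- paste0("SI", seq_len(k))
  n_i <- lengths(members)
  if (any(n_i == 0L)) {
    warning("component(s) with no assigned indicators: ",
            paste(which(n_i == 0L), collapse = ", "), call. = FALSE)
  }
  structure(list(component_of = comp, members = members, n_i = n_i),
            class = "cri_assignment")
}

#' Fit the full factor model for index construction
#'
#' Convenience wrapper running PCA, parallel-analysis retention, varimax
#' rotation of the retained components and max-loading assignment.
#'
#' @param z a `cri_standardized`.
#' @param n_reps,seed,quantile passed to [parallel_analysis()].
#' @param normalize passed to [varimax_rotate()].
#' @param rotate_all rotate all p components instead of the retained k
#'   before assignment (alternative reading; default `FALSE`).
#' @return A `cri_factor_model` list with the PCA, suitability report,
#'   retention results, rotated loadings and assignment.
#' @export
fit_factor_model <- function(z, n_reps = 1000L, seed = 1L, quantile = NULL,
                             normalize = FALSE, rotate_all = FALSE) {
  pca <- pca_correlation(z)
  suit <- suitability_tests(z)
  pa <- parallel_analysis(z, n_reps = n_reps, seed = seed, quantile = quantile)
  k <- max(pa$k_retained, 1L)
  L <- if (rotate_all) pca$loadings else pca$loadings[, seq_len(k), drop = FALSE]
  vr <- varimax_rotate(L, normalize = normalize)
  Lk <- vr$loadings[, seq_len(k), drop = FALSE]
  structure(list(pca = pca, suitability = suit, parallel = pa,
                 k_retained = pa$k_retained,
                 loadings_rotated = Lk, rotmat = vr$rotmat,
                 assignment = assign_to_subindices(Lk)),
            class = "cri_factor_model")
}

#' @export
print.cri_factor_model <- function(x, ...) {
  cat("Factor model:", x$pca$p, "indicators,", x$k_retained,
      "components retained (adjusted eigenvalues > 1)\n")
  cat(sprintf("  KMO %.3f; Bartlett chi2 %.1f on %d df (p %.3g)\n",
              x$suitability$kmo, x$suitability$bartlett_chi2,
              x$suitability$bartlett_df, x$suitability$bartlett_p))
  cat("  sub-index sizes:", paste(x$assignment$n_i, collapse = ", "), "\n")
  invisible(x)
}

#' Export a factor model as CSV tables
#'
#' Writes eigenvalue/retention and rotated-loading tables.
#'
#' @param model a `cri_factor_model`.
#' @param dir output directory.
#' @return Files written, invisibly.
#' @export
write_factor_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_eig <- file.path(dir, "eigenvalues.csv")
  f_load <- file.path(dir, "loadings_rotated.csv")
  eig <- data.frame(component = seq_along(model$pca$eigenvalues),
                    eigenvalue = model$pca$eigenvalues,
                    variance_explained_pct = 100 * model$pca$variance_explained,
                    random_mean = model$parallel$random_eigenvalue_means,
                    adjusted = model$parallel$adjusted_eigenvalues,
                    retained = seq_along(model$pca$eigenvalues) <=
                      model$k_retained)
  utils::write.csv(eig, f_eig, row.names = FALSE)
  load_df <- data.frame(indicator_id = rownames(model$loadings_rotated),
                        component = model$assignment$component_of,
                        as.data.frame(model$loadings_rotated))
  utils::write.csv(load_df, f_load, row.names = FALSE)
  invisible(c(f_eig, f_load))
}
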
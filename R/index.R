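#' @title Weighting and aggregation of the composite index
#' @description Indicator weights from normalised squared loadings,
#'   sub-index scores from direction-aligned percentile ranks, eigenvalue
#'   weighting of sub-indices, the composite resilience score, the
#'   unweighted BRIC-style variant, and the contribution audit.
#' @name index_builder
NULL

#' Indicator weights from rotated loadings
#'
#' Each indicator's weight is its squared rotated loading on the component
#' it was assigned to. Under the default `normalized_squared_loading` basis
#' the squared loadings are divided by their within-sub-index sum, so
#' weights sum to 1 inside every sub-index; `raw_squared_loading` keeps them
#' unnormalised.
#'
#' @param loadings_rotated p x k rotated loading matrix with indicator row
#'   names.
#' @param assignment a `cri_assignment` consistent with the loadings.
#' @param weight_basis `"normalized_squared_loading"` (default) or
#'   `"raw_squared_loading"`.
#' @return Named numeric vector of indicator weights.
#' @export
compute_indicator_weights <- function(loadings_rotated, assignment,
                                      weight_basis = c("normalized_squared_loading",
                                                       "raw_squared_loading")) {
  weight_basis <- match.arg(weight_basis)
  L <- as.matrix(loadings_rotated)
  comp <- assignment$component_of
  stopifnot(length(comp) == nrow(L), max(comp) <= ncol(L))
  w <- L[cbind(seq_len(nrow(L)), comp)]^2
  names(w) <- names(comp)
  if (weight_basis == "normalized_squared_loading") {
    for (i in unique(comp)) {
      s <- sum(w[comp == i])
      if (s == 0) {
        stop("sub-index ", i, " has zero total squared loading", call. = FALSE)
      }
      w[comp == i] <- w[comp == i] / s
    }
  }
  w
}

#' Sub-index scores from percentile ranks
#'
#' Aggregates direction-aligned percentile ranks into per-component
#' sub-index scores. `mode = "as_printed"` divides the weighted sum by the
#' member count `n_i` (the equation as published); `mode = "weighted_mean"`
#' takes the weighted sum with weights summing to 1 (the plain weighted
#' mean the accompanying text describes).
#'
#' @param ranks a `cri_rank_matrix` (or numeric matrix of ranks).
#' @param assignment a `cri_assignment`.
#' @param indicator_weights named weight vector covering every indicator.
#' @param mode `"as_printed"` (default) or `"weighted_mean"`.
#' @return Areas x components matrix of raw sub-index scores.
#' @export
compute_subindices <- function(ranks, assignment, indicator_weights,
                               mode = c("as_printed", "weighted_mean")) {
  mode <- match.arg(mode)
  X <- if (inherits(ranks, "cri_rank_matrix")) ranks$pct_ranks else as.matrix(ranks)
  if (anyNA(X)) stop("rank matrix contains missing values", call. = FALSE)
  comp <- assignment$component_of
  stopifnot(length(comp) == ncol(X))
  miss_w <- setdiff(colnames(X), names(indicator_weights))
  if (length(miss_w) > 0L) {
    stop("no weight for indicator(s): ", paste(miss_w, collapse = ", "),
         call. = FALSE)
  }
  k <- max(comp)
  out <- matrix(NA_real_, nrow = nrow(X), ncol = k,
                dimnames = list(rownames(X), paste0("SI", seq_len(k))))
  for (i in seq_len(k)) {
    members <- which(comp == i)
    if (length(members) == 0L) {
      stop("sub-index ", i, " has no member indicators", call. = FALSE)
    }
    w <- indicator_weights[colnames(X)[members]]
    s <- X[, members, drop = FALSE] %*% w
    out[, i] <- if (mode == "as_printed") s / length(members) else
      s / sum(w)
  }
  out
}

#' Composite score from weighted sub-indices
#'
#' Scales each sub-index by its weight (by default the eigenvalue of the
#' corresponding retained component) and sums across sub-indices to give
#' the composite score, recording per-area contribution shares.
#'
#' @param subindex_raw areas x components matrix from [compute_subindices()].
#' @param subindex_weights non-negative weight per component.
#' @return A `cri_index_result` list: `subindex_raw`, `subindex_weighted`,
#'   `cri`, `contributions` (per-area shares; `NA` where the composite is
#'   0), `mean_contributions`.
#' @export
compute_cri <- function(subindex_raw, subindex_weights) {
  S <- as.matrix(subindex_raw)
  stopifnot(length(subindex_weights) == ncol(S))
  if (any(subindex_weights < 0)) {
    stop("sub-index weights must be non-negative", call. = FALSE)
  }
  W <- sweep(S, 2, subindex_weights, "*")
  cri <- rowSums(W)
  contrib <- W / cri
  contrib[cri == 0, ] <- NA_real_
  structure(list(subindex_raw = S, subindex_weighted = W, cri = cri,
                 subindex_weights = subindex_weights,
                 contributions = contrib,
                 mean_contributions = colMeans(contrib, na.rm = TRUE)),
            class = "cri_index_result")
}

#' @export
print.cri_index_result <- function(x, ...) {
  cat("Composite index over", length(x$cri), "areas,",
      ncol(x$subindex_raw), "sub-indices\n")
  cat(sprintf("  mean %.1f (sd %.1f), range %.1f-%.1f\n", mean(x$cri),
              stats::sd(x$cri), min(x$cri), max(x$cri)))
  mc <- 100 * x$mean_contributions
  cat("  mean contributions (%):", paste(sprintf("%.1f", mc), collapse = ", "),
      "\n")
  invisible(x)
}

#' Unweighted BRIC-style composite
#'
#' The sensitivity variant: sub-indices are the plain means of percentile
#' ranks within each of the six BRIC domains, and the composite is their
#' unweighted sum.
#'
#' @param ranks a `cri_rank_matrix` (columns named by indicator id).
#' @param registry a `cri_registry` supplying each indicator's
#'   `bric_domain`.
#' @return A `cri_index_result` with one sub-index per BRIC domain.
#' @export
compute_bric_unweighted <- function(ranks, registry) {
  X <- if (inherits(ranks, "cri_rank_matrix")) ranks$pct_ranks else as.matrix(ranks)
  stopifnot(inherits(registry, "cri_registry"),
            identical(colnames(X), registry$id))
  doms <- unique(registry$bric_domain)
  empty <- setdiff(bric_domains, doms)
  if (length(empty) > 0L) {
    stop("BRIC domain(s) with no indicators: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  doms <- bric_domains
  S <- sapply(doms, function(d) {
    rowMeans(X[, registry$bric_domain == d, drop = FALSE])
  })
  colnames(S) <- doms
  compute_cri(S, rep(1, length(doms)))
}

#' Mean sub-index contributions
#'
#' The back-to-the-data audit: the mean over areas of each sub-index's share
#' of the composite, reported as percentages summing to 100. Areas with a
#' non-positive composite are excluded with a warning.
#'
#' @param result a `cri_index_result`.
#' @return Named numeric vector of percentages.
#' @export
audit_contributions <- function(result) {
  stopifnot(inherits(result, "cri_index_result"))
  ok <- result$cri > 0
  if (!all(ok)) {
    warning(sum(!ok), " area(s) with non-positive composite excluded from ",
            "the contribution audit", call. = FALSE)
  }
  shares <- result$subindex_weighted[ok, , drop = FALSE] /
    result$cri[ok]
  100 * colMeans(shares)
}

#' Write an index result as CSV
#'
#' One row per area: raw and weighted sub-index scores, the composite and
#' contribution shares.
#'
#' @param result a `cri_index_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_index_result <- function(result, path) {
  stopifnot(inherits(result, "cri_index_result"))
  k <- ncol(result$subindex_raw)
  out <- data.frame(area_id = rownames(result$subindex_raw))
  raw <- as.data.frame(result$subindex_raw)
  names(raw) <- paste0(colnames(result$subindex_raw), "_raw")
  wtd <- as.data.frame(result$subindex_weighted)
  names(wtd) <- paste0(colnames(result$subindex_weighted), "_weighted")
  ctr <- as.data.frame(result$contributions)
  names(ctr) <- paste0(colnames(result$contributions), "_share")
  out <- cbind(out, raw, wtd, cri = result$cri, ctr)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
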
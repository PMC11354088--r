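#' @title Imputation and normalisation
#' @description Deterministic imputation rules for the three missingness
#'   patterns found in assembled area-level datasets, z-score
#'   standardisation ahead of PCA, and direction-aligned percentile-rank
#'   transformation ahead of aggregation.
#' @name preprocess
NULL

#' Population-weighted mean
#'
#' @param values numeric vector of sub-unit values (e.g. per-capita rates).
#' @param weights non-negative populations, same length; at least one must
#'   be positive.
#' @return `sum(values * weights) / sum(weights)`.
#' @export
population_weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(weights)) {
    stop("missing values are not allowed in a population-weighted mean",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
  sum(values * weights) / sum(weights)
}

new_impute_log <- function(area_id, indicator_id, method, value) {
  data.frame(area_id = as.character(area_id),
             indicator_id = as.character(indicator_id),
             method = method, value = value, stringsAsFactors = FALSE)
}

#' Fill gaps from an upper-tier geography
#'
#' Each missing area receives the value observed for its upper-tier parent.
#' This is the broadcast reading of population-weighted upper-tier
#' imputation: for per-capita rates, constituent areas inherit the parent's
#' rate. Observed cells are never modified.
#'
#' @param column named numeric vector (names = area ids) with `NA` gaps.
#' @param upper_values named numeric vector of upper-tier values.
#' @param mapping named character vector, area id -> upper-tier id.
#' @param indicator_id label used in the imputation log.
#' @return List with `values` (completed column) and `log` (data frame of
#'   fills: area, indicator, method, value).
#' @export
impute_from_upper_tier <- function(column, upper_values, mapping,
                                   indicator_id = "indicator") {
  gaps <- which(is.na(column))
  if (length(gaps) == 0L) {
    return(list(values = column, log = new_impute_log(character(0),
                character(0), character(0), numeric(0))))
  }
  gap_ids <- names(column)[gaps]
  parents <- mapping[gap_ids]
  unmapped <- gap_ids[is.na(parents) | !(parents %in% names(upper_values))]
  if (length(unmapped) > 0L) {
    stop("no upper-tier value available for area(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  fills <- unname(upper_values[parents])
  if (anyNA(fills)) {
    stop("upper-tier value missing for area(s): ",
         paste(gap_ids[is.na(fills)], collapse = ", "), call. = FALSE)
  }
  column[gaps] <- fills
  list(values = column,
       log = new_impute_log(gap_ids, indicator_id, "upper_tier", fills))
}

#' Fill gaps from the previous year's data
#'
#' @param column named numeric vector with `NA` gaps.
#' @param prior named numeric vector of the same indicator observed the
#'   previous year; must cover every gap area.
#' @param indicator_id label used in the imputation log.
#' @return List with `values` and `log` as in [impute_from_upper_tier()].
#' @export
impute_prior_year <- function(column, prior, indicator_id = "indicator") {
  gaps <- which(is.na(column))
  if (length(gaps) == 0L) {
    return(list(values = column, log = new_impute_log(character(0),
                character(0), character(0), numeric(0))))
  }
  gap_ids <- names(column)[gaps]
  fills <- unname(prior[gap_ids])
  bad <- gap_ids[is.na(fills)]
  if (length(bad) > 0L) {
    stop("prior-year value also missing for area(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  column[gaps] <- fills
  list(values = column,
       log = new_impute_log(gap_ids, indicator_id, "prior_year", fills))
}

#' Fill gaps with peer-group means
#'
#' Each gap is filled with the arithmetic mean of the observed values of the
#' area's peer group (e.g. CIPFA nearest-neighbour groupings), excluding the
#' gap area itself.
#'
#' @param column named numeric vector with `NA` gaps.
#' @param peer_groups named list, area id -> character vector of peer area
#'   ids (or a named character vector of group labels, expanded internally).
#' @param indicator_id label used in the imputation log.
#' @return List with `values` and `log` as in [impute_from_upper_tier()].
#' @export
impute_peer_group <- function(column, peer_groups, indicator_id = "indicator") {
  gaps <- which(is.na(column))
  if (length(gaps) == 0L) {
    return(list(values = column, log = new_impute_log(character(0),
                character(0), character(0), numeric(0))))
  }
  if (!is.list(peer_groups)) {
    # group-label vector: peers of an area are the other members of its group
    labels <- peer_groups
    peer_groups <- lapply(names(labels), function(a) {
      setdiff(names(labels)[labels == labels[[a]]], a)
    })
    names(peer_groups) <- names(labels)
  }
  gap_ids <- names(column)[gaps]
  fills <- vapply(gap_ids, function(a) {
    peers <- setdiff(peer_groups[[a]], a)
    obs <- column[intersect(peers, names(column))]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) {
      stop("peer group of area ", a, " has no observed value", call. = FALSE)
    }
    mean(obs)
  }, numeric(1))
  column[gaps] <- fills
  list(values = column,
       log = new_impute_log(gap_ids, indicator_id, "peer_group",
                            unname(fills)))
}

#' Standardise indicators to z-scores
#'
#' Centres and scales every indicator column to mean 0, standard deviation 1
#' (sample sd, n-1 denominator), the normalisation applied before PCA.
#'
#' @param x a `cri_area_table` or a numeric matrix with no missing values.
#' @return A `cri_standardized` list: `z_values`, `column_means`,
#'   `column_sds`.
#' @export
standardize_indicators <- function(x) {
  values <- if (inherits(x, "cri_area_table")) x$values else as.matrix(x)
  if (anyNA(values)) {
    stop("missing values remain; run imputation before standardisation",
         call. = FALSE)
  }
  mu <- colMeans(values)
  sd_ <- apply(values, 2, stats::sd)
  zero <- which(sd_ == 0)
  if (length(zero) > 0L) {
    stop("constant indicator column(s): ",
         paste(colnames(values)[zero], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(values, 2, mu), 2, sd_, "/")
  structure(list(z_values = z, column_means = mu, column_sds = sd_),
            class = "cri_standardized")
}

#' Direction-aligned percentile ranks
#'
#' Transforms each indicator to percentile ranks in \[0, 100\], oriented so
#' that a higher rank always means a more resilience-favourable value:
#' `HIGH_GOOD` indicators are ranked ascending on their raw values,
#' `LOW_GOOD` indicators on their negated values. Ties receive the average
#' rank. The default Hazen convention, `100 * (rank - 0.5) / N`, gives every
#' tie-free column mean exactly 50; the plain convention `100 * rank / N` is
#' available for comparison.
#'
#' @param x a `cri_area_table` (directions taken from its registry) or a
#'   numeric matrix.
#' @param directions per-column direction vector, required when `x` is a
#'   bare matrix.
#' @param convention `"hazen"` (default) or `"plain"`.
#' @return A `cri_rank_matrix`: list with `pct_ranks` (areas x indicators
#'   matrix in \[0, 100\]) and `convention`.
#' @export
percentile_rank <- function(x, directions = NULL,
                            convention = c("hazen", "plain")) {
  convention <- match.arg(convention)
  if (inherits(x, "cri_area_table")) {
    values <- x$values
    directions <- x$registry$direction
  } else {
    values <- as.matrix(x)
    if (is.null(directions)) {
      stop("directions must be supplied for a bare matrix", call. = FALSE)
    }
  }
  if (anyNA(values)) {
    stop("missing values remain; run imputation before ranking",
         call. = FALSE)
  }
  stopifnot(length(directions) == ncol(values),
            all(directions %in% indicator_directions))
  n <- nrow(values)
  ranks <- matrix(NA_real_, nrow = n, ncol = ncol(values),
                  dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    v <- if (directions[j] == "LOW_GOOD") -values[, j] else values[, j]
    r <- rank(v, ties.method = "average")
    ranks[, j] <- if (convention == "hazen") 100 * (r - 0.5) / n else 100 * r / n
  }
  structure(list(pct_ranks = ranks, convention = convention),
            class = "cri_rank_matrix")
}
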
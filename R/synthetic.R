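#' @title Synthetic area data with known latent structure
#' @description Generates areas-by-indicators tables from a block latent
#'   factor model, together with area metadata (region, coastal flag,
#'   rurality, population), a nested lower-level geography, and a reference
#'   deprivation index built to be negatively associated with latent
#'   resilience. Every downstream stage of the pipeline can therefore be
#'   tested against known ground truth.
#' @name synthetic_data
NULL

#' Configuration for the synthetic generator
#'
#' Defaults emulate the shape of the English local-authority dataset the
#' pipeline targets: 307 areas, 44 indicators, five latent components,
#' primary loadings of 0.7 with 0.1 cross-loadings, nine regions, roughly a
#' fifth of areas coastal, and a log-normal population distribution with
#' median near 142,000.
#'
#' @param n_areas number of areas (default 307).
#' @param n_indicators number of indicators (default 44).
#' @param n_factors number of latent factors (default 5); each factor owns a
#'   contiguous block of indicators, block sizes differing by at most one.
#' @param loading_primary loading of an indicator on its own factor
#'   (default 0.7).
#' @param loading_cross loading on every other factor (default 0.1).
#' @param noise_sd indicator noise standard deviation; default `NULL`
#'   computes the value giving each indicator unit total variance,
#'   `sqrt(1 - loading_primary^2 - (n_factors - 1) * loading_cross^2)`.
#' @param low_good_fraction fraction of indicators whose direction is
#'   `LOW_GOOD` (default 0.5; ignored when `n_indicators == 44`, where the
#'   bundled registry's directions are used).
#' @param n_regions number of regions to cycle through (default 9).
#' @param coastal_fraction fraction of areas classified coastal
#'   (default 0.2).
#' @param rurality_fractions length-3 proportions for the three rurality
#'   classes, urban first (default `c(0.567, 0.163, 0.270)`).
#' @param lsoas_per_area lower-level units nested in each area (default 10).
#' @param deprivation_factor_weights weights of the latent factors in the
#'   deprivation construct (default all 1, so deprivation is built opposite
#'   to latent resilience).
#' @param deprivation_noise_sd noise added to the deprivation construct
#'   (default 3.3, giving a moderate rather than mirror-image negative
#'   association with resilience).
#' @param missingness character vector of missingness patterns to inject
#'   (default none); see [inject_missingness()].
#' @param seed integer seed; all randomness flows through it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_areas = 307L, n_indicators = 44L, n_factors = 5L,
                         loading_primary = 0.7, loading_cross = 0.1,
                         noise_sd = NULL, low_good_fraction = 0.5,
                         n_regions = 9L, coastal_fraction = 0.2,
                         rurality_fractions = c(0.567, 0.163, 0.270),
                         lsoas_per_area = 10L,
                         deprivation_factor_weights = rep(1, n_factors),
                         deprivation_noise_sd = 3.3,
                         missingness = character(0),
                         seed = 1L) {
  if (n_factors > n_indicators) {
    stop("n_factors (", n_factors, ") exceeds n_indicators (", n_indicators,
         ")", call. = FALSE)
  }
  stopifnot(n_areas >= 2, n_factors >= 1,
            loading_primary > 0, loading_primary < 1,
            loading_cross >= 0,
            low_good_fraction >= 0, low_good_fraction <= 1,
            coastal_fraction >= 0, coastal_fraction <= 1,
            n_regions >= 1, n_regions <= length(english_regions),
            lsoas_per_area >= 1,
            length(rurality_fractions) == 3L,
            all(rurality_fractions >= 0),
            length(deprivation_factor_weights) == n_factors,
            deprivation_noise_sd > 0)
  if (is.null(noise_sd)) {
    v <- 1 - loading_primary^2 - (n_factors - 1) * loading_cross^2
    if (v <= 0) {
      stop("loadings imply non-positive noise variance; lower ",
           "loading_primary or loading_cross", call. = FALSE)
    }
    noise_sd <- sqrt(v)
  }
  stopifnot(noise_sd > 0)
  structure(list(n_areas = as.integer(n_areas),
                 n_indicators = as.integer(n_indicators),
                 n_factors = as.integer(n_factors),
                 loading_primary = loading_primary,
                 loading_cross = loading_cross,
                 noise_sd = noise_sd,
                 low_good_fraction = low_good_fraction,
                 n_regions = as.integer(n_regions),
                 coastal_fraction = coastal_fraction,
                 rurality_fractions = rurality_fractions / sum(rurality_fractions),
                 lsoas_per_area = as.integer(lsoas_per_area),
                 deprivation_factor_weights = deprivation_factor_weights,
                 deprivation_noise_sd = deprivation_noise_sd,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# contiguous blocks of indicators per factor, sizes differing by <= 1
block_sizes <- function(p, k) {
  base <- p %/% k
  sizes <- rep(base, k)
  extra <- p %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a synthetic area table with known truth
#'
#' Indicator values are `factor_scores %*% t(loadings) + noise`; indicators
#' flagged `LOW_GOOD` are negated after generation so that their raw values
#' run against resilience, mirroring real direction-mixed indicator sets.
#' The reference deprivation index is the rank (1 = least deprived) of a
#' negatively-weighted combination of the factor scores plus noise, so it is
#' negatively associated with latent resilience by construction.
#'
#' @param config a [synth_config()].
#' @return A `cri_synthesis` list with elements:
#'   \describe{
#'     \item{table}{`cri_area_table` of generated values and metadata.}
#'     \item{truth}{factor scores, loading matrix, block assignment,
#'       per-area latent resilience (equal-weight factor-score sum) and true
#'       directions.}
#'     \item{reference}{data frame `area_id`, `reference_rank` (higher rank
#'       = more deprived).}
#'     \item{lsoas}{nested lower-level table: `lsoa_id`, `area_id`,
#'       `population`, `coastal`.}
#'   }
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_areas
  p <- config$n_indicators
  k <- config$n_factors
  set.seed(config$seed)

  sizes <- block_sizes(p, k)
  block <- rep(seq_len(k), times = sizes)
  loadings <- matrix(config$loading_cross, nrow = p, ncol = k)
  loadings[cbind(seq_len(p), block)] <- config$loading_primary

  scores <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
  noise <- matrix(stats::rnorm(n * p, sd = config$noise_sd), nrow = n, ncol = p)
  values <- scores %*% t(loadings) + noise

  if (p == 44L) {
    registry <- default_registry()
  } else {
    n_low <- round(config$low_good_fraction * p)
    dirs <- rep("HIGH_GOOD", p)
    if (n_low > 0L) dirs[sample.int(p, n_low)] <- "LOW_GOOD"
    registry <- cri_registry(data.frame(
      id = sprintf("ind%02d", seq_len(p)),
      name = sprintf("Synthetic indicator %d", seq_len(p)),
      theme = "Synthetic",
      bric_domain = bric_domains[(seq_len(p) - 1L) %% 6L + 1L],
      direction = dirs,
      source = "synthetic", year = "n/a",
      stringsAsFactors = FALSE))
  }
  low <- registry$direction == "LOW_GOOD"
  values[, low] <- -values[, low]
  colnames(values) <- registry$id

  area_id <- sprintf("A%03d", seq_len(n))
  region <- english_regions[(seq_len(n) - 1L) %% config$n_regions + 1L]
  n_coastal <- round(config$coastal_fraction * n)
  coastal <- rep(FALSE, n)
  if (n_coastal > 0L) coastal[sample.int(n, n_coastal)] <- TRUE
  rurality <- sample(rurality_levels, n, replace = TRUE,
                     prob = config$rurality_fractions)
  # log-normal population, median ~ 142k, IQR ratio matching ~103.9k-225.3k
  population <- round(stats::rlnorm(n, meanlog = log(142000), sdlog = 0.574))
  upper_tier_id <- paste0("UT", sprintf("%03d", (seq_len(n) - 1L) %/% 2L + 1L))
  peer_group <- paste0("PG", sprintf("%02d", (seq_len(n) - 1L) %% ceiling(n / 15) + 1L))
  areas <- data.frame(area_id = area_id, name = paste("Area", seq_len(n)),
                      region = region, coastal = coastal, rurality = rurality,
                      population = population, upper_tier_id = upper_tier_id,
                      peer_group = peer_group, stringsAsFactors = FALSE)

  # nested lower-level units: population shares via normalised gamma draws;
  # coastal areas get a clear majority of coastal population, inland a minority
  m <- config$lsoas_per_area
  shares <- matrix(stats::rgamma(n * m, shape = 5), nrow = n)
  shares <- shares / rowSums(shares)
  lsoa_pop <- round(shares * population)
  coastal_prob <- ifelse(coastal, 0.75, 0.08)
  lsoa_flags <- matrix(stats::runif(n * m) < rep(coastal_prob, m), nrow = n)
  lsoas <- data.frame(
    lsoa_id = paste0(rep(area_id, each = m), "L", sprintf("%02d", seq_len(m))),
    area_id = rep(area_id, each = m),
    population = as.vector(t(lsoa_pop)),
    coastal = as.vector(t(lsoa_flags)),
    stringsAsFactors = FALSE)

  latent_resilience <- rowSums(scores)
  dep_latent <- -drop(scores %*% config$deprivation_factor_weights) +
    stats::rnorm(n, sd = config$deprivation_noise_sd)
  reference <- data.frame(area_id = area_id,
                          reference_rank = rank(dep_latent, ties.method = "first"),
                          stringsAsFactors = FALSE)

  truth <- list(factor_scores = scores,
                loading_matrix = loadings,
                block_assignment = block,
                latent_resilience = latent_resilience,
                true_directions = registry$direction)

  structure(list(table = area_table(values, areas, registry),
                 truth = truth, reference = reference, lsoas = lsoas,
                 config = config),
            class = "cri_synthesis")
}

#' @export
print.cri_synthesis <- function(x, ...) {
  cat("Synthetic dataset:", x$config$n_areas, "areas x",
      x$config$n_indicators, "indicators,", x$config$n_factors,
      "latent factors (seed", paste0(x$config$seed, ")\n"))
  invisible(x)
}

#' Inject a missingness pattern into an area table
#'
#' Reproduces the three missingness patterns the imputation rules address:
#' \describe{
#'   \item{`upper_tier_only`}{entire indicator columns observed only at the
#'     upper-tier level; all area cells are blanked and a companion
#'     upper-tier table (population-weighted means of the true values) is
#'     emitted.}
#'   \item{`prior_year_gap`}{a few areas missing in one indicator column,
#'     with a complete prior-year column emitted.}
#'   \item{`peer_group_gap`}{a few areas missing in one indicator column, to
#'     be filled from peer-group means.}
#' }
#'
#' @param table a `cri_area_table`.
#' @param pattern one of `"upper_tier_only"`, `"prior_year_gap"`,
#'   `"peer_group_gap"`, or a zero-length vector for the identity.
#' @param n_indicators columns affected by `upper_tier_only` (default 2).
#' @param n_areas cells blanked for the gap patterns (defaults: 3 for
#'   `prior_year_gap`, 2 for `peer_group_gap`).
#' @param seed integer seed controlling which cells are blanked.
#' @return List with elements `table` (the blanked copy), `manifest` (data
#'   frame of `area_id`, `indicator_id`, `pattern`), and pattern-specific
#'   extras: `upper_values` + `mapping` for `upper_tier_only`, `prior` (a
#'   complete prior-year column, named vector) for `prior_year_gap`.
#' @export
inject_missingness <- function(table, pattern, n_indicators = 2L,
                               n_areas = NULL, seed = 1L) {
  stopifnot(inherits(table, "cri_area_table"))
  if (length(pattern) == 0L) {
    return(list(table = table,
                manifest = data.frame(area_id = character(0),
                                      indicator_id = character(0),
                                      pattern = character(0))))
  }
  pattern <- match.arg(pattern,
                       c("upper_tier_only", "prior_year_gap", "peer_group_gap"))
  set.seed(seed)
  values <- table$values
  ids <- table$areas$area_id

  if (pattern == "upper_tier_only") {
    cols <- sort(sample.int(ncol(values), n_indicators))
    col_ids <- colnames(values)[cols]
    ut <- table$areas$upper_tier_id
    if (is.null(ut)) stop("area metadata lacks upper_tier_id", call. = FALSE)
    pop <- table$areas$population
    upper_values <- lapply(col_ids, function(cid) {
      tapply(seq_along(ids), ut, function(idx) {
        population_weighted_mean(values[idx, cid], pop[idx])
      })
    })
    names(upper_values) <- col_ids
    manifest <- data.frame(area_id = rep(ids, times = length(col_ids)),
                           indicator_id = rep(col_ids, each = length(ids)),
                           pattern = pattern, stringsAsFactors = FALSE)
    values[, cols] <- NA_real_
    out <- table
    out$values <- values
    return(list(table = out, manifest = manifest,
                upper_values = upper_values,
                mapping = stats::setNames(ut, ids)))
  }

  n_gap <- if (is.null(n_areas)) {
    if (pattern == "prior_year_gap") 3L else 2L
  } else as.integer(n_areas)
  col <- sample.int(ncol(values), 1L)
  col_id <- colnames(values)[col]
  rows <- sort(sample.int(nrow(values), n_gap))
  manifest <- data.frame(area_id = ids[rows], indicator_id = col_id,
                         pattern = pattern, stringsAsFactors = FALSE)
  extras <- list()
  if (pattern == "prior_year_gap") {
    # prior-year column: the same quantity observed a year earlier; the
    # generator has no temporal drift, so the true values stand in for it
    extras$prior <- stats::setNames(values[, col], ids)
  }
  values[rows, col] <- NA_real_
  out <- table
  out$values <- values
  c(list(table = out, manifest = manifest), extras)
}

#' Write the components of a synthesis to CSV files
#'
#' @param synthesis a `cri_synthesis`.
#' @param dir output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_synthesis <- function(synthesis, dir) {
  stopifnot(inherits(synthesis, "cri_synthesis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_table <- file.path(dir, "area_table.csv")
  f_reg <- file.path(dir, "registry.csv")
  f_truth <- file.path(dir, "truth.csv")
  f_ref <- file.path(dir, "reference_index.csv")
  f_lsoa <- file.path(dir, "lsoas.csv")
  write_area_table(synthesis$table, f_table)
  write_registry(synthesis$table$registry, f_reg)
  truth_df <- data.frame(indicator_id = synthesis$table$registry$id,
                         block = synthesis$truth$block_assignment,
                         direction = synthesis$truth$true_directions)
  utils::write.csv(truth_df, f_truth, row.names = FALSE)
  utils::write.csv(synthesis$reference, f_ref, row.names = FALSE)
  utils::write.csv(synthesis$lsoas, f_lsoa, row.names = FALSE)
  invisible(c(f_table, f_reg, f_truth, f_ref, f_lsoa))
}
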
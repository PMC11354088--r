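#' @title Geographic comparison, validation and sensitivity analysis
#' @description North/South, coastal/inland and urban/rural comparisons of
#'   composite scores via t-tests and one-way ANOVA; validation against a
#'   reference deprivation index by correlation and predicted-vs-actual
#'   regression outliers; Spearman comparison of weighted and unweighted
#'   composites; and standard-deviation map binning.
#' @name evaluation
NULL

northern_regions <- c("North East", "North West", "Yorkshire and The Humber")

#' Is a region in the North of England?
#'
#' The North comprises the North East, North West, and Yorkshire and The
#' Humber.
#'
#' @param region_label one or more of the nine English region labels.
#' @return Logical vector.
#' @export
classify_north <- function(region_label) {
  bad <- setdiff(unique(region_label), english_regions)
  if (length(bad) > 0L) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  region_label %in% northern_regions
}

#' Coastal classification from nested lower-level units
#'
#' An area is coastal if strictly more than half of its population lives in
#' coastal lower-level units; a share of exactly one half is inland.
#'
#' @param lsoa_populations non-negative populations of the units, not all
#'   zero.
#' @param lsoa_coastal_flags logical flags, same length.
#' @return `TRUE` if the coastal population share exceeds 0.5.
#' @export
classify_coastal <- function(lsoa_populations, lsoa_coastal_flags) {
  stopifnot(length(lsoa_populations) == length(lsoa_coastal_flags),
            length(lsoa_populations) >= 1L)
  if (any(lsoa_populations < 0)) {
    stop("populations must be non-negative", call. = FALSE)
  }
  total <- sum(lsoa_populations)
  if (total == 0) stop("total population is zero", call. = FALSE)
  sum(lsoa_populations[lsoa_coastal_flags]) / total > 0.5
}

group_stats <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             mean = vapply(groups, mean, numeric(1)),
             sd = vapply(groups, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample t-test
#'
#' Pooled-variance two-sided t-test by default (Welch optional). Two
#' degenerate identical constant groups report `t = 0, p = 1` rather than
#' erroring.
#'
#' @param values_a,values_b numeric vectors, each of length at least 2.
#' @param welch use the Welch unequal-variance test?
#' @param group_names length-2 labels for the report.
#' @return A `cri_group_comparison` list: `group_stats`, `statistic`,
#'   `p_value`, `test`, `df`.
#' @export
two_group_test <- function(values_a, values_b, welch = FALSE,
                           group_names = c("A", "B")) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  n1 <- length(values_a); n2 <- length(values_b)
  v1 <- stats::var(values_a); v2 <- stats::var(values_b)
  if (v1 == 0 && v2 == 0 && mean(values_a) == mean(values_b)) {
    t_stat <- 0; df <- n1 + n2 - 2; p <- 1
  } else if (welch) {
    se2 <- v1 / n1 + v2 / n2
    t_stat <- (mean(values_a) - mean(values_b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t_stat <- (mean(values_a) - mean(values_b)) /
      sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  gl <- stats::setNames(list(values_a, values_b), group_names)
  structure(list(group_stats = group_stats(gl), statistic = t_stat,
                 df = df, p_value = p,
                 test = if (welch) "welch_t_test" else "t_test"),
            class = "cri_group_comparison")
}

#' One-way analysis of variance
#'
#' @param groups named list of numeric vectors (at least two groups; total
#'   observations must exceed the number of groups).
#' @return A `cri_group_comparison` with the F statistic, degrees of
#'   freedom and p-value. All-identical values give `F = 0, p = 1`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  sizes <- lengths(groups)
  stopifnot(all(sizes >= 1L))
  n <- sum(sizes)
  g <- length(groups)
  stopifnot(n > g)
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  ss_between <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  df1 <- g - 1L; df2 <- n - g
  if (ss_within == 0 && ss_between == 0) {
    f_stat <- 0; p <- 1
  } else {
    f_stat <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(group_stats = group_stats(groups), statistic = f_stat,
                 df = c(df1, df2), p_value = p, test = "anova"),
            class = "cri_group_comparison")
}

#' @export
print.cri_group_comparison <- function(x, ...) {
  cat(x$test, ": statistic ", sprintf("%.3f", x$statistic),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Geographic comparison report
#'
#' Runs the standard set of comparisons on a per-area score: one-way ANOVA
#' across regions and across rurality classes, and t-tests for
#' North-vs-rest and coastal-vs-inland.
#'
#' @param score named numeric vector of per-area scores.
#' @param areas area metadata data frame with `area_id`, `region`,
#'   `coastal`, `rurality`.
#' @param welch use Welch t-tests?
#' @return Named list of `cri_group_comparison` objects (`region`,
#'   `north_south`, `coastal_inland`, `urban_rural`).
#' @export
compare_geography <- function(score, areas, welch = FALSE) {
  stopifnot(!is.null(names(score)))
  areas <- areas[match(names(score), areas$area_id), ]
  north <- classify_north(areas$region)
  list(
    region = anova_oneway(split(score, areas$region)),
    north_south = two_group_test(score[north], score[!north], welch = welch,
                                 group_names = c("North", "Midlands and South")),
    coastal_inland = two_group_test(score[areas$coastal],
                                    score[!areas$coastal], welch = welch,
                                    group_names = c("Coastal", "Inland")),
    urban_rural = anova_oneway(split(score,
                                     factor(areas$rurality,
                                            levels = rurality_levels)))
  )
}

#' Validate a composite against a reference deprivation index
#'
#' Reports the Pearson correlation of the rank-transformed composite with
#' the reference rank (equivalently Spearman's rho, also reported), fits an
#' ordinary least-squares regression of the composite on the reference rank
#' and lists the largest positive and negative residual outliers.
#'
#' @param cri named numeric per-area composite scores.
#' @param reference_rank named numeric per-area reference ranks (higher =
#'   more deprived), same areas.
#' @param n_outliers outliers reported per sign (default 10).
#' @return A `cri_validation` list: `pearson_r` (on ranks), `spearman_rho`,
#'   `pearson_r_raw`, `slope`, `intercept`, `predicted`, `residuals`,
#'   `top_positive`, `top_negative`.
#' @export
validate_against_reference <- function(cri, reference_rank, n_outliers = 10L) {
  stopifnot(!is.null(names(cri)), !is.null(names(reference_rank)))
  common <- intersect(names(cri), names(reference_rank))
  if (length(common) < 3L) stop("need at least 3 common areas", call. = FALSE)
  cri <- cri[common]; ref <- reference_rank[common]
  if (stats::sd(cri) == 0) {
    stop("composite is constant; correlation undefined", call. = FALSE)
  }
  r_rank <- stats::cor(rank(cri), rank(ref))
  rho <- stats::cor(cri, ref, method = "spearman")
  fit <- stats::lm.fit(cbind(1, ref), cri)
  predicted <- stats::setNames(drop(cbind(1, ref) %*% fit$coefficients),
                               common)
  resid <- cri - predicted
  # residuals at numerical-noise scale are not outliers
  eps <- 1e-8 * max(1, max(abs(cri)))
  ord <- order(resid, decreasing = TRUE)
  top_pos <- utils::head(common[ord][resid[ord] > eps], n_outliers)
  ord_neg <- order(resid)
  top_neg <- utils::head(common[ord_neg][resid[ord_neg] < -eps], n_outliers)
  structure(list(pearson_r = r_rank, spearman_rho = rho,
                 pearson_r_raw = stats::cor(cri, ref),
                 slope = fit$coefficients[2], intercept = fit$coefficients[1],
                 predicted = predicted, residuals = resid,
                 top_positive = top_pos, top_negative = top_neg),
            class = "cri_validation")
}

#' @export
print.cri_validation <- function(x, ...) {
  cat(sprintf("Validation vs reference index: r (ranked) %.3f, Spearman %.3f\n",
              x$pearson_r, x$spearman_rho))
  cat("  top positive outliers:", paste(x$top_positive, collapse = ", "), "\n")
  cat("  top negative outliers:", paste(x$top_negative, collapse = ", "), "\n")
  invisible(x)
}

#' Compare weighted and unweighted composites
#'
#' Spearman rank correlation of the two composites plus per-region mean and
#' sd of the area ranks under each (rank 1 = least resilient).
#'
#' @param weighted,unweighted `cri_index_result` objects over the same
#'   areas.
#' @param areas area metadata with `area_id` and `region` (optional; region
#'   summary omitted when absent).
#' @return List with `spearman_rho` and `region_ranks` data frame.
#' @export
sensitivity_compare <- function(weighted, unweighted, areas = NULL) {
  w <- weighted$cri; u <- unweighted$cri
  stopifnot(length(w) == length(u))
  rho <- stats::cor(w, u, method = "spearman")
  region_ranks <- NULL
  if (!is.null(areas)) {
    ids <- rownames(weighted$subindex_raw)
    region <- areas$region[match(ids, areas$area_id)]
    rw <- rank(w); ru <- rank(u)
    region_ranks <- do.call(rbind, lapply(split(seq_along(ids), region),
      function(idx) {
        data.frame(region = region[idx[1]], n = length(idx),
                   weighted_mean_rank = mean(rw[idx]),
                   weighted_sd_rank = stats::sd(rw[idx]),
                   unweighted_mean_rank = mean(ru[idx]),
                   unweighted_sd_rank = stats::sd(ru[idx]))
      }))
    rownames(region_ranks) <- NULL
  }
  list(spearman_rho = rho, region_ranks = region_ranks)
}

#' Standard-deviation map bins
#'
#' Converts per-area values to z-scores and bins them at -2, -1, 0, 1 and 2
#' standard deviations from the mean (left-closed bins: a z-score of
#' exactly 0 falls in `[0,1)`).
#'
#' @param values numeric per-area values with positive spread.
#' @return Factor of bin labels, one per area, levels ordered from lowest
#'   to highest.
#' @export
map_bins <- function(values) {
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    stop("values are constant; standard-deviation bins undefined",
         call. = FALSE)
  }
  z <- (values - mean(values)) / s
  labels <- c("< -2 SD", "-2 to -1 SD", "-1 to 0 SD", "0 to 1 SD",
              "1 to 2 SD", "> 2 SD")
  idx <- findInterval(z, c(-2, -1, 0, 1, 2)) + 1L
  out <- factor(labels[idx], levels = labels)
  names(out) <- names(values)
  out
}

#' Attach per-area properties to a GeoJSON FeatureCollection
#'
#' Reads a GeoJSON file, matches features to areas via a feature property
#' holding the area id, attaches the supplied values (e.g. composite scores
#' or [map_bins()] labels) as a property, and writes the result.
#'
#' @param geojson_path input GeoJSON FeatureCollection.
#' @param values named per-area vector.
#' @param property property name to attach (default `"cri"`).
#' @param id_property feature property holding the area id (default
#'   `"area_id"`).
#' @param out_path output path (defaults to overwriting the input).
#' @return `out_path`, invisibly.
#' @export
attach_geojson_property <- function(geojson_path, values, property = "cri",
                                    id_property = "area_id",
                                    out_path = geojson_path) {
  gj <- jsonlite::read_json(geojson_path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  gj$features <- lapply(gj$features, function(feat) {
    aid <- feat$properties[[id_property]]
    if (!is.null(aid) && aid %in% names(values)) {
      v <- values[[aid]]
      feat$properties[[property]] <- if (is.factor(v)) as.character(v) else v
    }
    feat
  })
  jsonlite::write_json(gj, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out_path)
}
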
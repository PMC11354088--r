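#' @title Indicator registry and area tables
#' @description Core data model: per-indicator metadata (theme, BRIC domain,
#'   direction), per-area metadata (region, coastal flag, rurality,
#'   population) and the areas-by-indicators value matrix that the rest of
#'   the pipeline consumes.
#' @name registry
NULL

#' Enumerated vocabularies
#'
#' Fixed vocabularies used for validation throughout the package: the six
#' BRIC resilience domains, the nine English regions, the three rurality
#' classes and the two indicator directions.
#'
#' @format Character vectors.
#' @export
bric_domains <- c("social", "economic", "institutional", "infrastructure",
                  "environmental", "community_capital")

#' @rdname bric_domains
#' @export
english_regions <- c("East Midlands", "East of England", "London",
                     "North East", "North West", "South East", "South West",
                     "West Midlands", "Yorkshire and The Humber")

#' @rdname bric_domains
#' @export
rurality_levels <- c("predominantly_urban", "urban_with_significant_rural",
                     "predominantly_rural")

#' @rdname bric_domains
#' @export
indicator_directions <- c("HIGH_GOOD", "LOW_GOOD")

#' Construct and validate an indicator registry
#'
#' A registry is a data frame with one row per indicator and columns
#' `id`, `name`, `theme`, `bric_domain`, `direction`, `source`, `year`.
#' Ids must be unique, `direction` must be `"HIGH_GOOD"` or `"LOW_GOOD"`,
#' and `bric_domain` one of the six BRIC domains.
#'
#' @param df data frame of indicator metadata.
#' @return A `cri_registry` object (a validated data frame).
#' @export
cri_registry <- function(df) {
  required <- c("id", "bric_domain", "direction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("registry is empty: at least one indicator is required",
         call. = FALSE)
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0L) {
    stop("duplicate indicator id(s) in registry: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_dir <- unique(df$direction[!df$direction %in% indicator_directions])
  if (length(bad_dir) > 0L) {
    stop("unknown direction token(s): ", paste(bad_dir, collapse = ", "),
         "; expected one of ", paste(indicator_directions, collapse = ", "),
         call. = FALSE)
  }
  bad_dom <- unique(df$bric_domain[!df$bric_domain %in% bric_domains])
  if (length(bad_dom) > 0L) {
    stop("unknown bric_domain value(s): ", paste(bad_dom, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("name", "theme", "source", "year")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("cri_registry", "data.frame")
  df
}

#' Read an indicator registry from CSV
#'
#' @param path path to a CSV with the registry columns, one row per
#'   indicator; file order is preserved.
#' @return A validated [cri_registry()].
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) {
    stop("registry file ", path, " contains no indicator rows",
         call. = FALSE)
  }
  cri_registry(df)
}

#' Write an indicator registry to CSV
#'
#' @param registry a `cri_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
  invisible(path)
}

#' The bundled 44-indicator registry
#'
#' Loads the package's built-in registry of 44 indicators spanning the six
#' BRIC domains (10 social, 12 economic, 6 institutional, 5 infrastructure,
#' 3 environmental, 8 community capital), transcribed from the published
#' indicator set for English local authority districts.
#'
#' @return A `cri_registry` of 44 indicators.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "indicator_registry.csv",
                      package = "cribuild", mustWork = TRUE)
  read_registry(path)
}

#' @export
print.cri_registry <- function(x, ...) {
  cat("Indicator registry:", nrow(x), "indicators\n")
  tab <- table(factor(x$bric_domain, levels = bric_domains))
  for (d in names(tab)) cat(sprintf("  %-18s %d\n", d, tab[[d]]))
  invisible(x)
}

#' Construct an area table
#'
#' Bundles the numeric areas-by-indicators matrix with per-area metadata and
#' the indicator registry. Missing values are represented as `NA`.
#'
#' @param values numeric matrix, one row per area, one column per indicator;
#'   column names must match registry ids (set from the registry if absent).
#' @param areas data frame of area metadata with at least `area_id`;
#'   optional columns: `name`, `region`, `coastal`, `rurality`,
#'   `population`, `upper_tier_id`, `peer_group`.
#' @param registry a `cri_registry` describing the columns of `values`.
#' @return A `cri_area_table` object: list with elements `values`, `areas`,
#'   `registry`.
#' @export
area_table <- function(values, areas, registry) {
  registry <- if (inherits(registry, "cri_registry")) registry else cri_registry(registry)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  areas <- as.data.frame(areas, stringsAsFactors = FALSE)
  if (is.null(areas$area_id)) stop("area metadata must have an area_id column",
                                   call. = FALSE)
  areas$area_id <- as.character(areas$area_id)
  if (anyDuplicated(areas$area_id)) {
    stop("duplicate area_id(s): ",
         paste(unique(areas$area_id[duplicated(areas$area_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(values) != nrow(areas)) {
    stop("value matrix has ", nrow(values), " rows but ", nrow(areas),
         " areas", call. = FALSE)
  }
  if (ncol(values) != nrow(registry)) {
    stop("value matrix has ", ncol(values), " columns but registry lists ",
         nrow(registry), " indicators", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- registry$id
  } else if (!identical(colnames(values), registry$id)) {
    stop("value matrix column names do not match registry ids", call. = FALSE)
  }
  rownames(values) <- areas$area_id
  if (!is.null(areas$population) && any(areas$population < 0, na.rm = TRUE)) {
    stop("population must be non-negative", call. = FALSE)
  }
  if (!is.null(areas$rurality)) {
    bad <- setdiff(stats::na.omit(unique(areas$rurality)), rurality_levels)
    if (length(bad) > 0L) {
      stop("unknown rurality class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(areas$region)) {
    bad <- setdiff(stats::na.omit(unique(areas$region)), english_regions)
    if (length(bad) > 0L) {
      stop("unknown region label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(values = values, areas = areas, registry = registry),
            class = "cri_area_table")
}

#' @export
print.cri_area_table <- function(x, ...) {
  cat("Area table:", nrow(x$values), "areas x", ncol(x$values),
      "indicators\n")
  n_na <- sum(is.na(x$values))
  if (n_na > 0L) cat("  missing cells:", n_na, "\n")
  invisible(x)
}

#' Drop named areas from an area table
#'
#' Removes the listed areas (e.g. very small districts excluded from index
#' construction), preserving the order of the remaining areas.
#'
#' @param table a `cri_area_table`.
#' @param excluded_ids character vector of area ids to drop.
#' @param strict if `TRUE` (default), an id not present in the table is an
#'   error; if `FALSE`, unknown ids are skipped with a warning.
#' @return The reduced `cri_area_table`.
#' @export
apply_exclusions <- function(table, excluded_ids, strict = TRUE) {
  stopifnot(inherits(table, "cri_area_table"))
  excluded_ids <- as.character(excluded_ids)
  if (length(excluded_ids) == 0L) return(table)
  unknown <- setdiff(excluded_ids, table$areas$area_id)
  if (length(unknown) > 0L) {
    if (strict) {
      stop("cannot exclude unknown area id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    warning("skipping unknown area id(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    excluded_ids <- setdiff(excluded_ids, unknown)
  }
  keep <- !table$areas$area_id %in% excluded_ids
  if (!any(keep)) stop("exclusions would remove every area", call. = FALSE)
  area_table(table$values[keep, , drop = FALSE],
             table$areas[keep, , drop = FALSE],
             table$registry)
}

#' Observations-per-variable admissibility check
#'
#' PCA guidance calls for 5 to 10 observations per variable. Given the
#' number of areas, the admissible indicator count lies between
#' `ceiling(n_areas / max_obs_per_var)` and `floor(n_areas / min_obs_per_var)`;
#' with 307 areas this yields the range 31 to 61.
#'
#' @param n_areas number of areas (observations).
#' @param n_indicators number of indicators (variables).
#' @param min_obs_per_var,max_obs_per_var bounds of the
#'   observations-per-variable rule (defaults 5 and 10).
#' @return List with `lower`, `upper` and logical `within`.
#' @export
check_indicator_count <- function(n_areas, n_indicators,
                                  min_obs_per_var = 5L,
                                  max_obs_per_var = 10L) {
  stopifnot(n_areas > 0, n_indicators > 0,
            min_obs_per_var > 0, max_obs_per_var > 0)
  lower <- as.integer(ceiling(n_areas / max_obs_per_var))
  upper <- as.integer(floor(n_areas / min_obs_per_var))
  list(lower = lower, upper = upper,
       within = n_indicators >= lower && n_indicators <= upper)
}

#' Read / write an area table as CSV
#'
#' The CSV has the area metadata columns first, then one column per
#' indicator id; missing values are empty cells.
#'
#' @param table a `cri_area_table`.
#' @param path file path.
#' @param registry registry describing the indicator columns (for reading).
#' @return `write_area_table` returns `path` invisibly; `read_area_table`
#'   returns a `cri_area_table`.
#' @export
write_area_table <- function(table, path) {
  stopifnot(inherits(table, "cri_area_table"))
  out <- cbind(table$areas, as.data.frame(table$values))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_area_table
#' @export
read_area_table <- function(path, registry) {
  registry <- if (inherits(registry, "cri_registry")) registry else cri_registry(registry)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_ind <- setdiff(registry$id, names(df))
  if (length(missing_ind) > 0L) {
    stop("area table file lacks indicator column(s): ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  }
  meta_cols <- setdiff(names(df), registry$id)
  values <- as.matrix(df[, registry$id, drop = FALSE])
  area_table(values, df[, meta_cols, drop = FALSE], registry)
}
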
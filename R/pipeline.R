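#' @title Pipeline configuration, orchestration and command line
#' @description Ties the stages together in the canonical order: impute,
#'   standardise, suitability tests, PCA, parallel analysis, varimax,
#'   assignment, weighting, aggregation, unweighted variant, contribution
#'   audit, geographic comparison and validation, writing CSV reports and a
#'   JSON run manifest.
#' @name cli_io
NULL

#' Pipeline configuration
#'
#' All tunables in one validated object. Every enumerated field is checked
#' here so a bad configuration fails before any computation.
#'
#' @param percentile_convention `"hazen"` or `"plain"`.
#' @param varimax_normalize Kaiser row-normalisation during rotation?
#' @param pa_reps parallel-analysis replicates (default 1000).
#' @param pa_quantile `NULL` for mean random eigenvalues, or a probability.
#' @param weight_mode `"as_printed"` or `"weighted_mean"` sub-index
#'   aggregation.
#' @param weight_basis `"normalized_squared_loading"` or
#'   `"raw_squared_loading"`.
#' @param subindex_weight_source `"eigenvalues"` (unrotated eigenvalues of
#'   the retained components) or `"rotated_ssq"` (sums of squared rotated
#'   loadings).
#' @param welch Welch t-tests instead of pooled?
#' @param n_outliers validation outliers per sign.
#' @param exclusions area ids dropped before analysis.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir directory for output artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(percentile_convention = "hazen",
                            varimax_normalize = FALSE,
                            pa_reps = 1000L, pa_quantile = NULL,
                            weight_mode = "as_printed",
                            weight_basis = "normalized_squared_loading",
                            subindex_weight_source = "eigenvalues",
                            welch = FALSE, n_outliers = 10L,
                            exclusions = character(0),
                            seed = 1L, out_dir = NULL) {
  match.arg(percentile_convention, c("hazen", "plain"))
  match.arg(weight_mode, c("as_printed", "weighted_mean"))
  match.arg(weight_basis,
            c("normalized_squared_loading", "raw_squared_loading"))
  match.arg(subindex_weight_source, c("eigenvalues", "rotated_ssq"))
  stopifnot(is.logical(varimax_normalize), is.logical(welch),
            pa_reps >= 1, n_outliers >= 0,
            is.null(pa_quantile) ||
              (pa_quantile > 0 && pa_quantile < 1))
  structure(list(percentile_convention = percentile_convention,
                 varimax_normalize = varimax_normalize,
                 pa_reps = as.integer(pa_reps), pa_quantile = pa_quantile,
                 weight_mode = weight_mode, weight_basis = weight_basis,
                 subindex_weight_source = subindex_weight_source,
                 welch = welch, n_outliers = as.integer(n_outliers),
                 exclusions = exclusions,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields are [pipeline_config()] arguments;
#'   unknown fields are rejected.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full index-construction pipeline
#'
#' Executes, in order: exclusions, imputation of any remaining gaps from
#' peer-group means (the other two imputation rules require companion
#' inputs and are applied upstream via [impute_from_upper_tier()] /
#' [impute_prior_year()]), standardisation, suitability tests, PCA, parallel
#' analysis, varimax rotation of the retained components, max-loading
#' assignment, weighting, aggregation, the unweighted BRIC-style variant,
#' the contribution audit, geographic comparisons, and (when a reference
#' index is supplied) validation. If `config$out_dir` is set, all reports
#' are written as CSV along with a JSON run manifest sufficient to
#' reproduce the run.
#'
#' @param table a `cri_area_table`.
#' @param config a [pipeline_config()].
#' @param reference optional data frame with `area_id` and `reference_rank`.
#' @return A `cri_pipeline_result` list: `model`, `ranks`, `weights`,
#'   `index`, `bric`, `contribution_audit`, `geo`, `validation`,
#'   `sensitivity`, `imputation_log`, `manifest`.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         reference = NULL) {
  stopifnot(inherits(table, "cri_area_table"),
            inherits(config, "pipeline_config"))
  stage <- "exclusions"
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0("[", stage, "] ", ...))
  }
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (length(config$exclusions) > 0L) {
    table <- wrap(apply_exclusions(table, config$exclusions))
  }
  note(nrow(table$values), " areas retained")

  stage <- "imputation"
  impute_log <- new_impute_log(character(0), character(0), character(0),
                               numeric(0))
  if (anyNA(table$values)) {
    if (is.null(table$areas$peer_group)) {
      stop("pipeline stage 'imputation' failed: gaps remain but no ",
           "peer_group metadata is available", call. = FALSE)
    }
    pg <- stats::setNames(table$areas$peer_group, table$areas$area_id)
    for (j in which(colSums(is.na(table$values)) > 0)) {
      cid <- colnames(table$values)[j]
      res <- wrap(impute_peer_group(table$values[, j], pg,
                                    indicator_id = cid))
      table$values[, j] <- res$values
      impute_log <- rbind(impute_log, res$log)
    }
  }
  note(nrow(impute_log), " cells imputed")

  stage <- "standardise"
  z <- wrap(standardize_indicators(table))
  stage <- "factor_model"
  model <- wrap(fit_factor_model(z, n_reps = config$pa_reps,
                                 seed = config$seed,
                                 quantile = config$pa_quantile,
                                 normalize = config$varimax_normalize))
  note("k_retained = ", model$k_retained)

  stage <- "rank_transform"
  ranks <- wrap(percentile_rank(table,
                                convention = config$percentile_convention))

  stage <- "weighting"
  w_ind <- wrap(compute_indicator_weights(model$loadings_rotated,
                                          model$assignment,
                                          config$weight_basis))
  k <- max(model$k_retained, 1L)
  w_sub <- if (config$subindex_weight_source == "eigenvalues") {
    model$pca$eigenvalues[seq_len(k)]
  } else {
    colSums(model$loadings_rotated^2)
  }

  stage <- "aggregation"
  sub_raw <- wrap(compute_subindices(ranks, model$assignment, w_ind,
                                     mode = config$weight_mode))
  index <- wrap(compute_cri(sub_raw, w_sub))
  stage <- "bric_variant"
  bric <- wrap(compute_bric_unweighted(ranks, table$registry))
  stage <- "contribution_audit"
  contrib <- wrap(audit_contributions(index))

  stage <- "geo_comparison"
  geo <- NULL
  if (all(c("region", "coastal", "rurality") %in% names(table$areas))) {
    geo <- wrap(compare_geography(stats::setNames(index$cri,
                                                  table$areas$area_id),
                                  table$areas, welch = config$welch))
  } else {
    note("skipped: region/coastal/rurality metadata absent")
  }

  stage <- "validation"
  validation <- NULL
  if (!is.null(reference)) {
    ref <- stats::setNames(reference$reference_rank, reference$area_id)
    validation <- wrap(validate_against_reference(
      stats::setNames(index$cri, table$areas$area_id), ref,
      n_outliers = config$n_outliers))
  }
  stage <- "sensitivity"
  sens <- wrap(sensitivity_compare(index, bric, table$areas))

  manifest <- list(
    package = "cribuild",
    version = as.character(utils::packageVersion("cribuild")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = {
      cfg <- unclass(config)
      cfg$out_dir <- NULL    # a path, not part of the reproducible state
      cfg[!vapply(cfg, is.null, logical(1))]
    },
    n_areas = nrow(table$values), n_indicators = ncol(table$values),
    k_retained = model$k_retained,
    kmo = model$suitability$kmo,
    bartlett_p = model$suitability$bartlett_p,
    log = log_lines)

  result <- structure(list(model = model, ranks = ranks,
                           indicator_weights = w_ind,
                           subindex_weights = w_sub,
                           index = index, bric = bric,
                           contribution_audit = contrib,
                           geo = geo, validation = validation,
                           sensitivity = sens,
                           imputation_log = impute_log,
                           manifest = manifest,
                           table = table),
                      class = "cri_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.cri_pipeline_result <- function(x, ...) {
  cat("Pipeline run over", x$manifest$n_areas, "areas x",
      x$manifest$n_indicators, "indicators\n")
  print(x$index)
  if (!is.null(x$validation)) {
    cat(sprintf("  correlation with reference index (ranked): %.3f\n",
                x$validation$pearson_r))
  }
  cat(sprintf("  weighted vs unweighted Spearman rho: %.3f\n",
              x$sensitivity$spearman_rho))
  invisible(x)
}

write_group_comparison_csv <- function(geo, path) {
  rows <- do.call(rbind, lapply(names(geo), function(nm) {
    g <- geo[[nm]]
    cbind(comparison = nm, test = g$test, g$group_stats,
          statistic = g$statistic, p_value = g$p_value)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write all pipeline artifacts to a directory
#'
#' @param result a `cri_pipeline_result`.
#' @param dir output directory (created if absent).
#' @return Files written, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "cri_pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  files <- c(files, write_factor_model(result$model, dir))
  f <- file.path(dir, "index_result.csv")
  write_index_result(result$index, f); files <- c(files, f)
  f <- file.path(dir, "bric_result.csv")
  write_index_result(result$bric, f); files <- c(files, f)
  f <- file.path(dir, "indicator_weights.csv")
  utils::write.csv(data.frame(indicator_id = names(result$indicator_weights),
                              component = result$model$assignment$component_of,
                              weight = unname(result$indicator_weights)),
                   f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "imputation_log.csv")
  utils::write.csv(result$imputation_log, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(result$geo)) {
    f <- file.path(dir, "geo_comparisons.csv")
    write_group_comparison_csv(result$geo, f); files <- c(files, f)
  }
  if (!is.null(result$validation)) {
    v <- result$validation
    f <- file.path(dir, "validation.csv")
    utils::write.csv(data.frame(area_id = names(v$residuals),
                                predicted = unname(v$predicted),
                                residual = unname(v$residuals)),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(result$sensitivity$region_ranks)) {
    f <- file.path(dir, "sensitivity_region_ranks.csv")
    utils::write.csv(result$sensitivity$region_ranks, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

parse_cli_args <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `build-index`, `compare-geo`,
#' `validate` and `full-run`. Invoked by the `inst/cli/cribuild.R` script
#' via `Rscript`; callable directly for testing. Exit status: 0 on success,
#' 2 on a validation/usage error, 3 on a computation error.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly.
#' @export
cri_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cribuild <command> [options]",
    "commands:",
    "  simulate    --out DIR [--seed N] [--areas N] [--indicators N] [--factors N]",
    "  build-index --table CSV --registry CSV --out DIR [--reference CSV]",
    "              [--config JSON] [--seed N]",
    "  compare-geo --table CSV --registry CSV --out DIR [--seed N]",
    "  validate    --table CSV --registry CSV --reference CSV --out DIR [--seed N]",
    "  full-run    --out DIR [--seed N] [--config JSON]",
    sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[[1]]
  opts <- parse_cli_args(args[-1])
  need <- function(key) {
    if (is.null(opts[[key]])) {
      stop("missing required option --", key, call. = FALSE)
    }
    opts[[key]]
  }
  num <- function(key, default) {
    if (is.null(opts[[key]])) default else as.integer(opts[[key]])
  }

  status <- tryCatch({
    seed <- num("seed", 1L)
    switch(cmd,
      "simulate" = {
        out <- need("out")
        cfg <- synth_config(n_areas = num("areas", 307L),
                            n_indicators = num("indicators", 44L),
                            n_factors = num("factors", 5L), seed = seed)
        write_synthesis(synth_generate(cfg), out)
        0L
      },
      "build-index" = ,
      "compare-geo" = ,
      "validate" = {
        registry <- read_registry(need("registry"))
        table <- read_area_table(need("table"), registry)
        reference <- NULL
        if (!is.null(opts$reference) || cmd == "validate") {
          reference <- utils::read.csv(need("reference"),
                                       stringsAsFactors = FALSE)
        }
        cfg <- if (!is.null(opts$config)) {
          read_pipeline_config(opts$config)
        } else pipeline_config()
        cfg$seed <- seed
        cfg$out_dir <- need("out")
        run_pipeline(table, cfg, reference = reference)
        0L
      },
      "full-run" = {
        out <- need("out")
        synthesis <- synth_generate(synth_config(seed = seed))
        write_synthesis(synthesis, file.path(out, "synthetic"))
        cfg <- if (!is.null(opts$config)) {
          read_pipeline_config(opts$config)
        } else pipeline_config()
        cfg$seed <- seed
        cfg$out_dir <- out
        run_pipeline(synthesis$table, cfg, reference = synthesis$reference)
        0L
      },
      {
        message("unknown command: ", cmd, "\n", usage)
        2L
      })
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("validation|unknown|missing|duplicate|usage", msg)) 2L else 3L
  })
  invisible(status)
}
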
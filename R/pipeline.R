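#' Read a county covariate CSV
#'
#' Generic validated reader: requires a unique `county_id` column; all
#' other columns are carried as covariates.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_county_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, "county_id", basename(path))
  if (anyDuplicated(df$county_id))
    stop("duplicate county_id in ", basename(path), call. = FALSE)
  df
}

#' Read county centroids (`county_id`, `x`, `y`) from CSV
#' @param path file path.
#' @return data frame.
#' @export
read_centroid_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("county_id", "x", "y"), basename(path))
  df
}

#' Read a county adjacency pair list (`from`, `to`) from CSV
#' @param path file path.
#' @return data frame.
#' @export
read_adjacency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("from", "to"), basename(path))
  df
}

default_run_config <- function() {
  list(groups = c("White", "Black", "Hispanic", "Asian"),
       modes = c("place_centered", "person_centered"),
       model = list(outcome = "late_stage",
                    fixed_effects = c("race_ethnicity", "age_group"),
                    references = list(race_ethnicity = "White",
                                      age_group = "75+")),
       diagnostics = list(outlier_k = 2, n_perm = 999, knn_k = 5,
                          row_standardize = TRUE),
       quad_points = 7, tol = 1e-8, max_iter = 200, seed = 1L)
}

#' Run the full dual-model analysis pipeline
#'
#' One configuration drives both exposure constructions so that the
#' place-centered and person-centered models never diverge in cohort
#' construction: exclusions, isolation indices and exposures are built
#' once, then for each requested mode the three-level model is fitted and
#' summarised, per-person predictions (including the empirical-Bayes
#' intercepts) are aggregated to county observed-vs-predicted differences,
#' outliers are flagged, and residual spatial autocorrelation is tested by
#' permutation Moran's I. A failure in one mode is recorded and the other
#' mode still runs.
#'
#' @param config either a named list or the path of a YAML/JSON file.
#'   Required entries: `tracts` and `persons` (input CSV paths) and
#'   `outdir`. Optional: `county_covariates`, `adjacency`, `centroids`
#'   (CSV paths), `groups`, `modes` (subset of `"place_centered"`,
#'   `"person_centered"`), `model` (list: `outcome`, `fixed_effects`,
#'   `references`), `diagnostics` (list: `outlier_k`, `n_perm`, `knn_k`,
#'   `row_standardize`), `quad_points`, `tol`, `max_iter`, `seed`.
#'   Spatial weights use queen contiguity when `adjacency` is supplied,
#'   else k-nearest-neighbour centroid weights when `centroids` is; with
#'   neither, the Moran test is skipped.
#' @return an object of class `"isostage_run"`: per-mode results (`fit`,
#'   `odds_ratios`, `variance_components`, `diagnostics`, `moran`, or
#'   `error`), the exclusion tally, and the manifest. All artifacts are
#'   also written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  for (key in c("tracts", "persons", "outdir"))
    if (is.null(cfg[[key]]))
      stop("config entry '", key, "' is required", call. = FALSE)
  if (length(cfg$modes) == 0L)
    stop("at least one exposure mode must be requested", call. = FALSE)
  bad <- setdiff(cfg$modes, c("place_centered", "person_centered"))
  if (length(bad)) stop("unknown exposure mode(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  inputs <- c(tracts = cfg$tracts, persons = cfg$persons,
              county_covariates = cfg$county_covariates,
              adjacency = cfg$adjacency, centroids = cfg$centroids)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  tracts <- read_tract_table(cfg$tracts, cfg$groups)
  persons <- read_person_table(cfg$persons)
  note("read %d tracts, %d person records", nrow(tracts), nrow(persons))

  iso <- isolation_table(tracts, cfg$groups)
  write_isolation_table(iso, file.path(cfg$outdir, "isolation_indices.csv"))

  excl <- apply_exclusions(persons)
  note("exclusions: %s; retained %d of %d (%.1f%%)",
       paste(names(excl$tally), excl$tally, sep = "=", collapse = ", "),
       excl$n_retained, nrow(persons),
       100 * excl$n_retained / nrow(persons))
  cohort <- excl$retained
  cohort <- attach_place_centered(cohort, iso, cfg$groups)
  cohort <- attach_person_centered(cohort, iso)
  if (!is.null(cfg$county_covariates)) {
    cov <- read_county_table(cfg$county_covariates)
    idx <- match(cohort$county_id, cov$county_id)
    if (anyNA(idx))
      stop("county covariates missing for county ids: ",
           paste(unique(cohort$county_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    for (v in setdiff(names(cov), "county_id")) cohort[[v]] <- cov[[v]][idx]
  }
  write_cohort_table(cohort, file.path(cfg$outdir, "exposed_cohort.csv"))

  weights <- NULL
  all_ids <- unique(cohort$county_id)
  if (!is.null(cfg$adjacency)) {
    weights <- build_weights(all_ids,
                             adjacency = read_adjacency_table(cfg$adjacency),
                             scheme = "queen",
                             row_standardize = cfg$diagnostics$row_standardize)
  } else if (!is.null(cfg$centroids)) {
    weights <- build_weights(all_ids,
                             centroids = read_centroid_table(cfg$centroids),
                             scheme = "knn", k = cfg$diagnostics$knn_k,
                             row_standardize = cfg$diagnostics$row_standardize)
  }

  results <- list()
  for (mode in cfg$modes) {
    results[[mode]] <- tryCatch({
      spec <- model_spec(outcome = cfg$model$outcome,
                         fixed_effects = cfg$model$fixed_effects,
                         references = cfg$model$references,
                         exposure_mode = mode,
                         exposure_groups = cfg$groups)
      des <- build_design(cohort, spec)
      note("[%s] design: %d rows (%d dropped), %d terms", mode,
           length(des$y), des$n_dropped, length(des$terms))
      fit <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                                   quad_points = cfg$quad_points,
                                   tol = cfg$tol, max_iter = cfg$max_iter)
      note("[%s] logLik %.2f, converged %s, var(county) %.5f, var(state) %.5f",
           mode, fit$loglik, fit$converged, fit$var_county, fit$var_state)
      tabs <- write_fit_tables(
        fit,
        file.path(cfg$outdir, paste0("odds_ratios_", mode, ".csv")),
        file.path(cfg$outdir, paste0("variance_components_", mode, ".csv")))
      pred <- predict_probabilities(fit, des$x, des$county, des$state,
                                    include_random = TRUE)
      diags <- flag_outliers(aggregate_county(des$county, des$y, pred),
                             k = cfg$diagnostics$outlier_k)
      note("[%s] %d of %d counties flagged as outliers", mode,
           sum(diags$outlier_flag), nrow(diags))
      moran <- NULL
      if (!is.null(weights)) {
        wsub <- weights
        keep <- match(diags$county_id, wsub$ids)
        wsub$w <- wsub$w[keep, keep, drop = FALSE]
        wsub$ids <- diags$county_id
        moran <- global_morans_i(diags$difference, wsub,
                                 n_perm = cfg$diagnostics$n_perm,
                                 seed = cfg$seed)
        note("[%s] Moran's I = %.5f (perm p = %.4f)", mode, moran$I,
             moran$perm_p)
      }
      write_diagnostics(diags, moran,
                        file.path(cfg$outdir,
                                  paste0("county_diagnostics_", mode, ".csv")),
                        file.path(cfg$outdir,
                                  paste0("moran_", mode, ".json")))
      list(fit = fit, odds_ratios = tabs$odds_ratios,
           variance_components = tabs$variance_components,
           diagnostics = diags, moran = moran, n_dropped = des$n_dropped)
    }, error = function(e) {
      note("[%s] FAILED: %s", mode, conditionMessage(e))
      list(error = conditionMessage(e))
    })
  }

  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("isostage")),
    config = cfg,
    config_md5 = unname(tools::md5sum(cfg_json)),
    input_md5 = as.list(tools::md5sum(inputs)),
    exclusion_tally = as.list(excl$tally),
    n_retained = excl$n_retained,
    modes = lapply(results, function(r) {
      if (!is.null(r$error)) list(status = "error", message = r$error)
      else list(status = "ok", converged = r$fit$converged,
                loglik = r$fit$loglik)
    }))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$outdir, "run.log"))
  structure(list(results = results, exclusions = excl$tally,
                 manifest = manifest, outdir = cfg$outdir),
            class = "isostage_run")
}

#' @export
print.isostage_run <- function(x, ...) {
  cat("isostage pipeline run ->", x$outdir, "\n")
  for (mode in names(x$results)) {
    r <- x$results[[mode]]
    if (!is.null(r$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", mode, r$error))
    } else {
      cat(sprintf("  %s: logLik %.2f, converged %s, %d counties, %s\n",
                  mode, r$fit$loglik, r$fit$converged, nrow(r$diagnostics),
                  if (is.null(r$moran)) "Moran skipped"
                  else sprintf("Moran I %.4f (p %.3f)", r$moran$I,
                               r$moran$perm_p)))
    }
  }
  invisible(x)
}
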
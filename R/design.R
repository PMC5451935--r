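#' Specify the three-level late-stage diagnosis model
#'
#' Collects the outcome, fixed-effect terms, reference levels, clustering
#' keys and the exposure mode into a validated specification consumed by
#' [build_design()]. In `place_centered` mode the group-specific
#' `iso_<group>` columns enter as fixed effects; in `person_centered` mode
#' the single `person_centered_iso` column does.
#'
#' @param outcome binary outcome column name (default `"late_stage"`).
#' @param fixed_effects character vector of covariate column names,
#'   excluding the isolation exposures (those are added according to
#'   `exposure_mode`). Categorical columns are expanded to dummies.
#' @param references named list of reference levels for categorical terms;
#'   default White for `race_ethnicity` and `"75+"` for `age_group`.
#' @param exposure_mode `"place_centered"`, `"person_centered"`, or
#'   `"none"` (no isolation terms, e.g. for simulation truth models).
#' @param exposure_groups groups whose `iso_<group>` columns enter in
#'   place-centered mode.
#' @param county_key,state_key clustering key column names.
#' @return an object of class `"iso_model_spec"`.
#' @export
model_spec <- function(outcome = "late_stage",
                       fixed_effects = c("race_ethnicity", "age_group"),
                       references = list(race_ethnicity = "White",
                                         age_group = "75+"),
                       exposure_mode = c("none", "place_centered",
                                         "person_centered"),
                       exposure_groups = c("White", "Black", "Hispanic",
                                           "Asian"),
                       county_key = "county_id", state_key = "state_id") {
  exposure_mode <- match.arg(exposure_mode)
  structure(list(outcome = outcome, fixed_effects = fixed_effects,
                 references = references, exposure_mode = exposure_mode,
                 exposure_groups = exposure_groups,
                 county_key = county_key, state_key = state_key),
            class = "iso_model_spec")
}

#' Build the model design matrix
#'
#' Expands categorical terms to treatment-coded dummy columns against the
#' stated reference levels, appends the exposure columns implied by the
#' spec's mode, drops rows with any missing modelled value (complete-case
#' rule) and checks that counties nest strictly within states.
#'
#' @param cohort exposed cohort data frame.
#' @param spec an [model_spec()] object.
#' @return list with `x` (design matrix including intercept), `y` (outcome
#'   vector), `county`, `state` (cluster id vectors aligned with rows),
#'   `n_dropped` (rows removed for missingness) and `terms` (the design
#'   column names in order).
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "iso_model_spec"))
  vars <- spec$fixed_effects
  if (spec$exposure_mode == "place_centered")
    vars <- c(vars, paste0("iso_", spec$exposure_groups))
  if (spec$exposure_mode == "person_centered")
    vars <- c(vars, "person_centered_iso")
  assert_columns(cohort, c(spec$outcome, vars, spec$county_key,
                           spec$state_key), "cohort")
  dat <- cohort[c(spec$outcome, vars, spec$county_key, spec$state_key)]
  ok <- stats::complete.cases(dat)
  n_dropped <- sum(!ok)
  dat <- dat[ok, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no usable rows after complete-case filtering",
                            call. = FALSE)
  county <- dat[[spec$county_key]]
  state <- dat[[spec$state_key]]
  nest <- tapply(as.character(state), as.character(county),
                 function(s) length(unique(s)))
  if (any(nest > 1L))
    stop("county appearing under more than one state: ",
         paste(names(nest)[nest > 1L], collapse = ", "), call. = FALSE)
  y <- dat[[spec$outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (length(vars) == 0L) {
    x <- matrix(1, nrow(dat), 1L, dimnames = list(NULL, "(Intercept)"))
    return(list(x = x, y = as.numeric(y), county = county, state = state,
                n_dropped = n_dropped, terms = colnames(x)))
  }
  mf <- dat[vars]
  for (v in vars) {
    if (is.character(mf[[v]]) || is.factor(mf[[v]])) {
      ref <- spec$references[[v]]
      lev <- unique(as.character(mf[[v]]))
      if (!is.null(ref)) {
        if (!ref %in% lev)
          stop(sprintf("reference level '%s' absent from column '%s'",
                       ref, v), call. = FALSE)
        lev <- c(ref, sort(setdiff(lev, ref)))
      } else lev <- sort(lev)
      mf[[v]] <- factor(mf[[v]], levels = lev)
    }
  }
  x <- stats::model.matrix(~ ., data = mf)
  attr(x, "assign") <- NULL
  attr(x, "contrasts") <- NULL
  list(x = x, y = as.numeric(y), county = county, state = state,
       n_dropped = n_dropped, terms = colnames(x))
}
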
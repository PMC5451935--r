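#' Apply registry-style record exclusions
#'
#' Drops cases that are not the person's primary cancer, have unknown or
#' unstaged cancer stage, or were first identified at autopsy or on a death
#' certificate. When a record trips several rules it is tallied once, under
#' the first matching reason in `order` (default: non-primary, then unknown
#' stage, then autopsy/death-certificate).
#'
#' @param records person-level data frame with binary columns `is_primary`,
#'   `stage_known`, `dx_source_autopsy_or_dc`.
#' @param order character vector giving the precedence of the three reasons
#'   `"non_primary"`, `"unknown_stage"`, `"autopsy_dc"`.
#' @return list with `retained` (the surviving records), `tally` (named
#'   integer vector of exclusion counts per reason, in precedence order)
#'   and `n_retained`. Always `n_retained + sum(tally) == nrow(records)`.
#' @export
apply_exclusions <- function(records,
                             order = c("non_primary", "unknown_stage",
                                       "autopsy_dc")) {
  stopifnot(nrow(records) > 0)
  assert_columns(records,
                 c("is_primary", "stage_known", "dx_source_autopsy_or_dc"),
                 "person table")
  if (!setequal(order, c("non_primary", "unknown_stage", "autopsy_dc")))
    stop("order must be a permutation of the three exclusion reasons",
         call. = FALSE)
  fires <- cbind(
    non_primary   = records$is_primary == 0,
    unknown_stage = records$stage_known == 0,
    autopsy_dc    = records$dx_source_autopsy_or_dc == 1
  )[, order, drop = FALSE]
  reason <- rep(NA_character_, nrow(records))
  for (r in rev(order)) reason[fires[, r]] <- r  # earlier reasons overwrite
  tally <- vapply(order, function(r) sum(reason == r, na.rm = TRUE),
                  integer(1))
  retained <- records[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  if (nrow(retained) == 0L) message("all records excluded; none retained")
  list(retained = retained, tally = tally, n_retained = nrow(retained))
}

#' Attach place-centered isolation exposures
#'
#' Copies every requested group's county Isolation Index onto each person,
#' keyed by county of residence: all residents of a county carry the same
#' exposure vector regardless of their own race/ethnicity. New columns are
#' named `iso_<group>`.
#'
#' @param records person-level data frame with a `county_id` column.
#' @param iso_table county isolation table from [isolation_table()].
#' @param groups character vector of groups to attach (defaults to every
#'   group column in `iso_table`).
#' @return `records` with one `iso_<group>` column per group; missing
#'   county indices propagate as `NA`.
#' @export
attach_place_centered <- function(records, iso_table, groups = NULL) {
  assert_columns(records, "county_id", "person table")
  groups <- groups %||% setdiff(names(iso_table), c("county_id", "state_id"))
  if (length(groups) == 0L) return(records)
  assert_columns(iso_table, c("county_id", groups), "isolation table")
  idx <- match(records$county_id, iso_table$county_id)
  if (anyNA(idx))
    stop("county_id absent from isolation table: ",
         paste(unique(records$county_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  for (g in groups) records[[paste0("iso_", g)]] <- iso_table[[g]][idx]
  records
}

#' Attach the person-centered (race-matched) isolation exposure
#'
#' Each person receives the Isolation Index of their own racial/ethnic
#' group in their county of residence (e.g. a Black person gets the county
#' Black index). Persons in the residual "other" category, for whom no
#' group index exists, receive the arithmetic mean of the county's
#' non-missing group indices.
#'
#' @param records person-level data frame with `county_id` and
#'   `race_ethnicity` columns.
#' @param iso_table county isolation table.
#' @param race_to_group named character vector mapping each race level
#'   (except the other-label) to a group column of `iso_table`.
#' @param other_label race level treated by the averaging rule.
#' @param other_groups groups contributing to the "other" average; default
#'   all group columns of `iso_table`.
#' @return `records` with a `person_centered_iso` column; a missing matched
#'   index leaves `NA` (the affected records are counted in a message).
#' @export
attach_person_centered <- function(records, iso_table,
                                   race_to_group = c(White = "White",
                                                     Black = "Black",
                                                     Hispanic = "Hispanic",
                                                     Asian = "Asian"),
                                   other_label = "Other",
                                   other_groups = NULL) {
  assert_columns(records, c("county_id", "race_ethnicity"), "person table")
  all_groups <- setdiff(names(iso_table), c("county_id", "state_id"))
  other_groups <- other_groups %||% all_groups
  assert_columns(iso_table, c("county_id", unique(c(race_to_group,
                                                    other_groups))),
                 "isolation table")
  races <- setdiff(unique(records$race_ethnicity), other_label)
  unmapped <- setdiff(races, names(race_to_group))
  if (length(unmapped))
    stop("race level(s) without a group mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  idx <- match(records$county_id, iso_table$county_id)
  if (anyNA(idx))
    stop("county_id absent from isolation table: ",
         paste(unique(records$county_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  pc <- rep(NA_real_, nrow(records))
  is_other <- records$race_ethnicity == other_label
  for (r in races) {
    sel <- records$race_ethnicity == r
    pc[sel] <- iso_table[[race_to_group[[r]]]][idx[sel]]
  }
  if (any(is_other)) {
    avail <- as.matrix(iso_table[other_groups])
    pc[is_other] <- rowMeans(avail, na.rm = TRUE)[idx[is_other]]
    pc[is_other & is.nan(pc)] <- NA_real_
  }
  n_flag <- sum(is.na(pc) & !is_other)
  if (n_flag > 0)
    message(n_flag, " record(s) with a missing race-matched index; ",
            "exposure left missing")
  records$person_centered_iso <- pc
  records
}

#' Read a person-level case CSV
#'
#' Expects columns `person_id`, `county_id`, `state_id`, `race_ethnicity`,
#' `age_group`, `late_stage`, `is_primary`, `stage_known`,
#' `dx_source_autopsy_or_dc`.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_person_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("person_id", "county_id", "state_id",
                       "race_ethnicity", "age_group", "late_stage",
                       "is_primary", "stage_known",
                       "dx_source_autopsy_or_dc"),
                 basename(path))
  for (b in c("late_stage", "is_primary", "stage_known",
              "dx_source_autopsy_or_dc"))
    if (!all(df[[b]] %in% c(0L, 1L)))
      stop(sprintf("column '%s' in %s is not binary 0/1", b, basename(path)),
           call. = FALSE)
  if (anyDuplicated(df$person_id))
    stop("duplicate person_id in ", basename(path), call. = FALSE)
  df
}

#' Write an exposed cohort as CSV (missing values as empty fields)
#'
#' @param cohort exposed cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
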
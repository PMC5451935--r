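#' Residential Isolation Index for one county
#'
#' The exposure-dimension segregation measure of Massey and Denton: the
#' minority-weighted average, over a county's census tracts, of the tract
#' share of that minority,
#' \deqn{I_j = \sum_{i=1}^{N} \frac{x_i}{X} \cdot \frac{x_i}{t_i},}
#' where \eqn{x_i} is the group count in tract \eqn{i}, \eqn{t_i} the tract
#' total, and \eqn{X = \sum_i x_i} the county group total. It is the
#' probability that a randomly chosen within-county contact of a group
#' member belongs to the same group, and lies in \eqn{[0, 1]}.
#'
#' @param tracts data frame of tract compositions for a single county:
#'   columns `tract_id`, `county_id`, `total`, and one count column per
#'   group. Tracts with `total = 0` and a zero group count are dropped from
#'   the sum; a positive count with zero total is an error.
#' @param group name of the group count column.
#' @return the index in `[0, 1]`, or `NA` when the county group total
#'   \eqn{X} is zero (the index is undefined, not zero).
#' @examples
#' tr <- data.frame(tract_id = c("a", "b"), county_id = "c1",
#'                  total = c(100, 100), White = c(90, 10))
#' isolation_index(tr, "White")  # 0.9*0.9 + 0.1*0.1 = 0.82
#' @export
isolation_index <- function(tracts, group) {
  assert_columns(tracts, c("tract_id", "county_id", "total"), "tract table")
  if (!group %in% names(tracts))
    stop(sprintf("group column '%s' not found in tract table", group),
         call. = FALSE)
  if (length(unique(tracts$county_id)) > 1L)
    stop("tracts span more than one county_id", call. = FALSE)
  x <- as.numeric(tracts[[group]])
  t <- as.numeric(tracts$total)
  if (anyNA(x) || anyNA(t) || any(x < 0) || any(t < 0))
    stop("counts and totals must be non-negative and non-missing",
         call. = FALSE)
  if (any(x > t))
    stop(sprintf("group count exceeds tract total for tract(s): %s",
                 paste(tracts$tract_id[x > t], collapse = ", ")),
         call. = FALSE)
  keep <- t > 0
  if (any(x[!keep] > 0))  # unreachable given x <= t, kept as a guard
    stop("tract with zero total but positive group count", call. = FALSE)
  x <- x[keep]; t <- t[keep]
  X <- sum(x)
  if (X == 0) return(NA_real_)
  sum((x / X) * (x / t))
}

#' County-by-group table of Isolation Indices
#'
#' Applies [isolation_index()] to every county in a tract composition table,
#' for each requested group.
#'
#' @param tracts full tract composition table (`tract_id`, `county_id`,
#'   optionally `state_id`, `total`, one count column per group);
#'   `tract_id` must be unique.
#' @param groups character vector of group column names.
#' @return data frame with one row per distinct `county_id` (plus
#'   `state_id` when present) and one column per group holding the index;
#'   `NA` marks counties where the group is absent.
#' @export
isolation_table <- function(tracts, groups) {
  stopifnot(nrow(tracts) > 0, length(groups) > 0)
  assert_columns(tracts, c("tract_id", "county_id", "total", groups),
                 "tract table")
  if (anyDuplicated(tracts$tract_id))
    stop("duplicate tract_id in tract table", call. = FALSE)
  pieces <- split(tracts, factor(tracts$county_id,
                                 levels = unique(tracts$county_id)))
  out <- data.frame(county_id = names(pieces), stringsAsFactors = FALSE)
  if ("state_id" %in% names(tracts))
    out$state_id <- vapply(pieces, function(d) as.character(d$state_id[1L]),
                           character(1))
  for (g in groups)
    out[[g]] <- vapply(pieces, isolation_index, numeric(1), group = g)
  rownames(out) <- NULL
  out
}

#' Classify hyper-segregation
#'
#' A county is called hyper-segregated for a group when its Isolation Index
#' reaches at least the threshold (default 0.90, boundary inclusive). An
#' undefined (missing) index is never hyper-segregated.
#'
#' @param value numeric vector of index values in `[0, 1]`, `NA` allowed.
#' @param threshold classification threshold in `[0, 1]`.
#' @return logical vector, `FALSE` for missing inputs.
#' @export
classify_hypersegregation <- function(value, threshold = 0.90) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  if (any(value < 0 | value > 1, na.rm = TRUE))
    stop("index values must lie in [0, 1]", call. = FALSE)
  if (anyNA(value))
    message(sum(is.na(value)),
            " missing index value(s) classified as not hyper-segregated")
  !is.na(value) & value >= threshold
}

#' Read a tract composition CSV
#'
#' Expects a UTF-8, comma-delimited file with header columns `tract_id`,
#' `county_id`, `state_id`, one column per group count, and `total`.
#'
#' @param path file path.
#' @param groups optional character vector naming the group count columns;
#'   by default every column other than the identifiers and `total`.
#' @return validated data frame; group columns recorded in
#'   `attr(, "groups")`.
#' @export
read_tract_table <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("tract_id", "county_id", "state_id", "total"),
                 basename(path))
  groups <- groups %||%
    setdiff(names(df), c("tract_id", "county_id", "state_id", "total"))
  assert_columns(df, groups, basename(path))
  for (g in c(groups, "total")) {
    if (!is.numeric(df[[g]]))
      stop(sprintf("column '%s' in %s is not numeric", g, basename(path)),
           call. = FALSE)
  }
  if (anyDuplicated(df$tract_id))
    stop("duplicate tract_id in ", basename(path), call. = FALSE)
  structure(df, groups = groups)
}

#' Write a county isolation table as CSV
#'
#' Columns are `county_id` plus `iso_<group>` per group; missing values are
#' written as empty fields.
#'
#' @param iso data frame from [isolation_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isolation_table <- function(iso, path) {
  out <- iso
  grp <- setdiff(names(out), c("county_id", "state_id"))
  names(out)[match(grp, names(out))] <- paste0("iso_", grp)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
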
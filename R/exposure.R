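# Exposure inputs: one region/sex/age stratum of adult per-capita alcohol
# consumption and drinking-status prevalences, with their uncertainties.

#' Create an exposure profile for one region/sex/age stratum
#'
#' An exposure profile bundles everything the AAF machinery needs to know
#' about alcohol exposure in one population stratum: adult per-capita
#' consumption in grams of pure alcohol per day (total = recorded +
#' unrecorded, with standard error), the prevalences of lifetime abstainers
#' and former drinkers, the effective survey sample size behind those
#' prevalences, and the coverage factor applied to registry-based per-capita
#' estimates before modelling.
#'
#' @param region_label Character label for the region.
#' @param sex `"male"` or `"female"`.
#' @param age_group Character label, e.g. `"15-34"`.
#' @param per_capita_mean Adult per-capita consumption, g/day (> 0).
#' @param per_capita_se Standard error of `per_capita_mean`, g/day (>= 0).
#' @param recorded_mean,recorded_se Optional recorded component (g/day).
#' @param unrecorded_mean Optional unrecorded component (g/day). When a
#'   recorded/unrecorded split is given, the two means must add up to
#'   `per_capita_mean` (within `split_tol`).
#' @param p_abstainer Proportion of lifetime abstainers, in \[0, 1\].
#' @param p_former Proportion of former drinkers, in \[0, 1\].
#'   `p_abstainer + p_former` must be < 1 so a positive current-drinker
#'   fraction exists.
#' @param effective_n Effective survey sample size behind the prevalence
#'   estimates; defaults to 1000.
#' @param coverage_factor Fraction of the registry-based per-capita estimate
#'   assumed to reflect true consumption; defaults to 0.8.
#' @param split_tol Absolute tolerance (g/day) for checking that recorded +
#'   unrecorded equals the total.
#'
#' @return An object of class `"exposure_profile"`.
#' @seealso [read_exposure_table()], [prevalence_se()], [drinker_mean()]
#' @export
#' @examples
#' exposure_profile("Asia, Pacific (high income)", "male", "15-34",
#'                  per_capita_mean = 13.51, per_capita_se = 1.57,
#'                  p_abstainer = 0.05, p_former = 0.07)
exposure_profile <- function(region_label, sex = c("male", "female"),
                             age_group = "15-34",
                             per_capita_mean, per_capita_se,
                             recorded_mean = NA_real_, recorded_se = NA_real_,
                             unrecorded_mean = NA_real_,
                             p_abstainer, p_former,
                             effective_n = 1000L, coverage_factor = 0.8,
                             split_tol = 0.01) {
  sex <- match.arg(sex)
  obj <- structure(
    list(region_label = as.character(region_label),
         sex = sex,
         age_group = as.character(age_group),
         per_capita_mean = as.numeric(per_capita_mean),
         per_capita_se = as.numeric(per_capita_se),
         recorded_mean = as.numeric(recorded_mean),
         recorded_se = as.numeric(recorded_se),
         unrecorded_mean = as.numeric(unrecorded_mean),
         p_abstainer = as.numeric(p_abstainer),
         p_former = as.numeric(p_former),
         effective_n = as.numeric(effective_n),
         coverage_factor = as.numeric(coverage_factor)),
    class = "exposure_profile")
  problems <- validate_exposure_profile(obj, split_tol = split_tol)
  if (length(problems))
    stop("invalid exposure profile: ", paste(problems, collapse = "; "),
         call. = FALSE)
  obj
}

#' Validate an exposure profile
#'
#' Checks the domain invariants of an [exposure_profile()] and returns a
#' character vector of problems (empty when the profile is valid). Used by
#' the constructor and by [read_exposure_table()] for row-level error
#' reporting.
#'
#' @param x An `"exposure_profile"` (or a bare list with the same fields).
#' @param split_tol Absolute tolerance (g/day) for the recorded + unrecorded
#'   sum check.
#' @return Character vector of problem descriptions, `character(0)` if valid.
#' @export
validate_exposure_profile <- function(x, split_tol = 0.01) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.finite(x$per_capita_mean) && x$per_capita_mean > 0,
      "per_capita_mean must be > 0")
  chk(is.finite(x$per_capita_se) && x$per_capita_se >= 0,
      "per_capita_se must be >= 0")
  chk(is.finite(x$p_abstainer) && x$p_abstainer >= 0 && x$p_abstainer <= 1,
      "p_abstainer must be in [0, 1]")
  chk(is.finite(x$p_former) && x$p_former >= 0 && x$p_former <= 1,
      "p_former must be in [0, 1]")
  if (is.finite(x$p_abstainer) && is.finite(x$p_former))
    chk(x$p_abstainer + x$p_former < 1,
        "p_abstainer + p_former must be < 1 (no drinkers left)")
  chk(is.finite(x$effective_n) && x$effective_n >= 1,
      "effective_n must be >= 1")
  chk(is.finite(x$coverage_factor) && x$coverage_factor > 0 &&
        x$coverage_factor <= 1,
      "coverage_factor must be in (0, 1]")
  if (!is.na(x$recorded_mean)) {
    chk(x$recorded_mean >= 0, "recorded_mean must be >= 0")
    if (!is.na(x$recorded_se))
      chk(x$recorded_se >= 0, "recorded_se must be >= 0")
    if (!is.na(x$unrecorded_mean)) {
      chk(x$unrecorded_mean >= 0, "unrecorded_mean must be >= 0")
      if (is.finite(x$per_capita_mean))
        chk(abs(x$recorded_mean + x$unrecorded_mean - x$per_capita_mean) <=
              split_tol,
            "recorded_mean + unrecorded_mean must equal per_capita_mean")
    }
  }
  problems
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("Exposure profile: %s, %s, age %s\n",
              x$region_label, x$sex, x$age_group))
  cat(sprintf("  per-capita consumption: %.2f (SE %.2f) g/day\n",
              x$per_capita_mean, x$per_capita_se))
  if (!is.na(x$recorded_mean))
    cat(sprintf("  recorded %.2f + unrecorded %.2f g/day\n",
                x$recorded_mean,
                ifelse(is.na(x$unrecorded_mean), NA, x$unrecorded_mean)))
  cat(sprintf("  lifetime abstainers %.3f, former drinkers %.3f, current drinkers %.3f\n",
              x$p_abstainer, x$p_former, 1 - x$p_abstainer - x$p_former))
  cat(sprintf("  effective n %g, coverage factor %.2f\n",
              x$effective_n, x$coverage_factor))
  invisible(x)
}

#' Binomial standard error of a prevalence estimate
#'
#' Standard error of a survey proportion under simple binomial sampling,
#' `sqrt(p * (1 - p) / n)`. This is the variance rule used for the
#' prevalence of lifetime abstainers and former drinkers, with an effective
#' survey sample size conventionally taken as 1000.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param effective_n Effective sample size(s), >= 1.
#' @return Standard error(s), same units as `p`.
#' @export
#' @examples
#' prevalence_se(0.87, 1000)  # ~0.0106
prevalence_se <- function(p, effective_n = 1000) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]", call. = FALSE)
  if (!is.numeric(effective_n) || any(!is.finite(effective_n)) ||
        any(effective_n < 1))
    stop("effective_n must be >= 1", call. = FALSE)
  sqrt(p * (1 - p) / effective_n)
}

#' Standard deviation of unrecorded per-capita consumption
#'
#' Uncertainty about unrecorded consumption is not observed directly; it is
#' imputed as proportionally five times the recorded relative standard
#' deviation, applied to the unrecorded mean:
#' `5 * recorded_se * unrecorded_mean / recorded_mean`.
#'
#' The "proportionally five times larger" rule is read as a statement about
#' relative (not absolute) standard deviations, since unrecorded and
#' recorded means can differ by an order of magnitude; the absolute reading
#' would be `5 * recorded_se` independent of the unrecorded mean.
#'
#' @param recorded_se Standard error of recorded consumption, g/day (>= 0).
#' @param recorded_mean Recorded consumption mean, g/day (> 0).
#' @param unrecorded_mean Unrecorded consumption mean, g/day (>= 0).
#' @return Imputed standard error of unrecorded consumption, g/day.
#' @export
unrecorded_se <- function(recorded_se, recorded_mean, unrecorded_mean) {
  if (any(recorded_mean <= 0)) stop("recorded_mean must be > 0", call. = FALSE)
  if (any(recorded_se < 0) || any(unrecorded_mean < 0))
    stop("standard errors and means must be >= 0", call. = FALSE)
  5 * recorded_se * unrecorded_mean / recorded_mean
}

#' Combine recorded and unrecorded standard errors
#'
#' Total per-capita consumption is recorded + unrecorded; with no covariance
#' information available the two sources are treated as independent, so the
#' combined standard error is the Euclidean sum
#' `sqrt(recorded_se^2 + unrecorded_se^2)`.
#'
#' @param recorded_se,unrecorded_se Standard errors, g/day (>= 0).
#' @return Combined standard error, g/day.
#' @export
combined_per_capita_se <- function(recorded_se, unrecorded_se) {
  if (any(recorded_se < 0) || any(unrecorded_se < 0))
    stop("standard errors must be >= 0", call. = FALSE)
  sqrt(recorded_se^2 + unrecorded_se^2)
}

exposure_columns <- c("region_label", "sex", "age_group",
                      "per_capita_mean", "per_capita_se",
                      "recorded_mean", "recorded_se", "unrecorded_mean",
                      "p_abstainer", "p_former",
                      "effective_n", "coverage_factor")

#' Read an exposure table from CSV
#'
#' Reads a delimited table with one stratum per row into a list of
#' [exposure_profile()] objects. The file must have a header with at least
#' the required columns (`region_label`, `sex`, `age_group`,
#' `per_capita_mean`, `per_capita_se`, `p_abstainer`, `p_former`); the
#' optional columns (`recorded_mean`, `recorded_se`, `unrecorded_mean`,
#' `effective_n`, `coverage_factor`) may be absent or empty and take their
#' defaults. All profile invariants are validated and violations are
#' reported with their row index.
#'
#' @param path Path to a CSV file (UTF-8, decimal point, header mandatory).
#' @return A list of `"exposure_profile"` objects (empty for a header-only
#'   file).
#' @seealso [write_exposure_table()]
#' @export
read_exposure_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("exposure table '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("region_label", "sex", "age_group", "per_capita_mean",
                "per_capita_se", "p_abstainer", "p_former")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("exposure table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(list())

  get_num <- function(row, col, default = NA_real_) {
    if (!col %in% names(df)) return(default)
    v <- row[[col]]
    if (is.na(v) || (is.character(v) && !nzchar(trimws(v)))) return(default)
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num))
      stop(sprintf("non-numeric value '%s' in column %s", v, col),
           call. = FALSE)
    num
  }

  profiles <- vector("list", nrow(df))
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    res <- tryCatch(
      exposure_profile(
        region_label = row$region_label,
        sex = row$sex,
        age_group = row$age_group,
        per_capita_mean = get_num(row, "per_capita_mean"),
        per_capita_se = get_num(row, "per_capita_se"),
        recorded_mean = get_num(row, "recorded_mean"),
        recorded_se = get_num(row, "recorded_se"),
        unrecorded_mean = get_num(row, "unrecorded_mean"),
        p_abstainer = get_num(row, "p_abstainer"),
        p_former = get_num(row, "p_former"),
        effective_n = get_num(row, "effective_n", 1000),
        coverage_factor = get_num(row, "coverage_factor", 0.8)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, sprintf("row %d: %s", i, res))
    } else {
      profiles[[i]] <- res
    }
  }
  if (length(errors))
    stop("invalid exposure table:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  profiles
}

#' Write exposure profiles to CSV
#'
#' Inverse of [read_exposure_table()]: writes one stratum per row using the
#' fixed column layout, so that read and write round-trip up to float
#' formatting.
#'
#' @param profiles A list of `"exposure_profile"` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(profiles, path) {
  if (inherits(profiles, "exposure_profile")) profiles <- list(profiles)
  df <- exposure_table_frame(profiles)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert exposure profiles to a data frame
#'
#' @param profiles A list of `"exposure_profile"` objects.
#' @return A data frame with the standard exposure-table columns.
#' @export
exposure_table_frame <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    as.data.frame(p[exposure_columns], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
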
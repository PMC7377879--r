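#' Longitudinal cohort container
#'
#' A `cohort` bundles the three tables the package works with: a region panel
#' (the ordered set of measured regions and whether each is a cortical
#' thickness or a subcortical volume), a subject table (one row per subject
#' with group membership and covariates), and a long-format observation table
#' (one row per subject x visit x region).
#'
#' @param observations data.frame with columns `subject_id`, `visit_months`
#'   (numeric, >= 0), `region`, `value`.
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (`"control"` or `"patient"`) plus any covariate columns.
#' @param panel data.frame with columns `region` and `kind`
#'   (`"thickness"` or `"volume"`); its row order fixes the region order for
#'   the analysis. Defaults to the regions present in `observations`, in
#'   order of first appearance, with kind `"thickness"`.
#' @param standardized logical; whether `value` is on the control-referenced
#'   z-score scale (set by [to_zscores()]).
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [filter_min_visits()], [to_zscores()]
#' @export
cohort <- function(observations, subjects, panel = NULL, standardized = FALSE) {
  observations <- as.data.frame(observations)
  subjects <- as.data.frame(subjects)
  need_obs <- c("subject_id", "visit_months", "region", "value")
  miss <- setdiff(need_obs, names(observations))
  if (length(miss))
    stop("observations is missing column(s): ", paste(miss, collapse = ", "))
  need_sub <- c("subject_id", "group")
  miss <- setdiff(need_sub, names(subjects))
  if (length(miss))
    stop("subjects is missing column(s): ", paste(miss, collapse = ", "))
  observations$subject_id <- as.character(observations$subject_id)
  observations$region <- as.character(observations$region)
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  if (is.null(panel)) {
    panel <- data.frame(region = unique(observations$region),
                        kind = "thickness", stringsAsFactors = FALSE)
  }
  panel <- as.data.frame(panel)
  if (!all(c("region", "kind") %in% names(panel)))
    stop("panel needs columns region and kind")
  panel$region <- as.character(panel$region)
  x <- structure(list(observations = observations, subjects = subjects,
                      panel = panel, standardized = isTRUE(standardized)),
                 class = "cohort")
  validate_cohort(x)
}

validate_cohort <- function(x) {
  obs <- x$observations; sub <- x$subjects; panel <- x$panel
  if (anyDuplicated(panel$region))
    stop("panel regions must be unique")
  if (nrow(panel) == 0L) stop("panel must name at least one region")
  if (anyDuplicated(sub$subject_id)) {
    d <- sub$subject_id[duplicated(sub$subject_id)][1L]
    stop("duplicate subject_id in subject table: ", d)
  }
  bad <- !sub$group %in% c("control", "patient")
  if (any(bad))
    stop("unknown group label '", sub$group[bad][1L], "' for subject ",
         sub$subject_id[bad][1L], " (expected control or patient)")
  if (!is.numeric(obs$visit_months) || anyNA(obs$visit_months) ||
      any(obs$visit_months < 0))
    stop("visit_months must be numeric and >= 0")
  if (!is.numeric(obs$value)) stop("value must be numeric")
  key <- paste(obs$subject_id, obs$visit_months, obs$region, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (subject, visit, region) observation: subject ",
         obs$subject_id[i], ", visit ", obs$visit_months[i], ", region ",
         obs$region[i], " (row ", i, ")")
  }
  unk <- setdiff(obs$subject_id, sub$subject_id)
  if (length(unk))
    stop("observation subject_id not in subject table: ", unk[1L])
  unk <- setdiff(obs$region, panel$region)
  if (length(unk))
    stop("observation region not in panel: ", unk[1L])
  x
}

#' @export
print.cohort <- function(x, ...) {
  ns <- table(factor(x$subjects$group, c("control", "patient")))
  cat("Longitudinal cohort: ", nrow(x$subjects), " subjects (",
      ns[["control"]], " controls, ", ns[["patient"]], " patients), ",
      nrow(x$panel), " regions, ", nrow(x$observations), " observations\n",
      sep = "")
  cat("Scale:", if (x$standardized) "control-referenced z-scores" else
    "raw measurement units", "\n")
  invisible(x)
}

#' Number of distinct visits per subject
#' @param x a `cohort`.
#' @return named integer vector over subjects present in the observations.
#' @export
visit_counts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  u <- unique(x$observations[c("subject_id", "visit_months")])
  tab <- table(u$subject_id)
  setNames(as.integer(tab), names(tab))
}

#' Read a cohort from delimited files
#'
#' Reads the long-format measurement table and the per-subject covariate
#' table from comma-delimited UTF-8 files with header rows, and validates the
#' result. Parsing is locale-independent (dot decimal separator).
#'
#' @param measurements_path CSV with columns `subject_id`, `group`,
#'   `visit_months`, `region`, `value`.
#' @param covariates_path CSV with column `subject_id` plus covariates;
#'   `NULL` for a cohort without covariates (groups are then taken from the
#'   measurement file only).
#' @param panel optional panel data.frame (see [cohort()]).
#' @return a validated [cohort()].
#' @export
read_cohort <- function(measurements_path, covariates_path = NULL, panel = NULL) {
  if (!file.exists(measurements_path))
    stop("measurement file not found: ", measurements_path)
  meas <- read.csv(measurements_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "visit_months", "region", "value")
  miss <- setdiff(need, names(meas))
  if (length(miss))
    stop("measurement file is missing column(s): ", paste(miss, collapse = ", "))
  subjects <- unique(meas[c("subject_id", "group")])
  if (anyDuplicated(subjects$subject_id)) {
    d <- subjects$subject_id[duplicated(subjects$subject_id)][1L]
    stop("subject ", d, " appears with more than one group label")
  }
  if (!is.null(covariates_path)) {
    if (!file.exists(covariates_path))
      stop("covariate file not found: ", covariates_path)
    cov <- read.csv(covariates_path, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(cov))
      stop("covariate file is missing column subject_id")
    cov$subject_id <- as.character(cov$subject_id)
    subjects <- merge(subjects, cov, by = "subject_id", all.x = TRUE,
                      sort = TRUE)
  }
  cohort(meas[c("subject_id", "visit_months", "region", "value")],
         subjects, panel = panel)
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()]: writes the measurement and covariate tables in
#' the same CSV dialect, so that reading them back yields an identical cohort.
#'
#' @param x a `cohort`.
#' @param measurements_path,covariates_path output CSV paths
#'   (`covariates_path` may be `NULL` to skip the covariate table).
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, measurements_path, covariates_path = NULL) {
  stopifnot(inherits(x, "cohort"))
  grp <- setNames(x$subjects$group, x$subjects$subject_id)
  meas <- data.frame(subject_id = x$observations$subject_id,
                     group = unname(grp[x$observations$subject_id]),
                     visit_months = x$observations$visit_months,
                     region = x$observations$region,
                     value = x$observations$value)
  write.csv(meas, measurements_path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariates_path))
    write.csv(x$subjects[setdiff(names(x$subjects), "group")],
              covariates_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Drop subjects with too few visits
#'
#' Removes subjects whose number of distinct visit times falls below
#' `min_visits`; trajectory slopes are not identifiable from a single time
#' point, so cohorts are filtered to subjects with at least two. Controls are
#' subject to the same rule as patients. Removed subject ids are reported via
#' a message.
#'
#' @param x a `cohort`.
#' @param min_visits minimum number of distinct visit times (>= 1); default 2.
#' @param strict_continuity if `TRUE`, visits must also be consecutive
#'   nominal waves starting at the first attended one, given the schedule in
#'   `schedule` (so 0/24 without 12 months does not count as 2 continuous
#'   visits).
#' @param schedule nominal visit times in months used by the strict rule.
#' @param tolerance_months half-width of the window that maps an actual visit
#'   time to a nominal one for the strict rule.
#' @return the filtered `cohort`.
#' @export
filter_min_visits <- function(x, min_visits = 2L, strict_continuity = FALSE,
                              schedule = c(0, 12, 24), tolerance_months = 3) {
  stopifnot(inherits(x, "cohort"), min_visits >= 1L)
  counts <- visit_counts(x)
  keep_n <- names(counts)[counts >= min_visits]
  if (strict_continuity) {
    u <- unique(x$observations[c("subject_id", "visit_months")])
    nominal <- map_to_nominal(u$visit_months, schedule, tolerance_months)
    ok <- vapply(split(nominal, u$subject_id), function(v) {
      v <- sort(unique(v))
      length(v) >= min_visits && all(diff(match(v, sort(schedule))) == 1L)
    }, logical(1L))
    keep_n <- intersect(keep_n, names(ok)[ok])
  }
  dropped <- setdiff(unique(x$observations$subject_id), keep_n)
  if (length(dropped))
    message("filter_min_visits: removing ", length(dropped), " subject(s): ",
            paste(dropped, collapse = ", "))
  obs <- x$observations[x$observations$subject_id %in% keep_n, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no subjects left after the minimum-visit filter; ",
         "inspect the visit structure of the input")
  sub <- x$subjects[x$subjects$subject_id %in% keep_n, , drop = FALSE]
  cohort(obs, sub, panel = x$panel, standardized = x$standardized)
}

#' Restrict a cohort to one group
#' @param x a `cohort`.
#' @param group `"patient"` or `"control"`.
#' @return the sub-cohort of that group.
#' @export
subset_group <- function(x, group = c("patient", "control")) {
  stopifnot(inherits(x, "cohort"))
  group <- match.arg(group)
  ids <- x$subjects$subject_id[x$subjects$group == group]
  obs <- x$observations[x$observations$subject_id %in% ids, , drop = FALSE]
  sub <- x$subjects[x$subjects$subject_id %in% ids, , drop = FALSE]
  if (nrow(obs) == 0L) stop("cohort has no observations for group ", group)
  cohort(obs, sub, panel = x$panel, standardized = x$standardized)
}
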
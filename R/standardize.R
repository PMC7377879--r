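## Map actual acquisition times (months) to nominal scheduled visits within a
## tolerance window; NA where no nominal visit is close enough.
map_to_nominal <- function(times, schedule = c(0, 12, 24), tolerance_months = 3) {
  schedule <- sort(schedule)
  idx <- vapply(times, function(t) {
    d <- abs(schedule - t)
    i <- which.min(d)
    if (d[i] <= tolerance_months) i else NA_integer_
  }, integer(1L))
  schedule[idx]
}

#' Fit control reference norms
#'
#' Computes, for every (region, nominal visit) cell, the mean and sample
#' standard deviation (n-1 denominator) of the control group's measurements.
#' Patient values standardized against these norms are expressed in control
#' standard deviations at the matching region and visit, which removes both
#' the normal-ageing level and the normal change over time from the patient
#' trajectories.
#'
#' @param x a `cohort` containing the control subjects (any patients present
#'   are ignored).
#' @param schedule nominal visit times in months (default 0, 12, 24).
#' @param tolerance_months half-width of the window mapping an actual
#'   acquisition time to its scheduled visit (default 3).
#' @return data.frame of class `reference_norms` with columns `region`,
#'   `visit_months`, `mean`, `sd`, `n`.
#' @export
fit_reference <- function(x, schedule = c(0, 12, 24), tolerance_months = 3) {
  stopifnot(inherits(x, "cohort"))
  ids <- x$subjects$subject_id[x$subjects$group == "control"]
  obs <- x$observations[x$observations$subject_id %in% ids, , drop = FALSE]
  if (nrow(obs) == 0L) stop("cohort contains no control observations")
  nominal <- map_to_nominal(obs$visit_months, schedule, tolerance_months)
  if (anyNA(nominal)) {
    i <- which(is.na(nominal))[1L]
    stop("control visit at ", obs$visit_months[i], " months (subject ",
         obs$subject_id[i], ") maps to no scheduled visit within ",
         tolerance_months, " months")
  }
  key <- paste(obs$region, nominal, sep = "\r")
  grp <- split(obs$value, key)
  parts <- strsplit(names(grp), "\r", fixed = TRUE)
  norms <- data.frame(
    region = vapply(parts, `[`, "", 1L),
    visit_months = as.numeric(vapply(parts, `[`, "", 2L)),
    mean = vapply(grp, mean, 0),
    sd = vapply(grp, sd, 0),
    n = vapply(grp, length, 0L),
    row.names = NULL)
  full <- expand.grid(region = x$panel$region, visit_months = sort(schedule),
                      stringsAsFactors = FALSE)
  absent <- !paste(full$region, full$visit_months) %in%
    paste(norms$region, norms$visit_months)
  if (any(absent))
    stop("no control observations in cell (region ", full$region[absent][1L],
         ", visit ", full$visit_months[absent][1L], " months)")
  bad <- norms$n < 2L
  if (any(bad))
    stop("fewer than 2 controls in cell (region ", norms$region[bad][1L],
         ", visit ", norms$visit_months[bad][1L], " months)")
  bad <- !is.finite(norms$sd) | norms$sd <= 0
  if (any(bad))
    stop("zero control variance in cell (region ", norms$region[bad][1L],
         ", visit ", norms$visit_months[bad][1L],
         " months); z-scores are undefined there")
  norms <- norms[order(match(norms$region, x$panel$region), norms$visit_months), ]
  rownames(norms) <- NULL
  class(norms) <- c("reference_norms", "data.frame")
  norms
}

#' Standardize a cohort against control reference norms
#'
#' Replaces each measurement by the z-score
#' `(value - mean(region, visit)) / sd(region, visit)` with the moments taken
#' from the control reference at the same region and nominal visit. After the
#' transformation a value of, say, -2 reads "two control standard deviations
#' below the healthy mean at that region and visit".
#'
#' @param x a `cohort` (patients and/or controls).
#' @param norms a `reference_norms` object from [fit_reference()].
#' @inheritParams fit_reference
#' @return the standardized `cohort` (with `standardized = TRUE`).
#' @export
to_zscores <- function(x, norms, schedule = c(0, 12, 24), tolerance_months = 3) {
  stopifnot(inherits(x, "cohort"), inherits(norms, "reference_norms"))
  obs <- x$observations
  nominal <- map_to_nominal(obs$visit_months, schedule, tolerance_months)
  if (anyNA(nominal)) {
    i <- which(is.na(nominal))[1L]
    stop("visit at ", obs$visit_months[i], " months (subject ",
         obs$subject_id[i], ") maps to no scheduled visit within ",
         tolerance_months, " months")
  }
  idx <- match(paste(obs$region, nominal),
               paste(norms$region, norms$visit_months))
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1L]
    stop("no reference norm for cell (region ", obs$region[i], ", visit ",
         nominal[i], " months), needed for subject ", obs$subject_id[i])
  }
  obs$value <- (obs$value - norms$mean[idx]) / norms$sd[idx]
  cohort(obs, x$subjects, panel = x$panel, standardized = TRUE)
}

#' Write / read reference norms as CSV
#'
#' Norms round-trip through a plain CSV (`region, visit_months, mean, sd, n`)
#' for audit and reuse across analyses.
#'
#' @param norms a `reference_norms` object.
#' @param path CSV file path.
#' @return `write_norms` returns `norms` invisibly; `read_norms` returns the
#'   `reference_norms` object.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "reference_norms"))
  write.csv(as.data.frame(norms), path, row.names = FALSE, quote = FALSE)
  invisible(norms)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path)
  norms <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "visit_months", "mean", "sd", "n")
  miss <- setdiff(need, names(norms))
  if (length(miss))
    stop("norms file is missing column(s): ", paste(miss, collapse = ", "))
  if (any(norms$sd <= 0)) stop("norms file contains non-positive sd")
  if (any(norms$n < 2)) stop("norms file contains cells with n < 2")
  class(norms) <- c("reference_norms", "data.frame")
  norms
}
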
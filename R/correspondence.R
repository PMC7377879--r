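#' Read a cluster-correspondence matrix
#'
#' A correspondence matrix cross-tabulates two clusterings of the same
#' subjects — rows one solution, columns the other. The package ships the
#' correspondence between a cross-sectional AD-subtype clustering and the
#' longitudinal solution of the reference cohort as
#' `inst/extdata/crosssectional_correspondence.csv` (the default path).
#'
#' @param path CSV whose first column names the row clustering; defaults to
#'   the packaged matrix.
#' @return integer matrix with row/column cluster names as dimnames.
#' @export
read_correspondence <- function(path = NULL) {
  path <- path %||% system.file("extdata", "crosssectional_correspondence.csv",
                                package = "trajmix", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("correspondence counts must be non-negative")
  m
}

#' Aggregate a longitudinal solution into atrophy-pattern totals
#'
#' Collapses the longitudinal clusters of a correspondence matrix into the
#' interpretable atrophy patterns — typical/diffuse, minimal atrophy,
#' hippocampal sparing — plus the outlier clusters and the HPD-uncertain
#' group, and reports each pattern's share of the cohort as a percentage
#' (one decimal).
#'
#' @param m a correspondence matrix from [read_correspondence()], whose
#'   columns follow the packaged naming (`diffuse_*`, `minimal_atrophy`,
#'   `hs_*`, `cluster_*`, `hpd_uncertain`).
#' @return data.frame with columns `pattern`, `n`, `percent`.
#' @export
atrophy_pattern_totals <- function(m) {
  cols <- colnames(m)
  groups <- list(
    typical_diffuse = grep("^diffuse", cols, value = TRUE),
    minimal_atrophy = grep("^minimal", cols, value = TRUE),
    hippocampal_sparing = grep("^hs_", cols, value = TRUE),
    outlier = grep("^cluster_", cols, value = TRUE),
    hpd_uncertain = grep("^hpd", cols, value = TRUE))
  if (!setequal(unlist(groups), cols))
    stop("unrecognized column(s): ",
         paste(setdiff(cols, unlist(groups)), collapse = ", "))
  n <- vapply(groups, function(g) sum(m[, g, drop = FALSE]), 0)
  total <- sum(m)
  data.frame(pattern = names(groups), n = as.integer(n),
             percent = round(100 * n / total, 1), row.names = NULL)
}
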
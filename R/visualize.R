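#' Classical MDS embedding of the probability matrix
#'
#' Embeds subjects by classical (Torgerson) multidimensional scaling of the
#' pairwise Euclidean distances between their posterior probability rows.
#' Subjects confidently assigned to the same component land close together;
#' mixed-membership subjects sit between component corners. Coordinates are
#' ordered by descending eigenvalue and are centered by construction.
#'
#' @param prob_matrix row-stochastic N x K matrix (e.g. from
#'   [posterior_probabilities()]).
#' @param d requested embedding dimension (default `min(5, N - 1)`);
#'   truncated to the number of positive eigenvalues, with a warning when `d`
#'   was supplied explicitly and silently when it was defaulted.
#' @return object of class `mds_embedding`: list with `coordinates` (N x d',
#'   d' <= d), `eigenvalues`, `subject_ids`.
#' @export
mds_embed <- function(prob_matrix, d = NULL) {
  P <- as.matrix(prob_matrix)
  N <- nrow(P)
  if (N < 2L) stop("need at least 2 subjects to embed")
  explicit_d <- !is.null(d)
  d <- as.integer(d %||% min(5L, N - 1L))
  if (d < 1L || d > N - 1L) stop("d must lie in 1..N-1")
  mds <- cmdscale(dist(P), k = d, eig = TRUE)
  npos <- sum(mds$eig > sqrt(.Machine$double.eps) * max(abs(mds$eig), 1))
  if (npos < d) {
    if (explicit_d)
      warning("only ", npos, " positive eigenvalue(s); truncating embedding ",
              "from ", d, " to ", max(npos, 1L), " dimension(s)")
    d <- max(npos, 1L)
  }
  coords <- as.matrix(mds$points)[, seq_len(min(d, ncol(mds$points))), drop = FALSE]
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = mds$eig,
                 subject_ids = rownames(P) %||% as.character(seq_len(N))),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$coordinates), "subjects in",
      ncol(x$coordinates), "dimensions\n")
  ev <- x$eigenvalues[x$eigenvalues > 0]
  cat("  variance share of kept dimensions:",
      round(sum(x$eigenvalues[seq_len(ncol(x$coordinates))]) / sum(ev), 3), "\n")
  invisible(x)
}

#' Export an MDS embedding, with grouping, as CSV
#'
#' @param x an `mds_embedding`.
#' @param path output CSV path.
#' @param grouping optional vector (labels/flags) aligned with subjects, to
#'   color external plots by.
#' @return the exported data.frame, invisibly.
#' @export
write_embedding <- function(x, path, grouping = NULL) {
  stopifnot(inherits(x, "mds_embedding"))
  out <- data.frame(subject_id = x$subject_ids, x$coordinates)
  if (!is.null(grouping)) out$group <- as.character(grouping)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Cluster fitted-value maps at a covariate profile
#'
#' For each retained posterior draw, cluster k, time t and region j the
#' fitted value `x' beta_j + mu_k[intercept_j] + (t / time_scale)
#' mu_k[slope_j]` is evaluated at the supplied covariate profile; the
#' across-draw median and first/third quartiles are reported. On a
#' standardized cohort these are control-referenced z-values: a map value of
#' -2 means two control standard deviations below the healthy mean for that
#' region and time.
#'
#' @param fit a relabeled `mmlmm` fit.
#' @param profile named covariate values on the raw scale; must supply every
#'   covariate of the fixed design (ignored when the model has none).
#' @param times visit times in months (default 0, 12, 24).
#' @return data.frame of class `cluster_maps` with columns `cluster`,
#'   `time_months`, `region`, `median`, `q1`, `q3`, `masked` (all `FALSE`
#'   until [apply_display_mask()] is applied).
#' @export
fitted_maps <- function(fit, profile = NULL, times = c(0, 12, 24)) {
  stopifnot(inherits(fit, "mmlmm"))
  if (!fit$relabeled && fit$K > 1L)
    stop("relabel() the chain before computing cluster maps")
  frame <- fit$frame
  if (frame$p > 0L) {
    if (is.null(profile))
      stop("the model has fixed effects; supply a covariate profile")
    profile <- unlist(profile)
    miss <- setdiff(frame$covariate_names, names(profile))
    if (length(miss))
      stop("covariate profile is missing: ", paste(miss, collapse = ", "))
    xr <- (profile[frame$covariate_names] - frame$covariate_center) /
      frame$covariate_scale
  }
  R <- fit$n_retained
  out <- expand.grid(cluster = seq_len(fit$K), time_months = times,
                     region = frame$regions, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$median <- out$q1 <- out$q3 <- NA_real_
  for (row in seq_len(nrow(out))) {
    k <- out$cluster[row]
    j <- match(out$region[row], frame$regions)
    tt <- out$time_months[row] / frame$time_scale
    vals <- fit$draws$mu[, 2L * j - 1L, k] + tt * fit$draws$mu[, 2L * j, k]
    if (frame$p > 0L)
      vals <- vals + drop(matrix(fit$draws$beta[, , j], nrow = R) %*% xr)
    qq <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out$q1[row] <- qq[1L]; out$median[row] <- qq[2L]; out$q3[row] <- qq[3L]
  }
  out$masked <- FALSE
  attr(out, "quartile_basis") <- "posterior_draws"
  class(out) <- c("cluster_maps", "data.frame")
  out
}

#' Subject-dispersion variant of the quartile maps
#'
#' Alternative reading of the dispersion quartiles: instead of quartiles
#' across posterior draws, quartiles across the subjects assigned to each
#' cluster of their own fitted baseline/followup values (posterior-mean
#' random effects). The median column remains the cluster's fitted value.
#'
#' @inheritParams fitted_maps
#' @param classification an `mmlmm_classification` supplying the assignments.
#' @return a `cluster_maps` data.frame with
#'   `attr(, "quartile_basis") == "subjects"`.
#' @export
fitted_maps_subject_quartiles <- function(fit, classification, profile = NULL,
                                          times = c(0, 12, 24)) {
  stopifnot(inherits(classification, "mmlmm_classification"))
  out <- fitted_maps(fit, profile = profile, times = times)
  frame <- fit$frame
  lab <- classification$labels
  keep <- classification$flags == "assigned"
  for (row in seq_len(nrow(out))) {
    k <- out$cluster[row]
    j <- match(out$region[row], frame$regions)
    tt <- out$time_months[row] / frame$time_scale
    members <- which(keep & lab == k)
    if (length(members) < 2L) next
    vals <- fit$b_mean[members, 2L * j - 1L] +
      tt * fit$b_mean[members, 2L * j]
    out$q1[row] <- quantile(vals, 0.25, names = FALSE)
    out$q3[row] <- quantile(vals, 0.75, names = FALSE)
  }
  attr(out, "quartile_basis") <- "subjects"
  out
}

#' Mask fitted values that do not depart from the control mean
#'
#' Display rule for z-scale maps: only fitted values strictly below
#' `threshold` control standard deviations (default -2) are shown; entries at
#' or above the threshold get `masked = TRUE`. Underlying values are kept —
#' masking is a lossless display layer.
#'
#' @param maps a `cluster_maps` data.frame.
#' @param threshold display threshold in control SD units (default -2).
#' @return the maps with the `masked` flag set.
#' @export
apply_display_mask <- function(maps, threshold = -2) {
  stopifnot(inherits(maps, "cluster_maps"))
  maps$masked <- !(maps$median < threshold)
  maps
}

#' Write cluster maps to CSV
#' @param maps a `cluster_maps` data.frame.
#' @param path output CSV path.
#' @return `maps`, invisibly.
#' @export
write_maps <- function(maps, path) {
  stopifnot(inherits(maps, "cluster_maps"))
  df <- as.data.frame(maps)
  df$quartile_basis <- attr(maps, "quartile_basis") %||% "posterior_draws"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(maps)
}
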
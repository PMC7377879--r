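#' Posterior mean subject-component probabilities
#'
#' `p_hat[i, k]`: the mean over retained draws of the per-draw allocation
#' probabilities `P(U_i = k | y_i, theta^(r))` (the default estimator), or
#' the relative frequency of sampled allocations `U_i^(r) = k`
#' (`estimator = "frequency"`). Rows sum to 1.
#'
#' @param fit a relabeled `mmlmm` fit.
#' @param estimator `"mean"` (default) or `"frequency"`.
#' @return N x K matrix with subject ids as row names.
#' @export
posterior_probabilities <- function(fit, estimator = c("mean", "frequency")) {
  stopifnot(inherits(fit, "mmlmm"))
  if (!fit$relabeled)
    stop("chain must be relabeled first: call relabel() before averaging ",
         "allocation probabilities across draws")
  estimator <- match.arg(estimator)
  K <- fit$K
  P <- if (estimator == "mean") {
    apply(fit$draws$prob, c(2L, 3L), mean)
  } else {
    t(vapply(seq_len(fit$frame$N), function(i)
      tabulate(fit$draws$U[, i], K) / fit$n_retained, numeric(K)))
  }
  P <- matrix(P, ncol = K,
              dimnames = list(fit$frame$subject_ids,
                              paste0("cluster", seq_len(K))))
  P / rowSums(P)
}

#' Maximum-probability cluster labels
#'
#' Assigns each subject to the component with the highest posterior
#' probability; exact ties go to the lowest cluster index with a warning.
#'
#' @param prob_matrix row-stochastic N x K matrix.
#' @return integer labels named by the matrix row names.
#' @export
assign_max_prob <- function(prob_matrix) {
  P <- as.matrix(prob_matrix)
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("prob_matrix rows must sum to 1")
  lab <- max.col(P, ties.method = "first")
  tie <- vapply(seq_len(nrow(P)), function(i)
    sum(P[i, ] == max(P[i, ])) > 1L, logical(1L))
  if (any(tie))
    warning("tied maximum probabilities for ", sum(tie),
            " subject(s); ties broken toward the lowest cluster index")
  setNames(lab, rownames(P))
}

#' HPD-interval classification uncertainty
#'
#' For each subject and component the highest-posterior-density interval of
#' the per-draw allocation probabilities is computed (shortest-interval
#' method, see [hpd_interval()]). Under the default `"overlap"` rule a
#' subject is flagged uncertain when the HPD interval of its top component's
#' probability overlaps the interval of any other component: the chain then
#' does not separate the memberships with high certainty. The alternative
#' `"lower_bound"` rule flags subjects whose top-component lower HPD bound
#' falls below `lower_bound`.
#'
#' @param fit a relabeled `mmlmm` fit with at least 10 retained draws.
#' @param coverage HPD mass (default 0.95).
#' @param rule `"overlap"` or `"lower_bound"`.
#' @param lower_bound threshold for the `"lower_bound"` rule.
#' @return list with `intervals` (N x K x 2 array, lower/upper) and
#'   `uncertain` (logical per subject).
#' @export
hpd_uncertainty <- function(fit, coverage = 0.95,
                            rule = c("overlap", "lower_bound"),
                            lower_bound = 0.5) {
  stopifnot(inherits(fit, "mmlmm"), coverage > 0, coverage < 1)
  rule <- match.arg(rule)
  if (!fit$relabeled) stop("relabel() the chain before HPD classification")
  if (fit$n_retained < 10L)
    stop("need at least 10 retained draws for stable HPD intervals (have ",
         fit$n_retained, ")")
  N <- fit$frame$N; K <- fit$K
  intervals <- array(NA_real_, c(N, K, 2L),
                     dimnames = list(fit$frame$subject_ids,
                                     paste0("cluster", seq_len(K)),
                                     c("lower", "upper")))
  for (i in seq_len(N)) for (k in seq_len(K))
    intervals[i, k, ] <- hpd_interval(fit$draws$prob[, i, k], coverage)
  P <- posterior_probabilities(fit)
  top <- max.col(P, ties.method = "first")
  uncertain <- logical(N)
  for (i in seq_len(N)) {
    lo <- intervals[i, , 1L]; hi <- intervals[i, , 2L]
    k <- top[i]
    uncertain[i] <- if (rule == "overlap") {
      any(vapply(seq_len(K)[-k], function(l)
        lo[k] <= hi[l] && lo[l] <= hi[k], logical(1L)))
    } else {
      lo[k] < lower_bound
    }
  }
  if (K == 1L) uncertain[] <- FALSE
  list(intervals = intervals,
       uncertain = setNames(uncertain, fit$frame$subject_ids))
}

#' Flag members of outlier (undersized) clusters
#'
#' Clusters with fewer than `min_size` assigned subjects are too small to
#' interpret as population patterns; their members are flagged as outliers
#' rather than treated as a subtype.
#'
#' @param labels integer cluster labels (from [assign_max_prob()]).
#' @param min_size minimum interpretable cluster size (default 3).
#' @return logical vector, `TRUE` for members of undersized clusters.
#' @export
flag_outlier_clusters <- function(labels, min_size = 3L) {
  stopifnot(min_size >= 1L)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_size])
  setNames(labels %in% small, names(labels))
}

#' Classify subjects from a fitted mixture, with uncertainty
#'
#' Combines the soft clustering into explicit subject-level classifications:
#' posterior mean probabilities, maximum-probability labels, outlier-cluster
#' flags, and HPD-interval uncertainty flags. Flag precedence is
#' deterministic and sequential: outlier-cluster membership is evaluated
#' first on the max-probability labels; the HPD uncertainty rule is then
#' applied to the remaining subjects only.
#'
#' @param fit a relabeled `mmlmm` fit.
#' @param coverage HPD mass (default 0.95).
#' @param min_size minimum interpretable cluster size (default 3).
#' @param rule HPD uncertainty rule, see [hpd_uncertainty()].
#' @param lower_bound threshold for the `"lower_bound"` rule.
#' @param estimator probability estimator, see [posterior_probabilities()].
#' @return an object of class `mmlmm_classification`: list with
#'   `prob_matrix`, `labels`, `flags` (factor: `assigned`,
#'   `outlier_cluster_member`, `hpd_uncertain`), `hpd` (intervals array),
#'   `coverage`, `min_size`, `K`.
#' @export
classify <- function(fit, coverage = 0.95, min_size = 3L,
                     rule = c("overlap", "lower_bound"), lower_bound = 0.5,
                     estimator = c("mean", "frequency")) {
  rule <- match.arg(rule)
  P <- posterior_probabilities(fit, estimator = match.arg(estimator))
  labels <- assign_max_prob(P)
  outlier <- flag_outlier_clusters(labels, min_size = min_size)
  hpd <- hpd_uncertainty(fit, coverage = coverage, rule = rule,
                         lower_bound = lower_bound)
  flags <- rep("assigned", length(labels))
  flags[hpd$uncertain & !outlier] <- "hpd_uncertain"
  flags[outlier] <- "outlier_cluster_member"
  out <- list(prob_matrix = P, labels = labels,
              flags = factor(flags, levels = c("assigned",
                                               "outlier_cluster_member",
                                               "hpd_uncertain")),
              hpd = hpd$intervals, coverage = coverage,
              min_size = min_size, rule = rule, K = fit$K)
  class(out) <- "mmlmm_classification"
  out
}

#' @export
print.mmlmm_classification <- function(x, ...) {
  cat("Mixture classification of", length(x$labels), "subjects into",
      x$K, "components\n")
  kept <- x$flags == "assigned"
  cat("  assigned:", sum(kept),
      " outlier-cluster members:", sum(x$flags == "outlier_cluster_member"),
      " HPD-uncertain:", sum(x$flags == "hpd_uncertain"), "\n")
  cat("  cluster sizes (assigned subjects):\n")
  print(table(factor(x$labels[kept], seq_len(x$K))))
  invisible(x)
}

#' Export a classification as a flat table
#'
#' @param x an `mmlmm_classification`.
#' @param path optional CSV path; when given the table is also written there.
#' @return data.frame with subject id, label, flag, per-cluster posterior
#'   probabilities and HPD bounds.
#' @export
classification_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "mmlmm_classification"))
  K <- x$K
  out <- data.frame(subject_id = names(x$labels), label = unname(x$labels),
                    flag = as.character(x$flags))
  for (k in seq_len(K)) {
    out[[paste0("p", k)]] <- unname(x$prob_matrix[, k])
    out[[paste0("hpd", k, "_lower")]] <- unname(x$hpd[, k, 1L])
    out[[paste0("hpd", k, "_upper")]] <- unname(x$hpd[, k, 2L])
  }
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' @export
plot.mmlmm_classification <- function(x, dims = c(1L, 2L), ...) {
  emb <- suppressWarnings(mds_embed(x$prob_matrix, d = max(dims)))
  co <- emb$coordinates
  if (ncol(co) < max(dims))  # flat configurations: pad degenerate axes
    co <- cbind(co, matrix(0, nrow(co), max(dims) - ncol(co)))
  cols <- ifelse(x$flags == "hpd_uncertain", "orange",
                 ifelse(x$flags == "outlier_cluster_member", "black",
                        grDevices::hcl.colors(x$K, "Dark 3")[x$labels]))
  plot(co[, dims[1L]], co[, dims[2L]],
       col = cols, pch = 19,
       xlab = paste("MDS", dims[1L]), ylab = paste("MDS", dims[2L]),
       main = "MDS of subject-component probabilities", ...)
  invisible(x)
}
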
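#' Posterior mean deviance of a candidate chain
#'
#' @param fit an `mmlmm` fit.
#' @return scalar; the mean of the retained deviance trace.
#' @export
deviance_summary <- function(fit) {
  stopifnot(inherits(fit, "mmlmm"))
  if (!length(fit$draws$deviance)) stop("empty deviance trace")
  mean(fit$draws$deviance)
}

## |lag-1 autocorrelation| of one scalar trace; 0 (with warning) for a
## constant trace, where autocorrelation is undefined.
lag1_autocorrelation <- function(x) {
  if (sd(x) == 0 || !is.finite(sd(x))) {
    warning("constant trace: lag-1 autocorrelation reported as 0")
    return(0)
  }
  abs(acf(x, lag.max = 1L, plot = FALSE)$acf[2L])
}

#' Convergence quality via lag-1 autocorrelation
#'
#' The maximum absolute lag-1 autocorrelation over the monitored scalar
#' traces (by default the deviance trace and the mixture weights, which are
#' scalar and label-robust after relabeling). Lower is better: strongly
#' autocorrelated retained draws indicate poor mixing.
#'
#' @param fit an `mmlmm` fit with at least 20 retained draws.
#' @param monitored character subset of `c("deviance", "weights")`.
#' @return scalar in `[0, 1]`.
#' @export
autocorrelation_score <- function(fit, monitored = c("deviance", "weights")) {
  stopifnot(inherits(fit, "mmlmm"))
  if (fit$n_retained < 20L)
    stop("need at least 20 retained draws to estimate autocorrelation")
  monitored <- match.arg(monitored, several.ok = TRUE)
  traces <- list()
  if ("deviance" %in% monitored) traces$deviance <- fit$draws$deviance
  if ("weights" %in% monitored)
    for (k in seq_len(fit$K)) traces[[paste0("w", k)]] <- fit$draws$w[, k]
  max(vapply(traces, lag1_autocorrelation, 0))
}

#' Mean classification certainty
#'
#' The mean over subjects of the maximum posterior component probability;
#' ranges from 1/K (uniform soft clustering) to 1 (hard assignments).
#'
#' @param x an `mmlmm_classification`, an `mmlmm` fit (relabeled), or a
#'   row-stochastic probability matrix.
#' @return scalar in `[1/K, 1]`.
#' @export
certainty_score <- function(x) {
  P <- if (inherits(x, "mmlmm_classification")) x$prob_matrix
  else if (inherits(x, "mmlmm")) posterior_probabilities(x)
  else as.matrix(x)
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("probability rows must sum to 1")
  mean(apply(P, 1L, max))
}

#' Hybrid ranking of candidate mixture models
#'
#' Scores each candidate chain on three criteria — posterior mean deviance,
#' convergence quality (max lag-1 autocorrelation of monitored traces), and
#' classification certainty — min-max scales each criterion to `[0, 1]`
#' across candidates with orientation such that 1 is best (deviance and
#' autocorrelation are inverted), and ranks by the weighted mean of the three
#' scaled scores. When all candidates are identical on a criterion, that
#' criterion contributes 1 to every candidate (logged via a message). Ties
#' in the combined score go to the smaller K.
#'
#' @param fits list of relabeled `mmlmm` fits (>= 2).
#' @param weights positive length-3 weights for (deviance, autocorrelation,
#'   certainty); default equal.
#' @param labels optional candidate names.
#' @return a `model_scorecard` data.frame ordered best-first, with raw and
#'   scaled criteria and the combined score.
#' @export
hybrid_rank <- function(fits, weights = c(1, 1, 1) / 3, labels = NULL) {
  stopifnot(is.list(fits), length(fits) >= 2L, length(weights) == 3L,
            all(weights > 0))
  weights <- weights / sum(weights)
  raw <- data.frame(
    candidate = labels %||% paste0("chain", seq_along(fits)),
    K = vapply(fits, function(f) f$K, 0L),
    init = vapply(fits, function(f) f$control$init, ""),
    seed = vapply(fits, function(f) f$control$seed, 0L),
    deviance = vapply(fits, deviance_summary, 0),
    autocorrelation = vapply(fits, autocorrelation_score, 0),
    certainty = vapply(fits, function(f) certainty_score(f), 0))

  scale01 <- function(x, invert = FALSE) {
    rng <- range(x)
    if (rng[2L] - rng[1L] <= 1e-10 * max(1, abs(rng[2L]))) {
      message("hybrid_rank: all candidates identical on a criterion; ",
              "it contributes 1 to every candidate")
      return(rep(1, length(x)))
    }
    s <- (x - rng[1L]) / (rng[2L] - rng[1L])
    if (invert) 1 - s else s
  }
  raw$deviance_scaled <- scale01(raw$deviance, invert = TRUE)
  raw$autocorrelation_scaled <- scale01(raw$autocorrelation, invert = TRUE)
  raw$certainty_scaled <- scale01(raw$certainty)
  raw$combined <- weights[1L] * raw$deviance_scaled +
    weights[2L] * raw$autocorrelation_scaled +
    weights[3L] * raw$certainty_scaled
  ord <- order(-raw$combined, raw$K)
  out <- raw[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_scorecard", "data.frame")
  out
}

#' @export
print.model_scorecard <- function(x, ...) {
  cat("Hybrid model-selection scorecard (best first):\n")
  df <- as.data.frame(x)
  df[c("deviance", "autocorrelation", "certainty", "combined")] <-
    lapply(df[c("deviance", "autocorrelation", "certainty", "combined")],
           function(v) round(v, 4))
  print(df[c("candidate", "K", "init", "deviance", "autocorrelation",
             "certainty", "combined")])
  invisible(x)
}

#' Write a scorecard to CSV
#' @param x a `model_scorecard`.
#' @param path output CSV path.
#' @return `x`, invisibly.
#' @export
write_scorecard <- function(x, path) {
  stopifnot(inherits(x, "model_scorecard"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
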
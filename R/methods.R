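#' @export
print.mmlmm <- function(x, ...) {
  cat("Bayesian mixture of multivariate linear mixed models\n")
  cat("  components: ", x$K, ",  regions: ", x$frame$J,
      ",  subjects: ", x$frame$N, ",  observations: ", x$frame$M, "\n", sep = "")
  cat("  chain: ", x$control$n_iter, " sweeps, burn-in ", x$control$burn_in,
      ", thin ", x$control$thin, " -> ", x$n_retained,
      " retained draws (seed ", x$control$seed, ", init ", x$control$init,
      ")\n", sep = "")
  cat("  posterior mean deviance: ", format(mean(x$draws$deviance), digits = 6),
      if (!x$relabeled) "  [not yet relabeled]", "\n", sep = "")
  invisible(x)
}

#' @export
summary.mmlmm <- function(object, ...) {
  w_mean <- colMeans(object$draws$w)
  mu_mean <- apply(object$draws$mu, c(2L, 3L), mean)
  rownames(mu_mean) <- paste(rep(object$frame$regions, each = 2L),
                             c("intercept", "slope"), sep = ".")
  colnames(mu_mean) <- paste0("cluster", seq_len(object$K))
  out <- list(K = object$K, weights = w_mean, mu = mu_mean,
              phi = colMeans(object$draws$phi),
              deviance = mean(object$draws$deviance),
              n_retained = object$n_retained,
              relabeled = object$relabeled)
  if (object$frame$p > 0L) {
    beta_mean <- apply(object$draws$beta, c(2L, 3L), mean)
    beta_sd <- apply(object$draws$beta, c(2L, 3L), sd)
    dimnames(beta_mean) <- dimnames(beta_sd) <-
      list(object$frame$covariate_names, object$frame$regions)
    out$beta <- beta_mean
    out$beta_sd <- beta_sd
  }
  class(out) <- "summary.mmlmm"
  out
}

#' @export
print.summary.mmlmm <- function(x, ...) {
  cat("Mixture of multivariate linear mixed models, K =", x$K, "\n\n")
  cat("Posterior mean weights:\n")
  print(round(x$weights, 3))
  cat("\nPosterior mean cluster trajectories (random-effect means):\n")
  print(round(x$mu, 3))
  if (!is.null(x$beta)) {
    cat("\nFixed effects (posterior mean, scaled covariates):\n")
    print(round(x$beta, 3))
  }
  cat("\nResidual variances phi_j:", round(x$phi, 4), "\n")
  cat("Posterior mean deviance:", format(x$deviance, digits = 6),
      "over", x$n_retained, "draws\n")
  invisible(x)
}

#' @export
coef.mmlmm <- function(object, ...) {
  out <- list(weights = colMeans(object$draws$w),
              mu = apply(object$draws$mu, c(2L, 3L), mean),
              phi = colMeans(object$draws$phi))
  if (object$frame$p > 0L) {
    out$beta <- apply(object$draws$beta, c(2L, 3L), mean)
    dimnames(out$beta) <- list(object$frame$covariate_names,
                               object$frame$regions)
  }
  out
}

#' Posterior mean deviance of a fitted mixture
#'
#' The mean of the retained deviance trace (`-2 log f(y; theta)` per draw),
#' the fit criterion used when comparing candidate models.
#'
#' @param object an `mmlmm` fit.
#' @param ... unused.
#' @return scalar.
#' @export
deviance.mmlmm <- function(object, ...) mean(object$draws$deviance)

#' @export
logLik.mmlmm <- function(object, ...) {
  ll <- -mean(object$draws$deviance) / 2
  attr(ll, "df") <- NA_integer_
  attr(ll, "nobs") <- object$frame$M
  class(ll) <- "logLik"
  ll
}

#' Fitted cluster trajectories at a covariate profile
#'
#' For each posterior draw the cluster-k fitted value in region j at time t
#' is `x' beta_j + mu_k[j, intercept] + (t / time_scale) mu_k[j, slope]`,
#' with `x` the supplied covariate profile (raw scale; the frame's stored
#' centering and scaling are applied). The across-draw median and quartiles
#' are returned; see [fitted_maps()] for the display-oriented wrapper.
#'
#' @param object an `mmlmm` fit (relabel first for K > 1).
#' @param profile named list/vector of covariate values on the raw scale;
#'   required when the model has fixed effects.
#' @param times visit times in months.
#' @param ... unused.
#' @return data.frame with columns `cluster`, `time_months`, `region`,
#'   `median`, `q1`, `q3`.
#' @export
predict.mmlmm <- function(object, profile = NULL, times = c(0, 12, 24), ...) {
  fitted_maps(object, profile = profile, times = times)
}

#' @export
residuals.mmlmm <- function(object, ...) {
  frame <- object$frame
  state_beta <- if (frame$p > 0L)
    apply(object$draws$beta, c(2L, 3L), mean) else matrix(0, 0L, frame$J)
  fix <- if (frame$p > 0L) {
    CB <- frame$C %*% state_beta
    CB[cbind(frame$obs_subject, frame$obs_region)]
  } else numeric(frame$M)
  zb <- rowSums(frame$Z * object$b_mean[frame$obs_subject, , drop = FALSE])
  r <- frame$y - fix - zb
  names(r) <- paste(frame$subject_ids[frame$obs_subject],
                    frame$regions[frame$obs_region],
                    frame$visit_months, sep = ":")
  r
}

#' Simulate cohorts from a fitted mixture
#'
#' Draws new synthetic cohorts from the generative model at the posterior
#' mean parameters (weights, cluster means and covariances, residual
#' variances), using the fitted visit structure. Useful for posterior
#' predictive checks.
#'
#' @param object a relabeled `mmlmm` fit.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` results from [generate_cohort()].
#' @export
simulate.mmlmm <- function(object, nsim = 1, seed = 1L, ...) {
  frame <- object$frame
  co <- coef(object)
  Dbar <- apply(object$draws$D, c(2L, 3L, 4L), mean)
  intercepts <- co$mu[seq(1L, frame$q, 2L), , drop = FALSE]
  slopes <- co$mu[seq(2L, frame$q, 2L), , drop = FALSE]
  design <- simulation_design(
    n_controls = 0L, n_patients = frame$N, k = object$K,
    weights = co$weights / sum(co$weights),
    n_regions = frame$J, region_names = frame$regions,
    cluster_intercepts = intercepts, cluster_slopes = slopes,
    random_effect_cov = Dbar[, , 1L],
    residual_sd = sqrt(co$phi),
    covariates = list(),
    raw_scale = FALSE)
  lapply(seq_len(nsim), function(s) generate_cohort(design, seed = seed + s - 1L))
}

#' @export
plot.mmlmm <- function(x, which = c("deviance", "weights"), ...) {
  which <- match.arg(which)
  if (which == "deviance") {
    plot(x$draws$deviance, type = "l", xlab = "retained draw",
         ylab = "deviance", main = "Deviance trace", ...)
  } else {
    graphics::matplot(x$draws$w, type = "l", lty = 1L,
                      xlab = "retained draw", ylab = "mixture weight",
                      main = "Weight traces", ...)
  }
  invisible(x)
}
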
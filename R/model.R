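#' Build the model frame for a mixture fit
#'
#' Arranges a (standardized) cohort into the per-subject design used by the
#' mixture of multivariate linear mixed models: for subject i, region j and
#' visit l the conditional mean is `x_{ijl}' beta_j + z_{ijl}' b_{ij}`, where
#' `z_{ijl} = (1, t/time_scale)` is the random intercept-and-slope design and
#' `x_{ijl}` collects the fixed covariates (shared across regions, with
#' region-specific coefficients `beta_j`). The joint random-effect vector
#' `b_i` stacks the J per-region (intercept, slope) pairs, so `q = 2J`.
#'
#' Numeric covariates are centered and scaled to unit variance before
#' entering the design (the centers and scales are stored and re-applied to
#' any covariate profile supplied later, e.g. by [fitted_maps()]).
#'
#' @param x a `cohort`.
#' @param fixed one-sided formula over the subject covariate columns (e.g.
#'   `~ age + sex + icv`), or `NULL` for no fixed effects. No intercept is
#'   included: with hierarchically centered random effects the cluster means
#'   `mu_k` absorb the level.
#' @param group which subjects enter the model (default `"patient"`).
#' @param time_scale divisor converting `visit_months` to the slope's time
#'   unit; the default 12 measures slopes per year.
#' @param scale_covariates center and scale numeric covariates (default
#'   `TRUE`); turn off to interpret coefficients on the raw covariate scale.
#' @return an object of class `mmlmm_frame`.
#' @export
mmlmm_frame <- function(x, fixed = NULL, group = "patient", time_scale = 12,
                        scale_covariates = TRUE) {
  stopifnot(inherits(x, "cohort"), time_scale > 0)
  if (!is.null(group)) x <- subset_group(x, group)
  obs <- x$observations
  regions <- x$panel$region
  J <- length(regions)
  ids <- sort(unique(obs$subject_id))
  N <- length(ids)
  ord <- order(match(obs$subject_id, ids),
               match(obs$region, regions), obs$visit_months)
  obs <- obs[ord, , drop = FALSE]
  obs_subject <- match(obs$subject_id, ids)
  obs_region <- match(obs$region, regions)
  q <- 2L * J
  M <- nrow(obs)
  tt <- obs$visit_months / time_scale
  Z <- matrix(0, M, q)
  Z[cbind(seq_len(M), 2L * obs_region - 1L)] <- 1
  Z[cbind(seq_len(M), 2L * obs_region)] <- tt

  subj <- x$subjects[match(ids, x$subjects$subject_id), , drop = FALSE]
  if (is.null(fixed)) {
    C <- matrix(0, N, 0)
    centers <- scales <- numeric(0)
  } else {
    stopifnot(inherits(fixed, "formula"))
    vars <- all.vars(fixed)
    miss <- setdiff(vars, names(subj))
    if (length(miss))
      stop("covariate(s) not in subject table: ", paste(miss, collapse = ", "))
    for (v in vars) if (anyNA(subj[[v]])) {
      bad <- ids[is.na(subj[[v]])][1L]
      stop("covariate ", v, " is missing for subject ", bad,
           "; model covariates must be complete (no silent imputation)")
    }
    C <- model.matrix(fixed, data = subj)
    C <- C[, colnames(C) != "(Intercept)", drop = FALSE]
    if (scale_covariates) {
      centers <- colMeans(C)
      scales <- apply(C, 2L, sd)
      scales[!is.finite(scales) | scales == 0] <- 1
      C <- scale(C, center = centers, scale = scales)
      attr(C, "scaled:center") <- NULL
      attr(C, "scaled:scale") <- NULL
    } else {
      centers <- rep(0, ncol(C))
      scales <- rep(1, ncol(C))
      names(centers) <- names(scales) <- colnames(C)
    }
  }

  sub_len <- tabulate(obs_subject, N)
  sub_start <- cumsum(c(0L, sub_len[-N]))
  region_idx <- split(seq_len(M), factor(obs_region, seq_len(J)))
  XtX <- lapply(region_idx, function(ix)
    crossprod(C[obs_subject[ix], , drop = FALSE]))
  nij <- table(factor(obs_subject, seq_len(N)), factor(obs_region, seq_len(J)))
  if (any(nij == 0L)) {
    w <- which(nij == 0L, arr.ind = TRUE)[1L, ]
    stop("subject ", ids[w[1L]], " has no observations for region ",
         regions[w[2L]], "; every subject needs n_{i,j} >= 1")
  }

  structure(list(
    subject_ids = ids, regions = regions, panel = x$panel,
    N = N, J = J, q = q, p = ncol(C), M = M,
    y = obs$value, obs_subject = obs_subject, obs_region = obs_region,
    visit_months = obs$visit_months, Z = Z, C = C,
    covariate_names = colnames(C), covariate_center = centers,
    covariate_scale = scales, fixed = fixed, time_scale = time_scale,
    tt = tt, obs_region0 = obs_region - 1L,
    sub_start = as.integer(sub_start), sub_len = as.integer(sub_len),
    region_idx = region_idx, XtX = XtX,
    standardized = x$standardized, subjects = subj
  ), class = "mmlmm_frame")
}

#' Mixture model parameter state
#'
#' Validates one full set of model parameters: mixture weights `w` (a
#' K-simplex), cluster random-effect means `mu` (q x K), cluster covariances
#' `D` (list of K positive-definite q x q matrices), region fixed effects
#' `beta` (p x J), region residual variances `phi` (length J, positive),
#' subject random effects `b` (N x q) and allocations `U` (in 1..K).
#'
#' @param w,mu,D,beta,phi,b,U see description.
#' @return a validated object of class `mixture_state`.
#' @export
mixture_state <- function(w, mu, D, beta, phi, b, U) {
  w <- as.numeric(w)
  K <- length(w)
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
    stop("w must be positive and sum to 1")
  mu <- as.matrix(mu)
  if (ncol(mu) != K) stop("mu must have one column per component")
  q <- nrow(mu)
  if (!is.list(D) || length(D) != K) stop("D must be a list of K matrices")
  for (k in seq_len(K)) {
    Dk <- D[[k]]
    if (!isTRUE(all.equal(Dk, t(Dk), tolerance = 1e-8)))
      stop("D[[", k, "]] is not symmetric")
    ev <- eigen(Dk, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("D[[", k, "]] is not positive definite")
  }
  beta <- as.matrix(beta)
  phi <- as.numeric(phi)
  if (any(phi <= 0)) stop("phi must be positive")
  b <- as.matrix(b)
  if (ncol(b) != q) stop("b must have q columns")
  U <- as.integer(U)
  if (any(U < 1L | U > K)) stop("U must lie in 1..K")
  if (length(U) != nrow(b)) stop("U and b disagree on the number of subjects")
  structure(list(w = w, mu = mu, D = D, beta = beta, phi = phi, b = b, U = U,
                 K = K, q = q),
            class = "mixture_state")
}

check_state_frame <- function(frame, state) {
  if (state$q != frame$q)
    stop("state random-effect dimension ", state$q,
         " does not match the frame (q = ", frame$q, ")")
  if (nrow(state$beta) != frame$p || ncol(state$beta) != frame$J)
    stop("beta must be p x J = ", frame$p, " x ", frame$J)
  if (length(state$phi) != frame$J) stop("phi must have length J")
  if (nrow(state$b) != frame$N) stop("b must have one row per subject")
  invisible(TRUE)
}

## Component precisions D_k^{-1} (q x q x K cube) and log-determinants
## log|D_k|, from one Cholesky per component.
dinv_info <- function(D) {
  K <- length(D); q <- nrow(D[[1L]])
  Dinv <- array(0, c(q, q, K))
  logdetD <- numeric(K)
  for (k in seq_len(K)) {
    ch <- chol(D[[k]])
    Dinv[, , k] <- chol2inv(ch)
    logdetD[k] <- 2 * sum(log(diag(ch)))
  }
  list(Dinv = Dinv, logdetD = logdetD)
}

## Per-subject sufficient statistics at the state's (beta, phi).
subject_stats <- function(frame, state) {
  subject_stats_cpp(frame$y, frame$sub_start, frame$sub_len,
                    frame$obs_region0, frame$tt,
                    fixed_part(frame, state), state$phi)
}

## X_i beta contribution per observation (vector of length M).
fixed_part <- function(frame, state) {
  if (frame$p == 0L) return(numeric(frame$M))
  CB <- frame$C %*% state$beta
  CB[cbind(frame$obs_subject, frame$obs_region)]
}

#' Conditional fitted values for one subject and region
#'
#' Evaluates the conditional mean `x'beta_j + z'b_{ij}` over the subject's
#' visits in the given region, at the supplied parameter state.
#'
#' @param frame an [mmlmm_frame()].
#' @param state a [mixture_state()].
#' @param subject subject id (character) or index.
#' @param region region name (character) or index.
#' @return numeric vector of fitted values, one per visit, named by
#'   `visit_months`.
#' @export
linear_predictor <- function(frame, state, subject, region) {
  stopifnot(inherits(frame, "mmlmm_frame"), inherits(state, "mixture_state"))
  check_state_frame(frame, state)
  i <- if (is.character(subject)) match(subject, frame$subject_ids) else as.integer(subject)
  j <- if (is.character(region)) match(region, frame$regions) else as.integer(region)
  if (is.na(i) || i < 1L || i > frame$N) stop("unknown subject: ", subject)
  if (is.na(j) || j < 1L || j > frame$J) stop("unknown region: ", region)
  ix <- which(frame$obs_subject == i & frame$obs_region == j)
  if (!length(ix)) stop("subject has no visits for region ", region)
  fixed <- if (frame$p) drop(frame$C[i, , drop = FALSE] %*% state$beta[, j]) else 0
  z <- frame$Z[ix, c(2L * j - 1L, 2L * j), drop = FALSE]
  setNames(drop(fixed + z %*% state$b[i, c(2L * j - 1L, 2L * j)]),
           frame$visit_months[ix])
}

## N x K matrix of component marginal log-densities log f_{i,k}(y_i).
component_logdens <- function(frame, state) {
  check_state_frame(frame, state)
  st <- subject_stats(frame, state)
  ci <- dinv_info(state$D)
  comp_logdens_stats_cpp(st$u0, st$A, st$rq0, st$nlogphi, frame$sub_len,
                         state$mu, ci$Dinv, ci$logdetD)
}

#' Closed-form component marginal log-likelihood of one subject
#'
#' Integrating the random effects out of the conditional model gives
#' `y_i | U_i = k ~ N(X_i beta + Z_i mu_k, Z_i D_k Z_i' + Phi_i)` with
#' `Phi_i` diagonal (residual variance `phi_j` for each observation of
#' region j). This is that multivariate normal log-density, computed here in
#' plain R as the package's reference implementation (the sampler uses a
#' compiled equivalent).
#'
#' @inheritParams linear_predictor
#' @param k component index in 1..K.
#' @param subject subject id or index.
#' @return scalar log-density.
#' @export
log_component_marginal <- function(frame, state, subject, k) {
  stopifnot(inherits(frame, "mmlmm_frame"), inherits(state, "mixture_state"))
  check_state_frame(frame, state)
  k <- as.integer(k)
  if (k < 1L || k > state$K) stop("component index out of range")
  i <- if (is.character(subject)) match(subject, frame$subject_ids) else as.integer(subject)
  if (is.na(i) || i < 1L || i > frame$N) stop("unknown subject: ", subject)
  ix <- frame$sub_start[i] + seq_len(frame$sub_len[i])
  Zi <- frame$Z[ix, , drop = FALSE]
  m <- fixed_part(frame, state)[ix] + drop(Zi %*% state$mu[, k])
  Sig <- Zi %*% state$D[[k]] %*% t(Zi)
  diag(Sig) <- diag(Sig) + state$phi[frame$obs_region[ix]]
  R <- tryCatch(chol(Sig), error = function(e)
    stop("marginal covariance not positive definite for subject ",
         frame$subject_ids[i], " (condition number ", format(kappa(Sig)), ")"))
  r <- frame$y[ix] - m
  v <- backsolve(R, r, transpose = TRUE)
  -0.5 * (length(ix) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(v^2))
}

#' Mixture marginal log-likelihood of one subject
#'
#' `log f_i(y_i; theta) = log sum_k w_k f_{i,k}(y_i)`, evaluated by
#' log-sum-exp over [log_component_marginal()].
#'
#' @inheritParams log_component_marginal
#' @return scalar log-likelihood.
#' @export
log_mixture_likelihood <- function(frame, state, subject) {
  lk <- vapply(seq_len(state$K), function(k)
    log_component_marginal(frame, state, subject, k), 0)
  logsumexp(log(state$w) + lk)
}

#' Mixture deviance of a dataset at a parameter state
#'
#' `-2 sum_i log f_i(y_i; theta)`, additive over subjects.
#'
#' @inheritParams linear_predictor
#' @return scalar deviance.
#' @export
mixture_deviance <- function(frame, state) {
  stopifnot(inherits(frame, "mmlmm_frame"), inherits(state, "mixture_state"))
  lf <- component_logdens(frame, state)
  -2 * sum(row_logsumexp(sweep(lf, 2L, log(state$w), "+")))
}
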
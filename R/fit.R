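## Per-subject ordinary least squares (intercept, slope) per region, used by
## every initialization strategy; slope 0 where a subject-region has < 2
## distinct times. Returns N x q.
subject_ols <- function(frame) {
  B0 <- matrix(0, frame$N, frame$q)
  tt <- frame$visit_months / frame$time_scale
  for (i in seq_len(frame$N)) {
    ix <- frame$sub_start[i] + seq_len(frame$sub_len[i])
    for (j in unique(frame$obs_region[ix])) {
      jj <- ix[frame$obs_region[ix] == j]
      t_j <- tt[jj]; y_j <- frame$y[jj]
      if (length(unique(t_j)) >= 2L) {
        sl <- cov(t_j, y_j) / var(t_j)
        ic <- mean(y_j) - sl * mean(t_j)
      } else {
        sl <- 0; ic <- mean(y_j)
      }
      B0[i, 2L * j - 1L] <- ic
      B0[i, 2L * j] <- sl
    }
  }
  B0
}

## Baseline-visit value matrix (N x J): each subject's earliest visit per
## region, the cross-sectional view the baseline initializers cluster on.
baseline_matrix <- function(frame) {
  V <- matrix(NA_real_, frame$N, frame$J)
  for (i in seq_len(frame$N)) {
    ix <- frame$sub_start[i] + seq_len(frame$sub_len[i])
    for (j in unique(frame$obs_region[ix])) {
      jj <- ix[frame$obs_region[ix] == j]
      V[i, j] <- frame$y[jj[which.min(frame$visit_months[jj])]]
    }
  }
  V
}

#' Initialize the sampler state
#'
#' Builds a valid starting [mixture_state()] from the data. Allocation-based
#' strategies (`default`, `kmeans_baseline`, `hierarchical_baseline`) derive
#' starting allocations (randomly, or by k-means / Ward hierarchical
#' clustering of the baseline-visit values) and set each cluster mean to the
#' empirical mean of its members' per-subject OLS intercepts and slopes.
#' `given_means_plus_noise` perturbs supplied means by U(-h, h) per
#' coordinate and allocates each subject to the nearest perturbed mean.
#' Strategies that can leave a component empty are re-drawn up to
#' `control$max_init_retries` times before erroring.
#'
#' @param frame an [mmlmm_frame()].
#' @param k number of mixture components (>= 1).
#' @param priors an [mmlmm_priors()].
#' @param control an [mmlmm_control()]; consumes the current RNG stream (seed
#'   management belongs to the caller, [mmlmm()] seeds once per chain).
#' @return a [mixture_state()].
#' @export
initialize_state <- function(frame, k, priors, control) {
  stopifnot(inherits(frame, "mmlmm_frame"), k >= 1L, k <= frame$N)
  B0 <- subject_ols(frame)
  q <- frame$q
  mu <- NULL

  draw_alloc <- function() {
    switch(control$init,
      default = sample.int(k, frame$N, replace = TRUE),
      kmeans_baseline = {
        V <- baseline_matrix(frame)
        V[is.na(V)] <- 0
        if (k == 1L) rep(1L, frame$N) else
          kmeans(V, centers = k, nstart = 5L)$cluster
      },
      hierarchical_baseline = {
        V <- baseline_matrix(frame)
        V[is.na(V)] <- 0
        cutree(hclust(dist(V), method = "ward.D2"), k = k)
      },
      given_means_plus_noise = {
        if (is.null(control$init_means))
          stop("init_means is required for given_means_plus_noise")
        m0 <- as.matrix(control$init_means)
        if (nrow(m0) != q || ncol(m0) != k)
          stop("init_means must be a q x K = ", q, " x ", k, " matrix")
        h <- control$noise_half_width
        mu <<- m0 + matrix(runif(q * k, -h, h), q, k)
        d2 <- vapply(seq_len(k), function(kk)
          colSums((t(B0) - mu[, kk])^2), numeric(frame$N))
        max.col(-matrix(d2, frame$N, k), ties.method = "first")
      })
  }

  U <- draw_alloc()
  tries <- 0L
  while (length(unique(U)) < k) {
    tries <- tries + 1L
    if (tries > control$max_init_retries)
      stop("initialization left a component empty after ",
           control$max_init_retries, " retries (K = ", k,
           ", N = ", frame$N, ")")
    U <- draw_alloc()
  }

  if (is.null(mu) || control$init != "given_means_plus_noise") {
    mu <- vapply(seq_len(k), function(kk)
      colMeans(B0[U == kk, , drop = FALSE]), numeric(q))
    mu <- matrix(mu, q, k)
  }
  Dpool <- cov(B0)
  Dpool <- Dpool + diag(0.05 * mean(diag(Dpool)) + 1e-3, q)
  D <- rep(list(Dpool), k)
  phi <- vapply(seq_len(frame$J), function(j) {
    ix <- frame$region_idx[[j]]
    fitted <- rowSums(frame$Z[ix, , drop = FALSE] *
                        B0[frame$obs_subject[ix], , drop = FALSE])
    max(var(frame$y[ix] - fitted), 1e-3)
  }, 0)
  nk <- tabulate(U, k)
  mixture_state(w = nk / sum(nk), mu = mu, D = D,
                beta = matrix(0, frame$p, frame$J), phi = phi,
                b = B0, U = U)
}

#' One systematic-scan Gibbs sweep
#'
#' Updates, in order: allocations `U_i` from the collapsed categorical
#' conditional (proportional to `w_k f_{i,k}(y_i)` with random effects
#' integrated out), weights `w` from Dirichlet(`delta + n_k`), random effects
#' `b_i` from their Gaussian conditionals, cluster means `mu_k` (Gaussian),
#' cluster precisions `D_k^{-1}` (Wishart), fixed effects `beta_j`
#' (Gaussian, independent across regions), and residual variances `phi_j`
#' (inverse-gamma). Consumes the current R RNG stream.
#'
#' @param frame an [mmlmm_frame()].
#' @param state a [mixture_state()].
#' @param priors an [mmlmm_priors()].
#' @return the updated `mixture_state`.
#' @export
gibbs_sweep <- function(frame, state, priors) {
  gibbs_sweep_internal(frame, state, expand_priors(priors, frame$q))$state
}

## Unvalidated state constructor for the sampler's inner loop; the public
## mixture_state() checks invariants, the sweep preserves them by design.
new_state <- function(w, mu, D, beta, phi, b, U, K, q) {
  structure(list(w = w, mu = mu, D = D, beta = beta, phi = phi, b = b,
                 U = U, K = K, q = q), class = "mixture_state")
}

## --- full-conditional updates -----------------------------------------------
## Each update draws from one conjugate full conditional given its inputs;
## gibbs_sweep_internal chains them in the systematic-scan order.

## (a) U_i ~ Categorical(prop. to w_k f_{i,k}(y_i)), sampled by Gumbel-max.
update_allocations <- function(logf, w) {
  N <- nrow(logf); K <- ncol(logf)
  g <- logf + rep(log(w), each = N)
  gum <- -log(-log(matrix(runif(N * K), N, K)))
  max.col(g + gum, ties.method = "first")
}

## (b) w ~ Dirichlet(delta + n_1, ..., delta + n_K).
update_weights <- function(U, K, delta) {
  rdirichlet1(delta + tabulate(U, K))
}

## (d) mu_k ~ N((Cinv + n_k Dinv_k)^{-1} (Cinv xi + Dinv_k sum b_i), ...) and
## (e) D_k^{-1} ~ Wishart(nu + n_k, (Sinv + sum (b-mu)(b-mu)')^{-1}),
## with mu_k drawn at the incoming D_k.
update_cluster_params <- function(b, U, K, Dinv, pr) {
  q <- ncol(b)
  mu <- matrix(0, q, K)
  D <- vector("list", K)
  nk <- tabulate(U, K)
  for (k in seq_len(K)) {
    bs <- b[U == k, , drop = FALSE]
    Lam <- pr$Cinv + nk[k] * Dinv[, , k]
    m <- solve(Lam, pr$Cinv %*% pr$xi + Dinv[, , k] %*% colSums(bs))
    mu[, k] <- rmvnorm_prec(drop(m), Lam)
    ctr <- sweep(bs, 2L, mu[, k])
    Spost <- chol2inv(chol(pr$Sinv + crossprod(ctr)))
    Dinv_k <- rWishart(1L, pr$nu + nk[k], Spost)[, , 1L]
    D[[k]] <- chol2inv(chol(Dinv_k))
  }
  list(mu = mu, D = D)
}

## (f) beta_j ~ N(A^{-1} X_j' r_j / phi_j, A^{-1}), A = I/v + X_j'X_j/phi_j,
## independent across regions, then (g) phi_j ~ IG(a + n_j/2, b + RSS_j/2).
update_region_params <- function(frame, b, phi, pr) {
  beta <- matrix(0, frame$p, frame$J)
  e <- frame$y - rowSums(frame$Z * b[frame$obs_subject, , drop = FALSE])
  for (j in seq_len(frame$J)) {
    ix <- frame$region_idx[[j]]
    if (frame$p > 0L) {
      Xj <- frame$C[frame$obs_subject[ix], , drop = FALSE]
      A <- diag(1 / pr$vbeta, frame$p) + frame$XtX[[j]] / phi[j]
      rhs <- crossprod(Xj, e[ix]) / phi[j]
      beta[, j] <- rmvnorm_prec(drop(solve(A, rhs)), A)
      resid <- e[ix] - drop(Xj %*% beta[, j])
    } else {
      resid <- e[ix]
    }
    phi[j] <- 1 / rgamma(1L, shape = pr$a + length(ix) / 2,
                         rate = pr$bb + sum(resid^2) / 2)
  }
  list(beta = beta, phi = phi)
}

gibbs_sweep_internal <- function(frame, state, pr) {
  K <- state$K; q <- frame$q; N <- frame$N

  ## (a) allocations from the collapsed conditional
  st <- subject_stats(frame, state)
  ci <- dinv_info(state$D)
  logf <- comp_logdens_stats_cpp(st$u0, st$A, st$rq0, st$nlogphi,
                                 frame$sub_len, state$mu, ci$Dinv, ci$logdetD)
  U <- update_allocations(logf, state$w)

  ## (b) weights
  w <- update_weights(U, K, pr$delta)

  ## (c) random effects
  b <- draw_b_stats_cpp(st$u0, st$A, state$mu, ci$Dinv, U)

  ## (d) cluster means, (e) cluster precisions
  cp <- update_cluster_params(b, U, K, ci$Dinv, pr)

  ## (f) fixed effects, (g) dispersions
  rp <- update_region_params(frame, b, state$phi, pr)

  list(state = new_state(w, cp$mu, cp$D, rp$beta, rp$phi, b, U, K, q),
       logf = logf)
}

#' Fit a Bayesian mixture of multivariate linear mixed models
#'
#' Clusters subjects of a longitudinal cohort by their multi-region
#' intercept-and-slope trajectory patterns. Each subject's joint random
#' effect vector `b_i` (a per-region intercept and slope, length `q = 2J`)
#' follows, given latent cluster `U_i = k`, a multivariate normal
#' `N(mu_k, D_k)` (hierarchical centering: the cluster means carry the
#' trajectory levels). Conditional on `b_i` the observations are Gaussian
#' with region fixed effects `beta_j` and residual variances `phi_j` shared
#' across clusters. The model is fit by a systematic-scan Gibbs sampler with
#' conjugate full conditionals (see [gibbs_sweep()]); the returned object
#' holds every retained posterior draw plus the per-draw subject-component
#' probability matrices on which soft clustering is based.
#'
#' @param x a `cohort`, normally standardized with [to_zscores()] first
#'   (a warning is issued otherwise).
#' @param k number of mixture components.
#' @param fixed one-sided covariate formula (see [mmlmm_frame()]).
#' @param priors an [mmlmm_priors()].
#' @param control an [mmlmm_control()]; `control$seed` makes the chain
#'   bit-reproducible.
#' @param group which subjects enter the model (default `"patient"`).
#' @param time_scale months per slope time unit (default 12: slopes per year).
#' @param scale_covariates see [mmlmm_frame()].
#' @return an object of class `mmlmm` with components `draws` (retained
#'   parameter draws: `w`, `mu`, `D`, `beta`, `phi`, `U`, `prob`,
#'   `deviance`), `frame`, `priors`, `control`, `K`, `b_mean`, `relabeled`.
#' @examples
#' design <- simulation_design(n_controls = 12, n_patients = 24, k = 2,
#'                             n_regions = 2)
#' sim <- generate_cohort(design, seed = 1)
#' zc <- to_zscores(sim$cohort, fit_reference(sim$cohort))
#' fit <- mmlmm(zc, k = 2, control = mmlmm_control(n_iter = 400, burn_in = 200,
#'                                                 thin = 2, seed = 1))
#' fit
#' @export
mmlmm <- function(x, k, fixed = NULL, priors = mmlmm_priors(),
                  control = mmlmm_control(), group = "patient",
                  time_scale = 12, scale_covariates = TRUE) {
  cl <- match.call()
  frame <- if (inherits(x, "mmlmm_frame")) x else
    mmlmm_frame(x, fixed = fixed, group = group, time_scale = time_scale,
                scale_covariates = scale_covariates)
  if (!frame$standardized)
    warning("cohort is not standardized; consider to_zscores() first so the ",
            "priors' scale assumptions hold")
  stopifnot(inherits(priors, "mmlmm_priors"), inherits(control, "mmlmm_control"))
  k <- as.integer(k)
  pr <- expand_priors(priors, frame$q)
  R <- retained_sample_count(control)
  N <- frame$N; q <- frame$q; J <- frame$J; p <- frame$p

  set.seed(control$seed)
  state <- initialize_state(frame, k, priors, control)

  draws <- list(
    w = matrix(NA_real_, R, k),
    mu = array(NA_real_, c(R, q, k)),
    D = array(NA_real_, c(R, q, q, k)),
    beta = array(NA_real_, c(R, max(p, 0L), J)),
    phi = matrix(NA_real_, R, J),
    U = matrix(NA_integer_, R, N),
    prob = array(NA_real_, c(R, N, k)),
    deviance = numeric(R))
  b_sum <- matrix(0, N, q)

  r <- 0L
  for (iter in seq_len(control$n_iter)) {
    sw <- tryCatch(gibbs_sweep_internal(frame, state, pr),
                   error = function(e)
                     stop("chain aborted at iteration ", iter, ": ",
                          conditionMessage(e)))
    state <- sw$state
    if (iter > control$burn_in &&
        (iter - control$burn_in) %% control$thin == 0L && r < R) {
      r <- r + 1L
      ## probabilities and deviance are evaluated at the stored state
      st <- subject_stats(frame, state)
      ci <- dinv_info(state$D)
      logf <- comp_logdens_stats_cpp(st$u0, st$A, st$rq0, st$nlogphi,
                                     frame$sub_len, state$mu, ci$Dinv,
                                     ci$logdetD)
      g <- logf + rep(log(state$w), each = N)
      ll <- row_logsumexp(g)
      draws$w[r, ] <- state$w
      draws$mu[r, , ] <- state$mu
      for (kk in seq_len(k)) draws$D[r, , , kk] <- state$D[[kk]]
      if (p > 0L) draws$beta[r, , ] <- state$beta
      draws$phi[r, ] <- state$phi
      draws$U[r, ] <- state$U
      draws$prob[r, , ] <- exp(g - ll)
      draws$deviance[r] <- -2 * sum(ll)
      b_sum <- b_sum + state$b
    }
  }

  structure(list(draws = draws, frame = frame, priors = priors,
                 control = control, K = k, n_retained = R,
                 b_mean = b_sum / R, relabeled = (k == 1L),
                 final_state = state, call = cl),
            class = "mmlmm")
}

#' Correct label switching across retained draws
#'
#' Mixture likelihoods are invariant under permutation of component indices,
#' so a chain may visit equivalent relabelings; averaging allocation
#' probabilities across draws is only meaningful after aligning them.
#' Pivot relabeling is used: the retained draw with the highest posterior
#' density (smallest deviance) is the pivot, and every draw's components are
#' permuted to maximize the agreement `sum_k sum_i p_pivot[i,k] p_draw[i,k]`
#' with it. Per-draw deviances and mixture likelihoods are unchanged.
#'
#' @param fit an `mmlmm` object.
#' @return the fit with aligned draws and `relabeled = TRUE`.
#' @export
relabel <- function(fit) {
  stopifnot(inherits(fit, "mmlmm"))
  K <- fit$K
  if (K == 1L) {
    fit$relabeled <- TRUE
    return(fit)
  }
  pivot <- which.min(fit$draws$deviance)
  Ppiv <- fit$draws$prob[pivot, , , drop = TRUE]
  Ppiv <- matrix(Ppiv, ncol = K)
  perms <- if (K <= 7L) all_permutations(K) else NULL
  d <- fit$draws
  for (r in seq_len(fit$n_retained)) {
    Pr <- matrix(d$prob[r, , ], ncol = K)
    A <- crossprod(Ppiv, Pr)  # A[k, l] = sum_i p_piv[i,k] p_r[i,l]
    if (!is.null(perms)) {
      sc <- vapply(seq_len(nrow(perms)), function(m)
        sum(A[cbind(seq_len(K), perms[m, ])]), 0)
      sig <- perms[which.max(sc), ]
    } else {
      ## greedy assignment for large K: adequate when components are separated
      sig <- integer(K); taken <- logical(K)
      for (k in order(-apply(A, 1L, max))) {
        l <- which.max(ifelse(taken, -Inf, A[k, ]))
        sig[k] <- l; taken[l] <- TRUE
      }
    }
    if (all(sig == seq_len(K))) next
    invperm <- order(sig)
    d$w[r, ] <- d$w[r, sig]
    d$mu[r, , ] <- d$mu[r, , sig]
    d$D[r, , , ] <- d$D[r, , , sig]
    d$prob[r, , ] <- d$prob[r, , sig]
    d$U[r, ] <- invperm[d$U[r, ]]
  }
  fit$draws <- d
  fit$relabeled <- TRUE
  fit
}
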
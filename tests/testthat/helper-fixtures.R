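# Fixture builders shared across test files. Everything is generated in code;
# no data files beyond the packaged correspondence matrix.

## Small deterministic cohort: controls laid out so every (region, visit) cell
## has known mean/sd, patients with a simple visit structure.
toy_cohort <- function(n_controls = 4L, n_patients = 3L,
                       regions = c("hippocampus", "precuneus"),
                       visits = c(0, 12, 24)) {
  rows <- list()
  for (i in seq_len(n_controls)) {
    for (j in seq_along(regions)) {
      for (t in visits) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("C%02d", i), visit_months = t,
          region = regions[j],
          value = i + 0.1 * j + 0.01 * t)  # distinct values, sd > 0 per cell
      }
    }
  }
  for (i in seq_len(n_patients)) {
    for (j in seq_along(regions)) {
      for (t in visits[seq_len(min(i + 1L, length(visits)))]) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("P%02d", i), visit_months = t,
          region = regions[j], value = -i - 0.1 * j - 0.02 * t)
      }
    }
  }
  obs <- do.call(rbind, rows)
  subjects <- data.frame(
    subject_id = c(sprintf("C%02d", seq_len(n_controls)),
                   sprintf("P%02d", seq_len(n_patients))),
    group = c(rep("control", n_controls), rep("patient", n_patients)),
    age = seq(70, by = 1, length.out = n_controls + n_patients),
    sex = rep_len(c(0, 1), n_controls + n_patients))
  panel <- data.frame(region = regions,
                      kind = rep_len(c("volume", "thickness"), length(regions)))
  cohort(obs, subjects, panel = panel)
}

## Minimal standardized z-scale cohort from the simulator for model fitting.
small_sim <- function(seed = 1L, n_patients = 24L, n_controls = 10L, k = 2L,
                      n_regions = 2L, ...) {
  design <- simulation_design(n_controls = n_controls,
                              n_patients = n_patients, k = k,
                              n_regions = n_regions, ...)
  sim <- generate_cohort(design, seed = seed)
  norms <- fit_reference(sim$cohort)
  list(z = to_zscores(sim$cohort, norms), sim = sim, design = design)
}

## Hand-built "mmlmm" object carrying only the components the classification,
## selection and visualization layers read; prob is an R x N x K array.
make_fake_fit <- function(prob, deviance = NULL, w = NULL, mu = NULL,
                          beta = NULL, D = NULL, regions = NULL,
                          time_scale = 12, relabeled = TRUE,
                          subject_ids = NULL,
                          covariate_names = character(0),
                          covariate_center = NULL, covariate_scale = NULL) {
  stopifnot(length(dim(prob)) == 3L)
  R <- dim(prob)[1L]; N <- dim(prob)[2L]; K <- dim(prob)[3L]
  subject_ids <- subject_ids %||% sprintf("S%03d", seq_len(N))
  regions <- regions %||% paste0("region", seq_len(max(1L, dim(mu)[2L] %/% 2L)))
  q <- 2L * length(regions)
  p <- length(covariate_names)
  U <- t(apply(prob, 1L, function(m) max.col(matrix(m, ncol = K),
                                             ties.method = "first")))
  if (N == 1L) U <- matrix(U, R, 1L)
  default_w <- matrix(1 / K, R, K)
  if (K > 1L) {  # mild wiggle so monitored traces are not constant
    eps <- 0.01 * sin(seq_len(R))
    default_w[, 1L] <- default_w[, 1L] + eps
    default_w[, K] <- default_w[, K] - eps
  }
  draws <- list(
    prob = prob,
    w = w %||% default_w,
    mu = mu %||% array(0, c(R, q, K)),
    D = D %||% array(rep(diag(q), R * K), c(R, q, q, K)),
    beta = beta %||% array(0, c(R, p, length(regions))),
    phi = matrix(1, R, length(regions)),
    U = U,
    deviance = deviance %||% rep(100, R))
  frame <- list(subject_ids = subject_ids, regions = regions,
                J = length(regions), q = q, p = p, N = N,
                covariate_names = covariate_names,
                covariate_center = covariate_center %||% rep(0, p),
                covariate_scale = covariate_scale %||% rep(1, p),
                time_scale = time_scale)
  if (p > 0L) {
    names(frame$covariate_center) <- covariate_names
    names(frame$covariate_scale) <- covariate_names
  }
  structure(list(draws = draws, frame = frame, K = K, n_retained = R,
                 relabeled = relabeled,
                 b_mean = matrix(0, N, q),
                 control = mmlmm_control(n_iter = max(R, 2L), burn_in = 0L,
                                         thin = 1L, seed = 1L)),
            class = "mmlmm")
}

## `%||%` for helpers (tests run in their own environment).
`%||%` <- function(a, b) if (is.null(a)) b else a

## Monte-Carlo estimate of log f_{i,k}(y_i) by integrating the conditional
## Gaussian likelihood over b_i ~ N(mu_k, D_k); returns the estimate and its
## standard error on the log scale. Independent of the closed-form path.
mc_component_marginal <- function(frame, state, subject, k, n = 1e5,
                                  seed = 42L) {
  set.seed(seed)
  i <- if (is.character(subject)) match(subject, frame$subject_ids) else subject
  ix <- frame$sub_start[i] + seq_len(frame$sub_len[i])
  Zi <- frame$Z[ix, , drop = FALSE]
  fix <- if (frame$p) {
    CB <- frame$C %*% state$beta
    CB[cbind(frame$obs_subject, frame$obs_region)][ix]
  } else rep(0, length(ix))
  sds <- sqrt(state$phi[frame$obs_region[ix]])
  ch <- chol(state$D[[k]])
  ll <- vapply(seq_len(n), function(s) {
    b <- state$mu[, k] + drop(crossprod(ch, rnorm(frame$q)))
    sum(dnorm(frame$y[ix], mean = fix + drop(Zi %*% b), sd = sds, log = TRUE))
  }, 0)
  m <- max(ll)
  est <- m + log(mean(exp(ll - m)))
  rel <- exp(ll - m)
  se_log <- sd(rel) / (sqrt(n) * mean(rel))
  list(estimate = est, se = se_log)
}
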
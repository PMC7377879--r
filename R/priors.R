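#' Prior specification for the mixture model
#'
#' Conjugate, weakly-informative priors on the standardized (z-score) scale:
#' Dirichlet(`dirichlet_concentration`) on the weights; N(`mean_prior_mean`,
#' `mean_prior_var` I) on each cluster mean `mu_k`; Wishart(`wishart_df`,
#' `wishart_scale` I) on each cluster precision `D_k^{-1}` (so
#' `E[D_k^{-1}] = df * scale * I`); independent N(0, `beta_var`) on each fixed
#' effect; inverse-gamma(`disp_shape`, `disp_rate`) on each region's residual
#' variance `phi_j`.
#'
#' @param dirichlet_concentration Dirichlet concentration `delta` (> 0).
#' @param mean_prior_mean,mean_prior_var mean (scalar or length-q) and
#'   variance (scalar, diagonal) of the cluster-mean prior.
#' @param wishart_df Wishart degrees of freedom; `NULL` means `q + 1`
#'   (the smallest integer df giving a proper prior for any q).
#' @param wishart_scale scalar multiplying the identity Wishart scale matrix.
#' @param beta_var prior variance of each fixed-effect coefficient; large by
#'   default so the likelihood dominates (the posterior variance should come
#'   out much smaller than this, which is worth checking on a fitted model).
#' @param disp_shape,disp_rate inverse-gamma shape and rate for `phi_j`.
#' @return an object of class `mmlmm_priors`.
#' @export
mmlmm_priors <- function(dirichlet_concentration = 1,
                         mean_prior_mean = 0, mean_prior_var = 100,
                         wishart_df = NULL, wishart_scale = 1,
                         beta_var = 1e4,
                         disp_shape = 0.01, disp_rate = 0.01) {
  stopifnot(dirichlet_concentration > 0, mean_prior_var > 0,
            wishart_scale > 0, beta_var > 0, disp_shape > 0, disp_rate > 0)
  structure(list(dirichlet_concentration = dirichlet_concentration,
                 mean_prior_mean = mean_prior_mean,
                 mean_prior_var = mean_prior_var,
                 wishart_df = wishart_df, wishart_scale = wishart_scale,
                 beta_var = beta_var,
                 disp_shape = disp_shape, disp_rate = disp_rate),
            class = "mmlmm_priors")
}

## Expand scalar prior settings to the q-dimensional matrices the sampler uses.
expand_priors <- function(priors, q) {
  stopifnot(inherits(priors, "mmlmm_priors"))
  xi <- rep_len(priors$mean_prior_mean, q)
  nu <- priors$wishart_df %||% (q + 1)
  if (nu <= q - 1) stop("wishart_df must exceed q - 1 = ", q - 1)
  list(delta = priors$dirichlet_concentration,
       xi = xi,
       Cinv = diag(1 / priors$mean_prior_var, q),
       nu = nu,
       Sinv = diag(1 / priors$wishart_scale, q),
       vbeta = priors$beta_var,
       a = priors$disp_shape, bb = priors$disp_rate)
}

#' Chain configuration for the Gibbs sampler
#'
#' @param n_iter total Gibbs sweeps (>= 1).
#' @param burn_in discarded initial sweeps (`0 <= burn_in < n_iter`).
#' @param thin keep every `thin`-th post-burn-in state (>= 1).
#' @param seed integer RNG seed; the whole chain (initialization included)
#'   draws from one R RNG stream seeded with it.
#' @param init initialization strategy: `"default"` (random allocations),
#'   `"kmeans_baseline"` or `"hierarchical_baseline"` (cross-sectional
#'   clustering of the baseline-visit values), or `"given_means_plus_noise"`
#'   (supplied cluster means perturbed by uniform noise).
#' @param init_means q x K matrix of starting cluster means, required by
#'   `"given_means_plus_noise"`.
#' @param noise_half_width half-width h of the U(-h, h) perturbation used by
#'   `"given_means_plus_noise"`.
#' @param max_init_retries bound on re-draws when an initialization leaves a
#'   component empty.
#' @return an object of class `mmlmm_control`.
#' @export
mmlmm_control <- function(n_iter = 20000L, burn_in = 5000L, thin = 15L,
                          seed = 1L,
                          init = c("default", "kmeans_baseline",
                                   "hierarchical_baseline",
                                   "given_means_plus_noise"),
                          init_means = NULL, noise_half_width = 0.5,
                          max_init_retries = 25L) {
  init <- match.arg(init)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(n_iter >= 1L, burn_in >= 0L, thin >= 1L, noise_half_width >= 0)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  x <- structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                      seed = as.integer(seed), init = init,
                      init_means = init_means,
                      noise_half_width = noise_half_width,
                      max_init_retries = as.integer(max_init_retries)),
                 class = "mmlmm_control")
  if (retained_sample_count(x) < 1L)
    stop("configuration retains no draws: floor((n_iter - burn_in)/thin) < 1")
  x
}

#' Number of retained posterior draws implied by a chain configuration
#'
#' `floor((n_iter - burn_in) / thin)`; e.g. 750,000 iterations with a
#' 250,000-iteration burn-in thinned by 500 retain 1000 draws.
#'
#' @param control an [mmlmm_control()] (or a list with `n_iter`, `burn_in`,
#'   `thin`).
#' @return integer draw count.
#' @export
retained_sample_count <- function(control) {
  as.integer(floor((control$n_iter - control$burn_in) / control$thin))
}
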
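test_that("retained-draw bookkeeping follows floor((n_iter - burn_in)/thin)", {
  expect_equal(retained_sample_count(mmlmm_control(10L, 0L, 1L)), 10L)
  expect_equal(retained_sample_count(mmlmm_control(11L, 1L, 3L)), 3L)
  expect_equal(retained_sample_count(mmlmm_control(20000L, 5000L, 15L)), 1000L)
  expect_error(mmlmm_control(n_iter = 10L, burn_in = 10L), "burn_in")
  expect_error(mmlmm_control(n_iter = 5L, burn_in = 3L, thin = 10L),
               "retains no draws")
})

test_that("initialization strategies honour their contracts", {
  s <- small_sim(seed = 6, n_patients = 20, n_regions = 2, k = 2)
  fr <- mmlmm_frame(s$z)
  pri <- mmlmm_priors()

  # zero-noise given means are reproduced exactly
  m0 <- matrix(c(-2, -0.5, -2, -0.5, -0.4, -0.1, -0.4, -0.1), fr$q, 2)
  set.seed(1)
  st <- initialize_state(fr, 2L, pri,
                         mmlmm_control(init = "given_means_plus_noise",
                                       init_means = m0,
                                       noise_half_width = 0))
  expect_equal(st$mu, m0)

  # same seed, same initial state
  ctl <- mmlmm_control(init = "kmeans_baseline", seed = 3L)
  set.seed(3); a <- initialize_state(fr, 2L, pri, ctl)
  set.seed(3); b <- initialize_state(fr, 2L, pri, ctl)
  expect_identical(a, b)

  # k-means on two point clouds 10 SDs apart recovers the separation
  obs <- data.frame(
    subject_id = rep(sprintf("P%02d", 1:10), each = 2),
    visit_months = rep(c(0, 12), 10),
    region = "r1",
    value = rep(c(rep(0, 5), rep(10, 5)), each = 2) + rnorm(20, 0, 0.1))
  x <- cohort(obs, data.frame(subject_id = sprintf("P%02d", 1:10),
                              group = "patient"), standardized = TRUE)
  fr2 <- mmlmm_frame(x)
  set.seed(4)
  st2 <- initialize_state(fr2, 2L, pri, mmlmm_control(init = "kmeans_baseline"))
  expect_equal(length(unique(st2$U[1:5])), 1L)
  expect_equal(length(unique(st2$U[6:10])), 1L)
  expect_false(st2$U[1] == st2$U[6])
})

test_that("allocation full conditional matches its analytic categorical law", {
  logf <- rbind(c(log(0.7), log(0.3)), c(log(0.5), log(0.5)))
  w <- c(0.6, 0.4)
  probs <- exp(sweep(logf, 2, log(w), "+"))
  probs <- probs / rowSums(probs)
  set.seed(10)
  draws <- replicate(6000, trajmix:::update_allocations(logf, w))
  freq1 <- mean(draws[1, ] == 1)
  freq2 <- mean(draws[2, ] == 1)
  expect_lt(abs(freq1 - probs[1, 1]), 4 * sqrt(probs[1, 1] * (1 - probs[1, 1]) / 6000))
  expect_lt(abs(freq2 - probs[2, 1]), 4 * sqrt(probs[2, 1] * (1 - probs[2, 1]) / 6000))
})

test_that("weight full conditional matches the Dirichlet posterior moments", {
  # allocations (3, 1) over 4 subjects with delta = 1: E[w] = (4/6, 2/6)
  U <- c(1L, 1L, 1L, 2L)
  set.seed(11)
  draws <- t(replicate(8000, trajmix:::update_weights(U, 2L, 1)))
  a <- c(4, 2); a0 <- 6
  vmean <- a / a0
  vvar <- a * (a0 - a) / (a0^2 * (a0 + 1))
  for (k in 1:2) {
    expect_lt(abs(mean(draws[, k]) - vmean[k]), 4 * sqrt(vvar[k] / 8000))
    expect_equal(var(draws[, k]), vvar[k], tolerance = 0.1)
  }
  expect_equal(rowSums(draws), rep(1, 8000), tolerance = 1e-12)
})

test_that("random-effect full conditional has the analytic Gaussian moments", {
  s <- small_sim(seed = 12, n_patients = 4, n_regions = 2, k = 2)
  fr <- mmlmm_frame(s$z)
  q <- fr$q
  mu <- matrix(c(-1, -0.3, -0.8, -0.2, 0, 0, 0, 0), q, 2)
  D <- 0.3 * (0.8 * diag(q) + 0.2)
  st <- mixture_state(w = c(0.5, 0.5), mu = mu, D = list(D, D),
                      beta = matrix(0, fr$p, fr$J), phi = c(0.4, 0.6),
                      b = matrix(0, fr$N, q), U = rep(1L, fr$N))
  stats <- trajmix:::subject_stats(fr, st)
  ci <- trajmix:::dinv_info(st$D)
  U <- rep(1L, fr$N)
  # analytic conditional mean for subject 1
  Q <- stats$A[, , 1] + ci$Dinv[, , 1]
  m_true <- solve(Q, stats$u0[, 1] + ci$Dinv[, , 1] %*% mu[, 1])
  set.seed(13)
  draws <- replicate(4000,
    trajmix:::draw_b_stats_cpp(stats$u0, stats$A, st$mu, ci$Dinv, U)[1, ])
  emp_mean <- rowMeans(draws)
  sds <- sqrt(diag(solve(Q)))
  expect_true(all(abs(emp_mean - m_true) < 4 * sds / sqrt(4000)))
  # empirical covariance close to Q^{-1}
  expect_equal(cov(t(draws)), solve(Q), tolerance = 0.15)

  # degenerate-prior limit: D -> 0 pins the conditional mean at mu_k
  Dsmall <- diag(1e-8, q)
  ci2 <- trajmix:::dinv_info(list(Dsmall, Dsmall))
  set.seed(14)
  b2 <- trajmix:::draw_b_stats_cpp(stats$u0, stats$A, st$mu, ci2$Dinv, U)
  expect_equal(b2[1, ], mu[, 1], tolerance = 1e-3)
})

test_that("cluster mean and precision conditionals match analytic posteriors", {
  q <- 4L
  set.seed(15)
  D_true <- 0.5 * (0.7 * diag(q) + 0.3)
  mu_true <- c(-2, -0.5, -1, -0.3)
  b <- t(replicate(40, mu_true + drop(crossprod(chol(D_true), rnorm(q)))))
  U <- rep(1L, 40)
  pr <- trajmix:::expand_priors(mmlmm_priors(), q)
  Dinv <- trajmix:::dinv_info(list(D_true))$Dinv

  # mu | b, D: N(Lam^{-1} rhs, Lam^{-1})
  Lam <- pr$Cinv + 40 * Dinv[, , 1]
  m_true <- solve(Lam, pr$Cinv %*% pr$xi + Dinv[, , 1] %*% colSums(b))
  set.seed(16)
  mus <- replicate(4000,
    trajmix:::update_cluster_params(b, U, 1L, Dinv, pr)$mu[, 1])
  expect_true(all(abs(rowMeans(mus) - m_true) <
                    4 * sqrt(diag(solve(Lam))) / sqrt(4000) + 1e-8))

  # D^{-1} | b, mu: Wishart(nu + n, (Sinv + SS)^{-1}); pin mu via a
  # near-degenerate prior so the conditioning value is held fixed
  mu_fix <- m_true
  pr2 <- pr
  pr2$Cinv <- diag(1e12, q)
  pr2$xi <- drop(mu_fix)
  SS <- crossprod(sweep(b, 2, drop(mu_fix)))
  Spost <- solve(pr$Sinv + SS)
  EDinv <- (pr$nu + 40) * Spost
  set.seed(17)
  Dinvs <- replicate(2000, {
    Dk <- trajmix:::update_cluster_params(b, U, 1L, Dinv, pr2)$D[[1]]
    solve(Dk)
  })
  emp <- apply(Dinvs, c(1, 2), mean)
  # Wishart element SDs scale like sqrt(df) * scale
  tolm <- 4 * sqrt((pr$nu + 40)) * max(abs(Spost)) / sqrt(2000)
  expect_true(all(abs(emp - EDinv) < tolm + 0.05 * abs(EDinv)))
})

test_that("fixed-effect and dispersion conditionals match analytic posteriors", {
  s <- small_sim(seed = 18, n_patients = 12, n_regions = 2, k = 2)
  fr <- mmlmm_frame(s$z, fixed = NULL)
  q <- fr$q
  set.seed(19)
  b <- matrix(rnorm(fr$N * q, -1, 0.3), fr$N, q)
  pr <- trajmix:::expand_priors(mmlmm_priors(), q)

  # phi_j | b (no covariates): IG(a + n_j/2, b + RSS_j/2)
  e <- fr$y - rowSums(fr$Z * b[fr$obs_subject, ])
  set.seed(20)
  phis <- t(replicate(6000,
    trajmix:::update_region_params(fr, b, c(1, 1), pr)$phi))
  for (j in 1:2) {
    ix <- fr$region_idx[[j]]
    shape <- pr$a + length(ix) / 2
    rate <- pr$bb + sum(e[ix]^2) / 2
    Einv <- shape / rate
    expect_lt(abs(mean(1 / phis[, j]) - Einv),
              4 * sqrt(shape / rate^2 / 6000))
  }

  # beta_j | b, phi with covariates: N(A^{-1} rhs, A^{-1})
  frc <- mmlmm_frame(s$z, fixed = ~ age + sex)
  ec <- frc$y - rowSums(frc$Z * b[frc$obs_subject, ])
  phi_fix <- c(0.5, 0.8)
  set.seed(21)
  betas <- replicate(4000,
    trajmix:::update_region_params(frc, b, phi_fix, pr)$beta)
  for (j in 1:2) {
    ix <- frc$region_idx[[j]]
    Xj <- frc$C[frc$obs_subject[ix], , drop = FALSE]
    A <- diag(1 / pr$vbeta, frc$p) + crossprod(Xj) / phi_fix[j]
    m_true <- solve(A, crossprod(Xj, ec[ix]) / phi_fix[j])
    expect_true(all(abs(rowMeans(betas[, j, ]) - m_true) <
                      4 * sqrt(diag(solve(A))) / sqrt(4000)))
  }
})

test_that("chains are reproducible and store what the config promises", {
  s <- small_sim(seed = 22, n_patients = 16, n_regions = 2, k = 2)
  ctl <- mmlmm_control(n_iter = 300L, burn_in = 100L, thin = 2L, seed = 7L,
                       init = "kmeans_baseline")
  f1 <- mmlmm(s$z, k = 2, control = ctl)
  f2 <- mmlmm(s$z, k = 2, control = ctl)
  expect_equal(f1$n_retained, retained_sample_count(ctl))
  expect_equal(dim(f1$draws$prob), c(100L, 16L, 2L))
  expect_identical(f1$draws$deviance, f2$draws$deviance)
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_true(all(abs(apply(f1$draws$prob, c(1, 2), sum) - 1) < 1e-9))

  # a different seed moves the chain
  f3 <- mmlmm(s$z, k = 2,
              control = mmlmm_control(n_iter = 300L, burn_in = 100L,
                                      thin = 2L, seed = 8L,
                                      init = "kmeans_baseline"))
  expect_false(identical(f1$draws$deviance, f3$draws$deviance))
})

test_that("subject order does not change the fitted chain", {
  s <- small_sim(seed = 23, n_patients = 10, n_regions = 2, k = 2)
  z <- s$z
  perm <- sample(nrow(z$observations))
  z2 <- cohort(z$observations[perm, ],
               z$subjects[rev(seq_len(nrow(z$subjects))), ],
               panel = z$panel, standardized = TRUE)
  ctl <- mmlmm_control(n_iter = 200L, burn_in = 50L, thin = 2L, seed = 5L,
                       init = "kmeans_baseline")
  f1 <- mmlmm(z, k = 2, control = ctl)
  f2 <- mmlmm(z2, k = 2, control = ctl)
  expect_identical(f1$draws$deviance, f2$draws$deviance)
  expect_identical(f1$frame$subject_ids, f2$frame$subject_ids)
})

test_that("well-separated simulated clusters are recovered", {
  s <- small_sim(seed = 24, n_patients = 40, n_regions = 2, k = 2)
  fit <- relabel(mmlmm(s$z, k = 2,
                       control = mmlmm_control(n_iter = 1500L, burn_in = 500L,
                                               thin = 5L, seed = 24L,
                                               init = "kmeans_baseline")))
  rep <- truth_recovery_report(s$sim$truth, classify(fit))
  expect_gte(rep$ari, 0.9)
})

test_that("relabeling is a no-op without switching and inverts a forced swap", {
  s <- small_sim(seed = 25, n_patients = 20, n_regions = 2, k = 2)
  fit <- mmlmm(s$z, k = 2,
               control = mmlmm_control(n_iter = 400L, burn_in = 100L,
                                       thin = 3L, seed = 25L,
                                       init = "kmeans_baseline"))
  rl <- relabel(fit)
  expect_true(rl$relabeled)
  expect_identical(rl$draws$deviance, fit$draws$deviance)
  # with a well-separated 2-cluster fit the chain does not switch
  expect_identical(rl$draws$mu, fit$draws$mu)

  # force a swap in one draw; relabel must restore the original
  swapped <- fit
  r <- 5L
  swapped$draws$w[r, ] <- swapped$draws$w[r, 2:1]
  swapped$draws$mu[r, , ] <- swapped$draws$mu[r, , 2:1]
  swapped$draws$D[r, , , ] <- swapped$draws$D[r, , , 2:1]
  swapped$draws$prob[r, , ] <- swapped$draws$prob[r, , 2:1]
  swapped$draws$U[r, ] <- c(2L, 1L)[swapped$draws$U[r, ]]
  fixed <- relabel(swapped)
  expect_equal(fixed$draws$mu, fit$draws$mu)
  expect_equal(fixed$draws$prob, fit$draws$prob)
  expect_equal(fixed$draws$U, fit$draws$U)
  expect_identical(fixed$draws$deviance, swapped$draws$deviance)
})

test_that("the exported single sweep preserves state invariants", {
  s <- small_sim(seed = 26, n_patients = 10, n_regions = 2, k = 2)
  fr <- mmlmm_frame(s$z)
  set.seed(26)
  st <- initialize_state(fr, 2L, mmlmm_priors(), mmlmm_control())
  st2 <- gibbs_sweep(fr, st, mmlmm_priors())
  expect_s3_class(st2, "mixture_state")
  expect_equal(sum(st2$w), 1)
  expect_true(all(st2$phi > 0))
  expect_true(all(st2$U %in% 1:2))
})

test_that("a richer mixture does not fit worse than its nested submodel", {
  s <- small_sim(seed = 27, n_patients = 30, n_regions = 2, k = 2)
  ctl <- function(seed) mmlmm_control(n_iter = 1200L, burn_in = 400L,
                                      thin = 4L, seed = seed,
                                      init = "kmeans_baseline")
  f1 <- mmlmm(s$z, k = 1, control = ctl(27L))
  f2 <- mmlmm(s$z, k = 2, control = ctl(27L))
  # two genuinely separated clusters: K = 2 must improve the mean deviance
  expect_lt(deviance_summary(f2), deviance_summary(f1))
})
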
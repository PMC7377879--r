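# direct construction of tiny frames and states for the likelihood layer

one_region_frame <- function(times = c(0, 12, 24), values = NULL,
                             time_scale = 1, age = c(3, 5), fixed = NULL) {
  obs <- rbind(
    data.frame(subject_id = "P1", visit_months = times, region = "r1",
               value = values %||% rep(0, length(times))),
    data.frame(subject_id = "P2", visit_months = times, region = "r1",
               value = rep(1, length(times))))
  sub <- data.frame(subject_id = c("P1", "P2"), group = "patient", age = age)
  mmlmm_frame(cohort(obs, sub, standardized = TRUE), fixed = fixed,
              time_scale = time_scale, scale_covariates = FALSE)
}

state_for <- function(frame, K = 1L, mu = NULL, D = NULL, beta = NULL,
                      phi = NULL, b = NULL, U = NULL, w = NULL) {
  q <- frame$q
  mixture_state(
    w = w %||% rep(1 / K, K),
    mu = mu %||% matrix(0, q, K),
    D = D %||% rep(list(diag(q)), K),
    beta = beta %||% matrix(0, frame$p, frame$J),
    phi = phi %||% rep(1, frame$J),
    b = b %||% matrix(0, frame$N, q),
    U = U %||% rep(1L, frame$N))
}

test_that("linear predictor reduces correctly in degenerate designs", {
  fr <- one_region_frame(time_scale = 1)
  # intercept-only random effect: constant trajectory
  st <- state_for(fr, b = rbind(c(4.5, 0), c(0, 0)))
  expect_equal(unname(linear_predictor(fr, st, "P1", "r1")), rep(4.5, 3))
  # slope-only: fitted values are t * slope (time in months, time_scale 1)
  st <- state_for(fr, b = rbind(c(0, 0.25), c(0, 0)))
  expect_equal(unname(linear_predictor(fr, st, "P1", "r1")),
               c(0, 12, 24) * 0.25)
  # fixed effect only: covariate 3 with coefficient 2 gives constant 6
  fr2 <- one_region_frame(fixed = ~ age)
  st2 <- state_for(fr2, beta = matrix(2, 1, 1))
  expect_equal(unname(linear_predictor(fr2, st2, "P1", "r1")), rep(6, 3))
  expect_error(linear_predictor(fr, st, "P9", "r1"), "unknown subject")
})

test_that("component marginal matches the independent-noise limit as D -> 0", {
  fr <- one_region_frame(values = c(0.3, -0.2, 0.4), time_scale = 12)
  mu <- matrix(c(0.1, -0.05), 2, 1)
  st <- state_for(fr, mu = mu, D = list(diag(1e-12, 2)), phi = 0.7)
  got <- log_component_marginal(fr, st, "P1", 1)
  m <- mu[1] + mu[2] * c(0, 12, 24) / 12
  expected <- sum(dnorm(c(0.3, -0.2, 0.4), mean = m, sd = sqrt(0.7),
                        log = TRUE))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("closed-form marginal agrees with Monte-Carlo integration", {
  # 1 subject visible to the test, 2 regions, 2 visits, correlated D
  obs <- expand.grid(subject_id = c("P1", "P2"), visit_months = c(0, 12),
                     region = c("rA", "rB"), stringsAsFactors = FALSE)
  obs$value <- c(-1.2, 0.5, -0.8, 0.1, -2.0, 0.3, -1.5, 0.2)
  fr <- mmlmm_frame(cohort(obs, data.frame(subject_id = c("P1", "P2"),
                                           group = "patient"),
                           standardized = TRUE))
  q <- fr$q
  D <- 0.4 * (diag(q) * 0.7 + 0.3)
  st <- state_for(fr, mu = matrix(c(-1, -0.3, -0.6, -0.2), q, 1),
                  D = list(D), phi = c(0.3, 0.5))
  closed <- log_component_marginal(fr, st, "P1", 1)
  mc <- mc_component_marginal(fr, st, "P1", 1, n = 2e4, seed = 11)
  expect_lt(abs(closed - mc$estimate), 3 * mc$se)
})

test_that("marginal log-density is invariant to visit order in the input", {
  obs <- expand.grid(subject_id = "P1", visit_months = c(0, 12, 24),
                     region = c("rA", "rB"), stringsAsFactors = FALSE)
  obs$value <- c(-1, -2, -3, 0.5, 0.2, -0.1)
  sub <- data.frame(subject_id = "P1", group = "patient")
  shuffled <- obs[c(4, 1, 6, 3, 2, 5), ]
  fr1 <- mmlmm_frame(cohort(obs, sub, standardized = TRUE))
  fr2 <- mmlmm_frame(cohort(shuffled, sub,
                            panel = data.frame(region = c("rA", "rB"),
                                               kind = "thickness"),
                            standardized = TRUE))
  st1 <- state_for(fr1, mu = matrix(-0.5, fr1$q, 1), phi = c(0.4, 0.6))
  st2 <- state_for(fr2, mu = matrix(-0.5, fr2$q, 1), phi = c(0.4, 0.6))
  expect_equal(log_component_marginal(fr1, st1, "P1", 1),
               log_component_marginal(fr2, st2, "P1", 1))
})

test_that("compiled batch densities match the plain-R reference path", {
  s <- small_sim(seed = 3, n_patients = 8, n_regions = 2)
  fr <- mmlmm_frame(s$z)
  set.seed(9)
  st <- initialize_state(fr, 2L, mmlmm_priors(), mmlmm_control(seed = 9))
  batch <- trajmix:::component_logdens(fr, st)
  for (i in c(1L, 4L, 8L)) for (k in 1:2)
    expect_equal(batch[i, k], log_component_marginal(fr, st, i, k),
                 tolerance = 1e-8)
})

test_that("mixture likelihood collapses and respects label symmetry", {
  fr <- one_region_frame(values = c(-0.5, 0.2, 0.1), time_scale = 12)
  mu <- matrix(c(-0.4, 0.1), 2, 1)
  st1 <- state_for(fr, mu = mu, phi = 0.5)
  # K = 1: mixture equals the single component
  expect_equal(log_mixture_likelihood(fr, st1, "P1"),
               log_component_marginal(fr, st1, "P1", 1))
  # two identical components at weight 1/2 collapse to either component
  st2 <- state_for(fr, K = 2L, mu = cbind(mu, mu),
                   D = rep(list(diag(2)), 2), phi = 0.5)
  expect_equal(log_mixture_likelihood(fr, st2, "P1"),
               log_component_marginal(fr, st2, "P1", 1))
  # permuting (w, mu, D) leaves the mixture unchanged
  muA <- matrix(c(-1, 0), 2, 1); muB <- matrix(c(0.5, -0.2), 2, 1)
  st3 <- state_for(fr, K = 2L, w = c(0.3, 0.7), mu = cbind(muA, muB),
                   D = list(diag(2) * 0.5, diag(2) * 2), phi = 0.5)
  st4 <- state_for(fr, K = 2L, w = c(0.7, 0.3), mu = cbind(muB, muA),
                   D = list(diag(2) * 2, diag(2) * 0.5), phi = 0.5)
  expect_equal(log_mixture_likelihood(fr, st3, "P1"),
               log_mixture_likelihood(fr, st4, "P1"))
  # equidistant symmetric components give allocation (1/2, 1/2)
  fr0 <- one_region_frame(values = c(0, 0, 0), time_scale = 12)
  sts <- state_for(fr0, K = 2L, mu = cbind(c(-1, 0), c(1, 0)),
                   D = rep(list(diag(2)), 2), phi = 1)
  lk <- vapply(1:2, function(k)
    log_component_marginal(fr0, sts, "P1", k), 0)
  post <- exp(lk + log(sts$w)); post <- post / sum(post)
  expect_equal(post, c(0.5, 0.5))
})

test_that("deviance is additive over subjects", {
  s <- small_sim(seed = 4, n_patients = 6, n_regions = 2)
  fr <- mmlmm_frame(s$z)
  set.seed(2)
  st <- initialize_state(fr, 2L, mmlmm_priors(), mmlmm_control(seed = 2))
  dev <- mixture_deviance(fr, st)
  by_subject <- vapply(seq_len(fr$N), function(i)
    log_mixture_likelihood(fr, st, i), 0)
  expect_equal(dev, -2 * sum(by_subject), tolerance = 1e-8)

  # duplicating a subject doubles its contribution
  z <- s$z
  pat <- z$observations[z$observations$subject_id == "P001", ]
  pat$subject_id <- "P999"
  srow <- z$subjects[z$subjects$subject_id == "P001", ]
  srow$subject_id <- "P999"
  z2 <- cohort(rbind(z$observations, pat), rbind(z$subjects, srow),
               panel = z$panel, standardized = TRUE)
  fr2 <- mmlmm_frame(z2)
  st2 <- state_for(fr2, K = 2L, w = st$w, mu = st$mu, D = st$D,
                   beta = st$beta, phi = st$phi)
  expect_equal(mixture_deviance(fr2, st2) - dev,
               -2 * log_mixture_likelihood(fr2, st2, "P999"),
               tolerance = 1e-8)
})

test_that("priors and state validation enforce the documented constraints", {
  expect_error(mmlmm_priors(dirichlet_concentration = 0))
  expect_error(mixture_state(w = c(0.5, 0.6), mu = matrix(0, 2, 2),
                             D = rep(list(diag(2)), 2),
                             beta = matrix(0, 0, 1), phi = 1,
                             b = matrix(0, 2, 2), U = c(1L, 2L)),
               "sum to 1")
  expect_error(mixture_state(w = 1, mu = matrix(0, 2, 1),
                             D = list(matrix(c(1, 2, 2, 1), 2)),
                             beta = matrix(0, 0, 1), phi = 1,
                             b = matrix(0, 1, 2), U = 1L),
               "not positive definite")
  expect_error(mixture_state(w = 1, mu = matrix(0, 2, 1),
                             D = list(diag(2)), beta = matrix(0, 0, 1),
                             phi = -1, b = matrix(0, 1, 2), U = 1L),
               "phi")
})
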
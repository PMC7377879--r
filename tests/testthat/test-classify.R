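# fake chains exercise the classification layer with known probabilities

const_prob_fit <- function(P, R = 20L) {
  N <- nrow(P); K <- ncol(P)
  prob <- array(NA_real_, c(R, N, K))
  for (r in seq_len(R)) prob[r, , ] <- P
  make_fake_fit(prob, regions = "r1")
}

test_that("posterior probabilities average per-draw allocation probabilities", {
  # constant chain: the unit vector is reproduced
  P <- rbind(c(0, 1), c(1, 0))
  fit <- const_prob_fit(P)
  expect_equal(unname(posterior_probabilities(fit)), P)

  # two draws (1,0) and (0,1) average to (1/2, 1/2)
  prob <- array(NA_real_, c(2, 1, 2))
  prob[1, 1, ] <- c(1, 0); prob[2, 1, ] <- c(0, 1)
  fit2 <- make_fake_fit(prob, regions = "r1")
  expect_equal(unname(posterior_probabilities(fit2)), matrix(0.5, 1, 2))

  # K = 1 gives a column of ones
  fit3 <- make_fake_fit(array(1, c(5, 3, 1)), regions = "r1")
  expect_equal(unname(posterior_probabilities(fit3)), matrix(1, 3, 1))

  # frequency estimator counts sampled allocations
  expect_equal(unname(posterior_probabilities(fit2, "frequency")),
               matrix(0.5, 1, 2))

  # an unrelabeled chain is refused
  fit4 <- make_fake_fit(prob, regions = "r1", relabeled = FALSE)
  expect_error(posterior_probabilities(fit4), "relabel")
})

test_that("max-probability labels break ties to the lowest index", {
  expect_equal(unname(assign_max_prob(rbind(c(0.9, 0.1)))), 1L)
  expect_warning(lab <- assign_max_prob(rbind(c(0.5, 0.5))), "tie")
  expect_equal(unname(lab), 1L)
  # permuting columns permutes labels consistently
  P <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  l1 <- assign_max_prob(P)
  perm <- c(3L, 1L, 2L)
  l2 <- assign_max_prob(P[, perm])
  expect_equal(perm[l2], unname(l1))
  expect_error(assign_max_prob(rbind(c(0.5, 0.2))), "sum to 1")
})

test_that("shortest-interval HPD behaves and matches coda on samples", {
  expect_equal(hpd_interval(rep(1, 30), 0.95), c(1, 1))
  set.seed(31)
  x <- rnorm(500)
  got <- hpd_interval(x, 0.9)
  ref <- as.numeric(coda::HPDinterval(coda::as.mcmc(x), prob = 0.9))
  expect_equal(got, ref, tolerance = 0.05)
  # monotone in coverage
  i90 <- hpd_interval(x, 0.90)
  i99 <- hpd_interval(x, 0.99)
  expect_lte(i99[1], i90[1])
  expect_gte(i99[2], i90[2])
})

test_that("HPD uncertainty flags overlapping membership intervals", {
  R <- 40L
  # constant (1, 0): degenerate disjoint intervals, not uncertain
  fit <- const_prob_fit(rbind(c(1, 0), c(0, 1)), R = R)
  h <- hpd_uncertainty(fit)
  expect_equal(unname(h$intervals[1, , ]), rbind(c(1, 1), c(0, 0)))
  expect_false(any(h$uncertain))

  # alternating (0.9, 0.1)/(0.1, 0.9): overlapping intervals, uncertain
  prob <- array(NA_real_, c(R, 1, 2))
  for (r in seq_len(R))
    prob[r, 1, ] <- if (r %% 2) c(0.9, 0.1) else c(0.1, 0.9)
  fit2 <- make_fake_fit(prob, regions = "r1")
  expect_true(hpd_uncertainty(fit2)$uncertain[[1]])

  # concentrated near (0.8, 0.2): disjoint intervals, assigned
  set.seed(32)
  eps <- runif(R, -0.02, 0.02)
  prob3 <- array(NA_real_, c(R, 1, 2))
  prob3[, 1, 1] <- 0.8 + eps
  prob3[, 1, 2] <- 0.2 - eps
  fit3 <- make_fake_fit(prob3, regions = "r1")
  expect_false(hpd_uncertainty(fit3)$uncertain[[1]])

  # too few draws for stable intervals
  fit4 <- const_prob_fit(rbind(c(1, 0)), R = 5L)
  expect_error(hpd_uncertainty(fit4), "at least 10")

  # the lower-bound rule flags a top cluster with a weak floor
  expect_true(hpd_uncertainty(fit2, rule = "lower_bound",
                              lower_bound = 0.5)$uncertain[[1]])
  expect_false(hpd_uncertainty(fit3, rule = "lower_bound",
                               lower_bound = 0.5)$uncertain[[1]])
})

test_that("undersized clusters are flagged as outliers", {
  labels <- c(rep(1L, 34), rep(2L, 2))
  fl <- flag_outlier_clusters(labels, min_size = 3L)
  expect_equal(sum(fl), 2L)
  expect_true(all(fl[labels == 2L]))
  expect_false(any(flag_outlier_clusters(labels, min_size = 1L)))
})

## A 72-subject chain shaped like the reference cohort: max-probability
## cluster sizes (23, 17, 15, 4, 4, 5, 2, 2); the two members of cluster 7
## include one HPD-uncertain subject, and two cluster-2 members are
## HPD-uncertain.
reference_like_fit <- function(R = 50L) {
  sizes <- c(23L, 17L, 15L, 4L, 4L, 5L, 2L, 2L)
  K <- length(sizes)
  labels <- rep(seq_len(K), sizes)
  N <- length(labels)
  uncertain <- c(which(labels == 2L)[1:2], which(labels == 7L)[1L])
  alt <- c(1L, 1L, 8L)  # the competing cluster for each uncertain subject
  prob <- array(0.002 / (K - 1), c(R, N, K))
  for (i in seq_len(N)) prob[, i, labels[i]] <- 1 - 0.002
  for (u in seq_along(uncertain)) {
    i <- uncertain[u]
    own <- labels[i]; other <- alt[u]
    for (r in seq_len(R)) {
      hi <- if (r %% 5 < 3) own else other  # 60/40 split across draws
      prob[r, i, ] <- 0.002 / (K - 1)
      prob[r, i, hi] <- 1 - 0.002
    }
  }
  make_fake_fit(prob, regions = "r1")
}

test_that("flag precedence reproduces the sequential exclusion bookkeeping", {
  fit <- reference_like_fit()
  cls <- classify(fit, coverage = 0.95, min_size = 3L)
  expect_equal(sum(cls$flags == "outlier_cluster_member"), 4L)
  expect_equal(sum(cls$flags == "hpd_uncertain"), 2L)
  expect_equal(sum(cls$flags == "assigned"), 66L)
  # the uncertain member of the outlier cluster keeps the outlier flag
  i7 <- which(cls$labels == 7L)
  expect_true(all(cls$flags[i7] == "outlier_cluster_member"))
  # row-stochasticity survives the whole pipeline
  expect_true(all(abs(rowSums(cls$prob_matrix) - 1) < 1e-9))
})

test_that("classification tables export every advertised column", {
  fit <- const_prob_fit(rbind(c(1, 0), c(0, 1), c(0.6, 0.4)))
  cls <- classify(fit, min_size = 1L)
  tab <- classification_table(cls)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("subject_id", "label", "flag", "p1", "p2",
                    "hpd1_lower", "hpd2_upper") %in% names(tab)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  classification_table(cls, tmp)
  expect_true(file.exists(tmp))
  expect_equal(nrow(read.csv(tmp)), 3L)
})
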
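#' Design of a synthetic longitudinal cohort
#'
#' Describes a cohort with the exact statistical structure the mixture model
#' assumes, so every stage of the pipeline can be exercised against known
#' ground truth. Controls follow a per-region linear mean trajectory with
#' Gaussian noise and attend every scheduled visit; patients are drawn from K
#' latent clusters that differ in their random intercept/slope means, with
#' region-correlated random effects, covariate (fixed) effects common to all
#' clusters, Gaussian residual noise, and thinned attendance at the last
#' scheduled visit (2-3 visits per patient).
#'
#' Defaults mirror a two-year AD-versus-control neuroimaging cohort: 31
#' controls and 72 patients seen at 0/12/24 months with 24-month patient
#' attendance 57/72, and three patient trajectory patterns — diffuse atrophy
#' (low intercepts everywhere, fast decline), minimal atrophy (near-control
#' intercepts, slow decline) and a hippocampal-sparing pattern (cortical
#' atrophy with relatively preserved subcortical volume) — weighted
#' (34, 23, 9)/66.
#'
#' @param n_controls,n_patients group sizes.
#' @param k number of latent clusters.
#' @param weights cluster proportions (length k, positive, summing to 1).
#' @param n_regions number of regions J.
#' @param region_names optional region names (default `region1..J`).
#' @param region_kinds `"thickness"`/`"volume"` per region.
#' @param cluster_intercepts,cluster_slopes J x k matrices of cluster
#'   random-effect means on the control z-score scale (slopes per year).
#'   Defaults implement the three patterns above (requires k <= 3 if not
#'   supplied).
#' @param random_effect_cov q x q positive-definite covariance of the joint
#'   random effects (q = 2J), shared across clusters by default. The default
#'   has intercept SD 0.4, slope SD 0.15, intercept-slope correlation 0.3
#'   within region and 0.2 between regions.
#' @param residual_sd residual SD per region on the z scale (default 0.5).
#' @param control_levels,control_slopes per-region control mean level and
#'   annual change in raw units (defaults: thickness ~2.5 mm shrinking
#'   0.02/yr; volume ~3500 mm3 shrinking 35/yr).
#' @param control_sd per-region control SD in raw units.
#' @param covariates list of covariate generator descriptions; each element
#'   is `list(dist = "normal", mean=, sd=)` or `list(dist = "bernoulli",
#'   prob=)`. Defaults emulate age/sex/education/onset/ICV/CSF biomarkers.
#' @param beta J x p matrix of fixed-effect coefficients on the z scale
#'   (columns follow `names(covariates)`); default small age/sex/ICV effects,
#'   identical across clusters as the model assumes.
#' @param cluster_specific_beta optional list of k such matrices enabling a
#'   deliberate model-violation mode for robustness experiments.
#' @param schedule visit times in months.
#' @param attendance per-visit attendance probability for patients (defaults
#'   to 1 except the last visit at 57/72); controls attend all visits.
#' @param raw_scale if `TRUE` (default) values are emitted in raw units via
#'   the control trajectory (so the standardization stage is exercised);
#'   if `FALSE` values are emitted directly on the z scale.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_controls = 31L, n_patients = 72L, k = 3L,
                              weights = NULL, n_regions = 4L,
                              region_names = NULL, region_kinds = NULL,
                              cluster_intercepts = NULL,
                              cluster_slopes = NULL,
                              random_effect_cov = NULL,
                              residual_sd = 0.5,
                              control_levels = NULL, control_slopes = NULL,
                              control_sd = NULL,
                              covariates = NULL, beta = NULL,
                              cluster_specific_beta = NULL,
                              schedule = c(0, 12, 24),
                              attendance = NULL,
                              raw_scale = TRUE) {
  k <- as.integer(k); J <- as.integer(n_regions)
  stopifnot(k >= 1L, J >= 1L, n_patients >= k)
  q <- 2L * J
  weights <- weights %||% {
    base <- c(34, 23, 9)
    w <- if (k <= 3L) base[seq_len(k)] else c(base, rep(2, k - 3L))
    w / sum(w)
  }
  stopifnot(length(weights) == k, all(weights > 0),
            abs(sum(weights) - 1) < 1e-8)
  region_names <- region_names %||% paste0("region", seq_len(J))
  region_kinds <- region_kinds %||%
    rep(c("thickness", "volume"), length.out = J)
  if (is.null(cluster_intercepts) || is.null(cluster_slopes)) {
    if (k > 3L)
      stop("default cluster patterns exist for k <= 3; supply ",
           "cluster_intercepts and cluster_slopes")
    ## columns: diffuse, minimal, hippocampal-sparing
    subcort <- region_kinds == "volume"
    ic <- cbind(diffuse = rep(-2.5, J),
                minimal = rep(-0.5, J),
                sparing = ifelse(subcort, -0.5, -2.5))
    sl <- cbind(diffuse = rep(-0.5, J),
                minimal = rep(-0.1, J),
                sparing = ifelse(subcort, -0.1, -0.5))
    cluster_intercepts <- ic[, seq_len(k), drop = FALSE]
    cluster_slopes <- sl[, seq_len(k), drop = FALSE]
  }
  cluster_intercepts <- matrix(cluster_intercepts, J, k)
  cluster_slopes <- matrix(cluster_slopes, J, k)
  if (is.null(random_effect_cov)) {
    sds <- rep(c(0.4, 0.15), J)
    C <- matrix(0.2, q, q)
    for (j in seq_len(J)) {
      ii <- c(2L * j - 1L, 2L * j)
      C[ii, ii] <- matrix(c(1, 0.3, 0.3, 1), 2L)
    }
    random_effect_cov <- diag(sds) %*% C %*% diag(sds)
  }
  ev <- eigen(random_effect_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("random_effect_cov must be positive definite")
  residual_sd <- rep_len(residual_sd, J)
  control_levels <- control_levels %||%
    ifelse(region_kinds == "volume", 3500, 2.5)
  control_slopes <- control_slopes %||%
    ifelse(region_kinds == "volume", -35, -0.02)
  control_sd <- control_sd %||%
    ifelse(region_kinds == "volume", 350, 0.25)
  covariates <- covariates %||% list(
    age = list(dist = "normal", mean = 76, sd = 7.4),
    sex = list(dist = "bernoulli", prob = 0.47),
    education = list(dist = "normal", mean = 16, sd = 3),
    onset_years = list(dist = "normal", mean = 5, sd = 2),
    icv = list(dist = "normal", mean = 1.5e6, sd = 1.5e5),
    abeta = list(dist = "normal", mean = 137, sd = 24),
    ptau = list(dist = "normal", mean = 37, sd = 12))
  p <- length(covariates)
  if (is.null(beta)) {
    beta <- matrix(0, J, p, dimnames = list(region_names, names(covariates)))
    if ("age" %in% names(covariates)) beta[, "age"] <- -0.02
    if ("sex" %in% names(covariates)) beta[, "sex"] <- 0.15
    if ("icv" %in% names(covariates)) beta[, "icv"] <- 1e-7
  }
  beta <- matrix(beta, J, p, dimnames = list(region_names, names(covariates)))
  attendance <- attendance %||%
    c(rep(1, length(schedule) - 1L), 57 / 72)
  stopifnot(length(attendance) == length(schedule),
            all(attendance > 0), all(attendance <= 1))
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients), k = k,
                 weights = weights, n_regions = J,
                 region_names = region_names, region_kinds = region_kinds,
                 cluster_intercepts = cluster_intercepts,
                 cluster_slopes = cluster_slopes,
                 random_effect_cov = random_effect_cov,
                 residual_sd = residual_sd,
                 control_levels = control_levels,
                 control_slopes = control_slopes, control_sd = control_sd,
                 covariates = covariates, beta = beta,
                 cluster_specific_beta = cluster_specific_beta,
                 schedule = schedule, attendance = attendance,
                 raw_scale = isTRUE(raw_scale)),
            class = "simulation_design")
}

draw_covariate <- function(gen, n) {
  switch(gen$dist,
         normal = rnorm(n, gen$mean, gen$sd),
         bernoulli = as.numeric(runif(n) < gen$prob),
         stop("unknown covariate distribution: ", gen$dist))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from a [simulation_design()]: controls from the control
#' trajectory plus noise; patients by sampling a latent cluster
#' `U_i ~ Cat(w)`, joint random effects `b_i ~ N(mu_{U_i}, D)`, covariates
#' from their generators, and observations from the conditional Gaussian
#' model. Patient attendance at each scheduled visit is thinned by the
#' design's attendance probabilities; a patient left with fewer than two
#' visits has its attendance re-drawn (the re-draw is logged via a message),
#' so slopes remain identifiable for everyone.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed (one RNG stream drives the whole cohort).
#' @return list with `cohort` (a [cohort()]), `truth` (data.frame
#'   `subject_id`, `true_cluster`) and `random_effects` (patients x q matrix
#'   of the true `b_i`).
#' @export
generate_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(as.integer(seed))
  J <- design$n_regions; q <- 2L * J
  sched <- design$schedule
  Dchol <- chol(design$random_effect_cov)
  rows <- list(); ri <- 0L
  add_rows <- function(id, times, region, values) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(subject_id = id, visit_months = times,
                              region = region, value = values)
  }

  ## controls: attend every scheduled visit
  n_c <- design$n_controls
  if (n_c > 0L) {
    for (i in seq_len(n_c)) {
      id <- sprintf("C%03d", i)
      for (j in seq_len(J)) {
        m <- design$control_levels[j] + design$control_slopes[j] * sched / 12
        vals <- m + rnorm(length(sched), 0, design$control_sd[j])
        if (!design$raw_scale)
          vals <- rnorm(length(sched), 0, 1)
        add_rows(id, sched, design$region_names[j], vals)
      }
    }
  }

  ## patients
  n_p <- design$n_patients
  U <- sample.int(design$k, n_p, replace = TRUE, prob = design$weights)
  p <- length(design$covariates)
  covmat <- if (p > 0L) {
    matrix(vapply(design$covariates, draw_covariate, numeric(n_p), n = n_p),
           n_p, p, dimnames = list(NULL, names(design$covariates)))
  } else matrix(0, n_p, 0L)
  ## fixed effects enter centered so they shift subjects, not the cohort mean
  covctr <- scale(covmat, center = TRUE, scale = FALSE)
  B <- matrix(NA_real_, n_p, q)
  mu_full <- rbind(design$cluster_intercepts, design$cluster_slopes)
  ## interleave to (intercept1, slope1, intercept2, slope2, ...)
  interleave <- as.vector(rbind(seq_len(J), J + seq_len(J)))
  redraws <- 0L
  for (i in seq_len(n_p)) {
    id <- sprintf("P%03d", i)
    muk <- mu_full[interleave, U[i]]
    b <- muk + drop(crossprod(Dchol, rnorm(q)))
    B[i, ] <- b
    attend <- runif(length(sched)) < design$attendance
    while (sum(attend) < 2L) {
      redraws <- redraws + 1L
      attend <- runif(length(sched)) < design$attendance
    }
    times <- sched[attend]
    bmat <- if (!is.null(design$cluster_specific_beta))
      design$cluster_specific_beta[[U[i]]] else design$beta
    for (j in seq_len(J)) {
      z <- B[i, 2L * j - 1L] + B[i, 2L * j] * times / 12 +
        (if (p > 0L) sum(bmat[j, ] * covctr[i, ]) else 0) +
        rnorm(length(times), 0, design$residual_sd[j])
      vals <- if (design$raw_scale) {
        mT <- design$control_levels[j] + design$control_slopes[j] * times / 12
        mT + design$control_sd[j] * z
      } else z
      add_rows(id, times, design$region_names[j], vals)
    }
  }
  if (redraws > 0L)
    message("generate_cohort: re-drew attendance ", redraws,
            " time(s) to guarantee >= 2 visits per patient")

  obs <- do.call(rbind, rows)
  ids_c <- if (n_c > 0L) sprintf("C%03d", seq_len(n_c)) else character(0)
  ids_p <- sprintf("P%03d", seq_len(n_p))
  subjects <- data.frame(subject_id = c(ids_c, ids_p),
                         group = c(rep("control", n_c), rep("patient", n_p)))
  if (p > 0L) {
    covdf <- as.data.frame(covmat)
    covdf_c <- as.data.frame(matrix(NA_real_, n_c, p,
                                    dimnames = list(NULL, colnames(covmat))))
    subjects <- cbind(subjects, rbind(covdf_c, covdf))
  }
  panel <- data.frame(region = design$region_names, kind = design$region_kinds)
  truth <- data.frame(subject_id = ids_p, true_cluster = U)
  rownames(B) <- ids_p
  list(cohort = cohort(obs, subjects, panel = panel,
                       standardized = !design$raw_scale),
       truth = truth, random_effects = B)
}

#' Compare a classification against simulation ground truth
#'
#' Reports the adjusted Rand index between the true cluster labels and the
#' maximum-probability assignments (excluded subjects — outlier-cluster
#' members and HPD-uncertain — are left out of the ARI and reported
#' separately) plus a correspondence table with true clusters in rows and
#' assigned clusters / exclusion flags in columns.
#'
#' @param truth data.frame `subject_id`, `true_cluster` from
#'   [generate_cohort()].
#' @param classification an `mmlmm_classification` over the same subjects.
#' @return list with `ari`, `confusion` (table), `n_assigned`, `n_excluded`.
#' @export
truth_recovery_report <- function(truth, classification) {
  stopifnot(inherits(classification, "mmlmm_classification"))
  ids <- names(classification$labels)
  common <- intersect(truth$subject_id, ids)
  if (!length(common))
    stop("truth and classification share no subjects")
  tr <- truth$true_cluster[match(common, truth$subject_id)]
  lab <- classification$labels[common]
  fl <- as.character(classification$flags[match(common, ids)])
  assigned <- fl == "assigned"
  ari <- mclust::adjustedRandIndex(tr[assigned], lab[assigned])
  col <- ifelse(assigned, paste0("cluster", lab), fl)
  confusion <- table(true = paste0("true", tr), result = col)
  list(ari = ari, confusion = confusion,
       n_assigned = sum(assigned), n_excluded = sum(!assigned))
}

#' Serialize / deserialize a simulation design as YAML
#'
#' @param design a [simulation_design()].
#' @param path YAML file path.
#' @return `read_design` returns the reconstructed design.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "simulation_design"))
  x <- unclass(design)
  x$cluster_intercepts <- as.vector(x$cluster_intercepts)
  x$cluster_slopes <- as.vector(x$cluster_slopes)
  x$random_effect_cov <- as.vector(x$random_effect_cov)
  x$beta <- as.vector(x$beta)
  yaml::write_yaml(x, path)
  invisible(design)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  J <- x$n_regions; k <- x$k
  simulation_design(
    n_controls = x$n_controls, n_patients = x$n_patients, k = k,
    weights = x$weights, n_regions = J, region_names = x$region_names,
    region_kinds = x$region_kinds,
    cluster_intercepts = matrix(x$cluster_intercepts, J, k),
    cluster_slopes = matrix(x$cluster_slopes, J, k),
    random_effect_cov = matrix(x$random_effect_cov, 2L * J, 2L * J),
    residual_sd = x$residual_sd, control_levels = x$control_levels,
    control_slopes = x$control_slopes, control_sd = x$control_sd,
    covariates = x$covariates,
    beta = matrix(x$beta, J, length(x$covariates)),
    schedule = x$schedule, attendance = x$attendance,
    raw_scale = x$raw_scale)
}
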
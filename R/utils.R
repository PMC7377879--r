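# numeric helpers shared across modules

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## Dirichlet draw via normalized gammas (uses R's RNG stream).
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[] <- 1e-300  # guards alpha << 1 underflow
  g / sum(g)
}

## One multivariate normal draw given mean and *precision* matrix.
rmvnorm_prec <- function(mean, prec) {
  R <- chol(prec)
  mean + backsolve(R, rnorm(length(mean)))
}

## One multivariate normal draw given mean and covariance matrix.
rmvnorm_cov <- function(mean, cov) {
  R <- chol(cov)
  mean + drop(crossprod(R, rnorm(length(mean))))
}

#' Shortest-interval highest posterior density interval
#'
#' Computes the empirical HPD interval of a sample by the shortest-interval
#' method: among all contiguous windows of the sorted sample containing the
#' requested mass, the narrowest is returned.
#'
#' @param x numeric sample (at least 2 finite values).
#' @param coverage target posterior mass in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, coverage = 0.95) {
  stopifnot(is.numeric(x), coverage > 0, coverage < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite values for an HPD interval")
  m <- max(1L, ceiling(coverage * n))
  if (m >= n) return(c(x[1L], x[n]))
  lo <- seq_len(n - m)
  width <- x[lo + m] - x[lo]
  i <- which.min(width)
  c(x[i], x[i + m])
}

## All permutations of 1..n as a matrix (n! rows); n kept small by callers.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
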
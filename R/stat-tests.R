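# Supporting statistics: Lilliefors normality test with Monte-Carlo null,
# KL divergence between binned samples, Gini coefficient, and the regional
# flow-share error metric.

# Lilliefors KS statistic: max gap between the empirical CDF and a normal
# CDF with sample-estimated mean and SD, evaluated at both one-sided
# candidates of every sample point.
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  fz <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - fz, fz - (i - 1) / n)
}

#' Lilliefors test for normality with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov test against a normal distribution whose mean and
#' standard deviation are estimated from the sample. Because the reference
#' distribution is estimated, the classical KS null does not apply; the
#' p-value is obtained by Monte Carlo, re-running the identical estimation
#' step on normal samples of the same size.
#'
#' @param x numeric sample, `n >= 4`, nonzero variance.
#' @param n_montecarlo number of Monte-Carlo null samples. Uses the session
#'   RNG.
#' @return a list with `statistic`, `p_value`, `n`, `n_montecarlo`.
#' @export
lilliefors_test <- function(x, n_montecarlo = 2000L) {
  n <- length(x)
  if (n < 4L) stop("lilliefors test needs n >= 4")
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance")
  d_obs <- lilliefors_statistic(x)
  d_null <- vapply(
    seq_len(n_montecarlo),
    function(i) lilliefors_statistic(stats::rnorm(n)),
    numeric(1)
  )
  list(
    statistic = d_obs,
    p_value = (1 + sum(d_null >= d_obs)) / (n_montecarlo + 1),
    n = n,
    n_montecarlo = n_montecarlo
  )
}

#' Kullback-Leibler divergence between two samples
#'
#' Both samples are histogrammed on shared equal-width bins spanning their
#' pooled range; one pseudo-count is added to every bin before
#' normalization (guaranteeing a finite result), and
#' \eqn{D(p \| q) = \sum_b p_b \ln(p_b/q_b)} is returned in nats. The
#' divergence is nonnegative, zero only for identical binned distributions,
#' and asymmetric in its arguments.
#'
#' @param p_sample,q_sample non-empty numeric samples.
#' @param n_bins number of shared bins (>= 2).
#' @return KL divergence in nats.
#' @seealso [kl_from_probs()] for pre-binned probability vectors.
#' @export
kl_divergence <- function(p_sample, q_sample, n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (length(p_sample) == 0L || length(q_sample) == 0L) {
    stop("both samples must be non-empty")
  }
  pooled <- range(c(p_sample, q_sample))
  if (pooled[1] == pooled[2]) pooled <- pooled + c(-0.5, 0.5)
  brk <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  brk[1] <- brk[1] - abs(brk[1]) * 1e-12 - 1e-300
  cnt <- function(s) graphics::hist(s, breaks = brk, plot = FALSE)$counts + 1
  p <- cnt(p_sample); p <- p / sum(p)
  q <- cnt(q_sample); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Kullback-Leibler divergence of pre-binned distributions
#'
#' @param p,q probability vectors of equal length (renormalized if needed);
#'   `q` must be positive wherever `p` is.
#' @return KL divergence in nats.
#' @examples
#' kl_from_probs(c(0.5, 0.5), c(0.25, 0.75)) # 0.1438
#' @export
kl_from_probs <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
  p <- p / sum(p)
  q <- q / sum(q)
  nz <- p > 0
  if (any(q[nz] == 0)) stop("q must be positive wherever p is")
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Gini coefficient
#'
#' Mean absolute difference measure of dispersion,
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}, computed via the
#' equivalent sorted form. Zero for a constant series; invariant under
#' positive scaling.
#'
#' @param x nonnegative numeric series, `n >= 2`, positive mean.
#' @return Gini coefficient in \[0, 1).
#' @examples
#' gini(c(1, 2, 3)) # 2/9
#' @export
gini <- function(x) {
  n <- length(x)
  if (n < 2L) stop("gini needs n >= 2")
  if (any(x < 0)) stop("gini requires nonnegative values")
  if (mean(x) == 0) stop("degenerate series: all values zero")
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
}

#' Regional flow-share error
#'
#' Compares a simulated region-to-region patient-flow percentage matrix
#' against a reference one: the absolute error \eqn{|e_{ij}|} is taken
#' element-wise and its mean and standard deviation over all cells are
#' returned. Rows of both matrices must be percentages summing to 100.
#'
#' @param sim_share,ref_share numeric matrices of identical shape with rows
#'   summing to 100 (within 0.1).
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
flow_error <- function(sim_share, ref_share) {
  sim_share <- as.matrix(sim_share)
  ref_share <- as.matrix(ref_share)
  if (!identical(dim(sim_share), dim(ref_share))) {
    stop("flow matrices must have identical shape")
  }
  for (mname in c("sim_share", "ref_share")) {
    m <- get(mname)
    if (any(abs(rowSums(m) - 100) > 0.1)) {
      stop(mname, " rows must sum to 100 (within 0.1)")
    }
  }
  e <- abs(sim_share - ref_share)
  c(mean = mean(e), sd = stats::sd(as.vector(e)))
}
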
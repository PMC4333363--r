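#' Range-normalized variation series
#'
#' Period-to-period changes of a series normalized by the series' range:
#' \deqn{v_{n+1} = \frac{x_{n+1} - x_n}{x_{max} - x_{min}}}
#' Every variation lies in \[-1, 1\]. The transform is invariant to affine
#' rescaling of the input (`v(a*x + c) = v(x)` for `a > 0`): differencing
#' removes location, the range denominator removes scale.
#'
#' @param x numeric series of length >= 2 with `max(x) > min(x)`.
#' @return numeric vector of length `length(x) - 1`.
#' @examples
#' variation_series(c(10, 20, 15)) # 1.0 -0.5
#' @export
variation_series <- function(x) {
  if (length(x) < 2L) stop("series must have length >= 2")
  rng <- max(x) - min(x)
  if (rng == 0) stop("degenerate series: max(x) == min(x)")
  diff(x) / rng
}

#' Absolute variations
#'
#' Element-wise absolute value of a variation series; the quantity whose
#' distribution is examined for power-law behavior.
#'
#' @param v numeric vector of variations.
#' @return `abs(v)`.
#' @export
absolute_variations <- function(v) abs(v)

# Re-aggregate a run's realized waits into a per-hospital median-wait series
# at `len` steps per period. Periods with no completions carry the previous
# median forward (matching the release rule); leading empty periods are NA.
median_wait_series <- function(panel, len) {
  n_periods <- panel$horizon %/% len
  m <- ncol(panel$arrivals)
  log <- panel$completion_log
  period <- ceiling(log$end_time / len)
  keep <- period <= n_periods
  out <- matrix(NA_real_, n_periods, m, dimnames = list(NULL, colnames(panel$arrivals)))
  if (any(keep)) {
    med <- tapply(
      log$wait[keep],
      list(factor(period[keep], levels = seq_len(n_periods)),
           factor(log$hospital[keep], levels = seq_len(m))),
      stats::median
    )
    out[] <- med
  }
  # carry forward over empty periods
  for (j in seq_len(m)) {
    col <- out[, j]
    if (anyNA(col)) {
      for (p in seq_len(n_periods)[-1]) if (is.na(col[p])) col[p] <- col[p - 1L]
      out[, j] <- col
    }
  }
  out
}

#' Pool absolute wait-time variations across hospitals and replicates
#'
#' For each replicate and hospital, the realized waits of served patients
#' are re-aggregated into a median-wait series at the chosen time scale
#' (calendar periods of 30, 15, or 7 daily steps), the range-normalized
#' variation series is computed per hospital (each hospital's own min/max),
#' absolute values are taken, and the results are concatenated across
#' hospitals and replicates (`mode = "pooled"`). In `mode = "system"` the
#' across-hospital mean median-wait series is formed first and a single
#' variation series is computed per replicate. Exact zero variations are
#' excluded (power-law fitting works in the log domain); the number dropped
#' is recorded in the `"n_zero_dropped"` attribute, and degenerate constant
#' series are skipped with a warning.
#'
#' @param panels a `replicate_set`, a single `sim_panel`, or a list of
#'   panels.
#' @param scale one of `"month"` (30 steps), `"half-month"` (15), `"week"`
#'   (7).
#' @param mode `"pooled"` (default) or `"system"`.
#' @return numeric vector of positive absolute variations.
#' @export
pool_wait_variations <- function(panels, scale = c("month", "half-month", "week"),
                                 mode = c("pooled", "system")) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  len <- c(month = 30L, `half-month` = 15L, week = 7L)[[scale]]
  if (inherits(panels, "replicate_set")) panels <- panels$panels
  if (inherits(panels, "sim_panel")) panels <- list(panels)
  out <- numeric(0)
  n_skipped <- 0L
  for (panel in panels) {
    if (panel$horizon %/% len < 2L) {
      stop("horizon covers fewer than 2 periods at scale '", scale, "'")
    }
    wmat <- median_wait_series(panel, len)
    series_list <- if (mode == "pooled") {
      lapply(seq_len(ncol(wmat)), function(j) wmat[, j])
    } else {
      list(rowMeans(wmat, na.rm = TRUE))
    }
    for (x in series_list) {
      x <- x[!is.na(x)]
      if (length(x) < 2L || max(x) == min(x)) {
        n_skipped <- n_skipped + 1L
        next
      }
      out <- c(out, absolute_variations(variation_series(x)))
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " degenerate wait series skipped in pooling")
  }
  n_zero <- sum(out == 0)
  out <- out[out > 0]
  attr(out, "n_zero_dropped") <- n_zero
  out
}

#' Distributional summary with normality test
#'
#' Mean, standard deviation, and a Monte-Carlo Lilliefors normality test of
#' a sample (typically a variation series).
#'
#' @param x numeric sample.
#' @param n_montecarlo Monte-Carlo replicates for the Lilliefors p-value.
#' @return a list with `mean`, `sd`, `lilliefors_stat`, `lilliefors_p`, `n`.
#' @export
distribution_summary <- function(x, n_montecarlo = 2000L) {
  lt <- lilliefors_test(x, n_montecarlo = n_montecarlo)
  list(
    mean = mean(x), sd = stats::sd(x),
    lilliefors_stat = lt$statistic, lilliefors_p = lt$p_value,
    n = length(x)
  )
}
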
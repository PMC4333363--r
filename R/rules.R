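#' Hospital-selection probabilities from distance and resourcefulness
#'
#' Gravity-style choice rule for wait-time-insensitive patients. For a
#' patient in city `i`, the attraction of hospital `j` combines an
#' inverse-power distance factor with a power-law resourcefulness factor:
#' \deqn{d'_{ij} = \frac{\sum_k d_{ik}^{\alpha_d}}{d_{ij}^{\alpha_d}}, \quad
#'       f(d_{ij}) = \frac{d'_{ij}}{\sum_k d'_{ik}}, \quad
#'       f(r_j) = \frac{r_j^{\alpha_r}}{\sum_k r_k^{\alpha_r}}}
#' The product \eqn{f(d_{ij}) f(r_j)} is renormalized over hospitals so the
#' result is a categorical distribution (the raw product of two separately
#' normalized factors does not itself sum to one).
#'
#' @param city_index integer index of the patient's city.
#' @param env a [service_environment()].
#' @param alpha_d,alpha_r sensitivity exponents (defaults 4 and 1).
#' @return numeric probability vector over hospitals, summing to 1.
#' @examples
#' net <- city_hospital_network("a", c("h1", "h2"), matrix(c(1, 2), 1, 2))
#' env <- service_environment(net, c(1, 1), c(20, 20), 1e5, 1e-5)
#' dh_probabilities(1, env, alpha_d = 4, alpha_r = 1)
#' @export
dh_probabilities <- function(city_index, env, alpha_d = 4, alpha_r = 1) {
  dh_probability_matrix(env, alpha_d, alpha_r)[city_index, ]
}

#' Hospital-selection probabilities including released wait times
#'
#' Choice rule for wait-time-sensitive patients. Extends
#' [dh_probabilities()] with a wait-time factor built inverse-proportionally
#' to the released wait raised to `alpha_w`, symmetric to the distance
#' factor:
#' \deqn{w'_j = \frac{\sum_k w_k^{\alpha_w}}{w_j^{\alpha_w}}, \quad
#'       f(w_j) = \frac{w'_j}{\sum_k w'_k}}
#' Released waits are floored at `eps_w` days before use, so a hospital
#' that served everyone same-day cannot produce a division by zero.
#'
#' @inheritParams dh_probabilities
#' @param alpha_w wait-time sensitivity exponent (default 1).
#' @param eps_w floor applied to released waits, in days.
#' @return numeric probability vector over hospitals, summing to 1.
#' @export
dhw_probabilities <- function(city_index, env, alpha_d = 4, alpha_r = 1,
                              alpha_w = 1, eps_w = 0.5) {
  dhw_probability_matrix(env, alpha_d, alpha_r, alpha_w, eps_w)[city_index, ]
}

# N x M matrix of DH-rule probabilities, one row per city.
dh_probability_matrix <- function(env, alpha_d, alpha_r) {
  d <- env$network$driving_time
  r <- env$resourcefulness
  if (any(d <= 0)) stop("driving times must be > 0")
  if (all(r == 0)) stop("at least one hospital must have nonzero resourcefulness")
  dpow <- d^alpha_d
  dprime <- rowSums(dpow) / dpow               # d'_ij
  fd <- dprime / rowSums(dprime)               # f(d_ij), rows sum to 1
  fr <- r^alpha_r / sum(r^alpha_r)             # f(r_j)
  a <- sweep(fd, 2, fr, `*`)
  a / rowSums(a)
}

# N x M matrix of DHW-rule probabilities.
dhw_probability_matrix <- function(env, alpha_d, alpha_r, alpha_w, eps_w = 0.5) {
  a <- dh_probability_matrix(env, alpha_d, alpha_r)
  w <- pmax(env$released_wait, eps_w)
  wpow <- w^alpha_w
  wprime <- sum(wpow) / wpow                   # w'_j
  fw <- wprime / sum(wprime)                   # f(w_j)
  a <- sweep(a, 2, fw, `*`)
  a / rowSums(a)
}

#' Adjusted daily service rate
#'
#' Linear service-adjustment rule: every `tau_tilde` steps a hospital
#' rescales its baseline rate by the ratio of recent arrivals to its
#' reference load,
#' \deqn{\mu_j(t) = \bar\mu_j \left( b_j
#'   \frac{\sum_{t'=t-\tilde\tau}^{t-1} \tilde A_j(t')}{\tilde\tau \bar A_j}
#'   + g_j \right)}
#' With `b + g = 1` the rate equals the baseline exactly when the window
#' arrivals average out to the reference `a_bar`.
#'
#' @param mu_bar baseline daily service rate \eqn{\bar\mu_j}.
#' @param window_arrivals arrivals over the last `tau_tilde` steps
#'   (a vector, summed internally, or a precomputed sum).
#' @param tau_tilde window length in steps.
#' @param a_bar reference mean daily arrivals (> 0).
#' @param b,g adjustment coefficients in \[0, 1\].
#' @return the updated service rate, patients/day.
#' @examples
#' service_rate(2, 100, tau_tilde = 5, a_bar = 10, b = 0.57, g = 0.43) # 3.14
#' @export
service_rate <- function(mu_bar, window_arrivals, tau_tilde, a_bar, b, g) {
  if (any(a_bar <= 0)) stop("a_bar must be > 0")
  mu_bar * (b * sum(window_arrivals) / (tau_tilde * a_bar) + g)
}

#' Create a hospital state
#'
#' Holds one hospital's waiting queue (urgent patients ahead of non-urgent,
#' first-in-first-out within each class), current service rate, arrival
#' history, and last released wait. Initial queue members are non-urgent
#' with join time 0.
#'
#' @param hospital_id hospital identifier.
#' @param mu_bar baseline daily service rate.
#' @param initial_queue number of patients waiting at step 0.
#' @param initial_wait initially released wait time, days.
#' @param city_id optional host city identifier.
#' @return An object of class `hospital_state`.
#' @export
hospital_state <- function(hospital_id, mu_bar, initial_queue = 0,
                           initial_wait = 0, city_id = NA_character_) {
  structure(
    list(
      hospital_id = hospital_id,
      city_id = city_id,
      q_join = rep(0, initial_queue),
      q_urgent = rep(FALSE, initial_queue),
      mu_t = mu_bar,
      mu_bar = mu_bar,
      arrivals = integer(0),      # per-step totals, index = step
      released_wait = initial_wait,
      round_waits = numeric(0)    # realized waits completed this round
    ),
    class = "hospital_state"
  )
}

#' Enqueue one patient
#'
#' Inserts the patient behind all urgent patients if urgent, or at the tail
#' otherwise, preserving first-in-first-out order within each urgency class.
#' Priority is an ordering rule only: an urgent arrival never interrupts
#' completions already drawn for the day.
#'
#' @param h a [hospital_state()].
#' @param urgent logical, whether the patient is urgent.
#' @param t join step.
#' @return the updated `hospital_state`.
#' @export
enqueue <- function(h, urgent, t) {
  n_urgent <- sum(h$q_urgent)
  h$q_join <- append(h$q_join, t, after = if (urgent) n_urgent else length(h$q_join))
  h$q_urgent <- append(h$q_urgent, urgent, after = if (urgent) n_urgent else length(h$q_urgent))
  h
}

# Enqueue a batch of same-step arrivals: urgent ones ahead of the existing
# non-urgent block, non-urgent at the tail. Equivalent to repeated enqueue()
# calls in any order of the same-step batch (within-day order inside a class
# carries no information).
enqueue_batch <- function(h, urgent, t) {
  n_new <- length(urgent)
  if (n_new == 0L) return(h)
  n_u_old <- sum(h$q_urgent)
  n_u_new <- sum(urgent)
  h$q_join <- c(
    h$q_join[seq_len(n_u_old)], rep(t, n_u_new),
    h$q_join[seq_len(length(h$q_join) - n_u_old) + n_u_old], rep(t, n_new - n_u_new)
  )
  h$q_urgent <- c(
    rep(TRUE, n_u_old + n_u_new),
    rep(FALSE, length(h$q_urgent) - n_u_old + n_new - n_u_new)
  )
  h
}

#' Serve one day's completions
#'
#' Draws the number of completions as Poisson with mean `mu_t`, truncated at
#' the queue length — the departure law of a busy exponential-service
#' single-server queue observed over one day — and removes that many
#' patients in priority order. Realized waits are `t - join_time` days.
#'
#' @param h a [hospital_state()].
#' @param t current step; uses the session RNG.
#' @return list with `state` (updated `hospital_state`), `waits` (realized
#'   waits of the day's completions, days) and `urgent` (their classes).
#' @export
serve_day <- function(h, t) {
  n_q <- length(h$q_join)
  n_s <- if (h$mu_t <= 0 || n_q == 0L) 0L else min(stats::rpois(1L, h$mu_t), n_q)
  if (n_s == 0L) {
    return(list(state = h, waits = numeric(0), urgent = logical(0)))
  }
  idx <- seq_len(n_s)
  waits <- t - h$q_join[idx]
  urg <- h$q_urgent[idx]
  h$q_join <- h$q_join[-idx]
  h$q_urgent <- h$q_urgent[-idx]
  h$round_waits <- c(h$round_waits, waits)
  list(state = h, waits = waits, urgent = urg)
}

#' Release wait-time information
#'
#' At the end of a release round the hospital publishes the median realized
#' wait among patients completed during the round. If nobody completed, the
#' previously released value is carried forward. The released value is
#' stored raw; flooring at `eps_w` happens where the value enters the
#' wait-sensitive selection rule.
#'
#' @param h a [hospital_state()].
#' @return the updated `hospital_state`, with `released_wait` refreshed and
#'   the round's wait accumulator cleared.
#' @export
release_wait_info <- function(h) {
  if (length(h$round_waits) > 0) {
    h$released_wait <- stats::median(h$round_waits)
  }
  h$round_waits <- numeric(0)
  h
}

#' Update a hospital's service rate from its recent arrivals
#'
#' Applies the linear adjustment rule using the hospital's recorded arrival
#' history over the `tau_tilde` steps preceding `t`.
#'
#' @param h a [hospital_state()] whose `arrivals` history covers steps
#'   `t - tau_tilde` to `t - 1`.
#' @param t current step (must exceed `tau_tilde`).
#' @param tau_tilde adjustment window, steps.
#' @param a_bar reference mean daily arrivals (> 0).
#' @param b,g adjustment coefficients.
#' @return the updated `hospital_state`.
#' @export
adjust_service_rate <- function(h, t, tau_tilde, a_bar, b, g) {
  if (t <= tau_tilde) stop("service rate adjustment needs tau_tilde past steps")
  window <- h$arrivals[(t - tau_tilde):(t - 1L)]
  h$mu_t <- service_rate(h$mu_bar, window, tau_tilde, a_bar, b, g)
  h
}

# Vectorized inverse-CDF categorical draw: n draws from probability vector p
# using one uniform variate per draw.
draw_categorical <- function(n, p) {
  if (n == 0L) return(integer(0))
  findInterval(stats::runif(n), cumsum(p)[-length(p)]) + 1L
}
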
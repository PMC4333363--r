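#' Generate one city's patients for one day
#'
#' The number of new patients is Poisson with mean `pop_i * m_i`, where the
#' generation probability is multiplied by the warm-season factor during
#' warm calendar months. Each patient is urgent with probability
#' `urgent_fraction`, non-urgent otherwise. Uses the session RNG.
#'
#' @param city_index integer city index.
#' @param t current step (determines the calendar month).
#' @param env a [service_environment()].
#' @param cfg a [sim_config()].
#' @return a data frame with one row per generated patient and columns
#'   `city` (index) and `urgent` (logical).
#' @export
generate_daily_patients <- function(city_index, t, env, cfg) {
  m_eff <- env$gen_prob[city_index]
  if (month_of_step(t) %in% cfg$warm_months) m_eff <- m_eff * cfg$warm_multiplier
  n <- stats::rpois(1L, env$population[city_index] * m_eff)
  data.frame(
    city = rep(city_index, n),
    urgent = stats::runif(n) < cfg$urgent_fraction
  )
}

# Initialize the world state for a run. The returned state carries the
# aligned config, the mutable environment (released waits), hospital states,
# the static DH probability matrix, the current DHW matrix, and preallocated
# panel accumulators.
world_init <- function(cfg, env, seed) {
  viols <- validate_environment(env)
  if (length(viols)) {
    stop("invalid environment:\n  ", paste(viols, collapse = "\n  "))
  }
  cfg <- align_config(cfg, env)
  set.seed(as.integer(seed))
  net <- env$network
  n <- length(net$cities)
  m <- length(net$hospitals)
  t_max <- cfg$horizon
  n_rounds <- t_max %/% cfg$tau_hat
  env$released_wait[] <- cfg$initial_wait
  hospitals <- lapply(seq_len(m), function(j) {
    h <- hospital_state(
      net$hospitals[j], cfg$mu_bar[j],
      initial_queue = cfg$initial_queue[j],
      initial_wait = cfg$initial_wait[j],
      city_id = if (is.null(env$hospital_city)) NA_character_ else env$hospital_city[j]
    )
    h$arrivals <- integer(t_max)
    h
  })
  mk <- function(nr, nc, rn = NULL, cn = NULL) {
    matrix(0, nr, nc, dimnames = list(rn, cn))
  }
  list(
    cfg = cfg, env = env, seed = as.integer(seed),
    hospitals = hospitals,
    dh = dh_probability_matrix(env, cfg$alpha_d, cfg$alpha_r),
    dhw = dhw_probability_matrix(env, cfg$alpha_d, cfg$alpha_r, cfg$alpha_w, cfg$eps_w),
    arrivals = mk(t_max, m, NULL, net$hospitals),
    arrivals_urgent = mk(t_max, m, NULL, net$hospitals),
    completions = mk(t_max, m, NULL, net$hospitals),
    queue_len = mk(t_max, m, NULL, net$hospitals),
    mu = mk(t_max, m, NULL, net$hospitals),
    generated = mk(t_max, n, NULL, net$cities),
    released = mk(n_rounds, m, NULL, net$hospitals),
    flows = array(
      0,
      dim = c(n, m, 2L),
      dimnames = list(net$cities, net$hospitals, c("urgent", "non_urgent"))
    ),
    comp_log = vector("list", t_max)
  )
}

#' Advance the world by one step
#'
#' Within-step order of operations: (1) on adjustment steps
#' (`t = k*tau_tilde + 1`, `t > tau_tilde`) every hospital updates its
#' service rate from its last `tau_tilde` days of arrivals; (2) every city
#' generates patients; (3) each patient draws its rule (wait-sensitive with
#' probability `p_r`) and selects a hospital, and arrivals are enqueued with
#' urgent patients ahead of non-urgent; (4) every hospital serves the day;
#' (5) on release steps (`t` a multiple of `tau_hat`) hospitals publish the
#' round's median realized wait and wait-sensitive selection probabilities
#' are refreshed.
#'
#' @param state a world state from the internal initializer (see
#'   [simulate_run()]; exposed for step-level testing).
#' @param t the step to execute, 1-based.
#' @return the updated state. The per-step city-to-hospital referral ledger
#'   is attached as `state$last_ledger` (an N x M x 2 count array).
#' @export
sim_step <- function(state, t) {
  cfg <- state$cfg
  env <- state$env
  n <- length(env$network$cities)
  m <- length(env$network$hospitals)

  # (1) service-rate adjustment
  if (t > cfg$tau_tilde && (t - 1L) %% cfg$tau_tilde == 0L) {
    for (j in seq_len(m)) {
      state$hospitals[[j]] <- adjust_service_rate(
        state$hospitals[[j]], t, cfg$tau_tilde, cfg$a_bar[j], cfg$b[j], cfg$g[j]
      )
    }
  }

  # (2) patient generation (Poisson per city, seasonal modulation)
  lambda <- env$population * env$gen_prob
  if (month_of_step(t) %in% cfg$warm_months) lambda <- lambda * cfg$warm_multiplier
  counts <- stats::rpois(n, lambda)
  state$generated[t, ] <- counts

  # (3) rule assignment, hospital selection, enqueueing
  ledger <- array(0L, dim = c(n, m, 2L))
  arr_tot <- integer(m)
  arr_urg <- integer(m)
  step_hosp <- vector("list", n)
  step_urg <- vector("list", n)
  for (i in which(counts > 0L)) {
    k <- counts[i]
    uses_dhw <- stats::runif(k) < cfg$p_r
    choice <- integer(k)
    if (any(uses_dhw)) choice[uses_dhw] <- draw_categorical(sum(uses_dhw), state$dhw[i, ])
    if (any(!uses_dhw)) choice[!uses_dhw] <- draw_categorical(sum(!uses_dhw), state$dh[i, ])
    urgent <- stats::runif(k) < cfg$urgent_fraction
    step_hosp[[i]] <- choice
    step_urg[[i]] <- urgent
    for (kk in seq_len(k)) {
      layer <- if (urgent[kk]) 1L else 2L
      ledger[i, choice[kk], layer] <- ledger[i, choice[kk], layer] + 1L
    }
  }
  all_choice <- unlist(step_hosp, use.names = FALSE)
  all_urgent <- unlist(step_urg, use.names = FALSE)
  if (length(all_choice)) {
    arr_tot <- tabulate(all_choice, nbins = m)
    arr_urg <- tabulate(all_choice[all_urgent], nbins = m)
    for (j in which(arr_tot > 0L)) {
      state$hospitals[[j]] <- enqueue_batch(
        state$hospitals[[j]], all_urgent[all_choice == j], t
      )
    }
  }
  state$flows <- state$flows + ledger
  state$last_ledger <- ledger
  state$arrivals[t, ] <- arr_tot
  state$arrivals_urgent[t, ] <- arr_urg
  for (j in seq_len(m)) state$hospitals[[j]]$arrivals[t] <- arr_tot[j]

  # (4) service
  comp_j <- integer(0); comp_w <- numeric(0); comp_u <- logical(0)
  for (j in seq_len(m)) {
    served <- serve_day(state$hospitals[[j]], t)
    state$hospitals[[j]] <- served$state
    nc <- length(served$waits)
    state$completions[t, j] <- nc
    if (nc) {
      comp_j <- c(comp_j, rep(j, nc))
      comp_w <- c(comp_w, served$waits)
      comp_u <- c(comp_u, served$urgent)
    }
    state$queue_len[t, j] <- length(state$hospitals[[j]]$q_join)
    state$mu[t, j] <- state$hospitals[[j]]$mu_t
  }
  if (length(comp_j)) {
    state$comp_log[[t]] <- list(hospital = comp_j, wait = comp_w, urgent = comp_u)
  }

  # (5) wait-time release
  if (t %% cfg$tau_hat == 0L) {
    rho <- t %/% cfg$tau_hat
    for (j in seq_len(m)) {
      state$hospitals[[j]] <- release_wait_info(state$hospitals[[j]])
      state$released[rho, j] <- state$hospitals[[j]]$released_wait
    }
    state$env$released_wait[] <- state$released[rho, ]
    state$dhw <- dhw_probability_matrix(
      state$env, cfg$alpha_d, cfg$alpha_r, cfg$alpha_w, cfg$eps_w
    )
  }
  state
}

#' Run one simulation replicate
#'
#' Executes `horizon` daily steps and returns a step/round-level panel of
#' the run. Deterministic given (`cfg`, `env`, `seed`).
#'
#' @param cfg a [sim_config()].
#' @param env a [service_environment()].
#' @param seed integer seed for the run.
#' @return An object of class `sim_panel` with components:
#'   * `arrivals`, `arrivals_urgent`, `completions`, `queue_len`, `mu`:
#'     `T x M` step-level matrices;
#'   * `released`: `floor(T/tau_hat) x M` matrix of released waits (days);
#'   * `generated`: `T x N` matrix of per-city generated patients;
#'   * `flows`: `N x M x 2` city-to-hospital referral counts by urgency;
#'   * `completion_log`: data frame (`hospital`, `end_time`, `wait`,
#'     `urgent`) of every served patient;
#'   * `initial_queue`: per-hospital initial backlog;
#'   * `seed`, `config_hash`, `tau_hat`, `horizon`.
#' @export
simulate_run <- function(cfg, env, seed) {
  state <- world_init(cfg, env, seed)
  for (t in seq_len(state$cfg$horizon)) state <- sim_step(state, t)
  keep <- !vapply(state$comp_log, is.null, logical(1))
  steps <- which(keep)
  log_n <- vapply(state$comp_log[keep], function(x) length(x$wait), integer(1))
  completion_log <- data.frame(
    hospital = unlist(lapply(state$comp_log[keep], `[[`, "hospital"), use.names = FALSE),
    end_time = rep(steps, log_n),
    wait = unlist(lapply(state$comp_log[keep], `[[`, "wait"), use.names = FALSE),
    urgent = unlist(lapply(state$comp_log[keep], `[[`, "urgent"), use.names = FALSE)
  )
  structure(
    list(
      arrivals = state$arrivals,
      arrivals_urgent = state$arrivals_urgent,
      completions = state$completions,
      queue_len = state$queue_len,
      mu = state$mu,
      released = state$released,
      generated = state$generated,
      flows = state$flows,
      completion_log = completion_log,
      initial_queue = state$cfg$initial_queue,
      seed = state$seed,
      config_hash = config_hash(cfg, env),
      tau_hat = state$cfg$tau_hat,
      horizon = state$cfg$horizon
    ),
    class = "sim_panel"
  )
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d steps, %d hospitals, %d cities, seed %d\n",
    x$horizon, ncol(x$arrivals), ncol(x$generated), x$seed
  ))
  cat(sprintf(
    "  generated %d, completed %d, final queue %d\n",
    sum(x$generated), sum(x$completions), sum(x$queue_len[x$horizon, ])
  ))
  invisible(x)
}

# Derive a replicate seed below 2^31 from (master_seed, replicate index).
derive_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) %% 2147483629 * 1000003 + r * 7919) %% 2147483629) + 1L
}

#' Run independent replicate simulations
#'
#' Replicate `r` runs with a seed derived from (`master_seed`, `r`). The
#' element-wise mean panel over replicates summarizes mean trajectories;
#' distribution-level analyses should pool the per-replicate panels instead
#' (averaging destroys distributional shape).
#'
#' @param cfg a [sim_config()].
#' @param env a [service_environment()].
#' @param n_replicates number of replicates (defaults to `cfg$n_replicates`).
#' @param master_seed master seed (defaults to `cfg$master_seed`).
#' @return An object of class `replicate_set`: list with `panels` (list of
#'   [simulate_run()] panels), `mean` (element-wise mean of the numeric
#'   panel matrices), `seeds`, and `config_hash`.
#' @export
run_replicates <- function(cfg, env, n_replicates = cfg$n_replicates,
                           master_seed = cfg$master_seed) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  seeds <- vapply(seq_len(n_replicates), function(r) derive_seed(master_seed, r), integer(1))
  panels <- lapply(seeds, function(s) simulate_run(cfg, env, s))
  num_fields <- c(
    "arrivals", "arrivals_urgent", "completions", "queue_len", "mu",
    "released", "generated", "flows"
  )
  mean_panel <- lapply(num_fields, function(f) {
    Reduce(`+`, lapply(panels, `[[`, f)) / n_replicates
  })
  names(mean_panel) <- num_fields
  structure(
    list(
      panels = panels,
      mean = mean_panel,
      seeds = seeds,
      config_hash = panels[[1]]$config_hash
    ),
    class = "replicate_set"
  )
}

#' Per-round hospital arrival shares
#'
#' Aggregates step-level arrivals into release rounds and normalizes across
#' hospitals, giving each hospital's share of system arrivals per round.
#'
#' @param panel a [simulate_run()] panel.
#' @return a `rounds x M` matrix of shares, rows summing to 1 (a row of
#'   `NaN` if no arrivals occurred in a round).
#' @export
round_arrival_shares <- function(panel) {
  rounds <- ceiling(seq_len(nrow(panel$arrivals)) / panel$tau_hat)
  full <- rounds <= nrow(panel$released)
  tot <- rowsum(panel$arrivals[full, , drop = FALSE], rounds[full])
  tot / rowSums(tot)
}

#' Sweep the share of wait-time-sensitive patients
#'
#' For each value of `p_r`, runs replicate simulations, pools absolute
#' wait-time variations at the chosen time scale, and fits a power law.
#' All rows use the identical pooled-variation definition.
#'
#' @param cfg a [sim_config()] (its `p_r` is overridden per row).
#' @param env a [service_environment()].
#' @param pr_values numeric vector of `p_r` values in \[0, 1\].
#' @param n_replicates replicates per value.
#' @param master_seed master seed shared across rows.
#' @param scale,mode passed to [pool_wait_variations()].
#' @param n_bootstrap bootstrap resamples for the goodness-of-fit p-value.
#' @return a data frame with one row per `p_r`: fitted exponent, cutoff,
#'   Kolmogorov-Smirnov distance, bootstrap `gof_p`, log-log OLS slope and
#'   its p-value, tail and sample sizes, and both power-law classification
#'   flags (`plausible_clauset`: `gof_p >= 0.1`; `follows_inverted_convention`:
#'   `gof_p <= 0.1`).
#' @export
sweep_pr <- function(cfg, env, pr_values, n_replicates = cfg$n_replicates,
                     master_seed = cfg$master_seed, scale = "month",
                     mode = "pooled", n_bootstrap = 1000L) {
  if (length(pr_values) == 0L) stop("pr_values must be non-empty")
  if (any(pr_values < 0 | pr_values > 1)) stop("pr_values must lie in [0, 1]")
  rows <- lapply(pr_values, function(pr) {
    cfg$p_r <- pr
    reps <- run_replicates(cfg, env, n_replicates, master_seed)
    v <- pool_wait_variations(reps, scale = scale, mode = mode)
    fit <- fit_power_law(v, n_bootstrap = n_bootstrap)
    data.frame(
      p_r = pr, alpha = fit$alpha, xmin = fit$xmin, ks = fit$ks,
      gof_p = fit$gof_p, ols_slope = fit$ols_slope, ols_p = fit$ols_p,
      n_tail = fit$n_tail, n_sample = length(v),
      plausible_clauset = fit$gof_p >= 0.1,
      follows_inverted_convention = fit$gof_p <= 0.1
    )
  })
  do.call(rbind, rows)
}

#' Sweep the wait-information release period
#'
#' For each release period `tau_hat`, runs replicate simulations and
#' measures the dispersion of each hospital's released wait-time series by
#' its Gini coefficient (averaged over replicates), plus the across-hospital
#' mean.
#'
#' @param cfg a [sim_config()] (its `tau_hat` is overridden per row).
#' @param env a [service_environment()].
#' @param tau_hat_values integer vector of release periods, in steps.
#' @param n_replicates replicates per value.
#' @param master_seed master seed shared across rows.
#' @return a data frame with columns `tau_hat`, `gini_<hospital>` per
#'   hospital, and `mean_gini`.
#' @export
sweep_release_period <- function(cfg, env, tau_hat_values,
                                 n_replicates = cfg$n_replicates,
                                 master_seed = cfg$master_seed) {
  if (length(tau_hat_values) == 0L) stop("tau_hat_values must be non-empty")
  if (any(tau_hat_values < 1)) stop("tau_hat_values must be >= 1")
  hosp <- env$network$hospitals
  rows <- lapply(tau_hat_values, function(th) {
    cfg$tau_hat <- as.integer(th)
    reps <- run_replicates(cfg, env, n_replicates, master_seed)
    g <- sapply(seq_along(hosp), function(j) {
      mean(vapply(reps$panels, function(p) gini(p$released[, j]), numeric(1)))
    })
    out <- data.frame(tau_hat = as.integer(th))
    out[paste0("gini_", hosp)] <- as.list(g)
    out$mean_gini <- mean(g)
    out
  })
  do.call(rbind, rows)
}
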
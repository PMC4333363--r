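#' Simulation parameters
#'
#' Bundles every tunable scalar and per-hospital constant driving a
#' simulation run. Defaults follow the standard calibration of the model:
#' distance sensitivity `alpha_d = 4`, resourcefulness and wait sensitivities
#' `alpha_r = alpha_w = 1`, a 20% share of wait-time-sensitive patients
#' (`p_r = 0.2`), an urgent:non-urgent patient mix of 0.23:0.77, a 15%
#' seasonal reduction of arrivals in the warm months May-October, wait-time
#' releases every `tau_hat = 30` daily steps, service-rate adjustment every
#' `tau_tilde = 5` steps, and a 720-step (two-year) horizon.
#'
#' Per-hospital vectors (`b`, `g`, `mu_bar`, `a_bar`, `initial_wait`,
#' `initial_queue`) are recycled to the number of hospitals when the
#' configuration is paired with an environment.
#'
#' @param alpha_d,alpha_r,alpha_w selection-sensitivity exponents, each
#'   expected in \[1, 5\].
#' @param p_r probability (in \[0, 1\]) that a patient is wait-time
#'   sensitive, i.e. uses the distance + resourcefulness + wait rule.
#' @param urgent_fraction probability a generated patient is urgent.
#' @param warm_multiplier multiplicative factor applied to the
#'   patient-generation probability during warm months.
#' @param warm_months integer vector of calendar months counted as warm.
#' @param b,g per-hospital service-adjustment coefficients, each in \[0, 1\].
#' @param mu_bar per-hospital baseline daily service rate (patients/day).
#' @param a_bar per-hospital reference mean daily arrivals (patients/day).
#' @param tau_hat steps per wait-time release round (days).
#' @param tau_tilde steps between service-rate updates (days).
#' @param horizon total number of daily steps `T`.
#' @param eps_w floor (days) applied to released wait times before they
#'   enter the wait-sensitive selection rule, guarding against division by
#'   zero when a hospital served everyone same-day.
#' @param initial_wait,initial_queue per-hospital initial released wait
#'   (days) and initial queue length (patients).
#' @param n_replicates default replicate count for replicate averaging.
#' @param master_seed default master seed for replicate seed derivation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(alpha_d = 4, alpha_r = 1, alpha_w = 1,
                       p_r = 0.2,
                       urgent_fraction = 0.23,
                       warm_multiplier = 0.85,
                       warm_months = 5:10,
                       b = 0.57, g = 0.43,
                       mu_bar = NULL, a_bar = NULL,
                       tau_hat = 30, tau_tilde = 5,
                       horizon = 720,
                       eps_w = 0.5,
                       initial_wait = NULL, initial_queue = NULL,
                       n_replicates = 50, master_seed = 1L) {
  cfg <- structure(
    list(
      alpha_d = alpha_d, alpha_r = alpha_r, alpha_w = alpha_w,
      p_r = p_r,
      urgent_fraction = urgent_fraction,
      warm_multiplier = warm_multiplier,
      warm_months = as.integer(warm_months),
      b = b, g = g,
      mu_bar = mu_bar, a_bar = a_bar,
      tau_hat = as.integer(tau_hat), tau_tilde = as.integer(tau_tilde),
      horizon = as.integer(horizon),
      eps_w = eps_w,
      initial_wait = initial_wait, initial_queue = initial_queue,
      n_replicates = as.integer(n_replicates),
      master_seed = as.integer(master_seed)
    ),
    class = "sim_config"
  )
  viols <- validate_config(cfg)
  if (length(viols)) {
    stop("invalid simulation configuration:\n  ", paste(viols, collapse = "\n  "))
  }
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a [sim_config()] (or a plain list with the same fields).
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  chk_range <- function(val, name, lo, hi, lo_open = FALSE) {
    if (is.null(val) || any(!is.finite(val)) ||
        any(if (lo_open) val <= lo else val < lo) || any(val > hi)) {
      v <<- c(v, sprintf("%s must be in [%s, %s]", name, lo, hi))
    }
  }
  chk_range(cfg$p_r, "p_r", 0, 1)
  chk_range(cfg$urgent_fraction, "urgent_fraction", 0, 1)
  chk_range(cfg$b, "b", 0, 1)
  chk_range(cfg$g, "g", 0, 1)
  for (nm in c("alpha_d", "alpha_r", "alpha_w")) {
    if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] < 0)) {
      v <- c(v, sprintf("%s must be a nonnegative finite number", nm))
    }
  }
  if (!is.finite(cfg$warm_multiplier) || cfg$warm_multiplier < 0) {
    v <- c(v, "warm_multiplier must be >= 0")
  }
  if (cfg$tau_hat < 1L) v <- c(v, "tau_hat must be >= 1")
  if (cfg$tau_tilde < 1L) v <- c(v, "tau_tilde must be >= 1")
  if (cfg$horizon < cfg$tau_hat) v <- c(v, "horizon must be >= tau_hat")
  if (!is.finite(cfg$eps_w) || cfg$eps_w <= 0) v <- c(v, "eps_w must be > 0")
  for (nm in c("mu_bar", "a_bar", "initial_wait", "initial_queue")) {
    val <- cfg[[nm]]
    if (!is.null(val) && (any(!is.finite(val)) || any(val < 0))) {
      v <- c(v, sprintf("%s entries must be >= 0", nm))
    }
  }
  if (!is.null(cfg$a_bar) && any(cfg$a_bar == 0)) {
    v <- c(v, "a_bar entries must be > 0")
  }
  if (cfg$n_replicates < 1L) v <- c(v, "n_replicates must be >= 1")
  v
}

# Recycle per-hospital fields of cfg to length M, named by hospital id.
# Fills NULLs with neutral defaults (mu_bar/a_bar must be present).
align_config <- function(cfg, env) {
  m <- length(env$network$hospitals)
  rec <- function(x, name) {
    if (is.null(x)) stop(sprintf("%s must be set before running", name))
    if (length(x) == 1L) x <- rep(x, m)
    if (length(x) != m) stop(sprintf("%s must have length 1 or %d", name, m))
    stats::setNames(as.numeric(x), env$network$hospitals)
  }
  cfg$b <- rec(cfg$b, "b")
  cfg$g <- rec(cfg$g, "g")
  cfg$mu_bar <- rec(cfg$mu_bar, "mu_bar")
  cfg$a_bar <- rec(cfg$a_bar, "a_bar")
  cfg$initial_wait <- rec(
    if (is.null(cfg$initial_wait)) env$released_wait else cfg$initial_wait,
    "initial_wait"
  )
  cfg$initial_queue <- rec(
    if (is.null(cfg$initial_queue)) 0 else cfg$initial_queue,
    "initial_queue"
  )
  cfg
}

#' Map a time step to its calendar month
#'
#' The simulation starts in January; months are 30 daily steps long, so step
#' `t` (1-based) falls in month `((ceiling(t/30) - 1) mod 12) + 1`. The
#' calendar is fixed at 30-day months regardless of the wait-release period
#' `tau_hat`, so seasonal arrival modulation is unaffected when the release
#' period is varied.
#'
#' @param t integer vector of steps (1-based).
#' @return integer vector of calendar months in 1..12.
#' @export
month_of_step <- function(t) {
  ((ceiling(t / 30) - 1L) %% 12L) + 1L
}

#' Save a configuration bundle to a YAML file
#'
#' Writes a single structured text file with sections `parameters`, `cities`,
#' `hospitals`, and `distances` fully describing one experiment.
#'
#' @param cfg a [sim_config()].
#' @param env a [service_environment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
save_config <- function(cfg, env, path) {
  net <- env$network
  cfg_al <- align_config(cfg, env)
  cities <- lapply(seq_along(net$cities), function(i) {
    rec <- list(
      id = net$cities[i],
      pop = unname(env$population[i]),
      gen_prob = unname(env$gen_prob[i])
    )
    if (!is.null(env$region)) rec$region <- unname(env$region[i])
    rec
  })
  hospitals <- lapply(seq_along(net$hospitals), function(j) {
    rec <- list(
      id = net$hospitals[j],
      r = unname(env$resourcefulness[j]),
      mu_bar = unname(cfg_al$mu_bar[j]),
      a_bar = unname(cfg_al$a_bar[j]),
      b = unname(cfg_al$b[j]),
      g = unname(cfg_al$g[j]),
      init_wait = unname(cfg_al$initial_wait[j]),
      init_queue = unname(cfg_al$initial_queue[j])
    )
    if (!is.null(env$hospital_city)) rec$city <- unname(env$hospital_city[j])
    rec
  })
  params <- cfg_al[c(
    "alpha_d", "alpha_r", "alpha_w", "p_r", "urgent_fraction",
    "warm_multiplier", "warm_months", "tau_hat", "tau_tilde", "horizon",
    "eps_w", "n_replicates", "master_seed"
  )]
  doc <- list(
    parameters = params,
    cities = cities,
    hospitals = hospitals,
    distances = list(
      cities = net$cities,
      hospitals = net$hospitals,
      hours = apply(net$driving_time, 1, as.numeric, simplify = FALSE)
    )
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Load a configuration bundle from a YAML file
#'
#' Parses and validates the single-file experiment format written by
#' [save_config()]. Missing optional scalar parameters take the standard
#' defaults of [sim_config()]. All schema or invariant violations found are
#' reported together.
#'
#' @param path path to the YAML configuration file.
#' @return a list with components `cfg` (a [sim_config()]) and `env`
#'   (a [service_environment()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("config parse failure: ", conditionMessage(e))
  )
  need <- function(x, field, where) {
    if (is.null(x)) stop(sprintf("config schema error: missing %s in %s", field, where))
    x
  }
  cities <- need(doc$cities, "cities", "top level")
  hospitals <- need(doc$hospitals, "hospitals", "top level")
  dist <- need(doc$distances, "distances", "top level")
  city_id <- vapply(cities, function(x) as.character(need(x$id, "id", "cities")), "")
  hosp_id <- vapply(hospitals, function(x) as.character(need(x$id, "id", "hospitals")), "")
  if (!identical(as.character(dist$cities), city_id) ||
      !identical(as.character(dist$hospitals), hosp_id)) {
    stop("config schema error: distances section does not match city/hospital ids")
  }
  d <- do.call(rbind, lapply(dist$hours, as.numeric))
  if (!identical(dim(d), c(length(city_id), length(hosp_id)))) {
    stop("config schema error: distances/hours has wrong shape")
  }
  net <- city_hospital_network(city_id, hosp_id, d)
  getf <- function(recs, field, default = NULL) {
    vapply(recs, function(x) {
      val <- x[[field]]
      if (is.null(val)) {
        if (is.null(default)) stop(sprintf("config schema error: missing %s", field))
        val <- default
      }
      as.numeric(val)
    }, numeric(1))
  }
  region <- vapply(cities, function(x) {
    if (is.null(x$region)) NA_character_ else as.character(x$region)
  }, "")
  hosp_city <- vapply(hospitals, function(x) {
    if (is.null(x$city)) NA_character_ else as.character(x$city)
  }, "")
  env <- service_environment(
    net,
    resourcefulness = getf(hospitals, "r"),
    released_wait = getf(hospitals, "init_wait"),
    population = getf(cities, "pop"),
    gen_prob = getf(cities, "gen_prob"),
    hospital_city = if (!anyNA(hosp_city)) hosp_city,
    region = if (!anyNA(region)) region
  )
  p <- if (is.null(doc$parameters)) list() else doc$parameters
  defaults <- formals(sim_config)
  scal <- function(name) if (is.null(p[[name]])) eval(defaults[[name]]) else p[[name]]
  cfg <- sim_config(
    alpha_d = scal("alpha_d"), alpha_r = scal("alpha_r"), alpha_w = scal("alpha_w"),
    p_r = scal("p_r"),
    urgent_fraction = scal("urgent_fraction"),
    warm_multiplier = scal("warm_multiplier"),
    warm_months = scal("warm_months"),
    b = getf(hospitals, "b"),
    g = getf(hospitals, "g"),
    mu_bar = getf(hospitals, "mu_bar"),
    a_bar = getf(hospitals, "a_bar"),
    tau_hat = scal("tau_hat"), tau_tilde = scal("tau_tilde"),
    horizon = scal("horizon"),
    eps_w = scal("eps_w"),
    initial_wait = getf(hospitals, "init_wait"),
    initial_queue = getf(hospitals, "init_queue"),
    n_replicates = scal("n_replicates"),
    master_seed = scal("master_seed")
  )
  viols <- validate_environment(env)
  if (length(viols)) {
    stop("config validation error:\n  ", paste(viols, collapse = "\n  "))
  }
  list(cfg = cfg, env = env)
}

#' Write an environment as a CSV triplet
#'
#' Dumps `cities.csv` (`city_id,pop,gen_prob,region`), `hospitals.csv`
#' (`hospital_id,city_id,r,mu_bar,a_bar,b,g,init_wait,init_queue`), and
#' `distances.csv` (`city_id,hospital_id,hours`) into a directory.
#'
#' @param cfg a [sim_config()].
#' @param env a [service_environment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_environment_csv <- function(cfg, env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- env$network
  cfg_al <- align_config(cfg, env)
  utils::write.csv(
    data.frame(
      city_id = net$cities,
      pop = unname(env$population),
      gen_prob = unname(env$gen_prob),
      region = if (is.null(env$region)) NA_character_ else unname(env$region)
    ),
    file.path(dir, "cities.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(
      hospital_id = net$hospitals,
      city_id = if (is.null(env$hospital_city)) NA_character_ else unname(env$hospital_city),
      r = unname(env$resourcefulness),
      mu_bar = unname(cfg_al$mu_bar),
      a_bar = unname(cfg_al$a_bar),
      b = unname(cfg_al$b),
      g = unname(cfg_al$g),
      init_wait = unname(cfg_al$initial_wait),
      init_queue = unname(cfg_al$initial_queue)
    ),
    file.path(dir, "hospitals.csv"), row.names = FALSE
  )
  idx <- expand.grid(
    i = seq_along(net$cities), j = seq_along(net$hospitals),
    KEEP.OUT.ATTRS = FALSE
  )
  utils::write.csv(
    data.frame(
      city_id = net$cities[idx$i],
      hospital_id = net$hospitals[idx$j],
      hours = net$driving_time[cbind(idx$i, idx$j)]
    ),
    file.path(dir, "distances.csv"), row.names = FALSE
  )
  invisible(dir)
}

# Stable short hash of a configuration + environment pair, used to tag
# output panels so replicates can be checked for consistency.
config_hash <- function(cfg, env) {
  strip <- function(x) {
    # drop bookkeeping fields that do not affect dynamics
    x$master_seed <- NULL
    x$n_replicates <- NULL
    x
  }
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(list(strip(unclass(cfg)), unclass(env)), tmp, version = 3, compress = FALSE)
  unname(tools::md5sum(tmp))
}
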
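# Synthetic Ontario-like calibration bundles. The real calibration of this
# kind of model (census populations, registry service rates, road driving
# times) is proprietary; the generator emulates its structure so the full
# pipeline is exercisable end to end. Magnitudes are order-of-magnitude
# stand-ins, documented as synthetic throughout.

#' Specification for a synthetic calibration bundle
#'
#' Defaults emulate a province-scale cardiac-surgery system: 47 cities with
#' populations of at least 40,000 (log-normal above the floor), 11 hospitals
#' hosted in the largest cities, driving times of 0.3-8 hours derived from
#' uniform planar placement, 5-30 physicians per hospital, and baseline
#' service rates calibrated so total capacity is `capacity_ratio` (1.05)
#' times year-average expected arrivals — slightly above demand, so wait
#' times fluctuate near criticality without diverging. `target_daily = 24` expected patients
#' per day corresponds to roughly 8,800 surgeries a year at province scale.
#'
#' @param n_cities,n_hospitals,n_regions counts of cities, hospitals, and
#'   region labels (regions group cities for flow-share summaries).
#' @param target_daily expected province-wide daily patient generation in
#'   the cold season.
#' @param capacity_ratio total baseline service capacity over expected
#'   cold-season arrivals; must be positive, and should exceed 1 for a
#'   stable system.
#' @param distance_scale hours of driving time per unit of planar distance
#'   (cities are placed uniformly in a unit square).
#' @param distance_range clip range for driving times, hours.
#' @param r_range integer range of physicians per hospital.
#' @param init_wait_range,init_queue_range ranges for initial released
#'   waits (days) and initial queue lengths (patients).
#' @param pop_meanlog,pop_sdlog,pop_floor log-normal population parameters
#'   and the population floor.
#' @param seed integer seed making the bundle deterministic.
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_cities = 47L, n_hospitals = 11L,
                       n_regions = min(6L, n_cities),
                       target_daily = 24, capacity_ratio = 1.05,
                       distance_scale = 6, distance_range = c(0.3, 8),
                       r_range = c(5L, 30L),
                       init_wait_range = c(10, 40),
                       init_queue_range = c(20L, 120L),
                       pop_meanlog = log(60000), pop_sdlog = 1,
                       pop_floor = 40000,
                       seed = 1L) {
  if (n_hospitals > n_cities) stop("n_hospitals cannot exceed n_cities")
  if (n_regions > n_cities) stop("n_regions cannot exceed n_cities")
  if (!is.finite(capacity_ratio) || capacity_ratio <= 0) {
    stop("infeasible spec: capacity_ratio must be > 0")
  }
  structure(
    list(
      n_cities = as.integer(n_cities), n_hospitals = as.integer(n_hospitals),
      n_regions = as.integer(n_regions),
      target_daily = target_daily, capacity_ratio = capacity_ratio,
      distance_scale = distance_scale, distance_range = distance_range,
      r_range = as.integer(r_range),
      init_wait_range = init_wait_range,
      init_queue_range = as.integer(init_queue_range),
      pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog, pop_floor = pop_floor,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Generate a synthetic Ontario-like calibration bundle
#'
#' Places cities uniformly in a planar square, assigns log-normal
#' populations above the floor, hosts hospitals in the most populous
#' cities, converts planar distances to clipped driving times, draws
#' physician counts, scales per-city generation probabilities so expected
#' province-wide cold-season arrivals equal `target_daily`, and calibrates
#' each hospital's reference arrivals `a_bar` to its expected daily
#' arrivals under the distance + resourcefulness selection rule (cold
#' season), with baseline service rate `mu_bar = capacity_ratio *` the
#' hospital's year-average expected arrivals.
#' Cities are grouped into `n_regions` k-means clusters of the planar
#' coordinates for region-level flow summaries. Deterministic given the
#' spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return a list with components `cfg` (a [sim_config()] carrying the
#'   calibrated per-hospital constants) and `env` (a validated
#'   [service_environment()]).
#' @export
generate_synthetic_ontario <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_cities
  m <- spec$n_hospitals

  coords <- cbind(stats::runif(n), stats::runif(n))
  pop <- pmax(round(stats::rlnorm(n, spec$pop_meanlog, spec$pop_sdlog)), spec$pop_floor)
  cities <- sprintf("C%02d", seq_len(n))
  hosts <- order(pop, decreasing = TRUE)[seq_len(m)]
  hospitals <- sprintf("H%02d", seq_len(m))

  d_euclid <- sqrt(outer(coords[, 1], coords[hosts, 1], `-`)^2 +
                   outer(coords[, 2], coords[hosts, 2], `-`)^2)
  d <- pmin(pmax(spec$distance_scale * d_euclid, spec$distance_range[1]),
            spec$distance_range[2])

  region <- if (spec$n_regions >= n) {
    sprintf("R%d", seq_len(n))       # every city its own region
  } else {
    sprintf("R%d", stats::kmeans(coords, centers = spec$n_regions, nstart = 5)$cluster)
  }

  r <- sample(spec$r_range[1]:spec$r_range[2], m, replace = TRUE)

  # per-person rate jitter, then scale so expected cold-season arrivals hit
  # the target exactly
  jitter <- exp(stats::rnorm(n, 0, 0.2))
  gen_prob <- spec$target_daily * jitter / sum(pop * jitter)

  init_wait <- stats::runif(m, spec$init_wait_range[1], spec$init_wait_range[2])
  init_queue <- sample(spec$init_queue_range[1]:spec$init_queue_range[2], m, replace = TRUE)

  net <- city_hospital_network(cities, hospitals, d)
  env <- service_environment(
    net,
    resourcefulness = r,
    released_wait = init_wait,
    population = pop,
    gen_prob = gen_prob,
    hospital_city = cities[hosts],
    region = region
  )

  # reference arrivals under the DH rule at cold-season rates; capacity is
  # capacity_ratio times year-average expected arrivals (warm months run at
  # the warm multiplier), keeping every queue near-critical: backlog builds
  # in the cold season and drains in the warm one instead of vanishing
  dh <- dh_probability_matrix(env, 4, 1)
  a_bar <- as.numeric(crossprod(dh, pop * gen_prob))
  defaults <- sim_config()
  n_warm <- length(defaults$warm_months)
  seasonal_mean <- (12 - n_warm + n_warm * defaults$warm_multiplier) / 12
  mu_bar <- spec$capacity_ratio * seasonal_mean * a_bar

  cfg <- sim_config(
    mu_bar = mu_bar, a_bar = a_bar,
    initial_wait = init_wait, initial_queue = init_queue,
    master_seed = spec$seed
  )
  viols <- validate_environment(env)
  if (length(viols)) {
    stop("generated bundle failed validation:\n  ", paste(viols, collapse = "\n  "))
  }
  list(cfg = cfg, env = env)
}

#' Draw from a continuous power law
#'
#' Inverse-CDF sampling of \eqn{p(x) \propto x^{-\alpha}}, \eqn{x \ge
#' x_{min}}: \eqn{x = x_{min}(1-u)^{-1/(\alpha-1)}}. Used as a test fixture
#' for the power-law fitter.
#'
#' @param alpha exponent, > 1.
#' @param xmin lower bound, > 0.
#' @param n number of draws. Uses the session RNG.
#' @return numeric vector of `n` draws, all `>= xmin`.
#' @export
generate_powerlaw_sample <- function(alpha, xmin, n) {
  if (alpha <= 1) stop("alpha must be > 1")
  if (xmin <= 0) stop("xmin must be > 0")
  xmin * (1 - stats::runif(n))^(-1 / (alpha - 1))
}

#' Generate a synthetic reference flow-share matrix
#'
#' Runs one long simulation with only the distance + resourcefulness rule
#' active (`p_r = 0`) and aggregates city-to-hospital referrals into
#' region-to-region percentage shares (rows: patient-origin regions,
#' columns: hospital-host regions; rows sum to 100). Serves as a synthetic
#' stand-in for an observed regional flow table so the flow-error metric
#' can be exercised end to end.
#'
#' @param env a [service_environment()] with `region` and `hospital_city`
#'   set (as produced by [generate_synthetic_ontario()]).
#' @param cfg a [sim_config()].
#' @param seed run seed.
#' @return a region x region percentage matrix with rows summing to 100.
#' @export
generate_reference_flow_matrix <- function(env, cfg, seed = 1L) {
  if (is.null(env$region) || is.null(env$hospital_city)) {
    stop("environment must carry region and hospital_city assignments")
  }
  cfg$p_r <- 0
  panel <- simulate_run(cfg, env, seed)
  flows <- panel$flows[, , 1] + panel$flows[, , 2]   # city x hospital counts
  regions <- sort(unique(env$region))
  hosp_region <- env$region[env$hospital_city]
  out <- matrix(
    0, length(regions), length(regions),
    dimnames = list(regions, regions)
  )
  for (a in regions) {
    for (b in regions) {
      out[a, b] <- sum(flows[env$region == a, hosp_region == b, drop = FALSE])
    }
  }
  if (any(rowSums(out) == 0)) stop("a region generated no patients; use a longer run")
  100 * out / rowSums(out)
}
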
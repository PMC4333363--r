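#' Construct a city-hospital network
#'
#' A bipartite network connecting `N` cities to `M` hospitals, with edges
#' weighted by driving time in hours. City and hospital identifier sets must
#' be disjoint; every driving time must be strictly positive. Driving times
#' are treated as symmetric inputs and are not required to satisfy the
#' triangle inequality.
#'
#' @param cities character vector of city identifiers (length N).
#' @param hospitals character vector of hospital identifiers (length M).
#' @param driving_time N x M numeric matrix of driving times in hours;
#'   rows follow `cities`, columns follow `hospitals`.
#' @return An object of class `city_hospital_network`.
#' @examples
#' net <- city_hospital_network(c("a", "b"), "h1", matrix(c(1, 2), 2, 1))
#' @export
city_hospital_network <- function(cities, hospitals, driving_time) {
  cities <- as.character(cities)
  hospitals <- as.character(hospitals)
  driving_time <- as.matrix(driving_time)
  if (length(cities) < 1L) stop("need at least one city")
  if (length(hospitals) < 1L) stop("need at least one hospital")
  if (anyDuplicated(cities)) stop("duplicate city identifiers")
  if (anyDuplicated(hospitals)) stop("duplicate hospital identifiers")
  if (length(intersect(cities, hospitals)) > 0L)
    stop("city and hospital identifier sets must be disjoint")
  if (!identical(dim(driving_time), c(length(cities), length(hospitals))))
    stop("driving_time must be an N x M matrix matching cities x hospitals")
  if (any(!is.finite(driving_time)) || any(driving_time <= 0))
    stop("all driving times must be finite and > 0")
  dimnames(driving_time) <- list(cities, hospitals)
  structure(
    list(cities = cities, hospitals = hospitals, driving_time = driving_time),
    class = "city_hospital_network"
  )
}

#' Construct a simulation environment
#'
#' The environment is the shared information board that patients and their
#' general practitioners read when choosing a hospital: driving times,
#' per-hospital physician counts (resourcefulness), the most recently
#' released per-hospital wait times, city populations, and per-person daily
#' patient-generation probabilities.
#'
#' @param network a [city_hospital_network()].
#' @param resourcefulness integer vector, physicians per hospital (>= 1).
#' @param released_wait numeric vector, initial released wait time per
#'   hospital, in days.
#' @param population numeric vector, persons per city (> 0).
#' @param gen_prob numeric vector, per-person daily probability that a city
#'   resident becomes a surgical patient (in \[0, 1)).
#' @param hospital_city optional character vector naming the host city of
#'   each hospital (used for region-level flow summaries).
#' @param region optional character vector assigning each city to a region
#'   label.
#' @return An object of class `service_environment`.
#' @seealso [validate_environment()]
#' @export
service_environment <- function(network, resourcefulness, released_wait,
                                population, gen_prob,
                                hospital_city = NULL, region = NULL) {
  stopifnot(inherits(network, "city_hospital_network"))
  n <- length(network$cities)
  m <- length(network$hospitals)
  env <- structure(
    list(
      network = network,
      resourcefulness = stats::setNames(as.numeric(resourcefulness), network$hospitals),
      released_wait = stats::setNames(as.numeric(released_wait), network$hospitals),
      population = stats::setNames(as.numeric(population), network$cities),
      gen_prob = stats::setNames(as.numeric(gen_prob), network$cities),
      hospital_city = if (!is.null(hospital_city))
        stats::setNames(as.character(hospital_city), network$hospitals),
      region = if (!is.null(region))
        stats::setNames(as.character(region), network$cities)
    ),
    class = "service_environment"
  )
  if (length(env$resourcefulness) != m) stop("resourcefulness must have one entry per hospital")
  if (length(env$released_wait) != m) stop("released_wait must have one entry per hospital")
  if (length(env$population) != n) stop("population must have one entry per city")
  if (length(env$gen_prob) != n) stop("gen_prob must have one entry per city")
  env
}

#' Validate a simulation environment
#'
#' Checks every type invariant and returns a character vector describing all
#' violations found (empty when the environment is valid). Reporting rather
#' than throwing lets callers surface every problem in a configuration file
#' at once.
#'
#' @param env a [service_environment()].
#' @return character vector of violation descriptions; `character(0)` if valid.
#' @examples
#' net <- city_hospital_network("a", "h1", matrix(1, 1, 1))
#' env <- service_environment(net, 5, 20, 1e5, 1e-5)
#' validate_environment(env) # character(0)
#' @export
validate_environment <- function(env) {
  v <- character(0)
  if (!inherits(env, "service_environment")) {
    return("not a service_environment object")
  }
  net <- env$network
  d <- net$driving_time
  bad <- which(!is.finite(d) | d <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    v <- c(v, sprintf(
      "driving_time (%s, %s) must be finite and > 0",
      net$cities[bad[, 1]], net$hospitals[bad[, 2]]
    ))
  }
  bad_r <- which(!is.finite(env$resourcefulness) | env$resourcefulness < 1)
  if (length(bad_r)) {
    v <- c(v, sprintf("resourcefulness of %s must be >= 1", net$hospitals[bad_r]))
  }
  bad_w <- which(!is.finite(env$released_wait) | env$released_wait < 0)
  if (length(bad_w)) {
    v <- c(v, sprintf("released_wait of %s must be >= 0", net$hospitals[bad_w]))
  }
  bad_p <- which(!is.finite(env$population) | env$population <= 0)
  if (length(bad_p)) {
    v <- c(v, sprintf("population of %s must be > 0", net$cities[bad_p]))
  }
  bad_m <- which(!is.finite(env$gen_prob) | env$gen_prob < 0 | env$gen_prob >= 1)
  if (length(bad_m)) {
    v <- c(v, sprintf("gen_prob of %s must be in [0, 1)", net$cities[bad_m]))
  }
  if (!is.null(env$hospital_city)) {
    bad_h <- which(!(env$hospital_city %in% net$cities))
    if (length(bad_h)) {
      v <- c(v, sprintf(
        "hospital_city of %s names an unknown city", net$hospitals[bad_h]
      ))
    }
  }
  v
}

#' @export
print.service_environment <- function(x, ...) {
  cat(sprintf(
    "<service_environment> %d cities, %d hospitals\n",
    length(x$network$cities), length(x$network$hospitals)
  ))
  cat(sprintf(
    "  population total %.0f, expected daily patients %.2f (cold season)\n",
    sum(x$population), sum(x$population * x$gen_prob)
  ))
  cat(sprintf(
    "  physicians per hospital: %s\n",
    paste(x$resourcefulness, collapse = " ")
  ))
  invisible(x)
}
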
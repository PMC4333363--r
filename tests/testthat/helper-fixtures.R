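# Shared fixtures: small deterministic environments and a fast synthetic
# bundle for simulation-level tests.

# Two-hospital, three-city environment with hand-picked numbers.
tiny_env <- function(d = matrix(c(1, 2, 0.5, 1, 3, 1.5), 3, 2, byrow = FALSE),
                     r = c(10, 5), w = c(20, 20),
                     pop = c(5e4, 8e4, 6e4), m = c(1e-5, 2e-5, 1.5e-5)) {
  net <- city_hospital_network(c("c1", "c2", "c3"), c("h1", "h2"), d)
  service_environment(net, r, w, pop, m,
                      hospital_city = c("c1", "c2"),
                      region = c("R1", "R2", "R2"))
}

tiny_cfg <- function(...) {
  sim_config(mu_bar = c(1.5, 1.2), a_bar = c(1.4, 1.1),
             initial_wait = c(20, 25), initial_queue = c(15, 10),
             horizon = 120L, ...)
}

# Small but structurally full synthetic bundle; horizon shortened for speed.
small_bundle <- function(horizon = 240L, seed = 11L) {
  b <- generate_synthetic_ontario(synth_spec(
    n_cities = 8L, n_hospitals = 3L, n_regions = 2L,
    target_daily = 8, seed = seed
  ))
  b$cfg$horizon <- as.integer(horizon)
  b
}

expect_prob_vector <- function(p) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
}
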
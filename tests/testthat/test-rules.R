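env_2h <- function(d, r, w) {
  net <- city_hospital_network("c1", c("h1", "h2"), matrix(d, 1, 2))
  service_environment(net, r, w, 5e4, 1e-5)
}

test_that("distance-resourcefulness probabilities match direct arithmetic", {
  # single hospital: forced choice
  net1 <- city_hospital_network("c1", "h1", matrix(2, 1, 1))
  env1 <- service_environment(net1, 5, 20, 5e4, 1e-5)
  expect_equal(unname(dh_probabilities(1, env1, 4, 1)), 1.0)

  # d = (1, 2), alpha_d = 4, equal r: d' = (17, 17/16), normalized
  a <- dh_probabilities(1, env_2h(c(1, 2), c(1, 1), c(10, 10)), 4, 1)
  expect_prob_vector(a)
  expect_equal(unname(a), c(16 / 17, 1 / 17), tolerance = 1e-12)
  expect_equal(unname(round(a, 4)), c(0.9412, 0.0588))

  # equal distances, r = (2, 1): proportional to resourcefulness
  a <- dh_probabilities(1, env_2h(c(1, 1), c(2, 1), c(10, 10)), 4, 1)
  expect_equal(unname(a), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("wait-sensitive probabilities weight hospitals inversely by wait", {
  a <- dhw_probabilities(1, env_2h(c(1, 1), c(1, 1), c(10, 20)), 4, 1, 1)
  expect_equal(unname(a), c(2 / 3, 1 / 3), tolerance = 1e-12)
  a <- dhw_probabilities(1, env_2h(c(1, 1), c(1, 1), c(10, 20)), 4, 1, 2)
  expect_equal(unname(a), c(4 / 5, 1 / 5), tolerance = 1e-12)
  a <- dhw_probabilities(1, env_2h(c(1, 1), c(1, 1), c(15, 15)), 4, 1, 1)
  expect_equal(unname(a), c(0.5, 0.5), tolerance = 1e-12)
  # zero released wait is floored, not divided by
  a <- dhw_probabilities(1, env_2h(c(1, 1), c(1, 1), c(0, 10)), 4, 1, 1,
                         eps_w = 0.5)
  expect_prob_vector(a)
  expect_gt(a[1], a[2])
})

test_that("selection probabilities are scale-invariant and monotone", {
  set.seed(42)
  for (rep in 1:20) {
    d <- matrix(runif(8, 0.3, 8), 2, 4)
    r <- sample(5:30, 4)
    w <- runif(4, 1, 60)
    net <- city_hospital_network(c("c1", "c2"), paste0("h", 1:4), d)
    env <- service_environment(net, r, w, c(5e4, 6e4), c(1e-5, 1e-5))
    for (i in 1:2) {
      a <- dhw_probabilities(i, env, 3, 1.5, 2)
      expect_prob_vector(a)
      # common rescaling of distances and resources changes nothing
      net2 <- city_hospital_network(c("c1", "c2"), paste0("h", 1:4), d * 3.7)
      env2 <- service_environment(net2, r * 2, w, c(5e4, 6e4), c(1e-5, 1e-5))
      expect_equal(dhw_probabilities(i, env2, 3, 1.5, 2), a, tolerance = 1e-12)
    }
    # monotonicity in each factor, hospital 1 of city 1
    bump_d <- env; bump_d$network$driving_time[1, 1] <- d[1, 1] * 1.5
    expect_lt(dhw_probabilities(1, bump_d, 3, 1.5, 2)[1],
              dhw_probabilities(1, env, 3, 1.5, 2)[1])
    bump_r <- env; bump_r$resourcefulness[1] <- r[1] + 10
    expect_gt(dhw_probabilities(1, bump_r, 3, 1.5, 2)[1],
              dhw_probabilities(1, env, 3, 1.5, 2)[1])
    bump_w <- env; bump_w$released_wait[1] <- w[1] * 2
    expect_lt(dhw_probabilities(1, bump_w, 3, 1.5, 2)[1],
              dhw_probabilities(1, env, 3, 1.5, 2)[1])
  }
})

test_that("categorical draws reproduce their probabilities", {
  set.seed(7)
  p <- c(16 / 17, 1 / 17)
  draws <- hospwait:::draw_categorical(10000L, p)
  expect_equal(mean(draws == 1L), p[1], tolerance = 0.01)
  # degenerate rule shares
  expect_true(all(hospwait:::draw_categorical(100L, c(1, 0)) == 1L))
})

test_that("the service-rate rule is affine with the documented fixed point", {
  # at average load with b + g = 1 the rate equals the baseline
  expect_equal(service_rate(2, rep(10, 5), 5, 10, 0.57, 0.43), 2)
  # worked instance
  expect_equal(service_rate(2, 100, 5, 10, 0.57, 0.43), 3.14)
  # empty window leaves the floor term
  expect_equal(service_rate(2, 0, 5, 10, 0.57, 0.43), 0.86)
  expect_error(service_rate(2, 10, 5, 0, 0.57, 0.43), "a_bar")
  # affine: excess arrivals scale the excess rate linearly
  mu1 <- service_rate(2, 60, 5, 10, 0.57, 0.43)
  mu2 <- service_rate(2, 70, 5, 10, 0.57, 0.43)
  mu3 <- service_rate(2, 80, 5, 10, 0.57, 0.43)
  expect_equal(mu3 - mu2, mu2 - mu1, tolerance = 1e-12)
})

test_that("adjust_service_rate reads the trailing arrival window", {
  h <- hospital_state("h1", mu_bar = 2)
  h$arrivals <- c(5L, 20L, 20L, 20L, 20L, 20L, 3L)
  h <- adjust_service_rate(h, t = 7L, tau_tilde = 5L, a_bar = 10,
                           b = 0.57, g = 0.43)
  expect_equal(h$mu_t, 2 * (0.57 * 100 / 50 + 0.43))
  expect_error(
    adjust_service_rate(hospital_state("h1", 2), 3L, 5L, 10, 0.57, 0.43),
    "past steps"
  )
})

test_that("queues keep urgent patients ahead, first-in-first-out within class", {
  h <- hospital_state("h1", mu_bar = 1)
  expect_length(h$q_join, 0L)
  h <- enqueue(h, urgent = FALSE, t = 1)
  expect_equal(h$q_join, 1)
  h <- enqueue(h, urgent = TRUE, t = 2)
  expect_equal(h$q_urgent, c(TRUE, FALSE))   # urgent jumps the queue
  expect_equal(h$q_join, c(2, 1))
  h <- enqueue(h, urgent = TRUE, t = 3)
  h <- enqueue(h, urgent = FALSE, t = 3)
  expect_equal(h$q_urgent, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(h$q_join, c(2, 3, 1, 3))      # FIFO within each class
})

test_that("batch enqueue is equivalent to sequential enqueue", {
  set.seed(99)
  for (rep in 1:25) {
    h0 <- hospital_state("h1", 1, initial_queue = sample(0:5, 1))
    # seed some history
    for (t in 1:3) h0 <- enqueue(h0, runif(1) < 0.4, t)
    urgent <- runif(sample(0:6, 1)) < 0.5
    h_seq <- h0
    for (u in urgent) h_seq <- enqueue(h_seq, u, 9)
    h_bat <- hospwait:::enqueue_batch(h0, urgent, 9)
    expect_equal(h_bat$q_join, h_seq$q_join)
    expect_equal(h_bat$q_urgent, h_seq$q_urgent)
  }
})

test_that("daily service draws Poisson completions truncated at the queue", {
  h <- hospital_state("h1", mu_bar = 3)
  expect_length(serve_day(h, 1)$waits, 0L)          # empty queue
  h0 <- hospital_state("h1", mu_bar = 0, initial_queue = 10)
  expect_length(serve_day(h0, 1)$waits, 0L)         # zero rate
  # saturated server: mean daily completions equals the rate
  set.seed(123)
  h <- hospital_state("h1", mu_bar = 3, initial_queue = 60)
  total <- 0L
  for (t in 1:10000) {
    out <- serve_day(h, t)
    h <- out$state
    n <- length(out$waits)
    total <- total + n
    if (n > 0) h <- hospwait:::enqueue_batch(h, rep(FALSE, n), t)  # keep saturated
  }
  expect_equal(total / 10000, 3, tolerance = 0.06)  # 3 +/- 3*sqrt(3/1e4)
})

test_that("urgent patients are always served before older non-urgent ones", {
  set.seed(5)
  h <- hospital_state("h1", mu_bar = 2, initial_queue = 4)
  for (t in 1:50) {
    k <- rpois(1, 3)
    if (k > 0) h <- hospwait:::enqueue_batch(h, runif(k) < 0.3, t)
    out <- serve_day(h, t)
    # if any non-urgent patient was served, no urgent patient can remain
    if (any(!out$urgent)) expect_false(any(out$state$q_urgent))
    # queue invariant after every mutation: urgent block strictly first
    qu <- out$state$q_urgent
    expect_true(all(diff(as.integer(qu)) <= 0))
    h <- out$state
  }
})

test_that("wait release publishes the round median and carries forward", {
  h <- hospital_state("h1", 1, initial_wait = 22)
  h$round_waits <- c(3, 5, 100)
  h <- release_wait_info(h)
  expect_equal(h$released_wait, 5)           # median robust to the outlier
  expect_length(h$round_waits, 0L)
  h$round_waits <- c(4, 6)
  h <- release_wait_info(h)
  expect_equal(h$released_wait, 5)           # even n: midpoint
  h <- release_wait_info(h)                  # empty round
  expect_equal(h$released_wait, 5)           # carried forward
})
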
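test_that("daily patient generation has Poisson counts and the urgent mix", {
  env <- tiny_env()
  cfg <- tiny_cfg()
  env$gen_prob[["c1"]] <- 0
  set.seed(1)
  expect_equal(nrow(generate_daily_patients(1, 1, env, cfg)), 0L)

  env$gen_prob[["c2"]] <- 4 / env$population[["c2"]]  # pop * m = 4
  set.seed(2)
  pats <- lapply(1:10000, function(i) generate_daily_patients(2, 1, env, cfg))
  counts <- vapply(pats, nrow, integer(1))
  expect_equal(mean(counts), 4, tolerance = 0.06)
  urg <- unlist(lapply(pats, `[[`, "urgent"))
  expect_equal(mean(urg), 0.23, tolerance = 0.015)

  # warm months generate at the seasonal multiplier in expectation
  set.seed(3)
  warm_counts <- vapply(
    1:20000, function(i) nrow(generate_daily_patients(2, 121, env, cfg)),
    integer(1)
  )
  expect_equal(mean(warm_counts) / 4, 0.85, tolerance = 0.03)
})

test_that("every step conserves patients exactly", {
  b <- small_bundle(horizon = 120L)
  p <- simulate_run(b$cfg, b$env, 77)
  init <- sum(p$initial_queue)
  gen_cum <- cumsum(rowSums(p$generated))
  comp_cum <- cumsum(rowSums(p$completions))
  queued <- rowSums(p$queue_len)
  expect_equal(init + gen_cum, comp_cum + queued)
  # arrivals equal generated patients each step (every patient enqueues)
  expect_equal(rowSums(p$arrivals), rowSums(p$generated))
  # flows ledger agrees with totals
  expect_equal(sum(p$flows), sum(p$generated))
  expect_equal(sum(p$flows[, , 1]), sum(p$arrivals_urgent))
})

test_that("identical seeds give identical panels, different seeds differ", {
  b <- small_bundle(horizon = 90L)
  p1 <- simulate_run(b$cfg, b$env, 5)
  p2 <- simulate_run(b$cfg, b$env, 5)
  p3 <- simulate_run(b$cfg, b$env, 6)
  expect_identical(p1$arrivals, p2$arrivals)
  expect_identical(p1$released, p2$released)
  expect_identical(p1$completion_log, p2$completion_log)
  expect_false(identical(p1$arrivals, p3$arrivals))
})

test_that("release rounds count horizon / tau_hat", {
  b <- small_bundle(horizon = 60L)
  p <- simulate_run(b$cfg, b$env, 9)
  expect_equal(nrow(p$released), 2L)
  b$cfg$horizon <- 720L
  p <- simulate_run(b$cfg, b$env, 9)
  expect_equal(nrow(p$released), 24L)  # two years of monthly releases
})

test_that("a step with no generation only serves and releases", {
  b <- small_bundle(horizon = 60L)
  b$env$gen_prob[] <- 0
  p <- simulate_run(b$cfg, b$env, 4)
  expect_true(all(p$generated == 0))
  expect_true(all(p$arrivals == 0))
  expect_gt(sum(p$completions), 0)   # the initial backlog still drains
  expect_equal(nrow(p$released), 2L)
})

test_that("the per-step referral ledger sums to the city's generated patients", {
  b <- small_bundle(horizon = 40L)
  state <- hospwait:::world_init(b$cfg, b$env, 21)
  for (t in 1:10) {
    state <- sim_step(state, t)
    expect_equal(rowSums(state$last_ledger, dims = 1), state$generated[t, ],
                 ignore_attr = TRUE)
  }
})

test_that("replicate sets average panels element-wise and are seed-stable", {
  b <- small_bundle(horizon = 60L)
  r1 <- run_replicates(b$cfg, b$env, 1, master_seed = 31)
  expect_equal(r1$mean$arrivals, r1$panels[[1]]$arrivals)
  r3 <- run_replicates(b$cfg, b$env, 3, master_seed = 31)
  expect_equal(
    r3$mean$released,
    (r3$panels[[1]]$released + r3$panels[[2]]$released + r3$panels[[3]]$released) / 3
  )
  expect_identical(r3$seeds, run_replicates(b$cfg, b$env, 3, 31)$seeds)
  expect_true(all(vapply(r3$panels, `[[`, character(1), "config_hash") ==
                    r3$config_hash))
})

test_that("replicate-mean variance shrinks roughly as 1/R", {
  b <- small_bundle(horizon = 60L)
  b$cfg$p_r <- 0
  means_at <- function(R, n_sets, seed0) {
    vapply(seq_len(n_sets), function(s) {
      reps <- run_replicates(b$cfg, b$env, R, master_seed = seed0 + s)
      mean(reps$mean$arrivals)
    }, numeric(1))
  }
  v4 <- var(means_at(4L, 12L, 100))
  v16 <- var(means_at(16L, 12L, 200))
  expect_lt(v16, v4)           # CLT direction
  expect_lt(v16, v4 / 1.5)     # and by a material factor (~4 expected)
})

test_that("round arrival shares are a probability row per round", {
  b <- small_bundle(horizon = 120L)
  p <- simulate_run(b$cfg, b$env, 13)
  s <- round_arrival_shares(p)
  expect_equal(dim(s), c(4L, 3L))
  expect_equal(unname(rowSums(s)), rep(1, 4))
})

test_that("the p_r sweep yields one consistent row per value", {
  b <- small_bundle(horizon = 240L)
  tab <- sweep_pr(b$cfg, b$env, c(0, 0.5), n_replicates = 3,
                  master_seed = 17, n_bootstrap = 20L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$p_r, c(0, 0.5))
  expect_true(all(tab$n_tail >= 2))
  expect_true(all(tab$gof_p >= 0 & tab$gof_p <= 1))
  # schema survives a CSV round trip
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$gof_p, tab$gof_p)
  expect_named(back, names(tab))
  expect_error(sweep_pr(b$cfg, b$env, numeric(0)), "non-empty")
  expect_error(sweep_pr(b$cfg, b$env, 1.4), "\\[0, 1\\]")
})

test_that("the release-period sweep reports per-hospital and mean Ginis", {
  b <- small_bundle(horizon = 240L)
  tab <- sweep_release_period(b$cfg, b$env, c(15L, 30L), n_replicates = 2,
                              master_seed = 19)
  expect_equal(tab$tau_hat, c(15L, 30L))
  gcols <- grep("^gini_", names(tab))
  expect_length(gcols, 3L)
  expect_equal(tab$mean_gini, rowMeans(tab[gcols]))
  expect_true(all(tab$mean_gini >= 0 & tab$mean_gini < 1))
})
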
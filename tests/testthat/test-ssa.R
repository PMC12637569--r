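test_that("identical seeds reproduce runs bit-for-bit", {
  g <- build_oblique(5, 5, sigma = 0.5)
  p <- rate_params(c0 = 20)
  f1 <- first_passage_time(g, p, t_max = 1e6, seed = 123)
  f2 <- first_passage_time(g, p, t_max = 1e6, seed = 123)
  expect_identical(f1$T, f2$T)
  expect_identical(f1$n_events, f2$n_events)
  t1 <- simulate_trajectory(g, p, t_end = 50, seed = 42)
  t2 <- simulate_trajectory(g, p, t_end = 50, seed = 42)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$n_open, t2$n_open)
})

test_that("waiting increments are exponential with the total-rate parameter", {
  g1 <- tetramer()
  p <- rate_params(c0 = 6, delta = 0.5)
  st <- new_cluster_state(g1)
  r_tot <- sum(subunit_rates(st, g1, p)$rates)
  expect_equal(r_tot, 4 * p$kfo * p$c0 * exp(-1))  # four closed subunits
  set.seed(31)
  n <- 4000
  dts <- vapply(seq_len(n), function(i) ssa_step(st, g1, p)$dt, 0)
  expect_lt(abs(mean(dts) - 1 / r_tot), 3 * (1 / r_tot) / sqrt(n))
})

test_that("events are selected proportionally to subunit rates", {
  # one open subunit at rate kb = 3r against three closed at rate r each:
  # the open subunit is chosen with probability 3r / 6r = 1/2
  g1 <- tetramer()
  p <- rate_params(kfo = 1, c0 = 1, kb = 3, delta = 0, g = 0)
  st <- c(1L, -1L, -1L, -1L)
  expect_equal(subunit_rates(st, g1, p)$rates, c(3, 1, 1, 1))
  set.seed(9)
  n <- 4000
  picked <- vapply(seq_len(n), function(i) ssa_step(st, g1, p)$k, 0L)
  expect_lt(abs(mean(picked == 1L) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("a rate-free state is reported as absorbing", {
  g1 <- tetramer()
  p <- rate_params(kfo = 0)
  s <- ssa_step(new_cluster_state(g1), g1, p)
  expect_true(is.na(s$k))
  expect_identical(s$dt, Inf)
  fp <- first_passage_time(g1, p, t_max = 100, seed = 1)
  expect_true(fp$censored)
  expect_true(fp$absorbing)
  expect_false(fp$fired)
})

test_that("compiled engine reproduces the pure-R reference event by event", {
  g <- build_adjoining(2, 2, sigma = 0.6)
  p <- rate_params(c0 = 30, sigma = 0.6, nc = 2)
  for (seed in 1:5) {
    ref <- ryrspark:::fpt_reference(g, p, t_max = 1e6, seed = seed,
                                    max_events = 5e4)
    fp <- first_passage_time(g, p, t_max = 1e6, seed = seed)
    expect_true(ref$fired)
    expect_true(fp$fired)
    expect_equal(fp$T, ref$T, tolerance = 1e-9)
    expect_equal(fp$n_events, ref$n_events)
  }
})

test_that("incremental propensity bookkeeping matches from-scratch recomputation", {
  g <- build_oblique(10, 10, sigma = 1)
  p <- rate_params(c0 = 50, sigma = 1)
  out <- ryrspark:::run_core(g, p, t_stop = 1e9, seed = 77, event_cap = 2000,
                             stop_at_threshold = FALSE, record = FALSE,
                             paranoid = TRUE)
  expect_identical(out$n_events, 2000)
  expect_lt(out$max_bookkeeping_err, 1e-10)
})

test_that("a calcium change rescales opening rates without touching gamma", {
  g <- build_oblique(3, 3, sigma = 0.7)
  set.seed(5)
  st <- random_state(g)
  a <- subunit_rates(st, g, rate_params(c0 = 2, sigma = 0.7))
  b <- subunit_rates(st, g, rate_params(c0 = 8, sigma = 0.7))
  expect_equal(a$gamma, b$gamma)
  expect_equal(b$rates[a$opening] / a$rates[a$opening],
               rep(b$ca / a$ca, sum(a$opening)))
  expect_equal(b$rates[!a$opening], a$rates[!a$opening])
})

test_that("trajectories record every change of the open-channel count", {
  g <- build_oblique(10, 10, sigma = 0.5)
  p <- rate_params(c0 = 6)
  tr <- simulate_trajectory(g, p, t_end = 0, seed = 1)
  expect_identical(nrow(tr), 1L)            # only the initial record
  tr <- simulate_trajectory(g, p, t_end = 2000, seed = 1)
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr$n_open >= 0 & tr$n_open <= 100))
  expect_true(all(abs(diff(tr$n_open)) == 1L))
})

test_that("activation is explosive: slow nucleation then cluster-wide opening", {
  # reference conditions for spontaneous sparks: c0 = 6 uM, oblique, sigma 0.5
  g <- build_oblique(10, 10, sigma = 0.5)
  p <- rate_params(c0 = 6)
  tr <- simulate_trajectory(g, p, t_end = 2000, seed = 1)
  expect_gte(max(tr$n_open), 90)            # nearly all 100 channels open
  t5 <- tr$time[match(TRUE, tr$n_open >= 5)]
  t50 <- tr$time[match(TRUE, tr$n_open >= 50)]
  expect_lt(t50 - t5, 0.1 * t5)             # the rise is fast vs the wait
  expect_lte(max(tr$n_open[tr$time < 0.5 * t5]), 4)  # quiescent baseline
})

test_that("censoring reports t_max as a lower bound", {
  g <- build_oblique(3, 3, sigma = 1)
  p <- rate_params(c0 = 0.1, sigma = 1)    # diastolic calcium: sparks are rare
  fp <- first_passage_time(g, p, t_max = 10, seed = 2)
  expect_true(fp$censored)
  expect_identical(fp$T, 10)
  expect_false(fp$fired)
})

test_that("spark waiting times are near-exponential in the rare-event regime", {
  g <- build_oblique(10, 10, sigma = 0.5)
  p <- rate_params(c0 = 5)
  ts <- vapply(1:200, function(i)
    first_passage_time(g, p, t_max = 1e7, seed = 200000 + i)$T, 0)
  cv <- stats::sd(ts) / mean(ts)
  expect_gt(cv, 0.7)
  expect_lt(cv, 1.3)
})

test_that("waiting time is insensitive to nc above baseline fluctuations", {
  g <- build_oblique(10, 10, sigma = 0.5)
  p5 <- rate_params(c0 = 6, nc = 5)
  p10 <- rate_params(c0 = 6, nc = 10)
  d <- vapply(1:10, function(s) {
    a <- first_passage_time(g, p5, t_max = 1e6, seed = s)$T
    b <- first_passage_time(g, p10, t_max = 1e6, seed = s)$T
    c(a, b)
  }, c(0, 0))
  expect_true(all(d[2, ] >= d[1, ]))
  expect_lt(mean(d[2, ] - d[1, ]) / mean(d[1, ]), 0.05)
})
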
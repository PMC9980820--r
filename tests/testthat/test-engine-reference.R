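# The pure-R reference engine: one test per model operation, pinned by hand
# computation wherever the operation is deterministic.

test_that("init_group builds the boldness hierarchy at the refuge", {
  g <- init_group(sim_config(n = 10, omega_difference = 0.001, seed = 5))
  expect_equal(g$agents$omega[1], 0)
  expect_equal(g$agents$omega[4], 0.003) # identity 4 carries 3 increments
  expect_equal(g$agents$d, rep(0, 10))
  expect_equal(g$agents$p, rep(0.001, 10))
  expect_true(all(g$agents$speed >= 0.95 & g$agents$speed <= 1))
  expect_equal(g$t, 0)

  # zero increment: all individuals identical in omega and p
  g0 <- init_group(sim_config(omega_difference = 0, seed = 5))
  expect_equal(g0$agents$omega, rep(0, 10))
  expect_equal(g0$agents$p, rep(0.001, 10))

  # same seed, bit-identical speeds; different seed differs
  expect_identical(init_group(sim_config(seed = 42))$agents$speed,
                   init_group(sim_config(seed = 42))$agents$speed)
  expect_false(identical(init_group(sim_config(seed = 42))$agents$speed,
                         init_group(sim_config(seed = 43))$agents$speed))
})

test_that("probability update matches its closed form", {
  g <- make_group(c(0, 0), p = 0.001)
  g$agents$omega <- c(0, 0.001)
  for (k in 1:3) for (i in 1:2) g <- update_probability(g, i)
  expect_equal(g$agents$p[2], 0.004) # p_baseline + 3 * omega
  expect_equal(g$agents$p[1], 0.001) # omega = 0: unchanged forever

  # iterated recursion equals p_baseline + t * omega to 1e-12, and is
  # deliberately not clamped at 1
  g <- make_group(0, p = 0.001)
  g$agents$omega <- 0.0017
  for (t in 1:1000) g <- update_probability(g, 1)
  expect_equal(g$agents$p[1], 0.001 + 1000 * 0.0017, tolerance = 1e-12)
  expect_gt(g$agents$p[1], 1)
})

test_that("movement decision branches are exclusive and correct", {
  # (a) at the foraging site: never moves
  g <- make_group(100.3, d_food = 100, p = 1)
  expect_equal(decide_and_move(g, 1)$agents$d[1], 100.3)
  # (b) behind the refuge: forced outward by its speed, no draw consumed
  g <- make_group(-0.5, speed = 0.97)
  expect_equal(decide_and_move(g, 1)$agents$d[1], 0.47)
  # (c) p >= 1 in the corridor: always moves outward
  g <- make_group(c(0, 0), rule = "central", speed = 0.96, p = 1)
  expect_equal(decide_and_move(g, 1)$agents$d[1], 0.96)
})

test_that("central rule moves towards (or past) the mean of the others", {
  g <- make_group(c(2, 0, 10), speed = 1, p = 0)
  expect_equal(social_action_central(g, 1)$agents$d[1], 3) # mean 5, outward
  # exactly at the centroid: no move
  g <- make_group(c(5, 0, 10), speed = 1)
  expect_equal(social_action_central(g, 1)$agents$d[1], 5)
  # full-step overshoot past a nearby centroid
  g <- make_group(c(1, 1.2, 1.2), speed = 0.95)
  expect_equal(social_action_central(g, 1)$agents$d[1], 1.95)
})

test_that("nearest-neighbour rule targets the closest individual", {
  g <- make_group(c(7.5, 5, 9), speed = 0.97)
  expect_equal(social_action_nearest(g, 1)$agents$d[1], 7.5 + 0.97)
  # nearest neighbour co-located: no move
  g <- make_group(c(3, 3, 9), speed = 0.97)
  expect_equal(social_action_nearest(g, 1)$agents$d[1], 3)
  # exact tie: each direction chosen with probability 1/2
  set.seed(99)
  moves <- replicate(400, {
    g <- make_group(c(5, 3, 7), speed = 1)
    social_action_nearest(g, 1)$agents$d[1]
  })
  up <- mean(moves == 6)
  expect_lt(abs(up - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("majority rule follows strict counts and ties freeze", {
  g <- make_group(c(5, 6, 7, 8, 4, 3), speed = 0.97) # 3 ahead, 2 behind
  expect_equal(social_action_majority(g, 1)$agents$d[1], 5.97)
  g <- make_group(c(5, 6, 7, 4, 3), speed = 0.97) # 2 v 2 tie
  expect_equal(social_action_majority(g, 1)$agents$d[1], 5)
  # colleagues at the focal position count for neither side
  g <- make_group(c(5, 5, 5), speed = 0.97)
  expect_equal(social_action_majority(g, 1)$agents$d[1], 5)
})

test_that("step_group advances time and honours absorption", {
  # forced march: a lone individual with p = 1 advances by s every period
  cfg <- sim_config(n = 1, p_baseline = 1, omega_difference = 0,
                    d_food = 100, seed = 3)
  g <- init_group(cfg)
  s <- g$agents$speed[1]
  for (k in 1:5) g <- step_group(g)
  expect_equal(g$agents$d[1], 5 * s, tolerance = 1e-12)
  expect_equal(g$t, 5)

  # an absorbed group: stepping changes nothing but t
  g <- make_group(c(100.5, 100.2), rule = "central", d_food = 100, t = 7)
  g2 <- step_group(g)
  expect_equal(g2$agents$d, c(100.5, 100.2))
  expect_equal(g2$t, 8)
})

test_that("reference runs are reproducible and event-consistent", {
  cfg <- quick_config(rule = "nearest_neighbour", seed = 11)
  log1 <- run_simulation(cfg, engine = "reference")
  log2 <- run_simulation(cfg, engine = "reference")
  expect_identical(log1$agents, log2$agents)
  expect_identical(log1$end_time, log2$end_time)
  a <- log1$agents
  expect_true(all(a$leave_time <= a$arrival_time))
  expect_true(all(a$arrival_time <= log1$end_time))
  expect_equal(max(a$arrival_time), log1$end_time)

  # non-social positions never decrease
  tr <- run_simulation(quick_config(seed = 2), engine = "reference",
                       record_trajectory = TRUE)$trajectory
  expect_true(all(diff(tr) >= 0))
})

test_that("runs that cannot finish in max_steps fail loudly", {
  cfg <- sim_config(n = 2, rule = "central", p_baseline = 1e-6,
                    omega_difference = 0, max_steps = 50, seed = 1)
  expect_error(run_simulation(cfg, engine = "reference"), "max_steps")
  expect_error(run_simulation(cfg, engine = "compiled"), "max_steps")
})
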
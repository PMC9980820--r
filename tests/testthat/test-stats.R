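test_that("within-group rescaling maps fastest to 0 and slowest to 1", {
  expect_equal(rescale_within_group(c(5, 10, 15)), c(0, 0.5, 1))
  expect_equal(rescale_within_group(c(7, 7, 7)), c(0, 0, 0))
  x <- c(3, 9, 4, 12)
  expect_equal(rescale_within_group(x + 100), rescale_within_group(x))
  y <- rescale_within_group(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
})

test_that("one-way F equals the sums-of-squares oracle", {
  # tiny worked dataset: 2 levels x 3 runs
  toy <- data.frame(value = rep(c(0.1, 0.2), each = 3),
                    y = c(1, 2, 3, 7, 8, 9))
  a <- oneway_anova_f(toy, "y")
  expect_equal(a$F, 54) # SSB 54 on 1 df over SSW 4 on 4 df
  expect_equal(a$df, c(1, 4))
  expect_equal(a$F, oneway_oracle_f(toy$y, toy$value))

  # property: random unbalanced-free tables agree with the oracle
  set.seed(1)
  for (k in 1:5) {
    d <- data.frame(value = rep(seq_len(3 + k %% 2), each = 6),
                    y = rnorm(6 * (3 + k %% 2)))
    expect_equal(oneway_anova_f(d, "y")$F, oneway_oracle_f(d$y, d$value),
                 tolerance = 1e-10)
  }

  # zero within-level variance with distinct means diverges
  d0 <- data.frame(value = rep(1:2, each = 3), y = rep(c(1, 2), each = 3))
  expect_identical(oneway_anova_f(d0, "y")$F, Inf)
  expect_error(oneway_anova_f(data.frame(value = 1:2, y = 1:2), "y"),
               "observations per level")
})

test_that("one-way F is calibrated under the null", {
  set.seed(7)
  fs <- replicate(60, {
    d <- data.frame(value = rep(1:4, each = 30), y = rnorm(120))
    oneway_anova_f(d, "y")$F
  })
  expect_gt(mean(fs), 0.7)
  expect_lt(mean(fs), 1.4)
  crit <- qf(0.999, 3, 116)
  expect_lte(sum(fs > crit), 2) # ~0.1% nominal rate
})

test_that("repeated-measures F matches aov on small balanced tables", {
  # toy mixed design: 2 levels x 4 runs x 3 identities
  set.seed(2)
  toy <- random_rm_table(L = 2, R = 4, n_id = 3)
  mine <- repeated_measures_anova(toy, "y")
  orac <- rm_aov_oracle(toy, "y")
  expect_equal(mine$parameter_F, orac$parameter_F, tolerance = 1e-10)
  expect_equal(mine$individual_F, orac$individual_F, tolerance = 1e-10)

  # property: random balanced tables across design shapes
  for (k in 1:8) {
    L <- sample(2:3, 1); R <- sample(2:4, 1); n_id <- sample(2:4, 1)
    tab <- random_rm_table(L, R, n_id, id_effect = runif(1, 0, 2))
    mine <- repeated_measures_anova(tab, "y")
    orac <- rm_aov_oracle(tab, "y")
    expect_equal(mine$parameter_F, orac$parameter_F, tolerance = 1e-8)
    expect_equal(mine$individual_F, orac$individual_F, tolerance = 1e-8)
    # degrees of freedom follow the balanced design
    expect_equal(mine$table$df,
                 c(L - 1, L * (R - 1), n_id - 1,
                   (n_id - 1) * (L * R - 1)))
  }

  # pure identity signal: identity stratum diverges, parameter stratum empty
  pure <- expand.grid(identity = 1:4, replicate = 1:3, value = 1:2)
  pure$y <- (pure$identity - 1) / 3
  a <- repeated_measures_anova(pure, "y")
  expect_identical(a$individual_F, Inf)
  expect_identical(a$parameter_F, 0)

  # unbalanced tables are refused
  expect_error(repeated_measures_anova(pure[-1, ], "y"), "unbalanced")
})

test_that("identity F is calibrated when labels are shuffled within runs", {
  set.seed(3)
  fs <- replicate(40, {
    tab <- random_rm_table(L = 3, R = 8, n_id = 5, id_effect = 2)
    tab$identity <- ave(tab$identity,
                        interaction(tab$value, tab$replicate),
                        FUN = sample)
    repeated_measures_anova(tab, "y")$individual_F
  })
  expect_gt(mean(fs), 0.7)
  expect_lt(mean(fs), 1.4)
})

test_that("the ordering-difference metric is bounded, paired and antisymmetric", {
  base <- expand.grid(identity = 1:3, replicate = 1:2, value = 0.001)
  soc <- cbind(base, rule = "central",
               rescaled_travel_time = c(0, 0.5, 1, 0, 0.25, 1))
  ns <- cbind(base, rule = "non_social",
              rescaled_travel_time = c(1, 0.5, 0, 0, 0.25, 1))
  res <- rbind(soc, ns)
  d <- social_difference(res, "central", measures = "travel_time")
  expect_true(all(d$difference >= -1 & d$difference <= 1))
  # focal fastest socially, slowest non-socially
  expect_equal(d$difference[d$identity == 1 & d$replicate == 1], -1)
  # identical rescaled vectors give zero difference
  expect_equal(d$difference[d$replicate == 2], c(0, 0, 0))
  # swapping the arms negates the metric
  res_swap <- res
  res_swap$rule <- ifelse(res$rule == "central", "non_social", "central")
  d_swap <- social_difference(res_swap, "central", measures = "travel_time")
  expect_equal(d_swap$difference, -d$difference)
  # unpaired inputs are refused
  expect_error(social_difference(res[-1, ], "central",
                                 measures = "travel_time"), "unpaired")
  expect_error(social_difference(res, "non_social"), "social")
})

test_that("rescale_sweep and summarize_cells aggregate per run and cell", {
  res <- run_sweep(sweep_design("omega_difference", grid = c(5e-4, 2e-3),
                                replicates = 4, rules = c("non_social",
                                                          "central"),
                                protocol = "full_group", master_seed = 5,
                                baseline = list(n = 5, d_food = 30)))
  res <- rescale_sweep(res)
  by_run <- split(res, interaction(res$rule, res$value, res$replicate))
  for (r in by_run) {
    expect_equal(min(r$rescaled_travel_time), 0)
    expect_equal(max(r$rescaled_travel_time), 1)
    expect_equal(r$rescaled_leave_time,
                 rescale_within_group(r$leave_time))
  }
  cells <- summarize_cells(res, measures = "end_time")
  expect_equal(nrow(cells), 4) # 2 rules x 2 values
  one <- res[res$rule == "central" & res$value == 5e-4, ]
  expect_equal(cells$mean[cells$rule == "central" & cells$value == 5e-4],
               mean(one$end_time))
})
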
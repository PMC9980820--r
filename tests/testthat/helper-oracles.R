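# Independent oracles used across the suite.  Deliberately written from the
# model definitions, not from the package's implementation paths.

# Exact arrival-time distribution of a single non-social individual via
# dynamic programming over (moves made, period).  The individual needs the
# smallest m with m * speed >= d_food outward moves; at period t it moves
# with probability min(1, p_baseline + t * omega).  Returns P(arrival = t)
# for t = 1..t_max plus the remaining tail mass.
dp_arrival_dist <- function(p_baseline, omega, d_food, speed_min = 0.95,
                            t_max = 500) {
  # moves needed is the same for every speed in [0.95, 1): speed < 1 a.s.
  m_lo <- ceiling(d_food / speed_min)
  m_hi <- floor(d_food) + 1 # smallest m with m * s >= d_food for s -> 1-
  stopifnot(m_lo == m_hi) # choose d_food so M does not depend on speed
  M <- m_lo
  state <- c(1, rep(0, M - 1)) # state[m + 1] = P(m moves made, not arrived)
  prob <- numeric(t_max)
  for (t in seq_len(t_max)) {
    p <- min(1, p_baseline + t * omega)
    prob[t] <- state[M] * p
    new <- state * (1 - p)
    new[-1] <- new[-1] + state[-M] * p
    state <- new
  }
  list(prob = prob, tail = sum(state))
}

# Chi-square goodness-of-fit p-value of observed arrival times against a
# dp_arrival_dist() result, merging consecutive periods into bins with
# expected count >= 5.
dp_chisq_p <- function(arrivals, dist) {
  n <- length(arrivals)
  probs <- c(dist$prob, dist$tail) # index t_max + 1 = "later than t_max"
  gvec <- integer(length(probs))
  g <- 1L
  acc <- 0
  for (i in seq_along(probs)) {
    gvec[i] <- g
    acc <- acc + probs[i] * n
    if (acc >= 5 && i < length(probs)) {
      g <- g + 1L
      acc <- 0
    }
  }
  if (acc < 5 && g > 1L) gvec[gvec == g] <- g - 1L # fold a light tail bin
  expected_p <- as.vector(tapply(probs, gvec, sum))
  idx <- pmin(arrivals, length(probs))
  obs <- tabulate(gvec[idx], nbins = max(gvec))
  suppressWarnings(stats::chisq.test(obs, p = expected_p / sum(expected_p)))$p.value
}

# One-way F from first principles (between/within sums of squares).
oneway_oracle_f <- function(y, g) {
  g <- factor(g)
  m <- mean(y)
  mg <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (mg - m)^2)
  ssw <- sum((y - mg[g])^2)
  (ssb / (nlevels(g) - 1)) / (ssw / (length(y) - nlevels(g)))
}

# Repeated-measures F values via stats::aov with an Error(run) stratum —
# feasible only for small tables, which is exactly where it serves as the
# independent oracle for the closed-form implementation.
rm_aov_oracle <- function(df, response) {
  d <- data.frame(y = df[[response]],
                  value = factor(df$value),
                  identity = factor(df$identity),
                  run = interaction(df$value, df$replicate, drop = TRUE))
  fit <- stats::aov(y ~ value + identity + Error(run), data = d)
  s <- summary(fit)
  btab <- s[["Error: run"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  list(parameter_F = btab[trimws(rownames(btab)) == "value", "F value"],
       individual_F = wtab[trimws(rownames(wtab)) == "identity", "F value"])
}

# Random balanced full-group table with run effects, identity effects and
# noise, for property-style ANOVA checks.
random_rm_table <- function(L, R, n_id, id_effect = 1, run_sd = 0.5) {
  grid <- expand.grid(identity = seq_len(n_id), replicate = seq_len(R),
                      value = seq_len(L))
  run <- interaction(grid$value, grid$replicate)
  grid$y <- 0.1 * grid$value + id_effect * grid$identity / n_id +
    rnorm(nlevels(run), sd = run_sd)[run] + rnorm(nrow(grid), sd = 0.3)
  grid
}
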
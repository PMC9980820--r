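# Pure-R reference engine.  Deliberately literal: one function per model
# operation, operating on a transparent group-state list, driven by R's RNG.
# It exists so the model logic can be read, unit-tested operation by
# operation, and cross-validated against the compiled engine; it is far too
# slow for the sweep protocols.

#' Initialise a group at the refuge
#'
#' Creates `n` individuals at position 0 with outward probability
#' `p_baseline`, personal probability adjustments
#' `omega = (identity - 1) * omega_difference`, and speeds drawn
#' independently from U(0.95, 1.0).  Seeds R's RNG from `config$seed`
#' (reduced modulo 2^31 - 1), so equal seeds give bit-identical groups.
#'
#' @param config A [sim_config()].
#' @param seed_rng If `FALSE`, leave R's RNG state untouched (used when the
#'   caller manages seeding).
#' @return A list of class `group_state` with elements `config`, `t` (current
#'   period, starting at 0) and `agents` (data frame with `identity`,
#'   `speed`, `omega`, `p`, `d`, `leave_time`, `arrival_time`).
#' @export
init_group <- function(config, seed_rng = TRUE) {
  config <- validate_config(unclass(config))
  if (seed_rng) set.seed(as.integer(config$seed %% 2147483647))
  n <- config$n
  agents <- data.frame(identity = seq_len(n),
                       speed = runif(n, 0.95, 1.0),
                       omega = (seq_len(n) - 1) * config$omega_difference,
                       p = rep(config$p_baseline, n),
                       d = rep(0, n),
                       leave_time = rep(NA_real_, n),
                       arrival_time = rep(NA_real_, n))
  structure(list(config = config, t = 0, agents = agents),
            class = "group_state")
}

#' Advance one individual's outward-movement probability
#'
#' Applies the per-period update `p <- p + omega`, the recursion whose
#' closed form is `p[i, t] = p_baseline + t * omega[i]`.  The probability is
#' deliberately not clamped at 1: the movement draw `u < p` behaves
#' identically either way.
#'
#' @param group A `group_state`.
#' @param i Individual identity (1..n).
#' @return The updated `group_state`.
#' @export
update_probability <- function(group, i) {
  group$agents$p[i] <- group$agents$p[i] + group$agents$omega[i]
  group
}

#' One individual's movement decision
#'
#' Exactly one of: the individual is at the foraging site (`d >= d_food`)
#' and does not move; it is behind the refuge (`d < 0`) and moves outward by
#' its speed; or it is in the open corridor (`0 <= d < d_food`), consumes
#' one uniform draw, moves outward if the draw is below its current
#' probability, and otherwise performs the social action of the configured
#' rule.  First passages of the departure threshold and of `d_food` are
#' recorded at the current period.
#'
#' @inheritParams update_probability
#' @return The updated `group_state`.
#' @export
decide_and_move <- function(group, i) {
  cfg <- group$config
  d <- group$agents$d[i]
  if (d >= cfg$d_food) {
    # absorbed at the foraging site
  } else if (d < 0) {
    group$agents$d[i] <- d + group$agents$speed[i]
  } else if (runif(1) < group$agents$p[i]) {
    group$agents$d[i] <- d + group$agents$speed[i]
  } else {
    group <- switch(cfg$rule,
                    non_social = group,
                    central = social_action_central(group, i),
                    nearest_neighbour = social_action_nearest(group, i),
                    majority = social_action_majority(group, i))
  }
  record_passages(group, i)
}

record_passages <- function(group, i) {
  d <- group$agents$d[i]
  if (is.na(group$agents$leave_time[i]) && d >= group$config$threshold)
    group$agents$leave_time[i] <- group$t
  if (is.na(group$agents$arrival_time[i]) && d >= group$config$d_food)
    group$agents$arrival_time[i] <- group$t
  group
}

#' Social action: move towards the mean position of the others
#'
#' The target is the mean position of the other `n - 1` group members
#' (arrived individuals included).  The focal individual moves its full
#' speed towards — possibly past — the target, and does not move when it
#' already sits exactly on it.
#'
#' @inheritParams update_probability
#' @return The updated `group_state`.
#' @export
social_action_central <- function(group, i) {
  d <- group$agents$d
  target <- mean(d[-i])
  if (target > d[i]) {
    group$agents$d[i] <- d[i] + group$agents$speed[i]
  } else if (target < d[i]) {
    group$agents$d[i] <- d[i] - group$agents$speed[i]
  }
  group
}

#' Social action: move towards the nearest neighbour
#'
#' Nearest is by absolute position difference (exact floating-point
#' comparison); among exactly tied neighbours one is chosen uniformly at
#' random.  If the nearest neighbour occupies the focal position, the focal
#' individual does not move.
#'
#' @inheritParams update_probability
#' @return The updated `group_state`.
#' @export
social_action_nearest <- function(group, i) {
  d <- group$agents$d
  others <- setdiff(seq_along(d), i)
  dist <- abs(d[others] - d[i])
  best <- min(dist)
  if (best == 0) return(group)
  tied <- others[dist == best]
  pick <- if (length(tied) > 1L) tied[sample.int(length(tied), 1L)] else tied
  step <- if (d[pick] > d[i]) group$agents$speed[i] else -group$agents$speed[i]
  group$agents$d[i] <- d[i] + step
  group
}

#' Social action: move with the strict majority
#'
#' Counts colleagues strictly closer to the food and strictly closer to the
#' refuge than the focal individual; co-located colleagues count for neither
#' side.  The focal individual moves its full speed towards the larger
#' count, and does not move on a tie.
#'
#' @inheritParams update_probability
#' @return The updated `group_state`.
#' @export
social_action_majority <- function(group, i) {
  d <- group$agents$d
  ahead <- sum(d[-i] > d[i])
  behind <- sum(d[-i] < d[i])
  if (ahead > behind) {
    group$agents$d[i] <- d[i] + group$agents$speed[i]
  } else if (behind > ahead) {
    group$agents$d[i] <- d[i] - group$agents$speed[i]
  }
  group
}

#' Advance the group by one period
#'
#' Draws a uniformly random activation order over all individuals, then
#' processes them sequentially: probability update followed by the movement
#' decision.  Decisions are acted on immediately, so individuals later in
#' the order see the already-updated positions of earlier movers.
#'
#' @param group A `group_state`.
#' @return The updated `group_state` with `t` incremented by 1.
#' @export
step_group <- function(group) {
  group$t <- group$t + 1
  for (i in sample.int(group$config$n)) {
    group <- update_probability(group, i)
    group <- decide_and_move(group, i)
  }
  group
}

run_simulation_reference <- function(config, record_trajectory = FALSE) {
  group <- init_group(config)
  trajectory <- if (record_trajectory) list(group$agents$d)
  while (any(group$agents$d < config$d_food)) {
    if (group$t >= config$max_steps)
      stop(sprintf(paste("simulation exceeded max_steps = %.0f before all",
                         "individuals reached the foraging site"),
                   config$max_steps))
    group <- step_group(group)
    if (record_trajectory) trajectory[[length(trajectory) + 1L]] <- group$agents$d
  }
  focal <- sample.int(config$n, 1L)
  new_event_log(config, "reference",
                speed = group$agents$speed,
                leave = group$agents$leave_time,
                arrival = group$agents$arrival_time,
                end_time = group$t, focal = focal,
                trajectory = if (record_trajectory)
                  do.call(rbind, trajectory))
}
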
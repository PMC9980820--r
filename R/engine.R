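#' Run one simulation
#'
#' Steps the group from the refuge until every individual is inside the
#' foraging site at the end of a period, and records first-passage event
#' times online (no trajectory storage is needed unless requested).
#'
#' Two engines implement identical model semantics: `"compiled"` (the fast
#' C++ engine with its own per-run xoshiro256++ stream, used by all sweep
#' protocols) and `"reference"` (the step-by-step pure-R engine built from
#' [init_group()] and [step_group()], driven by R's RNG).  The two engines
#' draw from different random streams, so for a given seed they produce
#' different — but identically distributed — trajectories; each engine is
#' individually bit-reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param engine `"compiled"` or `"reference"`.
#' @param record_trajectory If `TRUE`, also return the full matrix of
#'   per-period positions (periods in rows, individuals in columns, period 0
#'   first).  Only sensible for small runs.
#' @return An object of class `event_log`: a list with `agents` (data frame
#'   with `identity`, `speed`, `omega`, `leave_time`, `arrival_time`,
#'   `travel_time`), `end_time`, `focal_identity` (chosen uniformly from the
#'   run's own stream), `config`, `engine`, and optionally `trajectory`.
#' @examples
#' log <- run_simulation(sim_config(d_food = 20, p_baseline = 0.05, seed = 7))
#' log$end_time
#' @export
run_simulation <- function(config, engine = c("compiled", "reference"),
                           record_trajectory = FALSE) {
  config <- validate_config(unclass(config))
  engine <- match.arg(engine)
  if (engine == "reference") {
    return(run_simulation_reference(config, record_trajectory))
  }
  res <- cpp_run_one(config$n, config$p_baseline, config$omega_difference,
                     config$d_food, config$threshold, config$max_steps,
                     .rule_id[[config$rule]], config$seed, record_trajectory)
  new_event_log(config, engine,
                speed = res$speed, leave = res$leave_time,
                arrival = res$arrival_time, end_time = res$end_time,
                focal = res$focal, trajectory = res$trajectory)
}

new_event_log <- function(config, engine, speed, leave, arrival, end_time,
                          focal, trajectory = NULL) {
  agents <- data.frame(identity = seq_len(config$n),
                       speed = speed,
                       omega = (seq_len(config$n) - 1) * config$omega_difference,
                       leave_time = leave,
                       arrival_time = arrival,
                       travel_time = arrival - leave)
  out <- list(agents = agents, end_time = end_time, focal_identity = focal,
              config = config, engine = engine)
  if (!is.null(trajectory)) out$trajectory <- trajectory
  structure(out, class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> rule: %s  n: %d  engine: %s\n",
              x$config$rule, x$config$n, x$engine))
  cat(sprintf("  end_time: %.0f  focal: %d\n", x$end_time, x$focal_identity))
  print(x$agents, row.names = FALSE)
  invisible(x)
}
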
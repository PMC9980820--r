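#' First-passage time of a trajectory past a boundary
#'
#' Smallest period `t` at which the position is at or beyond `boundary`.
#' The trajectory starts at period 0; a boundary of 0 is therefore passed
#' at `t = 0`.  Later backward moves across the boundary never reset the
#' first passage.
#'
#' @param trajectory Numeric vector of positions, one per period, starting
#'   at period 0.
#' @param boundary Distance from the refuge.
#' @return Integer period of first passage.
#' @examples
#' first_passage(c(0, 0.97, 1.94, 2.91), 1.5)
#' @export
first_passage <- function(trajectory, boundary) {
  hit <- which(trajectory >= boundary)
  if (!length(hit))
    stop("trajectory never reaches the boundary ", boundary)
  hit[1L] - 1L
}

#' Per-run focal statistics
#'
#' The six per-run statistics harvested from one randomly chosen focal
#' individual: its identity, departure (leave) time, departure latency,
#' arrival time, arrival latency, travel time, and the group's end time.
#' Latencies are measured against the first individual in the group to pass
#' the corresponding boundary; a focal individual that is itself first has
#' latency zero.
#'
#' @param log An `event_log` from [run_simulation()].
#' @param focal_identity Identity of the focal individual.  Defaults to the
#'   uniform choice already made by the run's own random stream
#'   (`log$focal_identity`); pass `NA` to draw a fresh choice from R's RNG.
#' @return One-row data frame with columns `focal_identity`, `leave_time`,
#'   `leave_latency`, `arrival_time`, `arrival_latency`, `travel_time`,
#'   `end_time`.
#' @export
summarize_focal <- function(log, focal_identity = log$focal_identity) {
  if (is.na(focal_identity))
    focal_identity <- sample.int(nrow(log$agents), 1L)
  a <- log$agents
  f <- a[a$identity == focal_identity, ]
  data.frame(focal_identity = focal_identity,
             leave_time = f$leave_time,
             leave_latency = f$leave_time - min(a$leave_time),
             arrival_time = f$arrival_time,
             arrival_latency = f$arrival_time - min(a$arrival_time),
             travel_time = f$travel_time,
             end_time = log$end_time)
}

#' Event times for every individual in a run
#'
#' @param log An `event_log` from [run_simulation()].
#' @return Data frame with one row per individual: `identity`, `speed`,
#'   `leave_time`, `arrival_time`, `travel_time`, `end_time`.
#' @export
full_group_times <- function(log) {
  cbind(log$agents[, c("identity", "speed", "leave_time", "arrival_time",
                       "travel_time")],
        end_time = log$end_time)
}
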
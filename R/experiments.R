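#' Deterministic child-seed derivation
#'
#' Hashes the tuple (master seed, rule, value index, replicate index)
#' through a splitmix64 chain and folds the result to 53 bits, giving a
#' platform-stable per-run seed.  Every run of a sweep gets its seed from
#' its indices, never from execution order, so sweeps are reproducible and
#' trivially parallelisable; changing any tuple component (including only
#' the rule) changes the seed, so the rules are statistically independent
#' arms.
#'
#' @param master_seed Master seed of the sweep (non-negative, < 2^53).
#' @param rule Rule name (see [sim_config()]) or stable integer id.
#' @param value_index 1-based index of the grid value within the design.
#' @param replicate_index 1-based replicate index.
#' @return Numeric vector of derived seeds (exact 53-bit integers).
#' @examples
#' derive_seed(1, "central", 3, 1:4)
#' @export
derive_seed <- function(master_seed, rule, value_index, replicate_index) {
  rule_id <- if (is.character(rule)) {
    if (any(!rule %in% .rules))
      stop_config("rule: must be one of %s", paste(.rules, collapse = ", "))
    .rule_id[rule]
  } else as.integer(rule)
  m <- max(length(rule_id), length(value_index), length(replicate_index))
  cpp_derive_seed(master_seed,
                  rep_len(as.integer(rule_id), m),
                  rep_len(as.integer(value_index), m),
                  rep_len(as.integer(replicate_index), m))
}

#' Define a single-parameter sweep
#'
#' A sweep varies one model parameter over a grid while the others stay at
#' their baseline values, and runs `replicates` independent simulations per
#' (rule, grid value) cell with deterministically derived seeds.
#'
#' @param parameter Parameter to sweep: `"omega_difference"`,
#'   `"p_baseline"`, `"d_food"` or `"n"`.
#' @param grid Grid of values; defaults to [default_sweep_grid()] for the
#'   chosen parameter.
#' @param replicates Simulations per (rule, value) cell.
#' @param rules Character vector of interaction rules to run as independent
#'   arms.
#' @param protocol `"focal"` records the six per-run focal statistics (one
#'   row per run); `"full_group"` records event times of every individual
#'   (n rows per run), the input of the variation analyses.
#' @param master_seed Master seed from which all run seeds are derived.
#' @param baseline Named list overriding baseline values of the non-swept
#'   parameters (e.g. `list(d_food = 30)`).
#' @param max_steps Per-run period cap.  The sweep default is 1e8 (well
#'   above the slowest cells of the standard grids, e.g. non-social runs at
#'   `p_baseline = 0.0001` average ~1e6 periods).
#' @param run_cap Guard: designs scheduling more than this many runs error
#'   out instead of silently consuming hours.
#' @return A list of class `sweep_design`.
#' @export
sweep_design <- function(parameter = c("omega_difference", "p_baseline",
                                       "d_food", "n"),
                         grid = NULL, replicates = 200,
                         rules = .rules,
                         protocol = c("focal", "full_group"),
                         master_seed = 1, baseline = list(),
                         max_steps = 1e8, run_cap = 2e6) {
  if (length(parameter) > 1) parameter <- parameter[1]
  if (length(protocol) > 1) protocol <- protocol[1]
  if (!parameter %in% c("omega_difference", "p_baseline", "d_food", "n"))
    stop_config("parameter: must be one of omega_difference, p_baseline, d_food, n")
  if (!protocol %in% c("focal", "full_group"))
    stop_config("protocol: must be 'focal' or 'full_group'")
  if (is.null(grid)) grid <- default_sweep_grid(parameter)
  if (!is.numeric(grid) || !length(grid) || anyNA(grid))
    stop_config("grid: must be a non-empty numeric vector")
  if (!all(rules %in% .rules))
    stop_config("rules: must be a subset of %s", paste(.rules, collapse = ", "))
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    stop_config("replicates: must be a positive integer")
  if (!is.list(baseline) ||
      (length(baseline) && is.null(names(baseline))))
    stop_config("baseline: must be a named list of sim_config fields")
  bad <- setdiff(names(baseline), names(formals(sim_config)))
  if (length(bad))
    stop_config("baseline: unknown field(s) %s", paste(bad, collapse = ", "))
  n_runs <- length(rules) * length(grid) * replicates
  if (n_runs > run_cap)
    stop_config("design schedules %d runs, above run_cap = %d",
                n_runs, as.integer(run_cap))
  # validate every cell configuration up front
  for (value in grid) {
    for (rule in rules) cell_config(parameter, value, rule, baseline, max_steps)
  }
  structure(list(parameter = parameter, grid = grid,
                 replicates = as.integer(replicates), rules = rules,
                 protocol = protocol, master_seed = master_seed,
                 baseline = baseline, max_steps = max_steps),
            class = "sweep_design")
}

cell_config <- function(parameter, value, rule, baseline, max_steps,
                        seed = 0) {
  args <- modifyList(list(rule = rule, max_steps = max_steps, seed = seed),
                     baseline)
  args[[parameter]] <- value
  do.call(sim_config, args)
}

#' @export
print.sweep_design <- function(x, ...) {
  cat("<sweep_design>\n")
  cat(sprintf("  parameter: %s  (%d values: %s ... %s)\n", x$parameter,
              length(x$grid), format(min(x$grid)), format(max(x$grid))))
  cat(sprintf("  rules: %s\n", paste(x$rules, collapse = ", ")))
  cat(sprintf("  protocol: %s   replicates/cell: %d   master_seed: %.0f\n",
              x$protocol, x$replicates, x$master_seed))
  invisible(x)
}

#' Run a sweep
#'
#' Executes every (rule, grid value, replicate) cell of the design with the
#' compiled engine and returns one tidy long-format data frame.  Re-running
#' the same design gives a bit-identical result.
#'
#' @param design A [sweep_design()].
#' @param verbose If `TRUE`, report cell progress on stderr.
#' @return For the `"focal"` protocol, one row per run with columns `rule`,
#'   `parameter`, `value`, `replicate`, `seed`, `focal_identity`,
#'   `leave_time`, `leave_latency`, `arrival_time`, `arrival_latency`,
#'   `travel_time`, `end_time`.  For `"full_group"`, one row per individual
#'   per run with `identity`, `speed`, `leave_time`, `arrival_time`,
#'   `travel_time`, `end_time` instead of the focal columns.
#' @export
run_sweep <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "sweep_design"))
  reps <- design$replicates
  cells <- vector("list", length(design$rules) * length(design$grid))
  k <- 0L
  for (rule in design$rules) {
    for (vi in seq_along(design$grid)) {
      value <- design$grid[vi]
      cfg <- cell_config(design$parameter, value, rule, design$baseline,
                         design$max_steps)
      seeds <- derive_seed(design$master_seed, rule, vi, seq_len(reps))
      batch <- cpp_run_batch(cfg$n, cfg$p_baseline, cfg$omega_difference,
                             cfg$d_food, cfg$threshold, cfg$max_steps,
                             .rule_id[[rule]], seeds)
      k <- k + 1L
      cells[[k]] <- if (design$protocol == "focal") {
        cell_focal_rows(design, rule, value, seeds, batch)
      } else {
        cell_full_rows(design, rule, value, seeds, batch, cfg$n)
      }
      if (verbose)
        message(sprintf("[foragesim] %s %s=%g done (%d/%d cells)",
                        rule, design$parameter, value, k, length(cells)))
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

cell_focal_rows <- function(design, rule, value, seeds, batch) {
  reps <- length(seeds)
  focal <- batch$focal
  idx <- cbind(seq_len(reps), focal)
  leave <- batch$leave_time[idx]
  arrival <- batch$arrival_time[idx]
  data.frame(rule = rule, parameter = design$parameter, value = value,
             replicate = seq_len(reps), seed = seeds,
             focal_identity = focal,
             leave_time = leave,
             leave_latency = leave - apply(batch$leave_time, 1L, min),
             arrival_time = arrival,
             arrival_latency = arrival - apply(batch$arrival_time, 1L, min),
             travel_time = arrival - leave,
             end_time = batch$end_time)
}

cell_full_rows <- function(design, rule, value, seeds, batch, n) {
  reps <- length(seeds)
  data.frame(rule = rule, parameter = design$parameter, value = value,
             replicate = rep(seq_len(reps), each = n),
             seed = rep(seeds, each = n),
             identity = rep(seq_len(n), times = reps),
             speed = as.vector(t(batch$speed)),
             leave_time = as.vector(t(batch$leave_time)),
             arrival_time = as.vector(t(batch$arrival_time)),
             travel_time = as.vector(t(batch$arrival_time - batch$leave_time)),
             end_time = rep(batch$end_time, each = n))
}
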
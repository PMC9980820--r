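#' @keywords internal
.rules <- c("non_social", "central", "nearest_neighbour", "majority")

# Stable rule ids used in seed derivation; independent of the order in which
# rules are listed in a design, so every rule is its own statistical arm.
.rule_id <- c(non_social = 0L, central = 1L, nearest_neighbour = 2L,
              majority = 3L)

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("foragesim_config_error", "error")))
}

#' Simulation configuration
#'
#' Bundle and validate the parameters of one simulation run.  Defaults are
#' the baseline condition of the study design: a group of `n = 10`
#' individuals, `p_baseline = 0.001`, `omega_difference = 0.001`, a foraging
#' site `d_food = 100` distance units away, and a departure threshold of 10
#' units.
#'
#' @param n Number of individuals (>= 1; social rules need >= 2, because the
#'   centroid of "the others" is undefined for a singleton group).
#' @param p_baseline Baseline per-period probability of moving outward, in
#'   (0, 1].
#' @param omega_difference Increment of the personal outward probability
#'   adjustment between successive identities (>= 0); individual `i` gets
#'   `omega = (i - 1) * omega_difference`.
#' @param d_food Distance from the refuge to the foraging site (> 0).
#' @param rule Social interaction rule: one of `"non_social"`, `"central"`,
#'   `"nearest_neighbour"`, `"majority"`.
#' @param threshold Departure threshold distance (0 < threshold < d_food).
#'   An individual "leaves" at its first passage of this boundary.
#' @param seed Seed of the run's random stream (non-negative, < 2^53).
#' @param max_steps Safety cap on the number of periods; exceeding it raises
#'   an error rather than looping forever.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(rule = "central", seed = 1)
#' cfg$omega_difference
#' @export
sim_config <- function(n = 10, p_baseline = 0.001, omega_difference = 0.001,
                       d_food = 100, rule = "non_social", threshold = 10,
                       seed = 1, max_steps = 1e6) {
  cfg <- list(n = n, p_baseline = p_baseline,
              omega_difference = omega_difference, d_food = d_food,
              rule = rule, threshold = threshold, seed = seed,
              max_steps = max_steps)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n) || cfg$n < 1 || cfg$n != as.integer(cfg$n))
    stop_config("n: must be a single positive integer, got %s",
                deparse(cfg$n))
  if (!is.character(cfg$rule) || length(cfg$rule) != 1L ||
      !cfg$rule %in% .rules)
    stop_config("rule: must be one of %s", paste(.rules, collapse = ", "))
  if (cfg$rule != "non_social" && cfg$n < 2)
    stop_config("n: social rule '%s' needs at least 2 individuals", cfg$rule)
  if (!num1(cfg$p_baseline) || cfg$p_baseline <= 0 || cfg$p_baseline > 1)
    stop_config("p_baseline: must lie in (0, 1], got %s",
                deparse(cfg$p_baseline))
  if (!num1(cfg$omega_difference) || cfg$omega_difference < 0)
    stop_config("omega_difference: must be >= 0, got %s",
                deparse(cfg$omega_difference))
  if (!num1(cfg$d_food) || cfg$d_food <= 0)
    stop_config("d_food: must be > 0, got %s", deparse(cfg$d_food))
  if (!num1(cfg$threshold) || cfg$threshold <= 0 ||
      cfg$threshold >= cfg$d_food)
    stop_config("threshold: must satisfy 0 < threshold < d_food, got %s",
                deparse(cfg$threshold))
  if (!num1(cfg$seed) || cfg$seed < 0 || cfg$seed >= 2^53)
    stop_config("seed: must be a non-negative number below 2^53, got %s",
                deparse(cfg$seed))
  if (!num1(cfg$max_steps) || cfg$max_steps < 1)
    stop_config("max_steps: must be >= 1, got %s", deparse(cfg$max_steps))
  cfg$n <- as.integer(cfg$n)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  rule: %s   n: %d\n", x$rule, x$n))
  cat(sprintf("  p_baseline: %g   omega_difference: %g\n",
              x$p_baseline, x$omega_difference))
  cat(sprintf("  d_food: %g   threshold: %g\n", x$d_food, x$threshold))
  cat(sprintf("  seed: %.0f   max_steps: %.0f\n", x$seed, x$max_steps))
  invisible(x)
}

#' Standard single-parameter exploration grids
#'
#' The grids used by the package's sweep protocols when one model parameter
#' is varied away from the baseline configuration:
#' `p_baseline` and `omega_difference` over `0.0001, 0.0002, ..., 0.0020`,
#' `d_food` over `20, 30, ..., 200` units, and `n` over `5, 10, ..., 50`.
#'
#' @param parameter One of `"omega_difference"`, `"p_baseline"`, `"d_food"`,
#'   `"n"`.
#' @return Numeric vector of grid values.
#' @export
default_sweep_grid <- function(parameter = c("omega_difference", "p_baseline",
                                             "d_food", "n")) {
  parameter <- match.arg(parameter)
  switch(parameter,
         omega_difference = seq(0.0001, 0.0020, by = 0.0001),
         p_baseline = seq(0.0001, 0.0020, by = 0.0001),
         d_food = seq(20, 200, by = 10),
         n = seq(5L, 50L, by = 5L))
}

#' Read a simulation or sweep configuration from a YAML or JSON file
#'
#' Missing fields are filled with the baseline defaults of [sim_config()]
#' (or [sweep_design()] when the file contains a `parameter` field, which
#' marks it as a sweep design).  Unknown keys are rejected with the
#' offending field names.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` or `sweep_design` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("rule: central", f)
#' load_config(f)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop_config("config file must end in .yaml, .yml or .json: %s", path)
  }
  if (!is.list(raw)) stop_config("config file must contain a mapping: %s", path)
  if (!is.null(raw$parameter)) {
    known <- names(formals(sweep_design))
    bad <- setdiff(names(raw), known)
    if (length(bad))
      stop_config("unknown sweep design field(s): %s",
                  paste(bad, collapse = ", "))
    return(do.call(sweep_design, raw))
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(sim_config, raw)
}
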
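#' Min-max rescale event times within one group
#'
#' Maps the fastest individual of the group to 0 and the slowest to 1:
#' `(x - min) / (max - min)`.  When all values are equal the group carries
#' no ordering information and the convention is to return all zeros.
#'
#' @param x Numeric vector of raw event times for one run and one measure.
#' @return Rescaled values in \[0, 1\].
#' @examples
#' rescale_within_group(c(5, 10, 15))
#' @export
rescale_within_group <- function(x) {
  r <- x - min(x)
  m <- max(r)
  if (m == 0) r else r / m
}

#' Add within-run rescaled time columns to a full-group sweep table
#'
#' For each run (a `(rule, value, replicate)` cell row group) and each
#' measure, applies [rescale_within_group()] across the run's individuals
#' and stores the result in a `rescaled_<measure>` column.
#'
#' @param results Full-group table from [run_sweep()].
#' @param measures Measure columns to rescale.
#' @return `results` with the additional `rescaled_*` columns.
#' @export
rescale_sweep <- function(results,
                          measures = c("travel_time", "leave_time",
                                       "arrival_time")) {
  stopifnot(all(c("rule", "value", "replicate", measures) %in%
                  names(results)))
  run <- interaction(results$rule, results$value, results$replicate,
                     drop = TRUE)
  for (m in measures) {
    results[[paste0("rescaled_", m)]] <-
      stats::ave(results[[m]], run, FUN = rescale_within_group)
  }
  results
}

#' One-way ANOVA F for a swept parameter
#'
#' Classical between/within variance ratio with the swept parameter treated
#' as a categorical factor: `F = MS_between / MS_within`, fitted with
#' [stats::lm()].  Used on per-run measures (e.g. focal statistics) to ask
#' how much of the variation a systematically altered parameter explains
#' relative to replicate noise.  A response with zero within-level variance
#' but distinct level means yields `Inf`.
#'
#' @param data Data frame of per-run measures.
#' @param response Name of the response column.
#' @param factor_col Name of the column holding the swept parameter value.
#' @return List of class `oneway_anova` with elements `F`, `df` (numerator,
#'   denominator), `ms_between`, `ms_within`.
#' @export
oneway_anova_f <- function(data, response, factor_col = "value") {
  g <- factor(data[[factor_col]])
  y <- data[[response]]
  if (nlevels(g) < 2)
    stop("oneway_anova_f needs at least 2 factor levels")
  if (min(table(g)) < 2)
    stop("oneway_anova_f needs at least 2 observations per level")
  tab <- suppressWarnings(anova(lm(y ~ g))) # warns on exact fits
  ms <- tab[["Mean Sq"]]
  # a residual mean square that is zero to numerical precision diverges
  f <- if (ms[1] > 0 && ms[2] <= 1e-12 * ms[1]) Inf else ms[1] / ms[2]
  structure(list(F = f, df = tab$Df, ms_between = ms[1], ms_within = ms[2],
                 response = response),
            class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %s\n", x$response,
              x$df[1], x$df[2], format(x$F, digits = 5)))
  invisible(x)
}

#' Repeated-measures ANOVA on within-run rescaled times
#'
#' Partitions the variance of rescaled per-individual event times into a
#' swept-parameter effect and an individual-identity effect, with the run
#' as the repeated-measures grouping unit.  The parameter (between-run
#' factor) is tested against the run-to-run stratum — runs nested in
#' parameter levels — and identity (within-run factor) against the
#' within-run residual:
#' \deqn{F_{param} = MS_{param} / MS_{run(level)}, \quad
#'       F_{ident} = MS_{ident} / MS_{within-run\ residual}.}
#' Larger identity F means individuals are easier to tell apart across
#' runs; larger parameter F means more of the variation lies between
#' parameter levels than between replicate runs.
#'
#' The design must be balanced (every run contributes every identity, every
#' level the same number of runs); the sums of squares are then orthogonal
#' and are computed in closed form from group means, which stays fast for
#' designs with thousands of runs where a dummy-coded run factor would be
#' impractical.  On small tables the result matches
#' `aov(y ~ level + identity + Error(run))`.
#'
#' @param data Data frame with one row per individual per run.
#' @param response Name of the (rescaled) response column.
#' @param value_col,replicate_col,identity_col Columns identifying the
#'   parameter level, the replicate run within a level, and the individual.
#' @return List of class `rm_anova` with `parameter_F`, `individual_F` and
#'   a `table` of df / sums of squares / mean squares per stratum.
#' @export
repeated_measures_anova <- function(data, response, value_col = "value",
                                    replicate_col = "replicate",
                                    identity_col = "identity") {
  y <- data[[response]]
  lev <- factor(data[[value_col]])
  run <- interaction(data[[value_col]], data[[replicate_col]], drop = TRUE)
  id <- factor(data[[identity_col]])
  L <- nlevels(lev); n_id <- nlevels(id); n_run <- nlevels(run)
  if (L < 2) stop("repeated_measures_anova needs at least 2 parameter levels")
  counts <- table(run, id)
  if (any(counts != 1))
    stop("unbalanced table: every run must contribute every identity exactly once")
  run_lev <- tapply(as.integer(lev), run, `[`, 1L) # level index of each run
  runs_per_level <- table(run_lev)
  if (length(runs_per_level) != L ||
      length(unique(as.vector(runs_per_level))) != 1)
    stop("unbalanced table: every level must have the same number of runs")
  R <- as.vector(runs_per_level)[1]

  grand <- mean(y)
  lev_mean <- tapply(y, lev, mean)
  run_mean <- tapply(y, run, mean)
  id_mean <- tapply(y, id, mean)

  ss_param <- R * n_id * sum((lev_mean - grand)^2)
  ss_run <- n_id * sum((run_mean - lev_mean[run_lev])^2)
  ss_ident <- n_run * sum((id_mean - grand)^2)
  ss_within <- sum((y - run_mean[run])^2)
  ss_resid <- ss_within - ss_ident

  df_param <- L - 1
  df_run <- L * (R - 1)
  df_ident <- n_id - 1
  df_resid <- n_run * (n_id - 1) - df_ident

  # degenerate strata: no effect variance -> 0; no error variance -> Inf
  ratio <- function(ms1, ms2) {
    if (ms1 == 0) 0 else if (ms2 == 0) Inf else ms1 / ms2
  }
  ms_param <- ss_param / df_param
  ms_run <- ss_run / df_run
  ms_ident <- ss_ident / df_ident
  ms_resid <- ss_resid / df_resid

  tab <- data.frame(
    term = c("parameter", "run(parameter)", "identity", "residual"),
    df = c(df_param, df_run, df_ident, df_resid),
    ss = c(ss_param, ss_run, ss_ident, ss_resid),
    ms = c(ms_param, ms_run, ms_ident, ms_resid))
  structure(list(parameter_F = ratio(ms_param, ms_run),
                 individual_F = ratio(ms_ident, ms_resid),
                 table = tab, response = response),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s\n", x$response))
  cat(sprintf("  parameter F  = %s (df %d, %d)\n",
              format(x$parameter_F, digits = 5),
              x$table$df[1], x$table$df[2]))
  cat(sprintf("  individual F = %s (df %d, %d)\n",
              format(x$individual_F, digits = 5),
              x$table$df[3], x$table$df[4]))
  invisible(x)
}

#' Paired social-minus-non-social ordering difference
#'
#' For every individual of every paired replicate, the difference between
#' its within-run rescaled time under a social rule and under the
#' non-social rule, bounded in \[-1, 1\]: -1 means the individual took the
#' minimum time socially and the maximum time non-socially, 0 means its
#' position in the group ordering is unchanged, +1 the reverse extreme.
#' Replicate `r` of the social arm is paired with replicate `r` of the
#' non-social arm at the same grid value.
#'
#' @param results Full-group sweep table containing both the social rule
#'   and the `non_social` arm, already passed through [rescale_sweep()].
#' @param rule The social rule to compare against `non_social`.
#' @param measures Measures (raw column names) whose `rescaled_*` columns
#'   are differenced.
#' @return Long data frame with columns `rule`, `measure`, `value`,
#'   `replicate`, `identity`, `difference`.
#' @export
social_difference <- function(results, rule,
                              measures = c("travel_time", "leave_time",
                                           "arrival_time")) {
  if (rule == "non_social")
    stop("rule must be one of the social rules")
  cols <- paste0("rescaled_", measures)
  stopifnot(all(cols %in% names(results)))
  keys <- c("value", "replicate", "identity")
  soc <- results[results$rule == rule, c(keys, cols)]
  ns <- results[results$rule == "non_social", c(keys, cols)]
  if (!nrow(soc) || !nrow(ns))
    stop("results must contain both the '", rule, "' and 'non_social' arms")
  merged <- merge(soc, ns, by = keys, suffixes = c(".social", ".nonsocial"))
  if (nrow(merged) != nrow(soc) || nrow(merged) != nrow(ns))
    stop("unpaired inputs: social and non_social arms do not share ",
         "identical (value, replicate, identity) cells")
  out <- do.call(rbind, lapply(seq_along(measures), function(k) {
    data.frame(rule = rule, measure = measures[k],
               value = merged$value, replicate = merged$replicate,
               identity = merged$identity,
               difference = merged[[paste0(cols[k], ".social")]] -
                 merged[[paste0(cols[k], ".nonsocial")]])
  }))
  rownames(out) <- NULL
  out
}

#' Cell means and standard deviations of sweep measures
#'
#' @param results A sweep table from [run_sweep()].
#' @param measures Measure columns to summarise.
#' @return Long data frame with columns `rule`, `value`, `measure`, `mean`,
#'   `sd`, `n_runs`.
#' @export
summarize_cells <- function(results,
                            measures = c("end_time", "travel_time",
                                         "leave_time", "leave_latency",
                                         "arrival_time", "arrival_latency")) {
  measures <- intersect(measures, names(results))
  out <- do.call(rbind, lapply(measures, function(m) {
    agg <- aggregate(results[[m]],
                     by = list(rule = results$rule, value = results$value),
                     FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                         n = length(v)))
    data.frame(rule = agg$rule, value = agg$value, measure = m,
               mean = agg$x[, "mean"], sd = agg$x[, "sd"],
               n_runs = agg$x[, "n"])
  }))
  rownames(out) <- NULL
  out
}
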
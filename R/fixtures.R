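#' Generate the bundled micro-sweep fixture
#'
#' A small deterministic full-group sweep (omega_difference over
#' `{0.0005, 0.001, 0.002}`, 8 replicates, all four rules, `n = 5`,
#' `d_food = 30`) used by the analysis-layer tests and examples.  The file
#' is written with fixed number formatting, so regenerating it with the
#' same seed reproduces the committed copy byte for byte.  The copy shipped
#' with the package is at
#' `system.file("extdata", "microsweep.csv", package = "foragesim")`.
#'
#' @param path Output CSV path.
#' @param master_seed Master seed of the micro-sweep.
#' @return The path, invisibly.
#' @export
generate_fixtures <- function(path, master_seed = 20230302) {
  design <- sweep_design(parameter = "omega_difference",
                         grid = c(0.0005, 0.001, 0.002),
                         replicates = 8, rules = .rules,
                         protocol = "full_group",
                         master_seed = master_seed,
                         baseline = list(n = 5, d_food = 30))
  res <- run_sweep(design)
  fmt <- res
  fmt$value <- sprintf("%g", res$value)
  fmt$seed <- sprintf("%.0f", res$seed)
  fmt$speed <- sprintf("%.17g", res$speed)
  for (m in c("leave_time", "arrival_time", "travel_time", "end_time"))
    fmt[[m]] <- sprintf("%.0f", res[[m]])
  con <- file(path, open = "wb") # fixed LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(fmt), collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(fmt)), sep = ",")), con)
  invisible(path)
}
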
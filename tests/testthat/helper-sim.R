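# Small-scale configs and hand-built group states used by the engine tests.

quick_config <- function(...) {
  args <- modifyList(list(d_food = 20, p_baseline = 0.02, seed = 1), list(...))
  do.call(sim_config, args)
}

# A group_state with positions (and optionally speeds/probabilities) pinned,
# for deterministic tests of individual model operations.
make_group <- function(d, rule = if (length(d) > 1) "central" else
                         "non_social",
                       speed = 0.97, p = 0.5,
                       d_food = 100, threshold = 10, t = 1) {
  cfg <- sim_config(n = length(d), rule = rule, d_food = d_food,
                    threshold = threshold, seed = 1)
  g <- init_group(cfg, seed_rng = FALSE) # leave the ambient RNG stream alone
  g$agents$d <- d
  g$agents$speed <- rep_len(speed, length(d))
  g$agents$p <- rep_len(p, length(d))
  g$t <- t
  g
}
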
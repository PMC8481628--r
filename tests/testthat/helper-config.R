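# small configurations reused across tests
quick_cfg <- function(n_runs = 20, seed = 1, ...) {
  sim_config(n_runs = n_runs, seed = seed, ...)
}

# defaults of the standard condition, used by several oracles
DEFAULT_GAMMA <- 0.85
DEFAULT_COST <- 0.1
DEFAULT_FEATURES <- c(0.52200625, 0.614125, 0.7225, 0.85, 1)
W_STAR <- 1 - 0.1 * sum(0.85^(1:4))  # 0.729136875
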
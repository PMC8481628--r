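#' Build a simulation configuration
#'
#' Bundles every tunable of the simulator with the standard defaults: a
#' 5-state chain with goal reward 1 and GO cost 0.1, discount factor 0.85,
#' inverse temperature 20, the decreasing learning-rate schedule
#' `a = 0.5 / (1 + 0.2 m)`, 20 forced-GO school-term episodes followed by 20
#' free-choice vacation episodes, and 10,000 independent runs.
#'
#' @param chain A [task_chain()].
#' @param gamma Discount factor in (0, 1).
#' @param beta Softmax inverse temperature (>= 0).
#' @param lr_mode `"scheduled"` (`0.5 / (1 + 0.2 m)`, with the episode index
#'   `m` restarting at 1 when the vacation begins) or `"constant"`.
#' @param lr_constant Learning-rate value used when `lr_mode = "constant"`.
#' @param school_episodes Number of forced-GO episodes.
#' @param vacation_episodes Number of free-choice episodes.
#' @param n_runs Number of independent simulation runs in an ensemble.
#' @param seed Master seed; per-run substreams are derived from it (see
#'   [run_seeds()]).
#' @param variant A [variant_config()].
#' @param max_steps_per_episode Safety cap on vacation episode length;
#'   episodes hitting it are truncated and flagged, never an error.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_runs = 100, seed = 1)
#' @export
sim_config <- function(chain = task_chain(),
                       gamma = 0.85,
                       beta = 20,
                       lr_mode = c("scheduled", "constant"),
                       lr_constant = 0.2,
                       school_episodes = 20,
                       vacation_episodes = 20,
                       n_runs = 10000,
                       seed = 1,
                       variant = variant_config("none"),
                       max_steps_per_episode = 10000) {
  lr_mode <- match.arg(lr_mode)
  stopifnot(
    inherits(chain, "task_chain"),
    inherits(variant, "variant_config"),
    gamma > 0, gamma < 1,
    beta >= 0,
    lr_constant > 0,
    school_episodes >= 1, vacation_episodes >= 0,
    n_runs >= 1,
    max_steps_per_episode >= 1,
    is.numeric(seed), length(seed) == 1L
  )
  structure(list(chain = chain, gamma = gamma, beta = beta,
                 lr_mode = lr_mode, lr_constant = lr_constant,
                 school_episodes = as.integer(school_episodes),
                 vacation_episodes = as.integer(vacation_episodes),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 variant = variant,
                 max_steps_per_episode = as.integer(max_steps_per_episode)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d states, reward %g, cost %g, gamma %g, beta %g\n",
           "  lr: %s%s; episodes: %d school + %d vacation; runs: %d; ",
           "seed: %d; variant: %s\n"),
    x$chain$n, x$chain$reward, x$chain$cost, x$gamma, x$beta,
    x$lr_mode,
    if (x$lr_mode == "constant") sprintf(" (%g)", x$lr_constant) else "",
    x$school_episodes, x$vacation_episodes, x$n_runs, x$seed,
    x$variant$type))
  invisible(x)
}

#' Named experiment presets
#'
#' Shorthand configurations for the standard experimental conditions:
#' `"base"` (all defaults), `"gamma095"` (cost 0.05 with gamma 0.95, the
#' mild-discounting condition), `"low-cost"` (cost 0.05), `"lr-const-0.2"` /
#' `"lr-const-0.4"` (constant learning rates), `"beta10"` / `"beta30"`
#' (alternative inverse temperatures), and the `"penalty"`, `"regret"` and
#' `"sr-update"` variants. `"cost-sweep"` is recognised by the command-line
#' interface, which expands it into a sweep over
#' cost = 0, 0.01, ..., 0.15 (see [parameter_sweep()]).
#'
#' @param preset Preset name.
#' @param ... Overrides passed on to [sim_config()] (e.g. `n_runs`, `seed`).
#' @return A `sim_config`.
#' @examples
#' preset_config("penalty", n_runs = 100, seed = 7)
#' @export
preset_config <- function(preset = "base", ...) {
  presets <- c("base", "cost-sweep", "gamma095", "low-cost",
               "lr-const-0.2", "lr-const-0.4", "beta10", "beta30",
               "penalty", "regret", "sr-update")
  preset <- match.arg(preset, presets)
  args <- switch(preset,
    "base" = ,
    "cost-sweep" = list(),
    "low-cost" = list(chain = task_chain(cost = 0.05)),
    "gamma095" = list(chain = task_chain(cost = 0.05), gamma = 0.95),
    "lr-const-0.2" = list(lr_mode = "constant", lr_constant = 0.2),
    "lr-const-0.4" = list(lr_mode = "constant", lr_constant = 0.4),
    "beta10" = list(beta = 10),
    "beta30" = list(beta = 30),
    "penalty" = list(variant = variant_config("penalty")),
    "regret" = list(variant = variant_config("regret")),
    "sr-update" = list(variant = variant_config("sr_update"))
  )
  do.call(sim_config, modifyList(args, list(...)))
}

#' Per-run seed substreams
#'
#' Derives one `set.seed()` value per run from the master seed by an
#' injective affine map on the integers modulo the Mersenne prime 2^31 - 1.
#' The mapping is counter-based: run `i` always receives the same seed for a
#' given master seed, so enlarging `n_runs` leaves earlier runs unchanged,
#' and distinct runs always receive distinct seeds.
#'
#' @param master_seed Master seed (integer).
#' @param n_runs Number of runs.
#' @return Integer vector of length `n_runs`.
#' @export
run_seeds <- function(master_seed, n_runs) {
  m <- 2147483647            # 2^31 - 1, prime
  s <- as.double(master_seed %% m)
  i <- as.double(seq_len(n_runs))
  # all intermediates stay below 2^53, so the arithmetic is exact
  z <- (s + (i %% m) * (2654435761 %% m)) %% m
  z <- (z * 48271) %% m
  as.integer(z)
}
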
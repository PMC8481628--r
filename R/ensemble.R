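#' Run an ensemble of independent simulations
#'
#' Runs `config$n_runs` independent school-term + vacation simulations, each
#' on its own deterministic seed substream (see [run_seeds()]), and collects
#' the per-run records into arrays. Identical configurations and master
#' seeds produce bit-identical ensembles, and because the substreams are
#' counter-based, enlarging `n_runs` leaves the earlier runs unchanged.
#'
#' @param config A [sim_config()].
#' @param engine `"cpp"` (compiled, the default) or `"r"` (the pure-R
#'   reference path). Both consume the same RNG stream and give identical
#'   results; the R engine is intended for small cross-checks.
#' @return An object of class `procrasim_ensemble`: a list with
#'   * `stay_counts`, `gap_approx`, `gap_true`: arrays
#'     `[n_runs, episodes, states 1..n-1]`,
#'   * `w_vacation`: array `[n_runs, episodes, n]`,
#'   * `w_school`: matrix `[episodes, n]` (the school term is deterministic,
#'     so it is shared by all runs),
#'   * `truncated`: matrix `[n_runs, episodes]`,
#'   * `config`, `seeds`.
#' @examples
#' ens <- run_ensemble(sim_config(n_runs = 20, seed = 1))
#' apply(ens$stay_counts[, 1, ], 2, mean)  # episode-1 mean STAY per state
#' @export
run_ensemble <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- config$chain$n
  E <- config$vacation_episodes
  R_ <- config$n_runs
  seeds <- run_seeds(config$seed, R_)

  stay_counts <- array(NA_integer_, c(R_, E, n - 1))
  gap_approx <- array(NA_real_, c(R_, E, n - 1))
  gap_true <- array(NA_real_, c(R_, E, n - 1))
  w_vacation <- array(NA_real_, c(R_, E, n))
  truncated <- matrix(NA, R_, E)
  w_school <- NULL

  variant_code <- match(config$variant$type,
                        c("none", "penalty", "regret", "sr_update")) - 1L

  for (i in seq_len(R_)) {
    set.seed(seeds[i])
    if (engine == "cpp") {
      rec <- sim_run_cpp(
        n, config$chain$reward, config$chain$cost, config$gamma, config$beta,
        config$school_episodes, E,
        config$lr_mode == "scheduled", config$lr_constant,
        variant_code, config$variant$c_p, config$variant$penalty_onset,
        config$variant$penalty_ramp, config$variant$c_r,
        config$variant$alpha_sr, config$max_steps_per_episode)
      if (i == 1L) w_school <- rec$w_school
      w_vac <- rec$w_vac
    } else {
      school <- run_school_term(config)
      vac <- run_vacation(config, school$w)
      rec <- vac
      if (i == 1L) w_school <- school$w_trace
      w_vac <- vac$w_trace
    }
    if (E > 0) {
      stay_counts[i, , ] <- rec$stay_counts
      gap_approx[i, , ] <- rec$gap_approx
      gap_true[i, , ] <- rec$gap_true
      w_vacation[i, , ] <- w_vac
      truncated[i, ] <- rec$truncated
    }
  }
  structure(list(stay_counts = stay_counts, gap_approx = gap_approx,
                 gap_true = gap_true, w_vacation = w_vacation,
                 w_school = w_school, truncated = truncated,
                 config = config, seeds = seeds),
            class = "procrasim_ensemble")
}

#' @export
print.procrasim_ensemble <- function(x, ...) {
  cat(sprintf("<procrasim_ensemble> %d runs, %d vacation episodes, seed %d\n",
              x$config$n_runs, x$config$vacation_episodes, x$config$seed))
  invisible(x)
}

#' Sweep model parameters over a grid
#'
#' Runs one ensemble per cell of the Cartesian grid of the supplied
#' parameter values (any of `cost`, `gamma`, `beta`, `lr_constant`; a `NULL`
#' leaves the configuration's value in place). Every cell reuses the same
#' master seed, so cells differ only in the parameter of interest and
#' paired run-by-run comparisons across cells are meaningful.
#'
#' @param config Base [sim_config()].
#' @param cost,gamma,beta,lr_constant Optional numeric vectors of values to
#'   sweep. Supplying `lr_constant` switches those cells to constant
#'   learning-rate mode.
#' @return A [tibble::tibble()] with one row per cell: the swept parameter
#'   values and a list-column `summary` of [summarize_ensemble()] results.
#' @examples
#' sw <- parameter_sweep(sim_config(n_runs = 20), cost = c(0, 0.1))
#' sw$summary[[1]]$stays
#' @export
parameter_sweep <- function(config, cost = NULL, gamma = NULL, beta = NULL,
                            lr_constant = NULL) {
  grid <- expand.grid(
    cost = if (is.null(cost)) config$chain$cost else cost,
    gamma = if (is.null(gamma)) config$gamma else gamma,
    beta = if (is.null(beta)) config$beta else beta,
    lr_constant = if (is.null(lr_constant)) NA_real_ else lr_constant,
    KEEP.OUT.ATTRS = FALSE)
  summaries <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- config
    cell$chain <- task_chain(config$chain$n, config$chain$reward,
                             grid$cost[i])
    cell$gamma <- grid$gamma[i]
    cell$beta <- grid$beta[i]
    if (!is.na(grid$lr_constant[i])) {
      cell$lr_mode <- "constant"
      cell$lr_constant <- grid$lr_constant[i]
    }
    summaries[[i]] <- summarize_ensemble(run_ensemble(cell))
  }
  out <- tibble::as_tibble(grid)
  out$summary <- summaries
  out
}
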
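#' Per-episode learning rate
#'
#' In scheduled mode the learning rate decays over episodes within a phase,
#' `a = 0.5 / (1 + 0.2 m)`, modelling habituation; the episode index `m`
#' restarts at 1 at the start of the vacation phase, so the rate jumps back
#' up when the context changes. In constant mode the configured value is
#' used throughout.
#'
#' @param m Episode index within the current phase (1-based).
#' @param lr_mode `"scheduled"` or `"constant"`.
#' @param lr_constant Value used in constant mode.
#' @return The learning rate.
#' @examples
#' learning_rate(1)    # 0.41667
#' learning_rate(20)   # 0.1
#' @export
learning_rate <- function(m, lr_mode = "scheduled", lr_constant = 0.2) {
  stopifnot(all(m >= 1))
  if (lr_mode == "scheduled") 0.5 / (1 + 0.2 * m) else
    rep(lr_constant, length(m))
}

#' Run the forced-GO school term
#'
#' The agent experiences `school_episodes` episodes under the policy of
#' choosing GO at every state (procrastination not allowed), starting from
#' `w = 0`, updating `w` by TD learning on every step. The phase is fully
#' deterministic. The weight is recorded "just after the agent left" each
#' state: after the GO update out of it, and after the terminal update for
#' the goal.
#'
#' @param config A [sim_config()].
#' @return A list with `w` (final weight) and `w_trace`
#'   (`school_episodes x n` matrix of recorded weights).
#' @examples
#' run_school_term(sim_config())$w
#' @export
run_school_term <- function(config) {
  n <- config$chain$n
  reward <- config$chain$reward
  cost <- config$chain$cost
  gamma <- config$gamma
  x <- goal_based_features(n, gamma)
  w <- 0
  w_trace <- matrix(NA_real_, config$school_episodes, n)
  for (m in seq_len(config$school_episodes)) {
    a <- learning_rate(m, config$lr_mode, config$lr_constant)
    for (k in seq_len(n - 1)) {
      v_k <- approx_state_value(w, x[k])
      v_k1 <- approx_state_value(w, x[k + 1])
      delta <- td_error(-cost, gamma, v_k1, v_k)
      w <- update_weight(w, a, delta, x[k])
      w_trace[m, k] <- w
    }
    # terminal update at the goal: successor value 0, reward delivered
    delta <- td_error(reward, gamma, 0, approx_state_value(w, x[n]))
    w <- update_weight(w, a, delta, x[n])
    w_trace[m, n] <- w
  }
  list(w = w, w_trace = w_trace)
}

#' Run the free-choice vacation phase (single run, pure R)
#'
#' Starting from the school-term weight, the agent chooses GO or STAY by
#' softmax over the approximated action values at every time-step until it
#' reaches the goal, for `vacation_episodes` episodes. In parallel a tabular
#' TD tracker, initialised at the closed-form true values, estimates the
#' true values of the policy actually being followed. Variant adjustments
#' (penalty, regret, slow SR update) are applied as configured.
#'
#' This is the reference implementation; [run_ensemble()] uses a compiled
#' engine that consumes the same random-number stream and produces identical
#' results (an equality asserted in the package tests). Random draws come
#' from the current R RNG state: seed before calling for reproducibility.
#'
#' @param config A [sim_config()].
#' @param w Initial weight (the final school-term weight).
#' @return A list with matrices over vacation episodes: `stay_counts`
#'   (episodes x (n-1)), `gap_approx` and `gap_true` (first-entry GO minus
#'   STAY value differences, NA where a state was never reached),
#'   `w_trace` (episodes x n), logical `truncated`, plus final `w`,
#'   `v_hat` and `features`.
#' @export
run_vacation <- function(config, w) {
  n <- config$chain$n
  reward <- config$chain$reward
  cost <- config$chain$cost
  gamma <- config$gamma
  beta <- config$beta
  variant <- config$variant
  E <- config$vacation_episodes
  x <- goal_based_features(n, gamma)
  v_hat <- closed_form_values(n, gamma, reward, cost)$value
  stay_counts <- matrix(0L, E, n - 1)
  gap_approx <- matrix(NA_real_, E, n - 1)
  gap_true <- matrix(NA_real_, E, n - 1)
  w_trace <- matrix(NA_real_, E, n)
  truncated <- logical(E)
  t_v <- 0

  record_entry <- function(m, k) {
    adj <- stay_adjustments(variant, t_v)
    q <- approx_action_values(w, x, k, gamma, cost)
    qh <- estimated_true_action_values(v_hat, k, gamma, cost)
    gap_approx[m, k] <<- q[["GO"]] - (q[["STAY"]] - adj$selection)
    gap_true[m, k] <<- qh[["GO"]] - (qh[["STAY"]] - adj$true_report)
  }

  for (m in seq_len(E)) {
    a <- learning_rate(m, config$lr_mode, config$lr_constant)
    k <- 1L
    steps <- 0L
    record_entry(m, k)
    repeat {
      adj <- stay_adjustments(variant, t_v)
      v_k <- approx_state_value(w, x[k])
      v_k1 <- approx_state_value(w, x[k + 1])
      q_go <- gamma * v_k1 - cost
      q_stay <- gamma * v_k - adj$selection
      p_go <- softmax_go_prob(q_go, q_stay, beta)
      u <- runif(1)
      t_v <- t_v + 1
      steps <- steps + 1L
      if (u < p_go) {
        delta <- td_error(-cost, gamma, v_k1, v_k)
        delta_true <- td_error(-cost, gamma, v_hat[k + 1], v_hat[k])
        w <- update_weight(w, a, delta, x[k])
        v_hat[k] <- v_hat[k] + a * delta_true
        if (variant$type == "sr_update") {
          x <- sr_feature_update(x, k, k + 1L, variant$alpha_sr, gamma)
        }
        w_trace[m, k] <- w
        k <- k + 1L
        if (k == n) {
          # goal occupancy is itself a time-step: the terminal update is
          # indexed by t like any other, so t_v advances here too
          delta <- td_error(reward, gamma, 0, approx_state_value(w, x[n]))
          w <- update_weight(w, a, delta, x[n])
          v_hat[n] <- v_hat[n] + a * td_error(reward, gamma, 0, v_hat[n])
          w_trace[m, n] <- w
          t_v <- t_v + 1
          break
        }
        record_entry(m, k)
      } else {
        stay_counts[m, k] <- stay_counts[m, k] + 1L
        delta <- td_error(0, gamma, v_k, v_k) - adj$rpe
        delta_true <- td_error(0, gamma, v_hat[k], v_hat[k]) - adj$rpe
        w <- update_weight(w, a, delta, x[k])
        v_hat[k] <- v_hat[k] + a * delta_true
        if (variant$type == "sr_update") {
          x <- sr_feature_update(x, k, k, variant$alpha_sr, gamma)
        }
      }
      if (steps >= config$max_steps_per_episode) {
        truncated[m] <- TRUE
        break
      }
    }
  }
  list(stay_counts = stay_counts, gap_approx = gap_approx,
       gap_true = gap_true, w_trace = w_trace, truncated = truncated,
       w = w, v_hat = v_hat, features = x)
}

#' Run one complete simulation (school term + vacation)
#'
#' Seeds the RNG with the substream for `run` derived from the master seed,
#' then runs the deterministic school term followed by the stochastic
#' vacation phase.
#'
#' @param config A [sim_config()].
#' @param run Run index used to derive the per-run seed substream.
#' @return A list combining the school-term results (`w_school`) and the
#'   vacation record (see [run_vacation()]), of class `procrasim_run`.
#' @examples
#' rec <- run_simulation(sim_config(n_runs = 1, seed = 42))
#' colMeans(rec$stay_counts)
#' @export
run_simulation <- function(config, run = 1L) {
  set.seed(run_seeds(config$seed, run)[run])
  school <- run_school_term(config)
  vac <- run_vacation(config, school$w)
  structure(c(list(w_school = school$w_trace), vac),
            class = "procrasim_run")
}
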
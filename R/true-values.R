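#' Closed-form true state values under the non-procrastinating policy
#'
#' Under the always-GO policy the true value of state `k` is
#' `v(S_k) = gamma^(n-k) * R - C_k`, where
#' `C_k = cost * (1 + gamma + ... + gamma^(n-k-1))` is the discounted sum of
#' all remaining GO costs (`C_n = 0`). These values satisfy the Bellman
#' identity `v(S_k) = gamma * v(S_{k+1}) - cost` exactly, so they are the
#' fixed point of tabular TD evaluation of that policy.
#'
#' @param n Number of states.
#' @param gamma Discount factor in (0, 1).
#' @param reward Goal reward.
#' @param cost GO cost.
#' @return A [tibble::tibble()] with columns `state`, `future_cost` (`C_k`)
#'   and `value` (`v(S_k)`).
#' @examples
#' closed_form_values(5, 0.85, 1, 0.1)
#' @export
closed_form_values <- function(n, gamma, reward, cost) {
  stopifnot("gamma must lie strictly in (0, 1)" = gamma > 0 && gamma < 1)
  k <- seq_len(n)
  future_cost <- vapply(k, function(kk) {
    steps <- n - kk            # GO actions remaining
    if (steps == 0) 0 else cost * sum(gamma^(0:(steps - 1)))
  }, numeric(1))
  tibble::tibble(state = k,
                 future_cost = future_cost,
                 value = gamma^(n - k) * reward - future_cost)
}

#' One tabular TD update of the estimated true values
#'
#' The agent is assumed to also track the true values of the policy it is
#' actually following, by ordinary tabular TD(0) over individual states:
#' `delta' = r + gamma * v^(S') - v^(S)` and `v^(S) <- v^(S) + a * delta'`.
#' Only the visited state's entry changes.
#'
#' @param v_hat Numeric vector of current estimates, one per state.
#' @param state Index of the state the step started from.
#' @param next_state Index of the successor, or `NA` for the terminal update
#'   (successor value treated as 0).
#' @param r Reward on the step.
#' @param a Learning rate.
#' @param gamma Discount factor.
#' @param delta_adjust Amount subtracted from `delta'` (used by the penalty
#'   and regret variants on STAY steps; 0 otherwise).
#' @return The updated estimate vector.
#' @examples
#' v <- closed_form_values(5, 0.85, 1, 0.1)$value
#' true_td_update(v, 4, 5, -0.1, 0.2, 0.85)  # fixed point: unchanged
#' @export
true_td_update <- function(v_hat, state, next_state, r, a, gamma,
                           delta_adjust = 0) {
  v_next <- if (is.na(next_state)) 0 else v_hat[next_state]
  delta <- td_error(r, gamma, v_next, v_hat[state]) - delta_adjust
  v_hat[state] <- v_hat[state] + a * delta
  v_hat
}

#' Estimated true action values at a non-goal state
#'
#' One-step lookahead through the tabular estimates:
#' `q^_GO = gamma * v^(S_{k+1}) - cost`, `q^_STAY = gamma * v^(S_k)`.
#'
#' @param v_hat Numeric vector of tabular value estimates.
#' @param k State index, `1 <= k < n`.
#' @param gamma Discount factor.
#' @param cost GO cost.
#' @return Named numeric vector `c(GO = ..., STAY = ...)`.
#' @export
estimated_true_action_values <- function(v_hat, k, gamma, cost) {
  n <- length(v_hat)
  if (k < 1 || k >= n) stop("no actions are defined at the goal state")
  c(GO = gamma * v_hat[k + 1] - cost, STAY = gamma * v_hat[k])
}
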
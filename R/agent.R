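#' Goal-based reduced successor representation features
#'
#' Each state is represented by a single scalar feature: its discounted
#' expected future occupancy of the goal state under the non-procrastinating
#' (always-GO) policy, `x_k = gamma^(n - k)`. The goal's own feature is 1.
#'
#' @param n Number of states in the chain.
#' @param gamma Discount factor, strictly between 0 and 1.
#' @return Numeric vector of length `n`: `(gamma^(n-1), ..., gamma, 1)`.
#' @examples
#' goal_based_features(5, 0.85)
#' @export
goal_based_features <- function(n, gamma) {
  stopifnot(
    "n must be >= 2" = is.numeric(n) && length(n) == 1L && n >= 2,
    "gamma must lie strictly in (0, 1)" =
      is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma < 1
  )
  gamma^(n - seq_len(n))
}

#' Approximated state value under the linear reduced-SR model
#'
#' The agent approximates the value of state `k` as `w * x_k`, a linear
#' function of the single reduced-SR feature with a shared scalar weight.
#'
#' @param w Scalar weight of the linear value function.
#' @param x Feature value(s) of the state(s).
#' @return `w * x`.
#' @export
approx_state_value <- function(w, x) w * x

#' Temporal-difference (reward prediction) error
#'
#' `delta = r + gamma * v_next - v_current`. When the successor is terminal
#' its value is taken as 0 by the caller.
#'
#' @param r Immediate reward on this step.
#' @param gamma Discount factor.
#' @param v_next Value of the successor state (0 if terminal).
#' @param v_current Value of the current state.
#' @return The TD error.
#' @export
td_error <- function(r, gamma, v_next, v_current) {
  r + gamma * v_next - v_current
}

#' Gradient update of the value-function weight
#'
#' `w <- w + a * delta * x_current`: the standard TD(0) update for a linear
#' value function, here with a one-dimensional feature.
#'
#' @param w Current weight.
#' @param a Learning rate (> 0).
#' @param delta TD error on this step.
#' @param x_current Feature of the state the error was computed at.
#' @return The updated weight.
#' @export
update_weight <- function(w, a, delta, x_current) {
  stopifnot("learning rate must be positive" = a > 0)
  w + a * delta * x_current
}

#' Approximated action values at a non-goal state
#'
#' One-step lookahead through the approximated state values:
#' `q_GO = gamma * v~(S_{k+1}) - cost`, `q_STAY = gamma * v~(S_k)`, with
#' `v~(S) = w * x(S)`.
#'
#' @param w Scalar weight.
#' @param features Feature vector (see [goal_based_features()]).
#' @param k State index, `1 <= k < n`.
#' @param gamma Discount factor.
#' @param cost Cost of the GO action.
#' @return Named numeric vector `c(GO = ..., STAY = ...)`.
#' @examples
#' x <- goal_based_features(5, 0.85)
#' approx_action_values(0.729136875, x, 4, 0.85, 0.1)
#' @export
approx_action_values <- function(w, features, k, gamma, cost) {
  n <- length(features)
  if (k < 1 || k >= n) stop("no actions are defined at the goal state")
  v_k <- approx_state_value(w, features[k])
  v_k1 <- approx_state_value(w, features[k + 1])
  c(GO = gamma * v_k1 - cost, STAY = gamma * v_k)
}

#' Softmax probability of choosing GO
#'
#' Two-action Boltzmann selection in its logistic form:
#' `P(GO) = 1 / (1 + exp(b * (q_STAY - q_GO)))`. The exponent is clipped at
#' +/- 700 so the probability saturates instead of overflowing for extreme
#' value gaps.
#'
#' @param q_go,q_stay Action values.
#' @param beta Inverse temperature (>= 0); 0 gives uniform choice.
#' @return Probability of GO, vectorised over the inputs.
#' @examples
#' softmax_go_prob(0.5, 0.5, 20)   # 0.5
#' softmax_go_prob(-0.1, 0, 20)
#' @export
softmax_go_prob <- function(q_go, q_stay, beta) {
  stopifnot("beta must be non-negative" = all(beta >= 0))
  z <- beta * (q_stay - q_go)
  z <- pmin(pmax(z, -700), 700)
  1 / (1 + exp(z))
}

#' Sample a GO/STAY choice
#'
#' @inheritParams softmax_go_prob
#' @param u A uniform draw in `[0, 1)`; defaults to a fresh `runif(1)`.
#' @return `"GO"` or `"STAY"`.
#' @export
softmax_choice <- function(q_go, q_stay, beta, u = runif(1)) {
  if (u < softmax_go_prob(q_go, q_stay, beta)) "GO" else "STAY"
}
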
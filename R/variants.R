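#' Configure a model variant
#'
#' Three modifications of the base agent are supported, applied only during
#' the free-choice (vacation) phase and mutually exclusive per run:
#'
#' * `"penalty"`: an elapsed-time pressure term. After `penalty_onset`
#'   vacation time-steps, the quantity `p(t_v) * c_p` with
#'   `p(t_v) = (t_v - penalty_onset) / penalty_ramp` is subtracted from the
#'   STAY value used for action selection, from the reported true STAY value,
#'   and from both TD errors on steps where STAY is taken.
#' * `"regret"`: an unpredictable post-hoc term. `c_r` is subtracted from the
#'   reported true STAY value and from both TD errors on STAY steps, but
#'   *not* from the STAY value used for action selection, so choice
#'   probabilities at fixed weights are unchanged.
#' * `"sr_update"`: the reduced-SR features themselves are slowly updated by
#'   TD learning during vacation (see [sr_feature_update()]), so repeated
#'   procrastination lowers each state's represented proximity to the goal.
#'
#' @param type One of `"none"`, `"penalty"`, `"regret"`, `"sr_update"`.
#' @param c_p Penalty scale (default 0.1).
#' @param penalty_onset Vacation time-step at which the penalty ramp starts
#'   (default 150).
#' @param penalty_ramp Denominator of the linear ramp (default 150).
#' @param c_r Regret magnitude (default 0.02).
#' @param alpha_sr Learning rate of the feature update (default 0.05).
#' @return An object of class `variant_config`.
#' @examples
#' variant_config("penalty")
#' @export
variant_config <- function(type = c("none", "penalty", "regret", "sr_update"),
                           c_p = 0.1, penalty_onset = 150, penalty_ramp = 150,
                           c_r = 0.02, alpha_sr = 0.05) {
  type <- match.arg(type)
  stopifnot(c_p >= 0, c_r >= 0, alpha_sr >= 0,
            penalty_onset > 0, penalty_ramp > 0)
  structure(list(type = type, c_p = c_p, penalty_onset = penalty_onset,
                 penalty_ramp = penalty_ramp, c_r = c_r, alpha_sr = alpha_sr),
            class = "variant_config")
}

#' @export
print.variant_config <- function(x, ...) {
  cat(sprintf("<variant_config> type = %s\n", x$type))
  invisible(x)
}

#' Elapsed-time penalty ramp
#'
#' `p(t_v) = max(0, (t_v - onset) / ramp)`: zero until the onset time-step,
#' then increasing linearly without upper bound. The amount subtracted from
#' STAY-related quantities is `p(t_v) * c_p`.
#'
#' @param t_v Vacation time-step counter (cumulative over the whole vacation
#'   phase, starting at 0).
#' @param variant A [variant_config()].
#' @return `p(t_v)`, vectorised over `t_v`.
#' @examples
#' penalty_magnitude(c(0, 150, 300), variant_config("penalty"))
#' @export
penalty_magnitude <- function(t_v, variant) {
  stopifnot(all(t_v >= 0))
  pmax(0, (t_v - variant$penalty_onset) / variant$penalty_ramp)
}

#' STAY-value adjustments implied by a variant
#'
#' Returns the amounts subtracted from (1) the approximated STAY value used
#' for action selection, (2) the TD errors (both the approximated system's
#' delta and the true tracker's delta') on steps where STAY is taken, and
#' (3) the reported estimated-true STAY value. With `type = "none"` all
#' three are 0, so the base model is recovered exactly.
#'
#' @inheritParams penalty_magnitude
#' @return A list with numeric elements `selection`, `rpe`, `true_report`.
#' @export
stay_adjustments <- function(variant, t_v = 0) {
  switch(variant$type,
    none = list(selection = 0, rpe = 0, true_report = 0),
    penalty = {
      amount <- penalty_magnitude(t_v, variant) * variant$c_p
      list(selection = amount, rpe = amount, true_report = amount)
    },
    regret = list(selection = 0, rpe = variant$c_r,
                  true_report = variant$c_r),
    sr_update = list(selection = 0, rpe = 0, true_report = 0)
  )
}

#' TD update of a reduced-SR feature
#'
#' During vacation under the `"sr_update"` variant the feature of the current
#' (non-goal) state is nudged toward consistency with the transition actually
#' taken: `x(S) <- x(S) + alpha_sr * (gamma * x(S') - x(S))`. STAY self-loops
#' therefore shrink the feature (the represented temporal proximity to the
#' goal decreases), while GO steps with self-consistent features leave it
#' unchanged. The goal feature is never updated and stays at 1.
#'
#' @param features Current feature vector.
#' @param state Index of the state whose feature is updated (must not be the
#'   goal).
#' @param next_state Index of the successor state (the goal for the final GO
#'   step, whose feature is 1).
#' @param alpha_sr Feature learning rate.
#' @param gamma Discount factor.
#' @return The updated feature vector.
#' @examples
#' x <- goal_based_features(5, 0.85)
#' sr_feature_update(x, 2, 2, 0.05, 0.85)  # STAY shrinks x_2
#' @export
sr_feature_update <- function(features, state, next_state, alpha_sr, gamma) {
  n <- length(features)
  if (state == n) stop("the goal feature is never updated")
  delta_sr <- gamma * features[next_state] - features[state]
  features[state] <- features[state] + alpha_sr * delta_sr
  features
}
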
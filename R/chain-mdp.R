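#' Define a sequential task chain
#'
#' The task (e.g. a set of assignments) is modelled as a chain of `n` states.
#' The agent starts at state 1 and must reach state `n`, the goal, where a
#' reward of magnitude `reward` is delivered. Each forward step ("GO") costs
#' `cost`; staying put ("STAY") is free but delays the goal.
#'
#' @param n Number of states (>= 2). State `n` is the terminal goal.
#' @param reward Reward magnitude delivered at the goal (> 0).
#' @param cost Cost charged for each "GO" action (>= 0).
#'
#' @return An object of class `task_chain`: a list with elements `n`,
#'   `reward` and `cost`.
#' @examples
#' task_chain()
#' task_chain(n = 3, cost = 0.05)
#' @export
task_chain <- function(n = 5, reward = 1, cost = 0.1) {
  stopifnot(
    "n must be a single integer >= 2" =
      is.numeric(n) && length(n) == 1L && n >= 2 && n == round(n),
    "reward must be a single positive number" =
      is.numeric(reward) && length(reward) == 1L && reward > 0,
    "cost must be a single non-negative number" =
      is.numeric(cost) && length(cost) == 1L && cost >= 0
  )
  structure(list(n = as.integer(n), reward = as.numeric(reward),
                 cost = as.numeric(cost)),
            class = "task_chain")
}

#' @export
print.task_chain <- function(x, ...) {
  cat(sprintf("<task_chain> %d states, goal reward %g, GO cost %g\n",
              x$n, x$reward, x$cost))
  invisible(x)
}

#' State transition of the task chain
#'
#' "GO" advances one state; "STAY" is a self-loop. No action is available at
#' the goal state, which is terminal.
#'
#' @param chain A [task_chain()].
#' @param state Current state index, `1 <= state < n`.
#' @param action `"GO"` or `"STAY"`.
#' @return The successor state index.
#' @examples
#' transition(task_chain(), 1, "GO")
#' transition(task_chain(), 3, "STAY")
#' @export
transition <- function(chain, state, action) {
  action <- match.arg(action, c("GO", "STAY"))
  if (state < 1 || state >= chain$n) {
    stop("no actions are available at the goal state (or state out of range)")
  }
  if (action == "GO") as.integer(state) + 1L else as.integer(state)
}

#' Immediate reward of an action at a non-goal state
#'
#' "GO" yields `-cost`; "STAY" yields 0. The goal reward itself is delivered
#' by the separate terminal update upon reaching the goal (see
#' [run_vacation()]), not by this function.
#'
#' @inheritParams transition
#' @return A single number.
#' @export
immediate_reward <- function(chain, action) {
  action <- match.arg(action, c("GO", "STAY"))
  if (action == "GO") -chain$cost else 0
}

#' Is a state the terminal goal?
#'
#' @inheritParams transition
#' @return `TRUE` iff `state` equals `n`.
#' @export
is_terminal <- function(chain, state) {
  if (state < 1 || state > chain$n) stop("state out of range")
  state == chain$n
}
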
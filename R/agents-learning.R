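#' Transition belief
#'
#' An agent's current estimate of P(state | action), initialized to 0.5
#' everywhere. In the two-step variant each action's two transition
#' probabilities are complementary (rows sum to 1); in the multi-goal
#' variant the reward- and punishment-state probabilities are free in
#' [0, 1] because states are reached independently.
#'
#' @param task `"twostep"` or `"multigoal"`.
#' @return a 2 x 2 matrix of class `transition_belief` with a `task`
#'   attribute; rows are actions. Columns are states 1/2 (twostep) or
#'   reward/punish (multigoal).
#' @export
transition_belief <- function(task = c("twostep", "multigoal")) {
  task <- match.arg(task)
  cols <- if (task == "twostep") c("1", "2") else c("reward", "punish")
  b <- matrix(0.5, 2, 2, dimnames = list(action = c("1", "2"), state = cols))
  structure(b, class = c("transition_belief", "matrix", "array"),
            task = task)
}

#' Incremental state-transition learning (ISTL) update
#'
#' Moves the chosen action's estimated transition probability toward the
#' observed outcome by a state prediction error scaled by the learning rate
#' `gamma`. In the two-step variant the observed transition's probability
#' moves toward 1 and its complement is set so the row sums to 1; in the
#' multi-goal variant each of the chosen action's two state probabilities
#' moves toward the binary reached/not-reached outcome. The untaken
#' action's estimates decay toward the initial prior of 0.5 at the same
#' rate (optional).
#'
#' @param belief a [transition_belief()].
#' @param action the chosen action (1 or 2).
#' @param outcome two-step: the observed second-stage state (1 or 2);
#'   multi-goal: named or length-2 binary vector (reward, punish) of which
#'   states were reached.
#' @param gamma learning rate in [0, 1].
#' @param decay_unchosen decay the untaken action's estimates toward 0.5.
#' @return the updated belief.
#' @export
istl_update <- function(belief, action, outcome, gamma,
                        decay_unchosen = TRUE) {
  stopifnot(inherits(belief, "transition_belief"), action %in% 1:2)
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]")
  task <- attr(belief, "task")
  if (task == "twostep") {
    stopifnot(outcome %in% 1:2)
    belief[action, outcome] <- belief[action, outcome] +
      gamma * (1 - belief[action, outcome])
    belief[action, 3 - outcome] <- 1 - belief[action, outcome]
    if (decay_unchosen) {
      u <- 3 - action
      belief[u, 1] <- belief[u, 1] + gamma * (0.5 - belief[u, 1])
      belief[u, 2] <- 1 - belief[u, 1]
    }
  } else {
    stopifnot(length(outcome) == 2, all(outcome %in% c(0, 1, FALSE, TRUE)))
    belief[action, ] <- belief[action, ] +
      gamma * (as.numeric(outcome) - belief[action, ])
    if (decay_unchosen) {
      u <- 3 - action
      belief[u, ] <- belief[u, ] + gamma * (0.5 - belief[u, ])
    }
  }
  belief
}

#' Counting state for the Typical transition model
#'
#' Running tally of observed action-to-state transitions on the two-step
#' task, used to infer which of the two candidate transition matrices is
#' the true one.
#'
#' @param p_common common-transition probability of the candidates.
#' @return an object of class `typical_counts`.
#' @export
typical_counts <- function(p_common = 0.7) {
  counts <- matrix(0, 2, 2, dimnames = list(action = c("1", "2"),
                                            state = c("1", "2")))
  structure(list(counts = counts, p_common = p_common),
            class = "typical_counts")
}

#' Record one observed transition in the counting state
#'
#' @param counting a [typical_counts()].
#' @param action,state observed first-stage action and second-stage state.
#' @return updated counting state.
#' @export
typical_observe <- function(counting, action, state) {
  stopifnot(inherits(counting, "typical_counts"),
            action %in% 1:2, state %in% 1:2)
  counting$counts[action, state] <- counting$counts[action, state] + 1
  counting
}

#' Infer the transition matrix from transition counts
#'
#' The candidate T1 (action 1 commonly leads to state 1) is inferred when
#' the diagonal tally C(1,1) + C(2,2) exceeds the off-diagonal tally
#' C(1,2) + C(2,1); the converse yields T2; a tie yields the element-wise
#' average of the two candidates (all entries 0.5).
#'
#' @param counting a [typical_counts()].
#' @return 2 x 2 inferred transition matrix, rows = actions.
#' @export
typical_infer <- function(counting) {
  stopifnot(inherits(counting, "typical_counts"))
  C <- counting$counts
  pc <- counting$p_common
  diag_sum <- C[1, 1] + C[2, 2]
  off_sum <- C[1, 2] + C[2, 1]
  p <- if (diag_sum > off_sum) pc else if (diag_sum < off_sum) 1 - pc else 0.5
  matrix(c(p, 1 - p, 1 - p, p), 2, 2, byrow = TRUE,
         dimnames = list(action = c("1", "2"), state = c("1", "2")))
}

#' Model-free value update with forgetting
#'
#' Chosen-action values move toward the reward by learning rate `alpha`
#' (equivalently decay by its complement 1 - alpha); unchosen-action values
#' decay toward 0 by their own rate `D`.
#'
#' @param Q numeric value vector.
#' @param chosen index of the chosen action.
#' @param reward obtained reward (update target).
#' @param alpha value learning rate in [0, 1].
#' @param D unchosen-value decay rate in [0, 1].
#' @return the updated values.
#' @export
mf_value_update <- function(Q, chosen, reward, alpha, D) {
  if (alpha < 0 || alpha > 1 || D < 0 || D > 1)
    stop("alpha and D must lie in [0, 1]")
  stopifnot(chosen >= 1, chosen <= length(Q))
  unchosen <- setdiff(seq_along(Q), chosen)
  Q[chosen] <- (1 - alpha) * Q[chosen] + alpha * reward
  Q[unchosen] <- (1 - D) * Q[unchosen]
  Q
}
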
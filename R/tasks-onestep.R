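#' One-step revaluation task schedule
#'
#' Two actions each lead to one of three states with fixed frequencies. In a
#' standard block each action is taken 10 times and leads to its common
#' state 5 times, its uncommon state 3 times and the shared rare state
#' twice. The practice block uses 20 forced choices per action with the
#' common state occurring 16 times and each other state twice. The test
#' phase queries, for each outcome state, which action produced it most
#' often; the rare state is reached equally often by both actions, so its
#' query has no optimal answer and is unscored.
#'
#' States are coded 1, 2, 3: state 1 is action 1's common state, state 2 is
#' action 2's common state, state 3 the shared rare state.
#'
#' @param practice logical; use the easy practice-block frequencies.
#' @param condition optional emotional-distractor condition label carried on
#'   the block (no image content is modeled).
#' @return an object of class `one_step_schedule` with elements `counts`
#'   (2 x 3 matrix of action-by-state outcome counts), `n_choices` (forced
#'   choices per action) and `queries` (one row per outcome state with
#'   `scored` flag and `optimal_action`).
#' @export
one_step_schedule <- function(practice = FALSE, condition = "neutral") {
  counts <- if (practice) {
    rbind(c(16L, 2L, 2L), c(2L, 16L, 2L))
  } else {
    rbind(c(5L, 3L, 2L), c(3L, 5L, 2L))
  }
  dimnames(counts) <- list(action = c("1", "2"), state = c("1", "2", "3"))
  queries <- data.frame(
    state = 1:3,
    scored = c(TRUE, TRUE, FALSE),
    optimal_action = c(1L, 2L, NA_integer_)
  )
  out <- list(counts = counts, n_choices = sum(counts[1, ]),
              queries = queries, practice = practice, condition = condition)
  class(out) <- "one_step_schedule"
  validate_one_step_schedule(out)
  out
}

validate_one_step_schedule <- function(schedule) {
  counts <- schedule$counts
  if (!is.matrix(counts) || !all(dim(counts) == c(2, 3)))
    stop("schedule counts must be a 2 x 3 matrix")
  if (any(counts < 0)) stop("schedule counts must be non-negative")
  if (length(unique(rowSums(counts))) != 1L)
    stop("both actions must be taken the same number of times")
  if (!schedule$practice) {
    for (a in 1:2) {
      if (!setequal(counts[a, ], c(5L, 3L, 2L)))
        stop("standard block requires outcome counts {5, 3, 2} per action")
    }
  }
  rare1 <- which(counts[1, ] == min(counts[1, ]))
  rare2 <- which(counts[2, ] == min(counts[2, ]))
  if (!length(intersect(rare1, rare2)))
    stop("the rare state must be shared by both actions")
  invisible(schedule)
}

#' Simulate the learning phase of a one-step revaluation block
#'
#' Forced-choice trials are generated with *exact* outcome counts: the
#' schedule states frequencies out of 10 (or 20) as task facts, so outcome
#' sequences are sampled as permutations of the scheduled multiset, not as
#' independent draws. The two actions are randomly interleaved.
#'
#' @param schedule a [one_step_schedule()].
#' @param seed optional integer seed.
#' @return list with `learning` (tibble: trial, action, state) and
#'   `queries` (the schedule's test queries).
#' @export
simulate_one_step_block <- function(schedule, seed = NULL) {
  validate_one_step_schedule(schedule)
  if (!is.null(seed)) set.seed(seed)
  counts <- schedule$counts
  outcomes <- lapply(1:2, function(a) {
    sample(rep(1:3, times = counts[a, ]))
  })
  action_order <- sample(rep(1:2, each = schedule$n_choices))
  state <- integer(length(action_order))
  taken <- c(0L, 0L)
  for (i in seq_along(action_order)) {
    a <- action_order[i]
    taken[a] <- taken[a] + 1L
    state[i] <- outcomes[[a]][taken[a]]
  }
  learning <- tibble::tibble(
    trial = seq_along(action_order),
    action = action_order,
    state = state,
    condition = schedule$condition
  )
  list(learning = learning, queries = schedule$queries)
}
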
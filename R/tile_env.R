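#' Reset the tile-revealing environment
#'
#' Starts an episode on a board: all tiles are covered except one red tile,
#' chosen uniformly at random among the red tiles (or fixed via
#' `start_tile`, which evaluation uses so every policy faces the same
#' start).  The goal is to reveal all red tiles while revealing as few blue
#' tiles as possible.
#'
#' @param board a board with at least 2 red tiles.
#' @param start_tile optional tile index (1..49, column-major) of the
#'   initially revealed red tile.
#' @return list of class `reveal_state` with `board`, `revealed` (logical
#'   matrix), `step_count`, `done`, `blue_count`, `total_reward`.
#' @export
env_reset <- function(board, start_tile = NULL) {
  g <- as.matrix(board)
  reds <- which(g == 1L)
  if (length(reds) < 2L) stop("board must have at least 2 red tiles")
  if (is.null(start_tile)) {
    start_tile <- reds[[sample.int(length(reds), 1L)]]
  } else if (!start_tile %in% reds) {
    stop("start_tile must index a red tile")
  }
  revealed <- matrix(FALSE, nrow(g), ncol(g))
  revealed[start_tile] <- TRUE
  structure(list(board = g, revealed = revealed, step_count = 0L,
                 done = FALSE, blue_count = 0L, total_reward = 0,
                 start_tile = start_tile),
            class = "reveal_state")
}

#' Advance the environment by one action
#'
#' Rewards: +1 for revealing a red tile, -1 for a blue tile, +10 for the
#' last red tile (which ends the episode), and -2 for clicking an already
#' revealed tile (state unchanged apart from the step counter).  The input
#' state is not modified; a new state is returned.
#'
#' @param state a `reveal_state`.
#' @param action tile index in 1..49 (column-major).
#' @return list with `state`, `reward`, `done`.
#' @export
env_step <- function(state, action) {
  n <- length(state$board)
  if (length(action) != 1L || action < 1L || action > n) {
    stop(sprintf("action must be in 1..%d", n))
  }
  if (state$done) stop("episode is already terminal")
  new <- state
  new$step_count <- state$step_count + 1L
  if (state$revealed[action]) {
    reward <- -2
  } else {
    new$revealed[action] <- TRUE
    if (state$board[action] == 1L) {
      all_red_revealed <- all(new$revealed[new$board == 1L])
      if (all_red_revealed) {
        reward <- 10
        new$done <- TRUE
      } else {
        reward <- 1
      }
    } else {
      reward <- -1
      new$blue_count <- state$blue_count + 1L
    }
  }
  new$total_reward <- state$total_reward + reward
  list(state = new, reward = reward, done = new$done)
}

#' Observation encoding of a state
#'
#' Per-cell 3-category one-hot encoding over the categories covered,
#' uncovered red, and uncovered blue.
#'
#' @param state a `reveal_state`.
#' @return 49 x 3 numeric matrix (rows = cells column-major, columns =
#'   covered/red/blue); each row sums to 1.
#' @export
env_observation <- function(state) {
  n <- length(state$board)
  obs <- matrix(0, n, 3L)
  covered <- !as.vector(state$revealed)
  obs[covered, 1L] <- 1
  red <- !covered & as.vector(state$board == 1L)
  blue <- !covered & as.vector(state$board == 0L)
  obs[red, 2L] <- 1
  obs[blue, 3L] <- 1
  colnames(obs) <- c("covered", "red", "blue")
  obs
}

neighbour_offsets <- function(nr, nc) {
  # list of 4-neighbour linear indices per cell, column-major
  lapply(seq_len(nr * nc), function(i) {
    r <- (i - 1L) %% nr + 1L
    c <- (i - 1L) %/% nr + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < nr) out <- c(out, i + 1L)
    if (c > 1L) out <- c(out, i - nr)
    if (c < nc) out <- c(out, i + nr)
    out
  })
}

#' Nearest-neighbour heuristic policy
#'
#' Chooses uniformly among covered tiles 4-adjacent to any revealed red
#' tile; when no such tile exists, uniformly among all covered tiles.
#'
#' @param state non-terminal `reveal_state`.
#' @return action (tile index).
#' @export
nn_heuristic_policy <- function(state) {
  if (state$done) stop("heuristic policy called on a terminal state")
  g <- state$board
  nr <- nrow(g); nc <- ncol(g)
  nbs <- neighbour_offsets(nr, nc)
  revealed_red <- which(state$revealed & g == 1L)
  cand <- integer(0)
  if (length(revealed_red)) {
    cand <- unique(unlist(nbs[revealed_red]))
    cand <- cand[!state$revealed[cand]]
  }
  if (!length(cand)) cand <- which(!as.vector(state$revealed))
  cand[[sample.int(length(cand), 1L)]]
}

#' Blue-count distribution of the heuristic baseline
#'
#' Runs the nearest-neighbour heuristic to termination `n_trials` times on a
#' board (fixed initial revealed tile) and returns the blue-tile counts with
#' their mean and population standard deviation, used to z-score agent
#' performance.
#'
#' @param board a board with >= 2 red tiles.
#' @param n_trials number of rollouts (default 1000).
#' @param start_tile initially revealed red tile; defaults to a uniform
#'   draw among red tiles.
#' @param seed integer seed for the rollouts.
#' @return list with `mean`, `sd`, `samples`, `start_tile`.
#' @export
heuristic_distribution <- function(board, n_trials = 1000L, start_tile = NULL,
                                   seed = NULL) {
  g <- as.matrix(board)
  reds <- which(g == 1L)
  if (length(reds) < 2L) stop("board must have at least 2 red tiles")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (is.null(start_tile)) {
    set.seed(seed)
    start_tile <- reds[[sample.int(length(reds), 1L)]]
  }
  samples <- cpp_heuristic_rollouts(as.integer(g), as.integer(n_trials),
                                    as.integer(start_tile), as.integer(seed))
  m <- mean(samples)
  s <- sqrt(mean((samples - m)^2))   # population sd
  list(mean = m, sd = s, samples = samples, start_tile = start_tile)
}

#' z-score an episode's blue count against the heuristic distribution
#'
#' `z = (blue_count - mean) / sd`; lower is better (fewer blue tiles than
#' the nearest-neighbour heuristic).  When the heuristic distribution is
#' degenerate (`sd = 0`), z is 0 if the score equals the mean and an error
#' otherwise (the board cannot rank performance).
#'
#' @param blue_count blue tiles revealed in the episode.
#' @param mean,sd heuristic blue-count mean and standard deviation.
#' @return numeric z-score.
#' @export
zscore_performance <- function(blue_count, mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (isTRUE(all.equal(blue_count, mean))) return(0)
    stop("sd = 0 with blue_count != mean: board cannot rank performance")
  }
  (blue_count - mean) / sd
}

#' Run one episode under a policy function
#'
#' @param board board with >= 2 red tiles.
#' @param policy function of the current `reveal_state` returning an action.
#' @param start_tile optional fixed initial red tile.
#' @param step_cap maximum steps before the episode is truncated (recorded
#'   in the result as `capped`).
#' @param record_trace if `TRUE`, also return the ordered
#'   (observation, action, reward) triples; observations are stored as
#'   per-cell category codes (0 covered, 1 red, 2 blue).
#' @return list with `blue_count`, `total_reward`, `steps`, `done`,
#'   `capped`, and (when recorded) `trace`.
#' @export
run_episode <- function(board, policy, start_tile = NULL, step_cap = 200L,
                        record_trace = FALSE) {
  state <- env_reset(board, start_tile = start_tile)
  trace <- if (record_trace) list()
  while (!state$done && state$step_count < step_cap) {
    action <- policy(state)
    if (record_trace) {
      obs_code <- as.integer(env_observation(state) %*% c(0L, 1L, 2L))
      trace[[length(trace) + 1L]] <- list(observation = obs_code,
                                          action = action)
    }
    res <- env_step(state, action)
    if (record_trace) {
      trace[[length(trace)]]$reward <- res$reward
    }
    state <- res$state
  }
  out <- list(blue_count = state$blue_count, total_reward = state$total_reward,
              steps = state$step_count, done = state$done,
              capped = !state$done)
  if (record_trace) out$trace <- trace
  out
}

#' Oracle policy that reads the true board
#'
#' Clicks an arbitrary covered red tile; used as a reward-accounting oracle
#' (blue count 0, total reward `(k - 2) + 10` on a board with k red tiles).
#'
#' @param state non-terminal `reveal_state`.
#' @return action (tile index).
#' @export
oracle_policy <- function(state) {
  cand <- which(state$board == 1L & !state$revealed)
  cand[[1L]]
}
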
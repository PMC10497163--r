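#' Gibbs sampler configuration
#'
#' One sweep visits all tile positions exactly once in a fresh uniformly
#' random order, resampling each tile from the model's conditional
#' red-probability given all the others.  The chain starts from an i.i.d.
#' Bernoulli(`init_red_probability`) board and runs `n_sweeps` sweeps (the
#' default 20 sweeps equals 980 single-tile updates on a 7x7 board, well
#' past the hypercube mixing threshold).
#'
#' @param n_sweeps number of full sweeps (`>= 1`).
#' @param init_red_probability per-tile red probability at initialisation.
#' @param seed optional integer seed.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_sweeps = 20L, init_red_probability = 0.5,
                         seed = NULL) {
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1")
  if (init_red_probability < 0 || init_red_probability > 1) {
    stop("init_red_probability must be in [0, 1]")
  }
  structure(list(n_sweeps = as.integer(n_sweeps),
                 init_red_probability = init_red_probability,
                 seed = seed),
            class = "gibbs_config")
}

#' One Gibbs sweep over a board
#'
#' Visits all positions in a fresh random permutation; at each position the
#' tile is masked, the model's conditional red-probability at that position
#' is read, and the tile is resampled from that Bernoulli.  Exactly one
#' single-tile conditional update happens per position.
#'
#' @param model a conditional model (see [predict_tile_prob()]).
#' @param board board object or 0/1 matrix of any dimensions.
#' @return board of the same shape after 1 sweep.  The number of single-tile
#'   updates performed is attached as attribute `updates`.
#' @export
gibbs_sweep <- function(model, board) {
  g <- as.matrix(board)
  dims <- dim(g)
  grid <- as.numeric(g)
  n <- length(grid)
  for (pos in sample.int(n)) {
    p <- predict_tile_prob(model, grid, pos)
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("conditional model produced a probability outside [0, 1]")
    }
    grid[pos] <- as.numeric(stats::runif(1) < p)
  }
  out <- matrix(as.integer(grid), dims[1], dims[2])
  attr(out, "updates") <- n
  out
}

#' Draw one board by Gibbs sampling
#'
#' Initialises every tile i.i.d. Bernoulli(`init_red_probability`), applies
#' `n_sweeps` Gibbs sweeps under the model's conditionals, and returns the
#' final board.  Deterministic given `config$seed`.
#'
#' @param model a conditional model.
#' @param config a [gibbs_config()].
#' @param dims grid dimensions (rows, cols); defaults to 7x7 for
#'   `masked_net` models of 49 cells.
#' @return a [new_board()] with attribute `updates` (total single-tile
#'   updates performed).
#' @export
gibbs_sample <- function(model, config = gibbs_config(), dims = NULL) {
  if (is.null(dims)) {
    n <- if (!is.null(model$n_cells)) model$n_cells else 49L
    side <- as.integer(round(sqrt(n)))
    if (side * side != n) stop("dims must be given for non-square cell counts")
    dims <- c(side, side)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- matrix(as.integer(stats::runif(prod(dims)) < config$init_red_probability),
              dims[1], dims[2])
  updates <- 0L
  for (s in seq_len(config$n_sweeps)) {
    g <- gibbs_sweep(model, g)
    updates <- updates + attr(g, "updates")
  }
  out <- new_board(unclass_grid(g))
  attr(out, "updates") <- updates
  out
}

#' Generate a set of metamer boards
#'
#' Draws `n` boards, each from an independent Gibbs chain (fresh random
#' initialisation).  By default boards with fewer than `min_red` red tiles
#' are resampled (the tile-revealing environment needs at least 2 red
#' tiles); set `min_red = 0` for raw samples when doing statistics work.
#' `masked_net` models use a compiled fast path; any other conditional model
#' goes through the generic [gibbs_sweep()] machinery.
#'
#' @param model a conditional model.
#' @param n number of boards (`>= 1`).
#' @param config a [gibbs_config()]; its `seed` (default the session RNG)
#'   seeds the whole set.
#' @param min_red minimum red tiles per accepted board.
#' @param max_retries resampling cap per board.
#' @param rule_label rule attribute attached to the boards (conventionally
#'   `"<rule>_metamer"`).
#' @return list of `n` boards.
#' @export
generate_metamer_set <- function(model, n, config = gibbs_config(),
                                 min_red = 2L, max_retries = 100L,
                                 rule_label = NULL) {
  if (n < 1L) stop("n must be >= 1")
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (inherits(model, "masked_net")) {
    res <- cpp_gibbs_sample_net(model$weights, n, config$n_sweeps,
                                config$init_red_probability, min_red,
                                max_retries, seed)
    side <- as.integer(round(sqrt(model$n_cells)))
    boards <- lapply(seq_len(n), function(j) {
      b <- new_board(matrix(res$boards[, j], side, side), rule = rule_label,
                     board_id = if (is.null(rule_label)) NULL else
                       sprintf("%s-%04d", rule_label, j))
      attr(b, "updates") <- res$updates[j]
      b
    })
    return(boards)
  }
  lapply(seq_len(n), function(j) {
    cfg <- gibbs_config(config$n_sweeps, config$init_red_probability,
                        seed = seed + j - 1L)
    for (attempt in seq_len(max_retries + 1L)) {
      b <- gibbs_sample(model, cfg)
      if (sum(b) >= min_red) {
        attr(b, "rule") <- rule_label
        return(b)
      }
      cfg$seed <- NULL  # retries continue the RNG stream
    }
    stop(sprintf("Gibbs sampling: retry cap reached without a board of >= %d red tiles",
                 min_red))
  })
}
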
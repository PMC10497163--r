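#' Encode a board with one tile masked
#'
#' Builds the input representation of the masked-tile conditional network: the
#' 49 tile values (1 = red, 0 = blue) with the masked entry zeroed, followed
#' by a 49-length mask indicator that is 1 only at the masked position.
#' Tiles are indexed 1..49 column-major (R-native).
#'
#' @param board a [new_board()] object or 0/1 matrix.
#' @param mask_index tile position in `1..49`.
#' @return numeric vector of length 98.
#' @export
encode_masked <- function(board, mask_index) {
  vals <- as.numeric(as.matrix(board))
  n <- length(vals)
  if (length(mask_index) != 1L || mask_index < 1L || mask_index > n) {
    stop(sprintf("mask_index must be in 1..%d", n))
  }
  mask <- numeric(n)
  mask[mask_index] <- 1
  vals[mask_index] <- 0
  c(vals, mask)
}

#' Training configuration for the conditional network
#'
#' Defaults follow the masked-prediction training protocol: up to 4000
#' epochs with early stopping when the 5-epoch moving average of masked-tile
#' accuracy reaches 0.99.  One uniformly random tile is masked per example
#' per epoch, and the loss is binary cross-entropy summed over all 49
#' outputs against the full true board.
#'
#' @param max_epochs maximum training epochs.
#' @param early_stop_acc accuracy threshold for early stopping.
#' @param early_stop_window number of epochs averaged for early stopping.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed for weight init, masking, and shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(max_epochs = 4000L, early_stop_acc = 0.99,
                         early_stop_window = 5L, batch_size = 64L,
                         learning_rate = 1e-3, seed = 1L) {
  structure(list(max_epochs = as.integer(max_epochs),
                 early_stop_acc = early_stop_acc,
                 early_stop_window = as.integer(early_stop_window),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

boards_to_matrix <- function(boards) {
  if (is.list(boards)) {
    vapply(boards, function(b) as.integer(as.matrix(b)), integer(length(as.matrix(boards[[1]]))))
  } else {
    m <- as.matrix(boards)
    storage.mode(m) <- "integer"
    m
  }
}

#' Train the masked-tile conditional network
#'
#' Fits a fully connected network (3 hidden layers of 49 ReLU units, sigmoid
#' outputs) that maps a masked-board encoding (see [encode_masked()]) to
#' per-tile red-probabilities.  With enough boards from a structured rule the
#' masked-tile accuracy typically reaches 95-99%.
#'
#' @param boards either a list of boards, a 49 x n integer matrix (one board
#'   per column, column-major cells), or a zero-argument sampler function
#'   (drawn `n_boards` times).
#' @param config a [train_config()].
#' @param n_boards number of boards to draw when `boards` is a sampler.
#' @return object of class `masked_net` with elements `weights`, `accuracy`
#'   (per-epoch masked-tile accuracy history), `epochs`, and `config`.
#' @export
train_conditional_model <- function(boards, config = train_config(),
                                    n_boards = 5000L) {
  if (is.function(boards)) {
    boards <- replicate(n_boards, boards(), simplify = FALSE)
  }
  mat <- boards_to_matrix(boards)
  fit <- cpp_train_masked_net(mat, config$max_epochs, config$batch_size,
                              config$learning_rate, config$early_stop_acc,
                              config$early_stop_window, config$seed)
  if (any(!is.finite(fit$accuracy))) {
    stop("conditional-model training produced non-finite accuracy")
  }
  structure(list(weights = fit$weights, accuracy = fit$accuracy,
                 epochs = fit$epochs, config = config,
                 n_cells = nrow(mat)),
            class = c("masked_net", "conditional_model"))
}

#' @export
print.masked_net <- function(x, ...) {
  cat(sprintf(
    "masked-tile conditional network: %d cells, %d epochs, final accuracy %.3f\n",
    x$n_cells, x$epochs, x$accuracy[length(x$accuracy)]))
  invisible(x)
}

#' Conditional red-probability of one masked tile
#'
#' Generic interface used by the Gibbs sampler: given the current grid values
#' and a masked position, return the model's probability that the masked tile
#' is red.  `masked_net` objects implement it via the trained network;
#' hand-built models (e.g. exact conditionals of a small known joint) can
#' supply their own method.
#'
#' @param model a conditional model.
#' @param grid numeric vector of current tile values (0/1), column-major.
#' @param mask_index tile position to predict.
#' @return probability in `[0, 1]`.
#' @export
predict_tile_prob <- function(model, grid, mask_index) {
  UseMethod("predict_tile_prob")
}

#' @export
predict_tile_prob.masked_net <- function(model, grid, mask_index) {
  n <- model$n_cells
  x <- numeric(2L * n)
  x[seq_len(n)] <- grid
  x[mask_index] <- 0
  x[n + mask_index] <- 1
  p <- cpp_masked_net_predict(model$weights, matrix(x, ncol = 1L))[mask_index, 1L]
  as.numeric(p)
}

#' Full predicted board from a masked encoding
#'
#' Runs the network on a masked board and returns all 49 red-probabilities
#' (the network is trained to reproduce the entire board).
#'
#' @param model a `masked_net`.
#' @param board board or 0/1 matrix.
#' @param mask_index masked tile position.
#' @return numeric vector of 49 probabilities.
#' @export
predict_board_probs <- function(model, board, mask_index) {
  x <- encode_masked(board, mask_index)
  as.numeric(cpp_masked_net_predict(model$weights, matrix(x, ncol = 1L)))
}

#' Masked-tile prediction accuracy
#'
#' Fraction of boards for which the model's red-probability at one uniformly
#' random masked position, thresholded at 0.5, matches the true colour.
#'
#' @param model a conditional model.
#' @param boards list of boards or 49 x n matrix.
#' @param seed optional seed for the random mask positions.
#' @return fraction in `[0, 1]`.
#' @export
masked_accuracy <- function(model, boards, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- boards_to_matrix(boards)
  n_cells <- nrow(mat)
  n <- ncol(mat)
  if (n == 0L) stop("boards must be non-empty")
  masks <- sample.int(n_cells, n, replace = TRUE)
  if (inherits(model, "masked_net")) {
    X <- matrix(0, 2L * n_cells, n)
    for (j in seq_len(n)) {
      X[seq_len(n_cells), j] <- mat[, j]
      X[masks[j], j] <- 0
      X[n_cells + masks[j], j] <- 1
    }
    P <- cpp_masked_net_predict(model$weights, X)
    preds <- P[cbind(masks, seq_len(n))] >= 0.5
  } else {
    preds <- vapply(seq_len(n), function(j) {
      predict_tile_prob(model, as.numeric(mat[, j]), masks[j]) >= 0.5
    }, logical(1))
  }
  mean(preds == (mat[cbind(masks, seq_len(n))] == 1L))
}
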
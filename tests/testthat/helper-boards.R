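# shared fixtures built in code

# board with the given red cells (matrix of [row, col] pairs)
board_from_cells <- function(cells, rule = NULL) {
  g <- matrix(0L, 7L, 7L)
  g[cells] <- 1L
  new_board(g, rule = rule)
}

filled_rect_board <- function(r0, c0, h, w) {
  g <- matrix(0L, 7L, 7L)
  g[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
  new_board(g, rule = "rectangle")
}

checkerboard <- function() {
  matrix(as.integer(outer(1:7, 1:7, function(r, c) (r + c) %% 2L)), 7L, 7L)
}

# all filled axis-aligned rectangles with both sides >= 2 on the 7x7 grid,
# as an exhaustive oracle for the rectangle validator
all_rectangle_boards <- function() {
  out <- list()
  for (h in 2:7) for (w in 2:7) {
    for (r0 in 1:(7 - h + 1)) for (c0 in 1:(7 - w + 1)) {
      out[[length(out) + 1L]] <- filled_rect_board(r0, c0, h, w)
    }
  }
  out
}

# cached conditional model trained on rectangle boards, shared across tests
# that need a trained metamer model (training it once keeps the suite fast)
.model_cache <- new.env(parent = emptyenv())
get_rectangle_model <- function(n_boards = 5000L, seed = 101L) {
  key <- sprintf("rect-%d-%d", n_boards, seed)
  if (is.null(.model_cache[[key]])) {
    set.seed(seed)
    boards <- replicate(n_boards, generate_board("rectangle"),
                        simplify = FALSE)
    .model_cache[[key]] <- list(
      model = train_conditional_model(boards, train_config(seed = seed)),
      boards = boards)
  }
  .model_cache[[key]]
}
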
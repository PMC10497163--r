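#' Board objects
#'
#' A board is a 7x7 integer matrix of tile colours, coded `1` = red and
#' `0` = blue, with optional `rule` and `board_id` attributes.  One board
#' defines one task instance of the tile-revealing game: the red set is the
#' target the player must uncover.  Every board carries at least 2 red tiles
#' so that an episode always starts with one red revealed and at least one
#' left to find.
#'
#' @param grid integer matrix of 0/1 values.
#' @param rule optional abstraction label (see [abstraction_rules()]).
#' @param board_id optional stable identifier string.
#' @return an object of class `board` (an integer matrix with attributes).
#' @export
new_board <- function(grid, rule = NULL, board_id = NULL) {
  grid <- as.matrix(grid)
  if (!all(grid %in% c(0L, 1L))) {
    stop("board grid must contain only 0 (blue) and 1 (red) values")
  }
  storage.mode(grid) <- "integer"
  structure(grid, rule = rule, board_id = board_id,
            class = c("board", class(grid)))
}

#' @export
print.board <- function(x, ...) {
  rule <- attr(x, "rule")
  id <- attr(x, "board_id")
  cat(sprintf("board %s%s(%d red / %d blue)\n",
              if (is.null(id)) "" else paste0("<", id, "> "),
              if (is.null(rule)) "" else paste0("[", rule, "] "),
              sum(x == 1L), sum(x == 0L)))
  for (r in seq_len(nrow(x))) {
    cat(paste(ifelse(x[r, ] == 1L, "#", "."), collapse = " "), "\n")
  }
  invisible(x)
}

#' Names of the eight abstraction rules
#'
#' Four rules (copy, symmetry, rectangle, connected) follow classic
#' perceptron-hard predicates; the other four (tree, pyramid, cross, zigzag)
#' are simple geometric structures.  Each rule has a paired generator
#' ([generate_board()]) and validator ([is_valid()]).
#'
#' @return character vector of rule identifiers.
#' @export
abstraction_rules <- function() {
  c("copy", "symmetry", "rectangle", "connected",
    "tree", "pyramid", "cross", "zigzag")
}

check_rule <- function(rule) {
  if (length(rule) != 1L || !rule %in% abstraction_rules()) {
    stop(sprintf("unknown rule '%s'; must be one of: %s",
                 paste(rule, collapse = ","),
                 paste(abstraction_rules(), collapse = ", ")))
  }
  rule
}

BOARD_N <- 7L

empty_grid <- function() matrix(0L, BOARD_N, BOARD_N)

# draw one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x) x[[sample.int(length(x), 1L)]]

## ---- generators ------------------------------------------------------------
## All generators draw from the session RNG; fix reproducibility with
## set.seed() or the seed arguments of the higher-level entry points.

gen_rectangle <- function() {
  h <- sample(2:5, 1L)
  w <- sample(2:5, 1L)
  r0 <- sample.int(BOARD_N - h + 1L, 1L)
  c0 <- sample.int(BOARD_N - w + 1L, 1L)
  g <- empty_grid()
  g[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
  g
}

gen_cross <- function() {
  # centre interior to both segments: all four arms have length >= 1
  r <- sample(2:6, 1L)
  c <- sample(2:6, 1L)
  left <- sample.int(c - 1L, 1L)
  right <- sample.int(BOARD_N - c, 1L)
  up <- sample.int(r - 1L, 1L)
  down <- sample.int(BOARD_N - r, 1L)
  g <- empty_grid()
  g[r, (c - left):(c + right)] <- 1L
  g[(r - up):(r + down), c] <- 1L
  g
}

gen_pyramid <- function() {
  w <- sample(c(3L, 5L, 7L), 1L)
  h <- (w + 1L) %/% 2L              # number of stacked rows
  half <- (w - 1L) %/% 2L
  cc <- sample1(seq.int(half + 1L, BOARD_N - half))   # centre column
  rb <- sample1(seq.int(h, BOARD_N))                  # base row
  g <- empty_grid()
  for (k in 0:(h - 1L)) {
    hw <- (w - 2L * k - 1L) %/% 2L
    g[rb - k, (cc - hw):(cc + hw)] <- 1L
  }
  g
}

# grow a random 4-connected blob of `size` cells inside the given row/col ranges
grow_blob <- function(size, rows, cols) {
  cells <- matrix(c(sample(rows, 1L), sample(cols, 1L)), ncol = 2L)
  while (nrow(cells) < size) {
    base <- cells[sample.int(nrow(cells), 1L), ]
    nb <- rbind(base + c(-1L, 0L), base + c(1L, 0L),
                base + c(0L, -1L), base + c(0L, 1L))
    nb <- nb[nb[, 1L] >= min(rows) & nb[, 1L] <= max(rows) &
             nb[, 2L] >= min(cols) & nb[, 2L] <= max(cols), , drop = FALSE]
    if (nrow(nb) == 0L) next
    cand <- nb[sample.int(nrow(nb), 1L), ]
    if (!any(cells[, 1L] == cand[1L] & cells[, 2L] == cand[2L])) {
      cells <- rbind(cells, cand)
    }
  }
  cells
}

gen_symmetry <- function() {
  # blob in the left half (columns 1..4) mirrored about the centre column 4
  blob <- grow_blob(sample(3:7, 1L), 1:BOARD_N, 1:4)
  g <- empty_grid()
  g[blob] <- 1L
  mirror <- cbind(blob[, 1L], BOARD_N + 1L - blob[, 2L])
  g[mirror] <- 1L
  g
}

gen_copy <- function() {
  for (i in seq_len(200L)) {
    shape <- grow_blob(sample(3:6, 1L), 1:BOARD_N, 1:BOARD_N)
    shape[, 1L] <- shape[, 1L] - min(shape[, 1L])   # normalise to origin 0
    shape[, 2L] <- shape[, 2L] - min(shape[, 2L])
    bh <- max(shape[, 1L]) + 1L
    bw <- max(shape[, 2L]) + 1L
    if (bh > BOARD_N || bw > BOARD_N) next
    r1 <- sample.int(BOARD_N - bh + 1L, 1L)
    c1 <- sample.int(BOARD_N - bw + 1L, 1L)
    dr <- sample.int(2L * (BOARD_N - bh) + 1L, 1L) - (BOARD_N - bh) - 1L
    dc <- sample.int(2L * (BOARD_N - bw) + 1L, 1L) - (BOARD_N - bw) - 1L
    if (dr == 0L && dc == 0L) next
    r2 <- r1 + dr; c2 <- c1 + dc
    if (r2 < 1L || c2 < 1L || r2 + bh - 1L > BOARD_N || c2 + bw - 1L > BOARD_N) next
    a <- cbind(shape[, 1L] + r1, shape[, 2L] + c1)
    b <- cbind(shape[, 1L] + r2, shape[, 2L] + c2)
    # copies must not overlap nor touch edge-wise, so that the two
    # components remain identifiable
    keys_a <- a[, 1L] * 100L + a[, 2L]
    near_b <- c(b[, 1L] * 100L + b[, 2L],
                (b[, 1L] - 1L) * 100L + b[, 2L], (b[, 1L] + 1L) * 100L + b[, 2L],
                b[, 1L] * 100L + b[, 2L] - 1L, b[, 1L] * 100L + b[, 2L] + 1L)
    if (any(keys_a %in% near_b)) next
    g <- empty_grid()
    g[a] <- 1L
    g[b] <- 1L
    return(g)
  }
  stop("copy generator failed to place two disjoint copies within 200 attempts")
}

gen_connected <- function() {
  h <- sample(3:6, 1L)
  w <- sample(3:6, 1L)
  r0 <- sample.int(BOARD_N - h + 1L, 1L)
  c0 <- sample.int(BOARD_N - w + 1L, 1L)
  g <- empty_grid()
  g[r0:(r0 + h - 1L), c(c0, c0 + w - 1L)] <- 1L
  g[c(r0, r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
  g
}

gen_tree <- function() {
  d <- sample(2:3, 1L)
  c0 <- sample1(seq.int(d + 1L, BOARD_N - d))
  g <- empty_grid()
  g[1L, c0] <- 1L
  for (k in seq_len(d)) {
    g[1L + k, c0 - k] <- 1L
    g[1L + k, c0 + k] <- 1L
  }
  g
}

# deterministic zigzag path: one red per column, rows step by +/-1,
# direction alternating with the given period and reflecting at borders
zigzag_rows <- function(r0, dir, period) {
  rows <- integer(BOARD_N)
  rows[1L] <- r0
  phase <- 0L
  for (cc in 2:BOARD_N) {
    if (phase == period) { dir <- -dir; phase <- 0L }
    if (rows[cc - 1L] + dir < 1L || rows[cc - 1L] + dir > BOARD_N) {
      dir <- -dir; phase <- 0L
    }
    rows[cc] <- rows[cc - 1L] + dir
    phase <- phase + 1L
  }
  rows
}

zigzag_family <- function() {
  boards <- list()
  for (r0 in 1:BOARD_N) for (dir in c(-1L, 1L)) for (p in 1:2) {
    g <- empty_grid()
    g[cbind(zigzag_rows(r0, dir, p), 1:BOARD_N)] <- 1L
    boards[[length(boards) + 1L]] <- g
  }
  boards
}

gen_zigzag <- function() {
  r0 <- sample.int(BOARD_N, 1L)
  dir <- sample(c(-1L, 1L), 1L)
  p <- sample(1:2, 1L)
  g <- empty_grid()
  g[cbind(zigzag_rows(r0, dir, p), 1:BOARD_N)] <- 1L
  g
}

## ---- validators ------------------------------------------------------------

red_cells <- function(grid) which(grid == 1L, arr.ind = TRUE)

validate_rectangle <- function(grid) {
  rc <- red_cells(grid)
  if (nrow(rc) == 0L) return(FALSE)
  rr <- range(rc[, 1L]); cr <- range(rc[, 2L])
  h <- diff(rr) + 1L; w <- diff(cr) + 1L
  h >= 2L && w >= 2L && nrow(rc) == h * w &&
    all(grid[rr[1L]:rr[2L], cr[1L]:cr[2L]] == 1L)
}

validate_cross <- function(grid) {
  rc <- red_cells(grid)
  if (nrow(rc) < 5L) return(FALSE)
  # the centre is the unique red tile whose four orthogonal neighbours are red
  is_red <- function(r, c) r >= 1L && r <= BOARD_N && c >= 1L && c <= BOARD_N && grid[r, c] == 1L
  centre <- NULL
  for (i in seq_len(nrow(rc))) {
    r <- rc[i, 1L]; c <- rc[i, 2L]
    if (is_red(r - 1L, c) && is_red(r + 1L, c) && is_red(r, c - 1L) && is_red(r, c + 1L)) {
      if (!is.null(centre)) return(FALSE)
      centre <- c(r, c)
    }
  }
  if (is.null(centre)) return(FALSE)
  r <- centre[1L]; c <- centre[2L]
  a <- c; while (a > 1L && grid[r, a - 1L] == 1L) a <- a - 1L
  b <- c; while (b < BOARD_N && grid[r, b + 1L] == 1L) b <- b + 1L
  u <- r; while (u > 1L && grid[u - 1L, c] == 1L) u <- u - 1L
  d <- r; while (d < BOARD_N && grid[d + 1L, c] == 1L) d <- d + 1L
  expected <- empty_grid()
  expected[r, a:b] <- 1L
  expected[u:d, c] <- 1L
  (b - a + 1L) >= 3L && (d - u + 1L) >= 3L && identical(expected, unclass_grid(grid))
}

unclass_grid <- function(grid) {
  g <- grid
  attributes(g) <- list(dim = dim(grid))
  storage.mode(g) <- "integer"
  g
}

validate_pyramid <- function(grid) {
  rc <- red_cells(grid)
  if (nrow(rc) == 0L) return(FALSE)
  rows <- sort(unique(rc[, 1L]))
  if (!identical(rows, seq(min(rows), max(rows)))) return(FALSE)
  rb <- max(rows)
  base_cols <- rc[rc[, 1L] == rb, 2L]
  w <- length(base_cols)
  if (!w %in% c(3L, 5L, 7L)) return(FALSE)
  if (length(rows) != (w + 1L) %/% 2L) return(FALSE)
  cc <- (min(base_cols) + max(base_cols)) / 2
  if (cc != round(cc)) return(FALSE)
  expected <- empty_grid()
  for (k in 0:(length(rows) - 1L)) {
    hw <- (w - 2L * k - 1L) %/% 2L
    expected[rb - k, (cc - hw):(cc + hw)] <- 1L
  }
  identical(expected, unclass_grid(grid))
}

validate_symmetry <- function(grid) {
  any(grid == 1L) && identical(unclass_grid(grid), unclass_grid(grid[, BOARD_N:1L]))
}

# 4-connected components of the red set; returns list of cell matrices
red_components <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  comp <- list()
  for (start in seq_along(grid)) {
    if (grid[start] != 1L || lab[start] != 0L) next
    id <- length(comp) + 1L
    queue <- start
    lab[start] <- id
    cells <- start
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      r <- (cur - 1L) %% nrow(grid) + 1L
      c <- (cur - 1L) %/% nrow(grid) + 1L
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nr <- r + dd[1L]; nc <- c + dd[2L]
        if (nr < 1L || nr > nrow(grid) || nc < 1L || nc > ncol(grid)) next
        ni <- (nc - 1L) * nrow(grid) + nr
        if (grid[ni] == 1L && lab[ni] == 0L) {
          lab[ni] <- id
          queue <- c(queue, ni)
          cells <- c(cells, ni)
        }
      }
    }
    comp[[id]] <- cbind((cells - 1L) %% nrow(grid) + 1L,
                        (cells - 1L) %/% nrow(grid) + 1L)
  }
  comp
}

normalise_cells <- function(cells) {
  cells[, 1L] <- cells[, 1L] - min(cells[, 1L])
  cells[, 2L] <- cells[, 2L] - min(cells[, 2L])
  cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
}

validate_copy <- function(grid) {
  comp <- red_components(grid)
  if (length(comp) != 2L) return(FALSE)
  if (nrow(comp[[1L]]) != nrow(comp[[2L]])) return(FALSE)
  identical(normalise_cells(comp[[1L]]), normalise_cells(comp[[2L]]))
}

validate_connected <- function(grid) {
  rc <- red_cells(grid)
  if (nrow(rc) < 4L) return(FALSE)
  # simple cycle: every red tile has exactly 2 red 4-neighbours, one component
  deg <- function(r, c) {
    s <- 0L
    if (r > 1L && grid[r - 1L, c] == 1L) s <- s + 1L
    if (r < BOARD_N && grid[r + 1L, c] == 1L) s <- s + 1L
    if (c > 1L && grid[r, c - 1L] == 1L) s <- s + 1L
    if (c < BOARD_N && grid[r, c + 1L] == 1L) s <- s + 1L
    s
  }
  for (i in seq_len(nrow(rc))) {
    if (deg(rc[i, 1L], rc[i, 2L]) != 2L) return(FALSE)
  }
  if (length(red_components(grid)) != 1L) return(FALSE)
  # the cycle must enclose at least one blue tile: flood-fill blue from the
  # border; any unreachable blue tile is enclosed
  reach <- matrix(FALSE, BOARD_N, BOARD_N)
  queue <- integer(0)
  for (r in 1:BOARD_N) for (c in 1:BOARD_N) {
    if ((r == 1L || r == BOARD_N || c == 1L || c == BOARD_N) && grid[r, c] == 0L) {
      if (!reach[r, c]) { reach[r, c] <- TRUE; queue <- c(queue, (c - 1L) * BOARD_N + r) }
    }
  }
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    r <- (cur - 1L) %% BOARD_N + 1L
    c <- (cur - 1L) %/% BOARD_N + 1L
    for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- r + dd[1L]; nc <- c + dd[2L]
      if (nr < 1L || nr > BOARD_N || nc < 1L || nc > BOARD_N) next
      if (grid[nr, nc] == 0L && !reach[nr, nc]) {
        reach[nr, nc] <- TRUE
        queue <- c(queue, (nc - 1L) * BOARD_N + nr)
      }
    }
  }
  any(grid == 0L & !reach)
}

validate_tree <- function(grid) {
  rc <- red_cells(grid)
  if (nrow(rc) < 5L) return(FALSE)
  top <- rc[rc[, 1L] == min(rc[, 1L]), , drop = FALSE]
  if (nrow(top) != 1L || top[1L, 1L] != 1L) return(FALSE)
  c0 <- top[1L, 2L]
  d <- max(rc[, 1L]) - 1L
  if (!d %in% c(2L, 3L)) return(FALSE)
  expected <- empty_grid()
  expected[1L, c0] <- 1L
  for (k in seq_len(d)) {
    if (c0 - k < 1L || c0 + k > BOARD_N) return(FALSE)
    expected[1L + k, c0 - k] <- 1L
    expected[1L + k, c0 + k] <- 1L
  }
  identical(expected, unclass_grid(grid))
}

validate_zigzag <- function(grid) {
  g <- unclass_grid(grid)
  for (fam in zigzag_family()) {
    if (identical(fam, g)) return(TRUE)
  }
  FALSE
}

## ---- public API ------------------------------------------------------------

#' Generate one board from an abstraction rule
#'
#' Draws a board from the named rule's generative distribution.  The result
#' always satisfies [is_valid()] for that rule and carries at least 2 red
#' tiles.  Generators are pure functions of the rule parameters and the RNG
#' state, so `set.seed()` gives reproducible boards.
#'
#' @param rule one of [abstraction_rules()].
#' @param board_id optional identifier attached to the board.
#' @return a [new_board()] object.
#' @examples
#' set.seed(1)
#' b <- generate_board("rectangle")
#' is_valid("rectangle", b)
#' @export
generate_board <- function(rule, board_id = NULL) {
  check_rule(rule)
  gen <- switch(rule,
    rectangle = gen_rectangle, cross = gen_cross, pyramid = gen_pyramid,
    symmetry = gen_symmetry, copy = gen_copy, connected = gen_connected,
    tree = gen_tree, zigzag = gen_zigzag)
  for (i in seq_len(10000L)) {
    g <- gen()
    if (sum(g) >= 2L) {
      return(new_board(g, rule = rule, board_id = board_id))
    }
  }
  stop(sprintf("rule '%s': rejection sampling cap (10000) exceeded", rule))
}

#' Check a board against a rule's defining predicate
#'
#' Pure structural test of whether the red set satisfies the rule.  The
#' validators are written independently of the generators (except zigzag,
#' which enumerates its 28-member family), so they serve as oracles for the
#' generators in the test suite.
#'
#' @param rule one of [abstraction_rules()].
#' @param board a [new_board()] object or a 0/1 matrix.
#' @return logical scalar.
#' @export
is_valid <- function(rule, board) {
  check_rule(rule)
  grid <- unclass_grid(as.matrix(board))
  if (!identical(dim(grid), c(BOARD_N, BOARD_N))) {
    stop("board must be a 7x7 grid")
  }
  validator <- switch(rule,
    rectangle = validate_rectangle, cross = validate_cross,
    pyramid = validate_pyramid, symmetry = validate_symmetry,
    copy = validate_copy, connected = validate_connected,
    tree = validate_tree, zigzag = validate_zigzag)
  isTRUE(validator(grid))
}

board_key <- function(board) paste(as.integer(board), collapse = "")

#' Build a training sampler and a held-out test set for one rule
#'
#' The test boards are pairwise distinct and the training sampler never
#' yields a board equal to any test board, mirroring evaluation on held-out
#' grids unseen during training.
#'
#' @param rule one of [abstraction_rules()].
#' @param n_train nominal training-set size (samplers are unbounded; kept for
#'   bookkeeping in experiment configs).
#' @param n_test number of held-out test boards (`>= 1`).
#' @param seed optional integer seed applied before sampling.
#' @param max_attempts cap on draws while collecting distinct test boards.
#' @return list with elements `sampler` (a zero-argument function returning a
#'   fresh training board), `test` (list of boards), and `rule`.
#' @export
generate_distribution <- function(rule, n_train = 1000L, n_test = 25L,
                                  seed = NULL, max_attempts = 10000L) {
  check_rule(rule)
  if (n_test < 1L) stop("n_test must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  test <- list()
  keys <- character(0)
  attempts <- 0L
  while (length(test) < n_test) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "rule '%s': could not collect %d distinct test boards in %d draws (support too small?)",
        rule, n_test, max_attempts))
    }
    b <- generate_board(rule)
    k <- board_key(b)
    if (!k %in% keys) {
      keys <- c(keys, k)
      attr(b, "board_id") <- sprintf("%s-%04d", rule, length(test) + 1L)
      test[[length(test) + 1L]] <- b
    }
  }
  test_keys <- keys
  sampler <- function() {
    for (i in seq_len(10000L)) {
      b <- generate_board(rule)
      if (!board_key(b) %in% test_keys) return(b)
    }
    stop(sprintf("rule '%s': training sampler exhausted 10000 rejections", rule))
  }
  list(rule = rule, sampler = sampler, test = test, n_train = n_train)
}

#' Uniform mixture sampler over several rules
#'
#' Each draw first picks a rule uniformly at random, then samples a board
#' from that rule (through the rule's training sampler when `exclude` test
#' keys are supplied).
#'
#' @param rules non-empty character vector of rule names.
#' @param exclude optional list of boards the sampler must never emit
#'   (e.g. the union of held-out test sets).
#' @return zero-argument function returning a fresh board.
#' @export
mixture_sampler <- function(rules, exclude = NULL) {
  if (length(rules) == 0L) stop("mixture_sampler needs a non-empty rule list")
  for (r in rules) check_rule(r)
  excl_keys <- if (is.null(exclude)) character(0) else
    vapply(exclude, board_key, character(1))
  function() {
    rule <- rules[[sample.int(length(rules), 1L)]]
    for (i in seq_len(10000L)) {
      b <- generate_board(rule)
      if (!board_key(b) %in% excl_keys) return(b)
    }
    stop("mixture sampler exhausted 10000 rejections")
  }
}
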
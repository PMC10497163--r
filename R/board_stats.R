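#' Low-order board statistics
#'
#' Integer summary statistics used to verify that a metamer distribution
#' matches its parent rule-based distribution:
#' * `order1(board)` — number of red tiles minus number of blue tiles.
#' * `order2(board)` — number of matching (same-colour) adjacent pairs minus
#'   the number of non-matching pairs.  Adjacency is the 4-neighbourhood by
#'   default; `neighbourhood = 8` adds diagonal pairs.
#' * `order3(board)` — number of matching collinear triples (a tile, its
#'   neighbour, and its neighbour's neighbour, in a row or column) minus the
#'   number of non-matching triples.  A triple matches only when all three
#'   tiles share a colour.  `triples = "bent"` additionally counts L-shaped
#'   3-step chains.
#'
#' On a 7x7 board: `order1` lies in `[-49, 49]` (odd), `order2` in
#' `[-84, 84]` (42 horizontal + 42 vertical pairs), and `order3` in
#' `[-70, 70]` (35 horizontal + 35 vertical collinear triples).
#'
#' @param board a 0/1 matrix (any size).
#' @param neighbourhood 4 (default) or 8; pair adjacency for `order2`.
#' @param triples `"collinear"` (default) or `"bent"`.
#' @return integer scalar.
#' @examples
#' b <- matrix(1L, 7, 7)
#' order1(b)  # 49
#' order2(b)  # 84
#' order3(b)  # 70
#' @name board_statistics
NULL

#' @rdname board_statistics
#' @export
order1 <- function(board) {
  g <- as.matrix(board)
  as.integer(2L * sum(g == 1L) - length(g))
}

#' @rdname board_statistics
#' @export
order2 <- function(board, neighbourhood = 4L) {
  g <- as.matrix(board)
  nr <- nrow(g); nc <- ncol(g)
  m <- sum(g[, -nc, drop = FALSE] == g[, -1L, drop = FALSE]) +
       sum(g[-nr, , drop = FALSE] == g[-1L, , drop = FALSE])
  total <- nr * (nc - 1L) + (nr - 1L) * nc
  if (neighbourhood == 8L) {
    m <- m + sum(g[-nr, -nc, drop = FALSE] == g[-1L, -1L, drop = FALSE]) +
             sum(g[-nr, -1L, drop = FALSE] == g[-1L, -nc, drop = FALSE])
    total <- total + 2L * (nr - 1L) * (nc - 1L)
  } else if (neighbourhood != 4L) {
    stop("neighbourhood must be 4 or 8")
  }
  as.integer(2L * m - total)
}

#' @rdname board_statistics
#' @export
order3 <- function(board, triples = c("collinear", "bent")) {
  triples <- match.arg(triples)
  g <- as.matrix(board)
  nr <- nrow(g); nc <- ncol(g)
  mono <- function(a, b, c) sum(a == b & b == c)
  m <- 0L; total <- 0L
  if (nc >= 3L) {
    m <- m + mono(g[, 1:(nc - 2L), drop = FALSE],
                  g[, 2:(nc - 1L), drop = FALSE],
                  g[, 3:nc, drop = FALSE])
    total <- total + nr * (nc - 2L)
  }
  if (nr >= 3L) {
    m <- m + mono(g[1:(nr - 2L), , drop = FALSE],
                  g[2:(nr - 1L), , drop = FALSE],
                  g[3:nr, , drop = FALSE])
    total <- total + (nr - 2L) * nc
  }
  if (triples == "bent") {
    # L-shaped chains i-j-k where j is 4-adjacent to both and i != k;
    # each unordered chain counted once via its four orientations
    shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    cells <- which(array(TRUE, dim(g)), arr.ind = TRUE)
    for (j in seq_len(nrow(cells))) {
      r <- cells[j, 1L]; c <- cells[j, 2L]
      nb <- list()
      for (s in shifts) {
        nr2 <- r + s[1L]; nc2 <- c + s[2L]
        if (nr2 >= 1L && nr2 <= nr && nc2 >= 1L && nc2 <= nc) {
          nb[[length(nb) + 1L]] <- c(nr2, nc2)
        }
      }
      if (length(nb) < 2L) next
      for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
        i <- nb[[a]]; k <- nb[[b]]
        if (i[1L] == k[1L] || i[2L] == k[2L]) next  # collinear already counted
        total <- total + 1L
        if (g[i[1L], i[2L]] == g[r, c] && g[r, c] == g[k[1L], k[2L]]) m <- m + 1L
      }
    }
  }
  as.integer(2L * m - total)
}

#' All three order statistics of a board
#'
#' @param board a 0/1 matrix.
#' @return named integer vector with elements `order1`, `order2`, `order3`.
#' @export
board_stats <- function(board) {
  c(order1 = order1(board), order2 = order2(board), order3 = order3(board))
}

#' Two-sample comparison of statistic distributions
#'
#' Compares two samples of a board statistic, as used to check that a metamer
#' distribution is statistically indistinguishable from its abstract parent.
#' The default is a label-permutation test on the difference of means with an
#' add-one-corrected two-sided p-value, which is exact under exchangeability;
#' `method = "welch_t"` gives Welch's two-sided t-test.
#'
#' @param samples_a,samples_b numeric vectors (non-empty).
#' @param method `"permutation"` or `"welch_t"`.
#' @param n_permutations number of label resamples for the permutation test.
#' @return list of class `dist_comparison` with `statistic` (difference of
#'   means, or t for Welch), `p_value`, `method`, and `n_permutations`.
#' @export
compare_distributions <- function(samples_a, samples_b,
                                  method = c("permutation", "welch_t"),
                                  n_permutations = 10000L) {
  method <- match.arg(method)
  if (length(samples_a) == 0L || length(samples_b) == 0L) {
    stop("both samples must be non-empty")
  }
  if (method == "welch_t") {
    if (length(samples_a) < 2L || length(samples_b) < 2L) {
      stop("welch_t needs at least 2 observations per sample")
    }
    tt <- stats::t.test(samples_a, samples_b, var.equal = FALSE)
    out <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                method = "welch_t", n_permutations = NA_integer_)
  } else {
    pooled <- c(samples_a, samples_b)
    na <- length(samples_a)
    obs <- mean(samples_a) - mean(samples_b)
    nb <- length(samples_b)
    # mean(a*) - mean(b*) is a linear function of sum(a*); resample labels
    perm <- vapply(seq_len(n_permutations), function(i) {
      sa <- sum(pooled[sample.int(na + nb, na)])
      sa / na - (sum(pooled) - sa) / nb
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_permutations)
    out <- list(statistic = obs, p_value = p,
                method = "permutation", n_permutations = n_permutations)
  }
  structure(out, class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat(sprintf("two-sample comparison (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}
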
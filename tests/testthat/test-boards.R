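test_that("generated boards satisfy their own rule validator", {
  set.seed(11)
  for (rule in abstraction_rules()) {
    boards <- replicate(100, generate_board(rule), simplify = FALSE)
    expect_true(all(vapply(boards, function(b) is_valid(rule, b), logical(1))),
                label = sprintf("all %s boards valid", rule))
    expect_true(all(vapply(boards, function(b) sum(b) >= 2L, logical(1))),
                label = sprintf("all %s boards have >= 2 red", rule))
    expect_true(all(vapply(boards, function(b)
      identical(dim(as.matrix(b)), c(7L, 7L)), logical(1))))
  }
})

test_that("unknown rules are rejected by name", {
  expect_error(generate_board("circle"), "circle")
  expect_error(is_valid("circle", matrix(0L, 7, 7)), "circle")
})

test_that("rectangle validator agrees with exhaustive rectangle enumeration", {
  rects <- all_rectangle_boards()
  expect_true(all(vapply(rects, function(b) is_valid("rectangle", b),
                         logical(1))))
  # the generated red set must be one of the enumerated rectangles
  keys <- vapply(rects, function(b) paste(as.integer(b), collapse = ""),
                 character(1))
  set.seed(21)
  for (i in 1:50) {
    b <- generate_board("rectangle")
    expect_true(paste(as.integer(b), collapse = "") %in% keys)
  }
  # a rectangle minus a corner is not a rectangle
  b <- filled_rect_board(1, 1, 2, 3)
  g <- as.matrix(b)
  g[1, 1] <- 0L
  expect_false(is_valid("rectangle", g))
  # 1-wide strips are not rectangles under the sides >= 2 convention
  g2 <- matrix(0L, 7, 7); g2[3, 2:5] <- 1L
  expect_false(is_valid("rectangle", g2))
})

test_that("cross validator accepts exactly the one-intersection plus shapes", {
  # oracle: enumerate segment pairs sharing exactly one interior tile
  set.seed(31)
  for (i in 1:30) {
    b <- generate_board("cross")
    g <- as.matrix(b)
    rows_with <- which(rowSums(g) > 1L)
    cols_with <- which(colSums(g) > 1L)
    expect_length(rows_with, 1L)
    expect_length(cols_with, 1L)
    # intersection is red and interior: 4 red neighbours
    r <- rows_with; c <- cols_with
    expect_equal(g[r, c], 1L)
    expect_equal(g[r - 1L, c] + g[r + 1L, c] + g[r, c - 1L] + g[r, c + 1L], 4L)
  }
  # T-shape (intersection at a segment end) is rejected
  g <- matrix(0L, 7, 7)
  g[3, 2:5] <- 1L
  g[3:6, 3] <- 1L          # vertical arm starts at the horizontal row
  expect_false(is_valid("cross", g))
})

test_that("symmetry validator is exactly mirror symmetry about the centre column", {
  g <- matrix(0L, 7, 7)
  g[2, 2] <- 1L; g[2, 6] <- 1L; g[4, 4] <- 1L
  expect_true(is_valid("symmetry", g))
  g[2, 6] <- 0L
  expect_false(is_valid("symmetry", g))
  expect_false(is_valid("symmetry", matrix(0L, 7, 7)))
})

test_that("structured-rule validators reject shuffled boards almost surely", {
  set.seed(41)
  for (rule in c("rectangle", "cross", "pyramid", "symmetry", "connected")) {
    fail_rate <- mean(vapply(1:300, function(i) {
      b <- generate_board(rule)
      shuffled <- matrix(sample(as.integer(b)), 7L, 7L)
      !is_valid(rule, shuffled)
    }, logical(1)))
    expect_gte(fail_rate, 0.99)
  }
})

test_that("generators are deterministic given the seed", {
  for (rule in abstraction_rules()) {
    set.seed(77)
    a <- generate_board(rule)
    set.seed(77)
    b <- generate_board(rule)
    expect_identical(as.integer(a), as.integer(b))
  }
})

test_that("generate_distribution holds out a distinct, excluded test set", {
  dist <- generate_distribution("rectangle", n_test = 25, seed = 5)
  keys <- vapply(dist$test, function(b) paste(as.integer(b), collapse = ""),
                 character(1))
  expect_length(unique(keys), 25L)
  expect_true(all(vapply(dist$test, function(b) is_valid("rectangle", b),
                         logical(1))))
  set.seed(6)
  draws <- replicate(500, dist$sampler(), simplify = FALSE)
  draw_keys <- vapply(draws, function(b) paste(as.integer(b), collapse = ""),
                      character(1))
  expect_false(any(draw_keys %in% keys))
  expect_true(all(vapply(draws, function(b) is_valid("rectangle", b),
                         logical(1))))
  # same seed twice -> identical test list
  dist2 <- generate_distribution("rectangle", n_test = 25, seed = 5)
  keys2 <- vapply(dist2$test, function(b) paste(as.integer(b), collapse = ""),
                  character(1))
  expect_identical(keys, keys2)
})

test_that("a rule with support smaller than n_test errors explicitly", {
  # the zigzag family has at most 28 distinct boards
  expect_error(generate_distribution("zigzag", n_test = 40, seed = 1,
                                     max_attempts = 2000),
               "distinct")
})

test_that("mixture sampler draws rules uniformly", {
  set.seed(51)
  sampler <- mixture_sampler(abstraction_rules())
  draws <- replicate(2000, attr(sampler(), "rule"))
  tab <- table(factor(draws, levels = abstraction_rules()))
  se <- sqrt(2000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(tab - 2000 / 8) <= 3 * se))
  expect_error(mixture_sampler(character(0)), "non-empty")
  # degenerate mixture yields only that rule's boards
  single <- mixture_sampler("rectangle")
  expect_true(all(replicate(20, is_valid("rectangle", single()))))
})
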
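test_that("masked encoding zeroes the tile and flags exactly one mask entry", {
  set.seed(3)
  b <- generate_board("rectangle")
  for (pos in c(1L, 25L, 49L)) {
    x <- encode_masked(b, pos)
    expect_length(x, 98L)
    expect_equal(x[49 + pos], 1)
    expect_equal(sum(x[50:98]), 1)
    expect_equal(x[pos], 0)
  }
  x1 <- encode_masked(b, 5L)
  x2 <- encode_masked(b, 6L)
  diff_at <- which(x1 != x2)
  expect_true(all(diff_at %in% c(5L, 6L, 49L + 5L, 49L + 6L)))
  expect_error(encode_masked(b, 0L), "1..49")
  expect_error(encode_masked(b, 50L), "1..49")
})

test_that("the conditional network memorises a single repeated board", {
  set.seed(4)
  b <- generate_board("rectangle")
  boards <- replicate(64, b, simplify = FALSE)
  model <- train_conditional_model(boards, train_config(max_epochs = 400,
                                                        seed = 5))
  expect_gte(masked_accuracy(model, boards, seed = 6), 0.99)
  # the early-stopping rule fired well before the epoch cap
  expect_lt(model$epochs, 400L)
  tail5 <- tail(model$accuracy, 5)
  expect_gte(mean(tail5), 0.99)
})

test_that("masked accuracy scores an oracle at 1 and constants at the red rate", {
  set.seed(7)
  boards <- replicate(60, generate_board("rectangle"), simplify = FALSE)
  expect_equal(masked_accuracy(oracle_cond_model(), boards, seed = 1), 1.0)
  # an always-red model is right exactly when the masked tile is red
  acc <- masked_accuracy(const_model(0.99), boards, seed = 2)
  set.seed(2)
  mat <- vapply(boards, function(b) as.integer(as.matrix(b)), integer(49))
  masks <- sample.int(49L, length(boards), replace = TRUE)
  red_rate <- mean(mat[cbind(masks, seq_along(boards))] == 1L)
  expect_equal(acc, red_rate)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
})

test_that("a Gibbs sweep visits every position exactly once", {
  set.seed(8)
  cm <- counting_model(p = 0.5)
  g <- matrix(rbinom(49, 1, 0.5), 7, 7)
  out <- gibbs_sweep(cm, g)
  expect_equal(attr(out, "updates"), 49L)
  expect_equal(sort(cm$log$visits), 1:49)
  # fresh random order per sweep: two sweeps almost surely differ
  cm2 <- counting_model(p = 0.5)
  invisible(gibbs_sweep(cm2, g))
  first <- cm2$log$visits
  invisible(gibbs_sweep(cm2, g))
  second <- cm2$log$visits[50:98]
  expect_equal(sort(second), 1:49)
})

test_that("degenerate conditionals drive the chain to their fixed point", {
  set.seed(9)
  out <- gibbs_sweep(const_model(1), matrix(0L, 7, 7))
  expect_true(all(out == 1L))
  out0 <- gibbs_sweep(const_model(0), matrix(1L, 7, 7))
  expect_true(all(out0 == 0L))
  expect_error(gibbs_sweep(bad_model(), matrix(0L, 2, 2)), "outside")
})

test_that("gibbs_sample is deterministic given a seed and counts its updates", {
  a <- gibbs_sample(const_model(0.5), gibbs_config(seed = 33))
  b <- gibbs_sample(const_model(0.5), gibbs_config(seed = 33))
  expect_identical(as.integer(a), as.integer(b))
  expect_equal(attr(a, "updates"), 20L * 49L)
  short <- gibbs_sample(const_model(0.5), gibbs_config(n_sweeps = 3, seed = 1))
  expect_equal(attr(short, "updates"), 3L * 49L)
})

test_that("the sampler reproduces a known 2x2 joint distribution", {
  set.seed(10)
  theta <- 0.8
  model <- ising2x2_model(theta)
  exact <- ising2x2_exact(theta)
  n_samp <- 4000
  counts <- numeric(16)
  cfg <- gibbs_config(n_sweeps = 8)
  for (i in seq_len(n_samp)) {
    b <- gibbs_sample(model, cfg, dims = c(2L, 2L))
    idx <- sum(as.integer(b) * c(1L, 2L, 4L, 8L)) + 1L
    counts[idx] <- counts[idx] + 1
  }
  emp <- counts / n_samp
  exact_p <- numeric(16)
  for (k in seq_len(16)) {
    exact_p[sum(exact$states[k, ] * c(1, 2, 4, 8)) + 1] <- exact$probs[k]
  }
  tv <- 0.5 * sum(abs(emp - exact_p))
  expect_lt(tv, 0.08)
})

test_that("independent-tile conditionals give independent-tile marginals", {
  # a masked net with zero weights and logit(p) output bias realises a
  # constant conditional; its stationary distribution is Bernoulli(p) i.i.d.
  p_target <- 0.3
  nets <- get_rectangle_model(n_boards = 200L, seed = 55L)$model
  w <- nets$weights
  for (nm in c("W1", "W2", "W3", "Wo")) w[[nm]] <- w[[nm]] * 0
  for (nm in c("b1", "b2", "b3")) w[[nm]] <- w[[nm]] * 0
  w$bo <- matrix(log(p_target / (1 - p_target)), 49, 1)
  const_net <- structure(list(weights = w, n_cells = 49L),
                         class = c("masked_net", "conditional_model"))
  expect_equal(predict_tile_prob(const_net, rep(0, 49), 7L), p_target,
               tolerance = 1e-6)
  boards <- generate_metamer_set(const_net, 300, gibbs_config(seed = 12),
                                 min_red = 0L)
  freq <- rowMeans(vapply(boards, function(b) as.numeric(b), numeric(49)))
  se <- sqrt(p_target * (1 - p_target) / 300)
  expect_true(all(abs(freq - p_target) <= 4 * se))
})

test_that("metamer sets have independent chains and respect the red minimum", {
  nets <- get_rectangle_model(n_boards = 200L, seed = 55L)$model
  set.seed(14)
  boards <- generate_metamer_set(nets, 10, gibbs_config(seed = 15),
                                 rule_label = "rectangle_metamer")
  expect_length(boards, 10L)
  expect_true(all(vapply(boards, function(b) sum(b) >= 2L, logical(1))))
  expect_true(all(vapply(boards, function(b) attr(b, "rule"), character(1)) ==
                    "rectangle_metamer"))
  # a model that never produces red exhausts the retry cap
  expect_error(
    generate_metamer_set(const_model(0), 1, gibbs_config(seed = 1),
                         min_red = 2L, max_retries = 3L),
    "retry cap")
})
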
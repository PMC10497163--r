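test_that("board files round-trip through the JSONL format", {
  set.seed(1)
  boards <- generate_distribution("connected", n_test = 10, seed = 2)$test
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_boards(boards, path)
  back <- read_boards(path)
  expect_length(back, 10L)
  for (i in seq_along(boards)) {
    expect_identical(as.integer(back[[i]]), as.integer(boards[[i]]))
    expect_equal(attr(back[[i]], "rule"), attr(boards[[i]], "rule"))
    expect_equal(attr(back[[i]], "board_id"), attr(boards[[i]], "board_id"))
  }
})

test_that("malformed board lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"schema":"board/v1","rule":"rectangle","board_id":"x-1","grid":[[0,0,0,0,0,0,0],[0,1,1,0,0,0,0],[0,1,1,0,0,0,0],[0,0,0,0,0,0,0],[0,0,0,0,0,0,0],[0,0,0,0,0,0,0],[0,0,0,0,0,0,0]]}'
  bad_shape <- '{"schema":"board/v1","grid":[[0,0,0,0,0,0,0],[0,0,0,0,0,0,0]]}'
  writeLines(c(good, bad_shape), path)
  expect_error(read_boards(path), "line 2.*7x7")
  bad_value <- sub('\\[0,1,1,0,0,0,0\\]', '[0,2,1,0,0,0,0]', good)
  writeLines(c(good, good, bad_value), path)
  expect_error(read_boards(path), "line 3.*0 or 1")
})

test_that("results tables are written atomically and read back", {
  df <- data.frame(board_id = c("a", "b"), z = c(-0.5, 1.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(df, path)
  expect_false(file.exists(paste0(path, ".tmp")))
  back <- read.csv(path)
  expect_equal(back$z, df$z)
})

test_that("condition comparison is a symmetric pooled t-test", {
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12, 1)
  fw <- compare_conditions(a, b)
  bw <- compare_conditions(b, a)
  expect_equal(fw$t, -bw$t)
  expect_equal(fw$p, bw$p)
  expect_equal(fw$df, 22)
  same <- compare_conditions(a, a)
  expect_equal(same$t, 0)
  expect_error(compare_conditions(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(compare_conditions(1, 2), "at least 2")
})

test_that("pooled t-test p-values agree with a permutation oracle", {
  set.seed(4)
  a <- rnorm(20, 0.3); b <- rnorm(20)
  tt <- compare_conditions(a, b)
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  perm <- replicate(10000, {
    pick <- sample.int(40, 20)
    mean(pooled[pick]) - mean(pooled[-pick])
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / 10001
  expect_lt(abs(tt$p - p_perm), 0.02)
})

test_that("a tiny end-to-end condition run yields a schema-valid results table", {
  model_fit <- get_rectangle_model(n_boards = 200L, seed = 55L)
  cfg <- experiment_config("rectangle", conditions = c("abstract", "metamer"),
                           architecture = "lstm", n_episodes = 60L,
                           seeds = 1L, n_test = 3L, heuristic_trials = 100L,
                           eval_reps = 2L,
                           a2c = a2c_config(n_envs = 2L))
  res <- run_condition(cfg, conditional_models = list(rectangle = model_fit$model))
  # 1 rule x 2 conditions x 1 seed x 3 boards x 2 reps
  expect_equal(nrow(res), 12L)
  expect_setequal(unique(res$condition), c("abstract", "metamer"))
  expect_false(any(duplicated(res[, c("rule", "condition", "seed",
                                      "board_id", "rep")])))
  expect_true(all(is.finite(res$z)))
  expect_error(run_condition(cfg, conditional_models = NULL),
               "train_conditional_model")
})

test_that("cross evaluation fills a rules-by-rules z matrix", {
  set.seed(5)
  agents <- list(rectangle = new_agent("corelnet", seed = 6),
                 cross = new_agent("corelnet", seed = 7))
  tests <- list(rectangle = generate_distribution("rectangle", n_test = 2,
                                                  seed = 8)$test,
                cross = generate_distribution("cross", n_test = 2,
                                              seed = 9)$test)
  z <- cross_eval(agents, tests, heuristic_trials = 100, reps = 1, seed = 10)
  expect_equal(dim(z), c(2L, 2L))
  expect_true(all(is.finite(z)))
  expect_error(cross_eval(list(rectangle = NULL), tests), "missing agent")
})
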
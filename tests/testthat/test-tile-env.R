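test_that("reset reveals exactly one red tile and respects the red minimum", {
  set.seed(1)
  b <- generate_board("rectangle")
  st <- env_reset(b)
  expect_equal(sum(st$revealed), 1L)
  expect_equal(st$board[which(st$revealed)], 1L)
  expect_equal(st$step_count, 0L)
  k <- sum(b)
  expect_equal(sum(st$board == 1L & !st$revealed), k - 1L)
  # deterministic under a fixed start tile
  reds <- which(as.matrix(b) == 1L)
  st1 <- env_reset(b, start_tile = reds[2])
  st2 <- env_reset(b, start_tile = reds[2])
  expect_identical(which(st1$revealed), which(st2$revealed))
  lonely <- matrix(0L, 7, 7); lonely[3, 3] <- 1L
  expect_error(env_reset(lonely), "at least 2")
  expect_error(env_reset(b, start_tile = which(as.matrix(b) == 0L)[1]), "red")
})

test_that("step rewards follow the four-case schedule", {
  b <- board_from_cells(rbind(c(1, 1), c(1, 2), c(1, 3)))   # 3 reds
  st <- env_reset(b, start_tile = 1L)                       # (1,1) revealed
  # covered red, another red remains: +1
  res <- env_step(st, 8L)                                   # (1,2) column-major
  expect_equal(res$reward, 1)
  expect_false(res$done)
  # covered blue: -1
  res2 <- env_step(res$state, 2L)
  expect_equal(res2$reward, -1)
  expect_equal(res2$state$blue_count, 1L)
  # already revealed: -2, mask unchanged
  res3 <- env_step(res2$state, 1L)
  expect_equal(res3$reward, -2)
  expect_identical(res3$state$revealed, res2$state$revealed)
  # last covered red: +10 and terminal
  res4 <- env_step(res3$state, 15L)
  expect_equal(res4$reward, 10)
  expect_true(res4$done)
  expect_error(env_step(res4$state, 1L), "terminal")
  expect_error(env_step(st, 0L), "1..49")
  expect_error(env_step(st, 50L), "1..49")
})

test_that("step does not mutate its input state", {
  b <- board_from_cells(rbind(c(2, 2), c(2, 3)))
  st <- env_reset(b, start_tile = 9L)
  before <- st
  invisible(env_step(st, 1L))
  expect_identical(st, before)
})

test_that("observations are per-cell one-hot over covered/red/blue", {
  set.seed(2)
  b <- generate_board("cross")
  st <- env_reset(b)
  o <- env_observation(st)
  expect_equal(dim(o), c(49L, 3L))
  expect_true(all(rowSums(o) == 1))
  expect_equal(sum(o[, "covered"]), 48)
  expect_equal(sum(o[, "red"]), 1)
  blue_tile <- which(as.matrix(b) == 0L)[1]
  res <- env_step(st, blue_tile)
  o2 <- env_observation(res$state)
  changed <- which(rowSums(o != o2) > 0)
  expect_equal(changed, blue_tile)
  expect_equal(unname(o2[blue_tile, "blue"]), 1)
})

test_that("the heuristic clicks covered tiles adjacent to revealed reds", {
  b <- board_from_cells(rbind(c(4, 4), c(4, 5)))
  st <- env_reset(b, start_tile = which(as.matrix(b) == 1L)[1])  # (4,4)
  set.seed(3)
  for (i in 1:50) {
    a <- nn_heuristic_policy(st)
    expect_false(st$revealed[a])
    rr <- which(st$revealed & st$board == 1L)
    nbs <- unique(unlist(metamerlab:::neighbour_offsets(7, 7)[rr]))
    expect_true(a %in% nbs)
  }
  # single candidate is chosen with probability 1
  b2 <- board_from_cells(rbind(c(1, 1), c(7, 7)))
  st2 <- env_reset(b2, start_tile = 1L)
  st2$revealed[] <- TRUE
  st2$revealed[2L] <- FALSE          # only (2,1) covered, adjacent to (1,1)
  expect_equal(nn_heuristic_policy(st2), 2L)
  expect_error(nn_heuristic_policy({ s <- st2; s$done <- TRUE; s }),
               "terminal")
})

test_that("heuristic episodes terminate and their scores reproduce under a seed", {
  set.seed(4)
  b <- generate_board("pyramid")
  start <- which(as.matrix(b) == 1L)[1]
  h1 <- heuristic_distribution(b, n_trials = 200, start_tile = start, seed = 5)
  h2 <- heuristic_distribution(b, n_trials = 200, start_tile = start, seed = 5)
  expect_identical(h1$samples, h2$samples)
  expect_length(h1$samples, 200L)
  expect_true(all(h1$samples >= 0 & h1$samples <= sum(b == 0L)))
  expect_equal(h1$sd, sqrt(mean((h1$samples - h1$mean)^2)))
  # all-red board reveals no blue tiles, ever
  all_red <- matrix(1L, 7, 7)
  h3 <- heuristic_distribution(all_red, n_trials = 50, start_tile = 1L, seed = 6)
  expect_equal(h3$mean, 0)
  expect_equal(h3$sd, 0)
  # the compiled rollouts agree with the R policy run to termination
  set.seed(7)
  r_scores <- vapply(1:100, function(i)
    run_episode(b, nn_heuristic_policy, start_tile = start,
                step_cap = 500L)$blue_count, numeric(1))
  expect_lt(abs(mean(r_scores) - h1$mean), 4 * h1$sd / sqrt(100) + 4 * h1$sd / sqrt(200))
})

test_that("oracle reward accounting holds for any red count", {
  set.seed(8)
  for (k in c(2, 5, 10)) {
    cells <- which(matrix(TRUE, 7, 7))[sample.int(49, k)]
    g <- matrix(0L, 7, 7); g[cells] <- 1L
    ep <- run_episode(g, oracle_policy, start_tile = cells[1])
    expect_equal(ep$total_reward, (k - 2) + 10)
    expect_equal(ep$blue_count, 0)
    expect_equal(ep$steps, k - 1)
    expect_true(ep$done)
  }
})

test_that("episode traces carry one reward per step and count blues by -1 rewards", {
  set.seed(9)
  b <- generate_board("rectangle")
  ep <- run_episode(b, nn_heuristic_policy,
                    start_tile = which(as.matrix(b) == 1L)[1],
                    record_trace = TRUE)
  rewards <- vapply(ep$trace, `[[`, numeric(1), "reward")
  expect_length(rewards, ep$steps)
  expect_equal(sum(rewards == -1), ep$blue_count)
  expect_equal(sum(rewards), ep$total_reward)
  first_obs <- ep$trace[[1]]$observation
  expect_length(first_obs, 49L)
  expect_equal(sum(first_obs == 1L), 1L)     # one revealed red at reset
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_traces(list(ep), path)
  rec <- jsonlite::fromJSON(readLines(path)[1], simplifyDataFrame = FALSE)
  expect_equal(rec$blue_count, ep$blue_count)
  expect_length(rec$steps, ep$steps)
})

test_that("z-scoring is linear in the heuristic scale and guards degeneracy", {
  expect_equal(zscore_performance(5, 5, 2), 0)
  expect_equal(zscore_performance(3, 5, 2), -1)
  expect_equal(zscore_performance(9, 5, 2), 2)
  expect_equal(zscore_performance(4, 4, 0), 0)
  expect_error(zscore_performance(5, 4, 0), "sd = 0")
  expect_error(zscore_performance(5, 4, -1), ">= 0")
})
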
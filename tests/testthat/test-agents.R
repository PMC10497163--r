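test_that("all four architectures satisfy the policy/value interface", {
  set.seed(1)
  b <- generate_board("rectangle")
  st <- env_reset(b, start_tile = which(as.matrix(b) == 1L)[1])
  obs <- env_observation(st)
  for (arch in c("lstm", "epn", "transformer", "corelnet")) {
    ag <- new_agent(arch, seed = 2)
    fw <- agent_forward(ag, obs)
    logits <- as.numeric(ad_value(fw$logits))
    expect_length(logits, 49L)
    expect_length(as.numeric(ad_value(fw$value)), 1L)
    p <- action_probabilities(ag, st)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    # fixed weights and state give identical outputs on repeated calls
    expect_identical(p, action_probabilities(ag, st))
    if (arch %in% c("lstm", "epn")) {
      expect_equal(nrow(ad_value(fw$hidden$h)), 120L)
      expect_equal(nrow(ad_value(fw$hidden$c)), 120L)
    }
  }
})

test_that("corelnet similarity is the one-hot category match matrix", {
  set.seed(2)
  b <- generate_board("cross")
  st <- env_reset(b, start_tile = which(as.matrix(b) == 1L)[1])
  ag <- new_agent("corelnet", seed = 3)
  # fresh episode: every cell covered except one -> compare to category match
  obs <- env_observation(st)
  fw <- corelnet_forward(ag, obs)
  S <- fw$similarity
  expect_equal(dim(S), c(49L, 49L))
  cats <- apply(obs, 1, which.max)
  expect_equal(S, outer(cats, cats, "==") + 0, ignore_attr = TRUE)
  expect_true(all(S %in% c(0, 1)))
  # an all-covered observation makes every cell identical: S is all ones
  all_covered <- cbind(rep(1, 49), 0, 0)
  expect_true(all(corelnet_forward(ag, all_covered)$similarity == 1))
})

test_that("transformer outputs are permutation-invariant only without positional encodings", {
  set.seed(3)
  b <- generate_board("pyramid")
  st <- env_reset(b, start_tile = which(as.matrix(b) == 1L)[1])
  obs <- env_observation(st)
  ag <- new_agent("transformer", seed = 4)
  perm <- sample.int(49)
  with_pos <- transformer_forward(ag, obs)
  with_pos_p <- transformer_forward(ag, obs[perm, ])
  expect_gt(max(abs(ad_value(with_pos$logits) - ad_value(with_pos_p$logits))),
            1e-6)
  no_pos <- transformer_forward(ag, obs, zero_posenc = TRUE)
  no_pos_p <- transformer_forward(ag, obs[perm, ], zero_posenc = TRUE)
  expect_equal(ad_value(no_pos$logits), ad_value(no_pos_p$logits),
               tolerance = 1e-10)
  expect_equal(ad_value(no_pos$value), ad_value(no_pos_p$value),
               tolerance = 1e-10)
})

test_that("epn memory buffer is a bounded queue of transition tuples", {
  buf <- memory_buffer(3)
  o <- matrix(0, 49, 3)
  for (k in 1:5) {
    buf <- memory_push(buf, o, metamerlab:::onehot49(k, 49), o)
    expect_lte(length(buf$entries), 3L)
  }
  expect_length(buf$entries, 3L)
  expect_length(buf$entries[[1]], 49 * 3 * 2 + 49)
  # oldest evicted: remaining actions are 3, 4, 5
  acts <- vapply(buf$entries, function(e) which(e[148:196] == 1), integer(1))
  expect_equal(acts, 3:5)
  # empty memory still yields a well-formed forward pass
  ag <- new_agent("epn", seed = 5)
  st <- env_reset(generate_board("tree"), start_tile = NULL)
  fw <- epn_forward(ag, env_observation(st), memory = memory_buffer(4))
  expect_true(all(is.finite(as.numeric(ad_value(fw$logits)))))
})

test_that("a2c loss terms match their closed forms", {
  cfg <- a2c_config(value_coef = 0.5, entropy_coef = 0.01)
  # single step with V = 1, R = 3 contributes (1-3)^2 to the value term
  lb <- a2c_loss(list(log_probs = -1, values = 1, returns = 3,
                      entropies = 0.5), cfg)
  expect_equal(lb$L_v, 4)
  # zero advantage nullifies the policy term
  lb0 <- a2c_loss(list(log_probs = c(-2, -0.5), values = c(1, 2),
                       returns = c(1, 2), entropies = c(1, 1)), cfg)
  expect_equal(lb0$L_pi, 0)
  # uniform policy over 49 actions has entropy log(49)
  expect_equal(-(-sum(rep(1 / 49, 49) * log(rep(1 / 49, 49)))), -log(49))
  lbu <- a2c_loss(list(log_probs = log(1 / 49), values = 0, returns = 0,
                       entropies = log(49)), cfg)
  expect_equal(lbu$L_ent, -log(49), tolerance = 1e-12)
  expect_equal(lbu$L_ent, -3.8918, tolerance = 1e-4)
  # total respects the weighted-sum identity
  expect_equal(lb$L_total, lb$L_pi + cfg$value_coef * lb$L_v +
                 cfg$entropy_coef * lb$L_ent)
  # batch order does not matter for the mean-reduced terms
  set.seed(6)
  batch <- list(log_probs = rnorm(10), values = rnorm(10),
                returns = rnorm(10), entropies = runif(10))
  perm <- sample.int(10)
  shuffled <- lapply(batch, function(x) x[perm])
  expect_equal(a2c_loss(batch, cfg)$L_total,
               a2c_loss(shuffled, cfg)$L_total)
  expect_error(a2c_loss(list(log_probs = c(-1, NaN), values = c(0, 0),
                             returns = c(0, 0), entropies = c(0, 0)), cfg),
               "step 2")
})

test_that("tape gradients match finite differences for every architecture", {
  set.seed(7)
  b <- generate_board("rectangle")
  st <- env_reset(b, start_tile = which(as.matrix(b) == 1L)[1])
  obs <- env_observation(st)
  rollout_loss <- function(agent, params, actions, returns, advs) {
    hid <- NULL; prev_a <- NULL; prev_r <- 0
    memory <- if (agent$arch == "epn") memory_buffer(5)
    loss <- NULL
    for (tt in seq_along(actions)) {
      fw <- agent_forward(agent, obs, prev_a, prev_r, hid, memory,
                          params = params)
      lp <- ad_log_softmax(fw$logits)
      pnode <- ad_exp(lp)
      ent <- ad_scale(ad_sum(ad_mul(pnode, lp)), -1)
      vdiff <- ad_sub(fw$value, matrix(returns[tt], 1, 1))
      term <- ad_add(ad_scale(ad_pick(lp, actions[tt]), -advs[tt] / 2),
                     ad_add(ad_scale(ad_mul(vdiff, vdiff), 0.25),
                            ad_scale(ent, -0.005)))
      loss <- if (is.null(loss)) term else ad_add(loss, term)
      hid <- fw$hidden
      prev_a <- metamerlab:::onehot49(actions[tt], 49)
      prev_r <- 1
      if (agent$arch == "epn") {
        memory <- memory_push(memory, obs,
                              metamerlab:::onehot49(actions[tt], 49), obs)
      }
    }
    loss
  }
  small_cfg <- list(
    lstm = list(conv_channels = 2L, embed_dim = 6L, lstm_units = 5L),
    epn = list(conv_channels = 2L, embed_dim = 6L, lstm_units = 5L,
               mem_embed = 4L, mem_ff = 4L),
    transformer = list(d_model = 8L, n_blocks = 1L, ff_dim = 6L,
                       readout_dim = 6L),
    corelnet = list(hidden_dim = 6L))
  actions <- c(3L, 17L); returns <- c(1.5, -0.5); advs <- c(0.7, -0.3)
  for (arch in names(small_cfg)) {
    ag <- new_agent(arch, config = small_cfg[[arch]], seed = 11)
    pn <- lapply(ag$params, ad_param)
    ad_backward(rollout_loss(ag, pn, actions, returns, advs))
    for (nm in names(ag$params)) {
      g <- ad_grad(pn[[nm]])
      if (is.null(g)) next
      ks <- sample(seq_along(ag$params[[nm]]),
                   min(2L, length(ag$params[[nm]])))
      for (k in ks) {
        eps <- 1e-5
        pp <- ag$params
        pp[[nm]][k] <- pp[[nm]][k] + eps
        up <- ad_value(rollout_loss(ag, pp, actions, returns, advs))
        pp[[nm]][k] <- pp[[nm]][k] - 2 * eps
        dn <- ad_value(rollout_loss(ag, pp, actions, returns, advs))
        fd <- (up - dn) / (2 * eps)
        expect_lt(abs(fd - g[k]) / max(1e-6, abs(fd), abs(g[k])), 1e-4)
      }
    }
  }
})

test_that("the compiled LSTM forward matches the R reference exactly", {
  set.seed(8)
  ag <- new_agent("lstm", seed = 9)
  b <- generate_board("connected")
  st <- env_reset(b, start_tile = which(as.matrix(b) == 1L)[1])
  obs <- env_observation(st)
  pa <- runif(49); pr <- 0.7
  h <- rnorm(120) * 0.1; cc <- rnorm(120) * 0.1
  fr <- lstm_meta_learner_forward(ag, obs, matrix(pa, ncol = 1), pr,
                                  list(h = matrix(h, ncol = 1),
                                       c = matrix(cc, ncol = 1)))
  fc <- metamerlab:::cpp_lstm_forward(ag$params,
                                      metamerlab:::conv_im2col_index(),
                                      as.numeric(obs), pa, pr, h, cc)
  expect_equal(as.numeric(ad_value(fr$logits)), as.numeric(fc$logits),
               tolerance = 1e-12)
  expect_equal(as.numeric(ad_value(fr$value)), fc$value, tolerance = 1e-12)
  expect_equal(as.numeric(ad_value(fr$hidden$h)), as.numeric(fc$h),
               tolerance = 1e-12)
  expect_equal(as.numeric(ad_value(fr$hidden$c)), as.numeric(fc$c),
               tolerance = 1e-12)
})

test_that("training runs are reproducible under a fixed seed", {
  set.seed(10)
  b <- generate_board("rectangle")
  cfg <- a2c_config(backend = "cpp", n_envs = 4L, seed = 12)
  r1 <- train_agent(new_agent("lstm", seed = 11), function() b, 40, cfg)
  set.seed(10)
  r2 <- train_agent(new_agent("lstm", seed = 11), function() b, 40, cfg)
  expect_identical(r1$episode_rewards, r2$episode_rewards)
  expect_identical(r1$agent$params, r2$agent$params)
  # R backend, feedforward architecture
  cfg_r <- a2c_config(backend = "r", seed = 13)
  s1 <- train_agent(new_agent("corelnet", seed = 14), function() b, 3, cfg_r)
  s2 <- train_agent(new_agent("corelnet", seed = 14), function() b, 3, cfg_r)
  expect_identical(s1$episode_rewards, s2$episode_rewards)
  expect_equal(length(s1$curve), 3L)
})

test_that("the compiled trainer improves on a fixed single board", {
  set.seed(15)
  b <- generate_board("rectangle")
  res <- train_agent(new_agent("lstm", seed = 16), function() b, 4000,
                     a2c_config(n_envs = 16L, seed = 17))
  first <- mean(res$episode_rewards[1:400])
  last <- mean(tail(res$episode_rewards, 400))
  expect_gt(last, first)
  # the trained policy beats the untrained one by a wide margin
  expect_gt(last, 0)
})

test_that("evaluation produces one scored row per board (or per rep)", {
  set.seed(18)
  boards <- generate_distribution("rectangle", n_test = 4, seed = 19)$test
  ag <- new_agent("corelnet", seed = 20)
  ev <- evaluate_agent(ag, boards, heuristic_trials = 200, reps = 2,
                       seed = 21)
  expect_equal(nrow(ev), 4L)
  evr <- evaluate_agent(ag, boards, heuristic_trials = 200, reps = 2,
                        seed = 21, per_rep = TRUE)
  expect_equal(nrow(evr), 8L)
  expect_equal(evr$z, (evr$blue_count - evr$heuristic_mean) / evr$heuristic_sd)
  # an untrained (near-uniform) policy scores worse than the red-adjacent
  # heuristic on average
  expect_gt(mean(ev$z), 0)
})
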
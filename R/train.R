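#' A2C training configuration
#'
#' Advantage actor-critic hyperparameters: the loss is
#' `L = L_pi + c_v * L_v + c_e * L_ent` with `L_pi` the policy-gradient
#' term over advantages `A = R - V`, `L_v` the squared value error, and
#' `L_ent` the negative policy entropy.  Returns are n-step bootstrapped
#' discounted sums.  Defaults: RMSprop at 7e-4 with a linear schedule,
#' value weight 0.5, entropy weight 0.01, discount 0.9, 5 environment steps
#' per update.
#'
#' @param learning_rate RMSprop step size.
#' @param lr_schedule `"constant"` or `"linear"` (decay to 0 over the
#'   episode budget).
#' @param value_coef weight `c_v` of the value loss.
#' @param entropy_coef weight `c_e` of the entropy loss.
#' @param gamma discount factor in `(0, 1]`.
#' @param n_steps environment steps per gradient update.
#' @param n_envs parallel environments (compiled LSTM path only).
#' @param step_cap maximum steps per training episode.
#' @param grad_clip global gradient-norm clip.
#' @param rmsprop_alpha,rmsprop_eps RMSprop decay and stabiliser.
#' @param backend `"auto"` (compiled path for the LSTM meta-learner, R
#'   otherwise), `"cpp"`, or `"r"`.
#' @param seed integer seed.
#' @return list of class `a2c_config`.
#' @export
a2c_config <- function(learning_rate = 7e-4, lr_schedule = c("linear", "constant"),
                       value_coef = 0.5, entropy_coef = 0.01, gamma = 0.9,
                       n_steps = 5L, n_envs = 32L, step_cap = 200L,
                       grad_clip = 0.5, rmsprop_alpha = 0.99,
                       rmsprop_eps = 1e-5,
                       backend = c("auto", "cpp", "r"), seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  backend <- match.arg(backend)
  if (value_coef < 0 || entropy_coef < 0) stop("loss weights must be >= 0")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  structure(list(learning_rate = learning_rate, lr_schedule = lr_schedule,
                 value_coef = value_coef, entropy_coef = entropy_coef,
                 gamma = gamma, n_steps = as.integer(n_steps),
                 n_envs = as.integer(n_envs), step_cap = as.integer(step_cap),
                 grad_clip = grad_clip, rmsprop_alpha = rmsprop_alpha,
                 rmsprop_eps = rmsprop_eps, backend = backend,
                 seed = as.integer(seed)),
            class = "a2c_config")
}

#' Advantage actor-critic loss breakdown
#'
#' Computes the three A2C loss terms from a rollout batch:
#' `L_pi = mean(-log pi(a_t | s_t) * A_t)` with `A_t = R_t - V(s_t)`,
#' `L_v = mean((V(s_t) - R_t)^2)`, `L_ent = -mean(H(pi(. | s_t)))`, and
#' `L_total = L_pi + c_v * L_v + c_e * L_ent`.
#'
#' @param batch list with numeric vectors `log_probs`, `values`, `returns`,
#'   `entropies` (one entry per step), and optionally `advantages`
#'   (defaults to `returns - values`).
#' @param config an [a2c_config()].
#' @return list of class `loss_breakdown` with `L_pi`, `L_v`, `L_ent`,
#'   `L_total`.
#' @export
a2c_loss <- function(batch, config = a2c_config()) {
  adv <- if (!is.null(batch$advantages)) batch$advantages else
    batch$returns - batch$values
  terms <- list(log_probs = batch$log_probs, values = batch$values,
                returns = batch$returns, entropies = batch$entropies)
  for (nm in names(terms)) {
    bad <- which(!is.finite(terms[[nm]]))
    if (length(bad)) {
      stop(sprintf("non-finite %s at step %d", nm, bad[1L]))
    }
  }
  L_pi <- mean(-batch$log_probs * adv)
  L_v <- mean((batch$values - batch$returns)^2)
  L_ent <- -mean(batch$entropies)
  structure(list(L_pi = L_pi, L_v = L_v, L_ent = L_ent,
                 L_total = L_pi + config$value_coef * L_v +
                   config$entropy_coef * L_ent),
            class = "loss_breakdown")
}

sample_from_logits <- function(logits) {
  p <- exp(ad_log_softmax(as.numeric(logits)))
  sample.int(length(p), 1L, prob = p)
}

rmsprop_step <- function(params, grads, state, lr, alpha, eps, clip) {
  gnorm <- sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2),
                           numeric(1))))
  scale <- if (clip > 0 && gnorm > clip) clip / gnorm else 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g * scale
    state[[nm]] <- alpha * state[[nm]] + (1 - alpha) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

#' Train an agent with advantage actor-critic
#'
#' One fresh board per episode drawn from `sampler`; n-step rollouts per
#' gradient update with truncated backpropagation through time for the
#' recurrent architectures.  The LSTM meta-learner uses a compiled batched
#' training loop by default (`backend = "auto"`); every architecture can be
#' trained through the R tape with `backend = "r"`.
#'
#' @param agent an `agent` from [new_agent()].
#' @param sampler zero-argument function returning a training board.
#' @param n_episodes episode budget.
#' @param config an [a2c_config()].
#' @return list with `agent` (updated parameters), `episode_rewards`
#'   (per-episode total reward in completion order), and `curve` (mean
#'   reward per 1%-of-budget logging block).
#' @export
train_agent <- function(agent, sampler, n_episodes, config = a2c_config()) {
  backend <- config$backend
  if (backend == "auto") backend <- if (agent$arch == "lstm") "cpp" else "r"
  if (backend == "cpp" && agent$arch != "lstm") {
    stop("the compiled training path supports only the LSTM meta-learner")
  }
  rewards <- if (backend == "cpp") {
    train_lstm_cpp(agent, sampler, n_episodes, config)
  } else {
    train_agent_r(agent, sampler, n_episodes, config)
  }
  agent$params <- rewards$params
  n_blocks <- min(100L, n_episodes)
  block <- ceiling(n_episodes / n_blocks)
  curve <- tapply(rewards$episode_rewards,
                  (seq_along(rewards$episode_rewards) - 1L) %/% block, mean)
  list(agent = agent, episode_rewards = rewards$episode_rewards,
       curve = as.numeric(curve))
}

train_lstm_cpp <- function(agent, sampler, n_episodes, config) {
  set.seed(config$seed)
  chunk_size <- 512L
  chunk_fn <- function() {
    vapply(seq_len(chunk_size), function(i) as.integer(sampler()),
           integer(agent$config$obs_cells))
  }
  res <- cpp_train_lstm_a2c(
    agent$params, conv_im2col_index(),
    agent$config$conv_channels, agent$config$embed_dim,
    agent$config$lstm_units,
    chunk_fn, as.integer(n_episodes),
    config$learning_rate, config$lr_schedule == "linear",
    config$value_coef, config$entropy_coef, config$gamma,
    config$n_steps, config$n_envs, config$step_cap,
    config$grad_clip, config$rmsprop_alpha, config$rmsprop_eps,
    config$seed)
  list(params = res$params, episode_rewards = as.numeric(res$episode_rewards))
}

train_agent_r <- function(agent, sampler, n_episodes, config) {
  set.seed(config$seed)
  params <- agent$params
  opt_state <- lapply(params, function(p) array(0, dim(p)))
  episode_rewards <- numeric(n_episodes)
  gamma <- config$gamma
  recurrent <- agent$arch %in% c("lstm", "epn")

  for (ep in seq_len(n_episodes)) {
    board <- sampler()
    state <- env_reset(board)
    prev_a <- zeros_col(agent$config$n_actions)
    prev_r <- 0
    hidden <- NULL
    memory <- if (agent$arch == "epn") memory_buffer(agent$config$memory_size)
    lr <- config$learning_rate *
      if (config$lr_schedule == "linear") (1 - (ep - 1) / n_episodes) else 1

    while (!state$done && state$step_count < config$step_cap) {
      pnodes <- lapply(params, ad_param)
      logp_nodes <- list(); ent_nodes <- list(); val_nodes <- list()
      rewards <- numeric(0); dones <- logical(0)
      hid_node <- hidden
      for (s in seq_len(config$n_steps)) {
        obs <- env_observation(state)
        fw <- agent_forward(agent, obs, prev_a, prev_r, hid_node, memory,
                            params = pnodes)
        lp <- ad_log_softmax(fw$logits)
        a <- sample_from_logits(ad_value(fw$logits))
        res <- env_step(state, a)
        if (agent$arch == "epn") {
          memory <- memory_push(memory, obs, onehot49(a, agent$config$n_actions),
                                env_observation(res$state))
        }
        logp_nodes[[s]] <- ad_pick(lp, a)
        p_node <- ad_exp(lp)
        ent_nodes[[s]] <- ad_scale(ad_sum(ad_mul(p_node, lp)), -1)
        val_nodes[[s]] <- fw$value
        rewards <- c(rewards, res$reward)
        dones <- c(dones, res$done)
        prev_a <- onehot49(a, agent$config$n_actions)
        prev_r <- res$reward
        hid_node <- fw$hidden
        state <- res$state
        if (state$done || state$step_count >= config$step_cap) break
      }
      T_ <- length(rewards)
      boot <- 0
      if (!state$done && state$step_count < config$step_cap) {
        hv <- if (recurrent && !is.null(hid_node))
          list(h = ad_value(hid_node$h), c = ad_value(hid_node$c))
        fw_next <- agent_forward(agent, env_observation(state), prev_a,
                                 prev_r, hv, memory, params = params)
        boot <- as.numeric(ad_value(fw_next$value))
      }
      returns <- numeric(T_)
      R <- boot
      for (tt in rev(seq_len(T_))) {
        R <- rewards[tt] + gamma * R * (1 - dones[tt])
        returns[tt] <- R
      }
      values_num <- vapply(val_nodes, function(v) as.numeric(ad_value(v)),
                           numeric(1))
      adv <- returns - values_num
      loss <- NULL
      for (tt in seq_len(T_)) {
        vdiff <- ad_sub(val_nodes[[tt]], matrix(returns[tt], 1L, 1L))
        term <- ad_add(
          ad_scale(logp_nodes[[tt]], -adv[tt] / T_),
          ad_add(ad_scale(ad_mul(vdiff, vdiff), config$value_coef / T_),
                 ad_scale(ent_nodes[[tt]], -config$entropy_coef / T_)))
        loss <- if (is.null(loss)) term else ad_add(loss, term)
      }
      if (!is.finite(ad_value(loss))) {
        stop(sprintf("A2C loss became non-finite at episode %d", ep))
      }
      ad_backward(loss)
      grads <- lapply(pnodes, ad_grad)
      upd <- rmsprop_step(params, grads, opt_state, lr,
                          config$rmsprop_alpha, config$rmsprop_eps,
                          config$grad_clip)
      params <- upd$params
      opt_state <- upd$state
      hidden <- if (recurrent && !is.null(hid_node))
        list(h = ad_value(hid_node$h), c = ad_value(hid_node$c))
    }
    episode_rewards[ep] <- state$total_reward
  }
  list(params = params, episode_rewards = episode_rewards)
}

onehot49 <- function(a, n) {
  v <- zeros_col(n)
  v[a] <- 1
  v
}

#' Evaluate an agent on held-out boards
#'
#' For every board: the initially revealed red tile is frozen (derived from
#' `seed`), the nearest-neighbour heuristic's blue-count distribution is
#' estimated from `heuristic_trials` rollouts with the same start, the
#' agent plays `reps` episodes (actions sampled from the softmax policy by
#' default, or greedy), and the blue count is z-scored against the
#' heuristic distribution (lower is better).
#'
#' @param agent a trained `agent`.
#' @param test_boards list of boards.
#' @param heuristic_trials heuristic rollouts per board (default 1000).
#' @param reps agent episodes per board.
#' @param mode `"sample"` or `"greedy"` action selection.
#' @param step_cap evaluation step cap.
#' @param seed integer seed (start tiles, heuristic, and policy sampling).
#' @param per_rep if `TRUE`, one row per (board, rep); otherwise one row per
#'   board with rep-averaged scores.
#' @return data.frame with columns `board_id`, `rule`, `rep` (per-rep mode),
#'   `blue_count`, `total_reward`, `steps`, `heuristic_mean`,
#'   `heuristic_sd`, `z`.
#' @export
evaluate_agent <- function(agent, test_boards, heuristic_trials = 1000L,
                           reps = 10L, mode = c("sample", "greedy"),
                           step_cap = 200L, seed = 1L, per_rep = FALSE) {
  mode <- match.arg(mode)
  rows <- list()
  for (i in seq_along(test_boards)) {
    b <- test_boards[[i]]
    reds <- which(as.matrix(b) == 1L)
    set.seed(seed + 7L * i)
    start <- reds[[sample.int(length(reds), 1L)]]
    heur <- heuristic_distribution(b, heuristic_trials, start_tile = start,
                                   seed = seed + 7L * i + 1L)
    board_id <- attr(b, "board_id")
    if (is.null(board_id)) board_id <- sprintf("board-%03d", i)
    rule <- attr(b, "rule")
    if (is.null(rule)) rule <- NA_character_
    per <- lapply(seq_len(reps), function(r) {
      run_agent_episode(agent, b, start, mode, step_cap)
    })
    blue <- vapply(per, `[[`, numeric(1), "blue_count")
    rew <- vapply(per, `[[`, numeric(1), "total_reward")
    stp <- vapply(per, `[[`, numeric(1), "steps")
    if (per_rep) {
      for (r in seq_len(reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          board_id = board_id, rule = rule, rep = r, blue_count = blue[r],
          total_reward = rew[r], steps = stp[r],
          heuristic_mean = heur$mean, heuristic_sd = heur$sd,
          z = zscore_performance(blue[r], heur$mean, heur$sd),
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        board_id = board_id, rule = rule, blue_count = mean(blue),
        total_reward = mean(rew), steps = mean(stp),
        heuristic_mean = heur$mean, heuristic_sd = heur$sd,
        z = zscore_performance(mean(blue), heur$mean, heur$sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Play one episode with an agent
#'
#' @param agent an `agent`.
#' @param board board with >= 2 red tiles.
#' @param start_tile fixed initially revealed red tile (optional).
#' @param mode `"sample"` or `"greedy"`.
#' @param step_cap maximum episode steps.
#' @return list with `blue_count`, `total_reward`, `steps`, `done`.
#' @export
run_agent_episode <- function(agent, board, start_tile = NULL,
                              mode = c("sample", "greedy"), step_cap = 200L) {
  mode <- match.arg(mode)
  state <- env_reset(board, start_tile = start_tile)
  prev_a <- NULL
  prev_r <- 0
  hidden <- NULL
  memory <- if (agent$arch == "epn") memory_buffer(agent$config$memory_size)
  while (!state$done && state$step_count < step_cap) {
    obs <- env_observation(state)
    fw <- agent_forward(agent, obs, prev_a, prev_r, hidden, memory)
    logits <- as.numeric(ad_value(fw$logits))
    a <- if (mode == "greedy") which.max(logits) else
      sample_from_logits(logits)
    res <- env_step(state, a)
    if (agent$arch == "epn") {
      memory <- memory_push(memory, obs, onehot49(a, agent$config$n_actions),
                            env_observation(res$state))
    }
    prev_a <- onehot49(a, agent$config$n_actions)
    prev_r <- res$reward
    hidden <- fw$hidden
    state <- res$state
  }
  list(blue_count = state$blue_count, total_reward = state$total_reward,
       steps = state$step_count, done = state$done)
}
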
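#' Agent architectures
#'
#' Four policy/value network architectures share one interface: given an
#' observation (49 cells x 3 one-hot categories) they produce 49 action
#' logits (policy over tiles, via softmax) and a scalar state-value
#' estimate.
#'
#' * `lstm` — the meta-learner: a 3x3 convolution plus a fully connected
#'   embedding of the board, concatenated with the previous action (one-hot)
#'   and previous reward (scalar), feeding 120 LSTM units.
#' * `epn` — episodic planning network: the LSTM meta-learner with one extra
#'   input, the pooled output of a single transformer self-attention block
#'   over a bounded buffer of past transitions `(o_prev, a, o_next)`.
#' * `transformer` — embeds the 49 cells, adds learned positional encodings,
#'   applies alternating self-attention and feedforward blocks, mean-pools,
#'   and reads out policy and value.
#' * `corelnet` — computes the 49 x 49 dot-product similarity matrix among
#'   cell encodings and passes its flattened form through fully connected
#'   layers.
#'
#' @param arch one of `"lstm"`, `"epn"`, `"transformer"`, `"corelnet"`.
#' @param config named list overriding architecture defaults (see
#'   [agent_defaults()]).
#' @param seed integer seed for weight initialisation.
#' @return object of class `agent` with elements `arch`, `params`, `config`.
#' @export
new_agent <- function(arch = c("lstm", "epn", "transformer", "corelnet"),
                      config = list(), seed = NULL) {
  arch <- match.arg(arch)
  cfg <- utils::modifyList(agent_defaults(arch), config)
  if (!is.null(seed)) set.seed(seed)
  params <- switch(arch,
    lstm = init_lstm_params(cfg),
    epn = init_epn_params(cfg),
    transformer = init_transformer_params(cfg),
    corelnet = init_corelnet_params(cfg))
  structure(list(arch = arch, params = params, config = cfg),
            class = c(paste0(arch, "_agent"), "agent"))
}

#' Default architecture hyperparameters
#'
#' @param arch architecture name.
#' @return named list of defaults.
#' @export
agent_defaults <- function(arch) {
  base <- list(n_actions = 49L, obs_cells = 49L, obs_channels = 3L)
  extra <- switch(arch,
    lstm = list(conv_channels = 8L, embed_dim = 32L, lstm_units = 120L),
    epn = list(conv_channels = 8L, embed_dim = 32L, lstm_units = 120L,
               memory_size = 10L, mem_embed = 64L, mem_heads = 2L,
               mem_ff = 64L),
    transformer = list(d_model = 64L, n_blocks = 2L, n_heads = 2L,
                       ff_dim = 128L, readout_dim = 64L),
    corelnet = list(hidden_dim = 128L))
  c(base, extra)
}

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

zeros_col <- function(n) matrix(0, n, 1L)

# column index map for the 3x3 convolution over the 7x7 x 3-channel
# observation; rows ordered channel-major then column offset then row
# offset; 0 marks zero padding
conv_im2col_index <- function(side = 7L, channels = 3L) {
  idx <- matrix(0L, 9L * channels, side * side)
  for (p in seq_len(side * side)) {
    r <- (p - 1L) %% side + 1L
    c <- (p - 1L) %/% side + 1L
    k <- 0L
    for (ch in seq_len(channels)) for (dc in -1:1) for (dr in -1:1) {
      k <- k + 1L
      nr <- r + dr; nc <- c + dc
      if (nr >= 1L && nr <= side && nc >= 1L && nc <= side) {
        idx[k, p] <- (ch - 1L) * side * side + (nc - 1L) * side + nr
      }
    }
  }
  idx
}

init_lstm_params <- function(cfg) {
  C <- cfg$conv_channels; E <- cfg$embed_dim; H <- cfg$lstm_units
  A <- cfg$n_actions
  in_dim <- E + A + 1L
  list(conv_w = glorot_mat(C, 9L * cfg$obs_channels), conv_b = zeros_col(C),
       fc_w = glorot_mat(E, C * cfg$obs_cells), fc_b = zeros_col(E),
       lstm_w = glorot_mat(4L * H, in_dim + H), lstm_b = zeros_col(4L * H),
       pol_w = glorot_mat(A, H), pol_b = zeros_col(A),
       val_w = glorot_mat(1L, H), val_b = zeros_col(1L))
}

init_epn_params <- function(cfg) {
  p <- init_lstm_params(cfg)
  M <- cfg$mem_embed
  tuple_dim <- 2L * cfg$obs_cells * cfg$obs_channels + cfg$n_actions
  in_dim <- cfg$embed_dim + cfg$n_actions + 1L + M
  p$lstm_w <- glorot_mat(4L * cfg$lstm_units, in_dim + cfg$lstm_units)
  p$mem_w <- glorot_mat(M, tuple_dim); p$mem_b <- matrix(0, 1L, M)
  p$attn_wq <- glorot_mat(M, M); p$attn_wk <- glorot_mat(M, M)
  p$attn_wv <- glorot_mat(M, M); p$attn_wo <- glorot_mat(M, M)
  p$mlp_w1 <- glorot_mat(cfg$mem_ff, M); p$mlp_b1 <- matrix(0, 1L, cfg$mem_ff)
  p$mlp_w2 <- glorot_mat(M, cfg$mem_ff); p$mlp_b2 <- matrix(0, 1L, M)
  p
}

init_transformer_params <- function(cfg) {
  d <- cfg$d_model
  p <- list(emb_w = glorot_mat(d, cfg$obs_channels), emb_b = matrix(0, 1L, d),
            posenc = glorot_mat(cfg$obs_cells, d))
  for (l in seq_len(cfg$n_blocks)) {
    p[[paste0("wq", l)]] <- glorot_mat(d, d)
    p[[paste0("wk", l)]] <- glorot_mat(d, d)
    p[[paste0("wv", l)]] <- glorot_mat(d, d)
    p[[paste0("wo", l)]] <- glorot_mat(d, d)
    p[[paste0("ff_w1_", l)]] <- glorot_mat(cfg$ff_dim, d)
    p[[paste0("ff_b1_", l)]] <- matrix(0, 1L, cfg$ff_dim)
    p[[paste0("ff_w2_", l)]] <- glorot_mat(d, cfg$ff_dim)
    p[[paste0("ff_b2_", l)]] <- matrix(0, 1L, d)
  }
  p$ro_w <- glorot_mat(cfg$readout_dim, d); p$ro_b <- zeros_col(cfg$readout_dim)
  p$pol_w <- glorot_mat(cfg$n_actions, cfg$readout_dim)
  p$pol_b <- zeros_col(cfg$n_actions)
  p$val_w <- glorot_mat(1L, cfg$readout_dim); p$val_b <- zeros_col(1L)
  p
}

init_corelnet_params <- function(cfg) {
  Hc <- cfg$hidden_dim; n <- cfg$obs_cells
  list(fc_w = glorot_mat(Hc, n * n), fc_b = zeros_col(Hc),
       pol_w = glorot_mat(cfg$n_actions, Hc), pol_b = zeros_col(cfg$n_actions),
       val_w = glorot_mat(1L, Hc), val_b = zeros_col(1L))
}

## ---- forward passes --------------------------------------------------------
## Each forward works on plain matrices (inference) or adnode parameters
## (training); the ops in autodiff.R forward numeric inputs untouched.

# single transformer block (self-attention + feedforward, residual)
attention_block <- function(X, wq, wk, wv, wo, w1, b1, w2, b2, n_heads) {
  d <- ncol(ad_value(X))
  dh <- d %/% n_heads
  Q <- ad_mm(X, ad_t(wq)); K <- ad_mm(X, ad_t(wk)); V <- ad_mm(X, ad_t(wv))
  heads <- lapply(seq_len(n_heads), function(h) {
    ix <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ad_cols(Q, ix); Kh <- ad_cols(K, ix); Vh <- ad_cols(V, ix)
    A <- ad_softmax_rows(ad_scale(ad_mm(Qh, ad_t(Kh)), 1 / sqrt(dh)))
    ad_mm(A, Vh)
  })
  attn <- ad_mm(ad_hconcat(heads), ad_t(wo))
  res1 <- ad_add(X, attn)
  ff <- ad_mm(ad_relu(ad_add_rowbias(ad_mm(res1, ad_t(w1)), b1)), ad_t(w2))
  ad_add(res1, ad_add_rowbias(ff, b2))
}

lstm_cell <- function(p, x, hidden) {
  H <- nrow(ad_value(hidden$h))
  z <- ad_vconcat(list(x, hidden$h))
  gates <- ad_add(ad_mm(p$lstm_w, z), p$lstm_b)
  i <- ad_sigmoid(ad_rows(gates, 1:H))
  f <- ad_sigmoid(ad_rows(gates, (H + 1L):(2L * H)))
  g <- ad_tanh(ad_rows(gates, (2L * H + 1L):(3L * H)))
  o <- ad_sigmoid(ad_rows(gates, (3L * H + 1L):(4L * H)))
  c_new <- ad_add(ad_mul(f, hidden$c), ad_mul(i, g))
  h_new <- ad_mul(o, ad_tanh(c_new))
  list(h = h_new, c = c_new)
}

conv_embed <- function(p, obs, cfg, idx) {
  obs_vec <- matrix(as.numeric(obs), ncol = 1L)
  xcol <- ad_gather_pad(obs_vec, idx)
  conv <- ad_relu(ad_add_bias(ad_mm(p$conv_w, xcol), p$conv_b))
  flat <- ad_reshape(conv, cfg$conv_channels * cfg$obs_cells, 1L)
  ad_relu(ad_add_bias(ad_mm(p$fc_w, flat), p$fc_b))
}

policy_value_head <- function(p, h) {
  list(logits = ad_add(ad_mm(p$pol_w, h), p$pol_b),
       value = ad_add(ad_mm(p$val_w, h), p$val_b))
}

#' LSTM meta-learner forward pass
#'
#' @param agent an `agent` with `arch = "lstm"` (or its parameter list via
#'   `params`).
#' @param obs observation matrix from [env_observation()].
#' @param prev_action one-hot 49-vector of the previous action (zeros at
#'   episode start).
#' @param prev_reward previous scalar reward (0 at episode start).
#' @param hidden list with `h` and `c` (120 x 1); `NULL` for a fresh state.
#' @param params optional parameter list overriding `agent$params` (used
#'   during training with taped parameters).
#' @return list with `logits` (49 x 1), `value` (1 x 1), `hidden`.
#' @export
lstm_meta_learner_forward <- function(agent, obs, prev_action = NULL,
                                      prev_reward = 0, hidden = NULL,
                                      params = NULL) {
  cfg <- agent$config
  p <- if (is.null(params)) agent$params else params
  if (is.null(prev_action)) prev_action <- zeros_col(cfg$n_actions)
  if (is.null(hidden)) hidden <- list(h = zeros_col(cfg$lstm_units),
                                      c = zeros_col(cfg$lstm_units))
  idx <- conv_im2col_index()
  emb <- conv_embed(p, obs, cfg, idx)
  x <- ad_vconcat(list(emb, matrix(prev_action, ncol = 1L),
                       matrix(prev_reward, 1L, 1L)))
  hid <- lstm_cell(p, x, hidden)
  c(policy_value_head(p, hid$h), list(hidden = hid))
}

#' Episodic planning network forward pass
#'
#' Adds to the LSTM meta-learner one extra input: the mean-pooled output of
#' a single transformer block applied to the embedded memory of past
#' transition tuples.  An empty memory contributes a zero embedding.
#'
#' @inheritParams lstm_meta_learner_forward
#' @param memory a [memory_buffer()] of transition tuples.
#' @return list with `logits`, `value`, `hidden`.
#' @export
epn_forward <- function(agent, obs, memory = NULL, prev_action = NULL,
                        prev_reward = 0, hidden = NULL, params = NULL) {
  cfg <- agent$config
  p <- if (is.null(params)) agent$params else params
  if (is.null(prev_action)) prev_action <- zeros_col(cfg$n_actions)
  if (is.null(hidden)) hidden <- list(h = zeros_col(cfg$lstm_units),
                                      c = zeros_col(cfg$lstm_units))
  idx <- conv_im2col_index()
  emb <- conv_embed(p, obs, cfg, idx)
  if (is.null(memory) || length(memory$entries) == 0L) {
    mem_vec <- zeros_col(cfg$mem_embed)
  } else {
    M <- do.call(rbind, memory$entries)          # m x tuple_dim
    E <- ad_add_rowbias(ad_mm(M, ad_t(p$mem_w)), p$mem_b)
    out <- attention_block(E, p$attn_wq, p$attn_wk, p$attn_wv, p$attn_wo,
                           p$mlp_w1, p$mlp_b1, p$mlp_w2, p$mlp_b2,
                           cfg$mem_heads)
    mem_vec <- ad_colmeans(out)
  }
  x <- ad_vconcat(list(emb, matrix(prev_action, ncol = 1L),
                       matrix(prev_reward, 1L, 1L), mem_vec))
  hid <- lstm_cell(p, x, hidden)
  c(policy_value_head(p, hid$h), list(hidden = hid))
}

#' Transformer forward pass
#'
#' Embeds the 49 cell one-hots, adds learned positional encodings, applies
#' the configured number of self-attention + feedforward blocks, mean-pools
#' over cells, and reads out 49 logits and a value.
#'
#' @inheritParams lstm_meta_learner_forward
#' @param zero_posenc if `TRUE` the learned positional encodings are
#'   replaced by zeros (permutation-equivariance diagnostics).
#' @return list with `logits`, `value`, `hidden = NULL`.
#' @export
transformer_forward <- function(agent, obs, params = NULL,
                                zero_posenc = FALSE) {
  cfg <- agent$config
  p <- if (is.null(params)) agent$params else params
  X <- ad_add_rowbias(ad_mm(obs, ad_t(p$emb_w)), p$emb_b)
  if (!zero_posenc) X <- ad_add(X, p$posenc)
  for (l in seq_len(cfg$n_blocks)) {
    X <- attention_block(X, p[[paste0("wq", l)]], p[[paste0("wk", l)]],
                         p[[paste0("wv", l)]], p[[paste0("wo", l)]],
                         p[[paste0("ff_w1_", l)]], p[[paste0("ff_b1_", l)]],
                         p[[paste0("ff_w2_", l)]], p[[paste0("ff_b2_", l)]],
                         cfg$n_heads)
  }
  pooled <- ad_colmeans(X)
  h <- ad_relu(ad_add(ad_mm(p$ro_w, pooled), p$ro_b))
  c(policy_value_head(p, h), list(hidden = NULL))
}

#' CoRelNet forward pass
#'
#' Computes the 49 x 49 similarity matrix `S[i, j] = <cell_i, cell_j>` among
#' the one-hot cell encodings (1 iff two cells share a category) and passes
#' its flattened form through a fully connected hidden layer to the policy
#' and value heads.
#'
#' @inheritParams lstm_meta_learner_forward
#' @return list with `logits`, `value`, `hidden = NULL`, and the similarity
#'   matrix as `similarity`.
#' @export
corelnet_forward <- function(agent, obs, params = NULL) {
  cfg <- agent$config
  p <- if (is.null(params)) agent$params else params
  S <- obs %*% t(obs)                  # observation is a plain input
  flat <- matrix(as.numeric(S), ncol = 1L)
  h <- ad_relu(ad_add(ad_mm(p$fc_w, flat), p$fc_b))
  c(policy_value_head(p, h), list(hidden = NULL, similarity = S))
}

#' Architecture-dispatching forward pass
#'
#' @param agent an `agent`.
#' @param obs observation matrix.
#' @param prev_action,prev_reward,hidden,memory recurrent inputs (ignored by
#'   feedforward architectures).
#' @param params optional parameter override.
#' @return list with `logits`, `value`, `hidden`.
#' @export
agent_forward <- function(agent, obs, prev_action = NULL, prev_reward = 0,
                          hidden = NULL, memory = NULL, params = NULL) {
  switch(agent$arch,
    lstm = lstm_meta_learner_forward(agent, obs, prev_action, prev_reward,
                                     hidden, params),
    epn = epn_forward(agent, obs, memory, prev_action, prev_reward, hidden,
                      params),
    transformer = transformer_forward(agent, obs, params),
    corelnet = corelnet_forward(agent, obs, params))
}

#' Bounded transition-memory buffer (EPN)
#'
#' Holds up to `capacity` transition tuples `(o_prev, a_onehot, o_next)`
#' flattened to vectors; pushing beyond capacity evicts the oldest entry.
#'
#' @param capacity maximum number of entries.
#' @return list of class `memory_buffer`.
#' @export
memory_buffer <- function(capacity = 10L) {
  structure(list(entries = list(), capacity = as.integer(capacity)),
            class = "memory_buffer")
}

#' @rdname memory_buffer
#' @param buffer a `memory_buffer`.
#' @param o_prev,o_next observation matrices before/after the transition.
#' @param action_onehot one-hot 49-vector of the action taken.
#' @export
memory_push <- function(buffer, o_prev, action_onehot, o_next) {
  entry <- c(as.numeric(o_prev), as.numeric(action_onehot), as.numeric(o_next))
  buffer$entries[[length(buffer$entries) + 1L]] <- entry
  if (length(buffer$entries) > buffer$capacity) {
    buffer$entries <- buffer$entries[-1L]
  }
  buffer
}

#' Action probabilities of an agent in a state
#'
#' Softmax of the agent's 49 policy logits for the given state.
#'
#' @param agent a trained (or fresh) `agent`.
#' @param state a `reveal_state`.
#' @param prev_action,prev_reward,hidden,memory recurrent context (optional).
#' @return numeric probability vector of length 49 (sums to 1).
#' @export
action_probabilities <- function(agent, state, prev_action = NULL,
                                 prev_reward = 0, hidden = NULL,
                                 memory = NULL) {
  out <- agent_forward(agent, env_observation(state), prev_action,
                       prev_reward, hidden, memory)
  as.numeric(exp(ad_log_softmax(ad_value(out$logits))))
}
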
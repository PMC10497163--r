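# hand-built conditional models for oracle checks of the Gibbs machinery

# constant red-probability model (stationary distribution = independent
# Bernoulli(p) per tile)
const_model <- function(p, n_cells = 49L) {
  structure(list(p = p, n_cells = n_cells),
            class = c("const_model", "conditional_model"))
}
.S3method("predict_tile_prob", "const_model",
          function(model, grid, mask_index) model$p)

# oracle that reads the true tile value off the grid
oracle_cond_model <- function(n_cells = 49L) {
  structure(list(n_cells = n_cells),
            class = c("oracle_cond_model", "conditional_model"))
}
.S3method("predict_tile_prob", "oracle_cond_model",
          function(model, grid, mask_index) as.numeric(grid[mask_index]))

# records every visited mask index (shared environment)
counting_model <- function(p = 0.5, n_cells = 49L) {
  log_env <- new.env(parent = emptyenv())
  log_env$visits <- integer(0)
  structure(list(p = p, n_cells = n_cells, log = log_env),
            class = c("counting_model", "conditional_model"))
}
.S3method("predict_tile_prob", "counting_model",
          function(model, grid, mask_index) {
            model$log$visits <- c(model$log$visits, mask_index)
            model$p
          })

# exact conditionals of a known 2x2 Ising-style joint:
#   pi(x) proportional to exp(theta * #matching adjacent pairs)
# (4 adjacent pairs on the 2x2 grid; cells column-major).  The conditional
# of each cell given the rest depends only on its two 4-neighbours (the
# opposite pair's contribution cancels in the ratio), so the constructor
# tabulates p(red | neighbours) once from the joint's log-weights.
ising2x2_model <- function(theta) {
  nb <- list(c(2L, 3L), c(1L, 4L), c(1L, 4L), c(2L, 3L))
  tab <- matrix(0, 4L, 4L)          # [cell, x_a + 2 x_b + 1]
  for (i in 1:4) for (xa in 0:1) for (xb in 0:1) {
    grid <- numeric(4)
    grid[nb[[i]][1L]] <- xa
    grid[nb[[i]][2L]] <- xb
    x1 <- grid; x1[i] <- 1
    x0 <- grid; x0[i] <- 0
    w1 <- exp(ising2x2_logweight(x1, theta))
    w0 <- exp(ising2x2_logweight(x0, theta))
    tab[i, xa + 2L * xb + 1L] <- w1 / (w1 + w0)
  }
  structure(list(theta = theta, nb = nb, tab = tab, n_cells = 4L),
            class = c("ising2x2_model", "conditional_model"))
}

ising2x2_logweight <- function(x, theta) {
  # cells: 1=(1,1) 2=(2,1) 3=(1,2) 4=(2,2); pairs: 1-2, 3-4, 1-3, 2-4
  pairs <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  theta * sum(x[pairs[, 1]] == x[pairs[, 2]])
}

ising2x2_exact <- function(theta) {
  states <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  w <- exp(apply(states, 1, ising2x2_logweight, theta = theta))
  list(states = states, probs = w / sum(w))
}

.S3method("predict_tile_prob", "ising2x2_model",
          function(model, grid, mask_index) {
            n <- model$nb[[mask_index]]
            model$tab[mask_index, grid[n[1L]] + 2 * grid[n[2L]] + 1]
          })

# misbehaving model for error-path checks
bad_model <- function() {
  structure(list(n_cells = 4L),
            class = c("bad_model", "conditional_model"))
}
.S3method("predict_tile_prob", "bad_model",
          function(model, grid, mask_index) 1.5)
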
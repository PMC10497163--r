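#' Experiment configuration
#'
#' Describes a full abstract-versus-metamer experiment: which rules, which
#' conditions, the architecture, the episode budget, and the seeds (one
#' trained agent per seed, mirroring "individuals" in the condition
#' comparisons).
#'
#' @param rules character vector of rule names.
#' @param conditions subset of `c("abstract", "metamer", "mixture")`.
#' @param architecture agent architecture (see [new_agent()]).
#' @param n_episodes training episodes per agent.
#' @param seeds integer vector; one agent is trained per seed.
#' @param n_test held-out test boards per rule (default 25).
#' @param heuristic_trials heuristic rollouts per board (default 1000).
#' @param eval_reps evaluation episodes per board.
#' @param a2c an [a2c_config()] template (its seed is replaced per run).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(rules, conditions = c("abstract", "metamer"),
                              architecture = "lstm", n_episodes = 10000L,
                              seeds = 1:3, n_test = 25L,
                              heuristic_trials = 1000L, eval_reps = 10L,
                              a2c = a2c_config()) {
  conditions <- match.arg(conditions, c("abstract", "metamer", "mixture"),
                          several.ok = TRUE)
  for (r in rules) check_rule(r)
  structure(list(rules = rules, conditions = conditions,
                 architecture = architecture,
                 n_episodes = as.integer(n_episodes),
                 seeds = as.integer(seeds), n_test = as.integer(n_test),
                 heuristic_trials = as.integer(heuristic_trials),
                 eval_reps = as.integer(eval_reps), a2c = a2c),
            class = "experiment_config")
}

#' Run a full train-and-evaluate condition grid
#'
#' For each (rule, condition, seed): builds the training sampler (abstract
#' rule generator, metamer Gibbs sampler from the rule's trained conditional
#' model, or a uniform mixture over all rules), trains an agent, evaluates
#' it on the held-out test set, and z-scores performance against the
#' nearest-neighbour heuristic.  One row per (board, rep).
#'
#' @param config an [experiment_config()].
#' @param conditional_models named list of trained [train_conditional_model()]
#'   objects keyed by rule; required for the `"metamer"` condition.
#' @return data.frame with columns `rule`, `condition`, `architecture`,
#'   `seed`, `board_id`, `rep`, `blue_count`, `z`, `total_reward`, `steps`.
#' @export
run_condition <- function(config, conditional_models = NULL) {
  out <- list()
  for (rule in config$rules) {
    dist <- generate_distribution(rule, n_test = config$n_test,
                                  seed = config$seeds[1L] * 1000L)
    for (condition in config$conditions) {
      setup <- switch(condition,
        abstract = list(sampler = dist$sampler, test = dist$test),
        metamer = {
          model <- conditional_models[[rule]]
          if (is.null(model)) {
            stop(sprintf(
              "no conditional model for rule '%s': run train_conditional_model() on its boards first",
              rule))
          }
          test <- generate_metamer_set(model, config$n_test,
                                       gibbs_config(seed = config$seeds[1L] * 1000L + 1L),
                                       rule_label = paste0(rule, "_metamer"))
          test_keys <- vapply(test, board_key, character(1))
          sampler <- function() {
            repeat {
              b <- generate_metamer_set(model, 1L)[[1L]]
              if (!board_key(b) %in% test_keys) return(b)
            }
          }
          list(sampler = sampler, test = test)
        },
        mixture = list(sampler = mixture_sampler(config$rules,
                                                 exclude = dist$test),
                       test = dist$test))
      for (seed in config$seeds) {
        agent <- new_agent(config$architecture, seed = seed)
        a2c <- config$a2c
        a2c$seed <- seed
        trained <- train_agent(agent, setup$sampler, config$n_episodes, a2c)
        ev <- evaluate_agent(trained$agent, setup$test,
                             heuristic_trials = config$heuristic_trials,
                             reps = config$eval_reps, seed = seed,
                             per_rep = TRUE)
        ev$rule <- rule
        ev$condition <- condition
        ev$architecture <- config$architecture
        ev$seed <- seed
        out[[length(out) + 1L]] <-
          ev[, c("rule", "condition", "architecture", "seed", "board_id",
                 "rep", "blue_count", "z", "total_reward", "steps")]
      }
    }
  }
  do.call(rbind, out)
}

#' Cross-training evaluation matrix
#'
#' Cell (i, j) holds the mean z-score (against the nearest-neighbour
#' heuristic) of the agent trained on rule i when evaluated on rule j's
#' held-out test set.
#'
#' @param agents named list of trained agents keyed by training rule.
#' @param test_sets named list of board lists keyed by rule.
#' @param heuristic_trials,reps,seed evaluation settings (see
#'   [evaluate_agent()]).
#' @return numeric matrix with training rules as rows and test rules as
#'   columns.
#' @export
cross_eval <- function(agents, test_sets, heuristic_trials = 1000L,
                       reps = 10L, seed = 1L) {
  if (is.null(names(agents)) || is.null(names(test_sets))) {
    stop("agents and test_sets must be named by rule")
  }
  z <- matrix(NA_real_, length(agents), length(test_sets),
              dimnames = list(names(agents), names(test_sets)))
  for (i in names(agents)) {
    for (j in names(test_sets)) {
      if (is.null(agents[[i]])) stop(sprintf("missing agent for rule '%s'", i))
      if (is.null(test_sets[[j]])) stop(sprintf("missing test set for rule '%s'", j))
      ev <- evaluate_agent(agents[[i]], test_sets[[j]],
                           heuristic_trials = heuristic_trials, reps = reps,
                           seed = seed)
      z[i, j] <- mean(ev$z)
    }
  }
  z
}

#' Two-sample t-test between condition scores
#'
#' Planned two-sample independent t-test (pooled variance, two-sided)
#' between per-agent mean z-scores of two conditions; each entry of a
#' sample is one agent's (seed's) mean across its test boards.
#'
#' @param scores_a,scores_b numeric vectors of per-agent mean scores
#'   (length >= 2 each).
#' @return list with `t`, `p`, and `df`.
#' @export
compare_conditions <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each condition needs at least 2 per-agent scores")
  }
  tt <- tryCatch(
    stats::t.test(scores_a, scores_b, var.equal = TRUE),
    error = function(e) {
      stop(sprintf("degenerate condition comparison: %s", conditionMessage(e)))
    })
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
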
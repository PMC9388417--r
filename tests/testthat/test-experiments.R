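test_that("with no information the agent guesses at probability one half", {
  cond <- make_condition("learning_off")
  agent <- anticipatr:::.condition_agent(cond)
  set.seed(2)
  trial <- run_trial(agent$model, agent$dirichlet, cond$env, "normal")
  n_act <- length(trial$actions)
  expect_equal(trial$action_probs[n_act], 0.5, tolerance = 1e-9)
  expect_identical(trial$actions[1], "wait")
})

test_that("the stronger information source dictates the single-trial commitment", {
  # strong contextual prior, weak cue: the opposing cue cannot revise beliefs
  strong <- make_condition("single_strong_prior_weak_cue")
  a <- anticipatr:::.condition_agent(strong)
  set.seed(3)
  t1 <- run_trial(a$model, a$dirichlet, strong$env, "changeup", mode = "argmax")
  expect_identical(t1$committed, "normal")
  expect_identical(t1$cue, "cue_changeup")
  # the belief at cue time (before the outcome is revealed) still favours
  # normal despite the opposing cue
  obs <- observation_matrix(a$model, cue = c("null", "cue_changeup"),
                            feedback = c("null", "null"))
  pre <- infer_states(a$model, obs, 1)
  expect_gt(pre$context[1, 2], 0.5)

  # weak prior, precise cue: beliefs are revised and the commitment follows
  weak <- make_condition("single_weak_prior_precise_cue")
  b <- anticipatr:::.condition_agent(weak)
  set.seed(3)
  t2 <- run_trial(b$model, b$dirichlet, weak$env, "changeup", mode = "argmax")
  expect_identical(t2$committed, "changeup")
})

test_that("trial records are internally consistent", {
  cond <- make_condition("congruency_both_congruent")
  agent <- anticipatr:::.condition_agent(cond)
  set.seed(5)
  trial <- run_trial(agent$model, agent$dirichlet, cond$env, "normal")
  expect_true(all(trial$action_probs >= 0 & trial$action_probs <= 1))
  expect_equal(colSums(trial$context_posterior), rep(1, 3), tolerance = 1e-9)
  expect_identical(trial$success, trial$feedback == "correct")
  expect_equal(nrow(trial$efe), 2L)
  expect_true(all(is.finite(trial$efe$G)))
})

test_that("batches are deterministic under a base seed and flag degenerate CIs", {
  r1 <- run_batch("learning_context", n_observers = 3, n_trials = 8,
                  base_seed = 17)
  r2 <- run_batch("learning_context", n_observers = 3, n_trials = 8,
                  base_seed = 17)
  expect_identical(r1$trials, r2$trials)
  r3 <- run_batch("learning_context", n_observers = 3, n_trials = 8,
                  base_seed = 18)
  expect_false(identical(r1$trials, r3$trials))

  solo <- run_batch("learning_off", n_observers = 1, n_trials = 5)
  expect_true(attr(solo, "ci_degenerate"))
  expect_equal(solo$summary$ci_lower, solo$summary$prop_normal)
  expect_equal(solo$summary$ci_upper, solo$summary$prop_normal)
})

test_that("summary statistics are recomputable from the per-trial table", {
  r <- run_batch("learning_context", n_observers = 4, n_trials = 10,
                 base_seed = 9)
  redo <- tapply(r$trials$committed == "normal", r$trials$trial, mean)
  expect_equal(unname(as.numeric(redo)), r$summary$prop_normal)
  redo_s <- tapply(r$trials$success, r$trials$trial, mean)
  expect_equal(unname(as.numeric(redo_s)), r$summary$success)
  expect_true(all(r$summary$ci_lower <= r$summary$ci_upper))
})

test_that("beta summaries map counts to Beta parameters and densities", {
  flat <- beta_summary(c(1, 1))
  expect_equal(flat$mean_alpha, 1)
  expect_true(all(abs(flat$density$y - 1) < 1e-12))

  b <- beta_summary(c(41, 11), grid_n = 20001L)
  expect_equal(b$mode, (41 - 1) / (52 - 2))
  # Simpson's rule on the returned grid: density integrates to 1
  x <- b$density$x
  y <- b$density$y
  h <- x[2] - x[1]
  n <- length(x)
  simpson <- h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
                        2 * sum(y[seq(3, n - 2, 2)]))
  expect_equal(simpson, 1, tolerance = 1e-6)
  expect_error(beta_summary(matrix(1, 2, 3)), "2 categories")
})

test_that("after a context reversal the cue learner adapts faster than the context learner", {
  ctx <- run_batch("learning_context_reversal", n_observers = 12, base_seed = 2)
  cue <- run_batch("learning_cue_reversal", n_observers = 12, base_seed = 2)
  cross_after <- function(r) {
    s <- r$summary
    post <- s$prop_normal[s$trial > 25]
    idx <- which(post < 0.5)[1]
    if (is.na(idx)) Inf else idx
  }
  expect_lt(cross_after(cue), cross_after(ctx))
})

test_that("batteries run every registered condition and write tidy artifacts", {
  res <- run_battery("single_trial", base_seed = 4)
  expect_s3_class(res, "aip_battery")
  expect_setequal(names(res), list_batteries()$single_trial)
  out <- withr::local_tempdir()
  paths <- write_battery(res, out)
  expect_true(all(file.exists(paths)))
  csv <- utils::read.csv(file.path(out, "single_trial",
                                   "single_strong_prior_weak_cue.csv"))
  expect_true(all(c("observer", "trial", "action", "action_prob", "success",
                    "posterior_changeup_t2", "free_energy") %in% names(csv)))
  expect_error(run_battery("nope"), "unknown battery")
})
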
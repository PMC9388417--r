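test_that("trial sequences follow the scheduled probabilities", {
  env0 <- environment_spec(p_changeup = 0)
  expect_true(all(generate_trial_sequence(env0, 100, seed = 1) == "normal"))

  env <- environment_spec(p_changeup = 0.2)
  balls <- generate_trial_sequence(env, 10000, seed = 2)
  expect_equal(attr(balls, "realised_marginal"), 0.2, tolerance = 0.01)

  expect_error(generate_trial_sequence(env, 0), "at least 1")
})

test_that("stable and volatile schedules share the same marginal", {
  stable <- environment_spec(p_changeup = 0.5)
  volatile <- environment_spec(
    schedule = data.frame(length = c(10, 10), p_changeup = c(0.8, 0.2))
  )
  b1 <- generate_trial_sequence(stable, 20000, seed = 3)
  b2 <- generate_trial_sequence(volatile, 20000, seed = 4)
  # scheduled marginals are analytically identical (0.5)
  expect_equal(mean(attr(b2, "p_trial")), mean(attr(b1, "p_trial")))
  expect_equal(attr(b1, "realised_marginal"),
               attr(b2, "realised_marginal"), tolerance = 0.02)
  # block bookkeeping cycles through the schedule
  expect_identical(attr(b2, "block")[1:21], c(rep(1L, 10), rep(2L, 10), 3L))
})

test_that("identical seeds give bit-identical sequences", {
  env <- environment_spec(p_changeup = 0.37)
  expect_identical(generate_trial_sequence(env, 500, seed = 11),
                   generate_trial_sequence(env, 500, seed = 11))
})

test_that("cue emission respects reliability and congruency", {
  con <- environment_spec(rho_true = 1, cue_congruent = TRUE)
  inc <- environment_spec(rho_true = 1, cue_congruent = FALSE)
  for (i in 1:10) {
    expect_identical(step_environment(con, "changeup", "observing")[["cue"]],
                     "cue_changeup")
    expect_identical(step_environment(inc, "changeup", "observing")[["cue"]],
                     "cue_normal")
  }
  forced <- environment_spec(cue_forced = "cue_changeup")
  expect_identical(step_environment(forced, "normal", "observing")[["cue"]],
                   "cue_changeup")
  # null outside the watching stage
  expect_identical(step_environment(con, "normal", "start")[["cue"]], "null")
})

test_that("feedback follows the deterministic rule and commitment absorbs", {
  env <- environment_spec(scenario = "tradeoff")
  expect_identical(step_environment(env, "normal", "late_normal")[["feedback"]],
                   "late_correct")
  expect_identical(step_environment(env, "changeup", "late_normal")[["feedback"]],
                   "incorrect")
  expect_identical(
    step_environment(env, "normal", "early_outcome_normal")[["feedback"]],
    "early_correct")
  simple <- environment_spec()
  expect_identical(step_environment(simple, "normal", "committed_normal")[["feedback"]],
                   "correct")
  expect_error(
    anticipatr:::.env_stage_step("simple", "committed_normal", "commit_changeup"),
    "after commitment")
  expect_error(
    anticipatr:::.env_stage_step("tradeoff", "late_normal", "late_changeup"),
    "after commitment")
})

test_that("the condition registry is complete and validated", {
  expect_setequal(names(list_batteries()),
                  c("learning_curves", "single_trial", "congruency",
                    "precision_conflict", "policy_precision", "reward_sweep",
                    "volatility"))
  for (nm in list_conditions()) {
    cond <- make_condition(nm)
    expect_s3_class(cond, "aip_condition")
    expect_s3_class(cond$env, "aip_env")
  }
  expect_error(make_condition("nope"), "unknown condition")
})

test_that("registered conditions encode their manipulations", {
  both <- make_condition("congruency_both_congruent")
  expect_true(both$env$cue_congruent && both$env$context_congruent)
  worst <- make_condition("congruency_both_incongruent")
  expect_false(worst$env$cue_congruent || worst$env$context_congruent)

  # the precision pair shares the 4:1 belief ratios but swaps which source
  # carries the high count mass
  cue_hi <- make_condition("precision_strong_cue")
  ctx_hi <- make_condition("precision_strong_context")
  expect_equal(cue_hi$agent$d_counts / sum(cue_hi$agent$d_counts),
               ctx_hi$agent$d_counts / sum(ctx_hi$agent$d_counts))
  expect_lt(sum(cue_hi$agent$d_counts), sum(ctx_hi$agent$d_counts))
  expect_gt(cue_hi$agent$cue_strength, ctx_hi$agent$cue_strength)

  med <- make_condition("reward_medium")
  expect_equal(med$agent$r_early, 4)
  gammas <- vapply(paste0("policy_precision_gamma", c(16, 4, 2, 1)),
                   function(nm) make_condition(nm)$agent$gamma, numeric(1))
  expect_equal(unname(gammas), c(16, 4, 2, 1))
})

test_that("condition overrides apply and unknown keys are rejected", {
  cond <- make_condition("learning_off", overrides = list(gamma = 4,
                                                          p_changeup = 0.3))
  expect_equal(cond$agent$gamma, 4)
  expect_equal(cond$env$p_changeup, 0.3)
  expect_error(make_condition("learning_off", overrides = list(bogus = 1)),
               "unknown override")
})
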
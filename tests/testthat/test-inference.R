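test_that("no information leaves the context posterior at the prior", {
  # uninformative cue: posterior 0.5/0.5 throughout
  m <- build_simple_model(d_counts = c(1, 1), rho_agent = 0.5)
  obs <- observation_matrix(m, cue = c("null", "cue_changeup"),
                            feedback = c("null", "null"))
  p <- infer_states(m, obs, 1)
  expect_equal(p$context, matrix(0.5, 2, 3), tolerance = 1e-9)
  # a prior carried through identity transitions
  m2 <- build_simple_model(d_counts = c(8, 2))
  obs2 <- observation_matrix(m2, cue = "null", feedback = "null")
  p2 <- infer_states(m2, obs2, 1)
  expect_equal(p2$context, matrix(c(0.8, 0.2), 2, 3), tolerance = 1e-9)
})

test_that("a reliable cue shifts the posterior to the exact Bayes value", {
  m <- build_simple_model(d_counts = c(1, 1), rho_agent = 0.9, cue_strength = 10)
  obs <- observation_matrix(m, cue = c("null", "cue_changeup"),
                            feedback = c("null", "null"))
  p <- infer_states(m, obs, 2)
  expect_equal(p$context[, 2], c(0.1, 0.9), tolerance = 1e-6)
  expect_true(p$converged)
})

test_that("posteriors match brute-force Bayes enumeration on random models", {
  set.seed(42)
  for (i in 1:40) {
    m <- if (i %% 4 == 0) random_tradeoff_model() else random_simple_model()
    pol <- sample(nrow(m$policies), 1)
    obs <- random_observations(m, pol)
    got <- infer_states(m, obs, pol)
    want <- brute_force_posterior(m, obs, pol)
    expect_lt(max(abs(got$joint - want$joint)), 1e-6)
    expect_equal(got$log_evidence, want$log_evidence, tolerance = 1e-8)
  }
})

test_that("free energy is zero for perfectly predicted observations", {
  m <- build_simple_model(d_counts = c(3, 7))
  obs <- observation_matrix(m, cue = "null", feedback = "null")
  p <- infer_states(m, obs, 1)
  expect_equal(variational_free_energy(m, p, obs, 1), 0, tolerance = 1e-10)
})

test_that("an uninformative binary observation costs ln 2 of free energy", {
  m <- build_simple_model(d_counts = c(1, 1), rho_agent = 0.5, cue_strength = 2)
  obs <- observation_matrix(m, cue = c("null", "cue_changeup"),
                            feedback = c("null", "null"))
  p <- infer_states(m, obs, 1)
  f <- variational_free_energy(m, p, obs, 1)
  expect_equal(f, log(2), tolerance = 1e-9)
  expect_equal(f, -p$log_evidence, tolerance = 1e-9)
})

test_that("converged posteriors attain lower free energy than prior beliefs", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_simple_model()
    pol <- sample(2, 1)
    obs <- random_observations(m, pol)
    prior_obs <- observation_matrix(m)  # nothing observed
    q_prior <- infer_states(m, prior_obs, pol)
    q_post <- infer_states(m, obs, pol)
    f_prior <- variational_free_energy(m, q_prior, obs, pol)
    f_post <- variational_free_energy(m, q_post, obs, pol)
    expect_lte(f_post, f_prior + 1e-9)
  }
})

test_that("expected free energy decomposes into risk + ambiguity - novelty", {
  set.seed(11)
  for (i in 1:10) {
    m <- if (i %% 2) random_simple_model() else random_tradeoff_model()
    dir <- dirichlet_beliefs(a_counts = m$a_counts, learn_cue = TRUE)
    obs <- observation_matrix(m, cue = "null", feedback = "null")
    for (pol in seq_len(nrow(m$policies))) {
      p <- infer_states(m, obs, pol)
      e <- expected_free_energy(m, p, pol, dir, from_t = 1)
      expect_equal(e$G, e$risk + e$ambiguity - e$novelty, tolerance = 1e-12)
      expect_gte(e$ambiguity, 0)
      expect_gte(e$risk, -1e-12)
      expect_gte(e$novelty, -1e-12)
    }
  }
})

test_that("risk and ambiguity match explicit enumeration, and ambiguity vanishes for a deterministic likelihood", {
  m <- build_simple_model(d_counts = c(1, 1), rho_agent = 0.8)
  obs <- observation_matrix(m, cue = "null", feedback = "null")
  p <- infer_states(m, obs, 1)
  got <- expected_free_energy(m, p, 1, from_t = 1)
  want <- brute_force_efe(m, p$joint, from_t = 1)
  expect_equal(got$risk, want$risk, tolerance = 1e-9)
  expect_equal(got$ambiguity, want$ambiguity, tolerance = 1e-9)
  # deterministic cue and feedback: no ambiguity anywhere
  md <- build_simple_model(rho_agent = 1, q_hit = 1)
  pd <- infer_states(md, obs, 1)
  expect_equal(expected_free_energy(md, pd, 1, from_t = 1)$ambiguity, 0,
               tolerance = 1e-9)
})

test_that("label-swap symmetry gives both policies equal expected free energy", {
  m <- build_simple_model(d_counts = c(1, 1), rho_agent = 0.8)
  obs <- observation_matrix(m, cue = "null", feedback = "null")
  G <- vapply(1:2, function(pol) {
    expected_free_energy(m, infer_states(m, obs, pol), pol, from_t = 1)$G
  }, numeric(1))
  expect_equal(G[1], G[2], tolerance = 1e-10)
})

test_that("policy posterior is a softmax with precision gamma", {
  expect_equal(policy_posterior(c(2, 2, 2), gamma = 5), rep(1 / 3, 3))
  expect_equal(policy_posterior(c(0.1, 9), gamma = 0), c(0.5, 0.5))
  # softmax(-G) computed by hand for G = (1, 2), gamma = 1
  expect_equal(policy_posterior(c(1, 2), gamma = 1),
               c(0.731058578630005, 0.268941421369995), tolerance = 1e-12)
  expect_error(policy_posterior(c(1, 2), gamma = -1), "nonnegative")
  expect_error(policy_posterior(c(1, NaN), gamma = 1), "finite")
})

test_that("higher gamma concentrates the posterior on the best policy", {
  set.seed(5)
  G <- runif(4, 0, 3)
  best <- which.min(G)
  p_best <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(g) {
    policy_posterior(G, g)[best]
  }, numeric(1))
  expect_true(all(diff(p_best) > 0))
})

test_that("action selection marginalises, samples reproducibly, and breaks ties low", {
  policies <- rbind(c(1L, 2L), c(1L, 3L))
  sel <- select_action(c(1, 0), policies, t = 2, mode = "argmax")
  expect_identical(sel$action, 2L)
  expect_equal(sel$prob, 1)
  # both policies share the same first action: probability mass 1
  sel1 <- select_action(c(0.3, 0.7), policies, t = 1)
  expect_identical(sel1$action, 1L)
  expect_equal(sel1$prob, 1)
  # argmax tie -> lowest action index
  tie <- select_action(c(0.5, 0.5), policies, t = 2, mode = "argmax")
  expect_identical(tie$action, 2L)
  # seeded sampling reproduces
  a <- replicate(5, select_action(c(0.5, 0.5), policies, t = 2, seed = 9)$action)
  expect_true(all(a == a[1]))
})

test_that("sampled action frequencies follow the marginal", {
  policies <- rbind(c(1L, 2L), c(1L, 3L))
  set.seed(123)
  draws <- replicate(10000,
    select_action(c(0.75, 0.25), policies, t = 2)$action)
  expect_equal(mean(draws == 2L), 0.75, tolerance = 0.02)
})

test_that("dirichlet updates add posterior-weighted counts only when enabled", {
  d0 <- dirichlet_beliefs(d_counts = c(1, 1))
  trial <- list(context_posterior_t1 = c(1, 0), cue_index = 3L,
                context_posterior_cue = c(1, 0))
  expect_identical(update_dirichlet(d0, trial), d0)

  d1 <- dirichlet_beliefs(d_counts = c(1, 1), learn_context = TRUE)
  expect_equal(update_dirichlet(d1, trial)$d_counts, c(2, 1))

  # 40 certain normal + 10 certain changeup observations
  d <- dirichlet_beliefs(d_counts = c(1, 1), learn_context = TRUE)
  for (i in 1:40) d <- update_dirichlet(d, list(context_posterior_t1 = c(1, 0)))
  for (i in 1:10) d <- update_dirichlet(d, list(context_posterior_t1 = c(0, 1)))
  expect_equal(d$d_counts, c(41, 11))
  expect_equal(normalize_counts(d$d_counts), c(41, 11) / 52, tolerance = 1e-12)

  # cue learning updates only the observed cue row; null cue is a no-op
  a0 <- rbind(null = c(0, 0), cue_normal = c(2, 1), cue_changeup = c(1, 2))
  dc <- dirichlet_beliefs(a_counts = a0, learn_cue = TRUE)
  up <- update_dirichlet(dc, list(cue_index = 3L,
                                  context_posterior_cue = c(0.2, 0.8)))
  expect_equal(up$a_counts["cue_changeup", ], c(1.2, 2.8))
  expect_equal(up$a_counts["cue_normal", ], a0["cue_normal", ])
  same <- update_dirichlet(dc, list(cue_index = 1L,
                                    context_posterior_cue = c(0.2, 0.8)))
  expect_identical(same$a_counts, a0)
})
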
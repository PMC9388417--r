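# Independent oracles used across the suite.
#
# brute_force_posterior enumerates every joint-state trajectory of the
# three-timepoint chain and computes Bayes posteriors by direct summation; it
# shares only the model's probability tables with infer_states, not its
# message-passing algorithm.

brute_force_posterior <- function(model, observations, policy) {
  actions <- if (length(policy) == 1L) model$policies[policy, ] else policy
  n <- model$n_joint
  horizon <- model$horizon
  ev <- matrix(1, n, horizon)
  for (m in seq_along(model$modalities)) {
    for (tau in seq_len(horizon)) {
      o <- observations[m, tau]
      if (!is.na(o)) ev[, tau] <- ev[, tau] * model$A_joint[[m]][o, ]
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), horizon)))
  w <- model$D_joint[paths[, 1L]] * ev[cbind(paths[, 1L], 1L)]
  for (tau in 2:horizon) {
    B <- model$B_joint[[actions[tau - 1L]]]
    w <- w * B[cbind(paths[, tau], paths[, tau - 1L])] *
      ev[cbind(paths[, tau], tau)]
  }
  z <- sum(w)
  joint <- vapply(seq_len(horizon), function(tau) {
    as.numeric(tapply(w, paths[, tau], sum)) / z
  }, numeric(n))
  n_ctx <- length(model$labels$context)
  list(
    joint = joint,
    context = apply(joint, 2L, function(qt) rowSums(matrix(qt, nrow = n_ctx))),
    log_evidence = log(z)
  )
}

# Independent expected-free-energy evaluation by explicit summation over
# outcomes and joint states (no KL/entropy helpers shared with the package).
brute_force_efe <- function(model, joint_posteriors, from_t = 1L) {
  risk <- 0
  ambiguity <- 0
  for (tau in seq_len(model$horizon)) {
    if (tau <= from_t) next
    qt <- joint_posteriors[, tau]
    for (m in names(model$modalities)) {
      A <- model$A_joint[[m]]
      cvec <- exp(model$C[[m]][, tau])
      cvec <- cvec / sum(cvec)
      o_pred <- as.numeric(A %*% qt)
      for (o in seq_along(o_pred)) {
        if (o_pred[o] > 0) {
          risk <- risk + o_pred[o] * (log(o_pred[o]) - log(max(cvec[o], 1e-16)))
        }
      }
      for (s in seq_len(ncol(A))) {
        h <- 0
        for (o in seq_len(nrow(A))) {
          if (A[o, s] > 0) h <- h - A[o, s] * log(A[o, s])
        }
        ambiguity <- ambiguity + qt[s] * h
      }
    }
  }
  list(risk = risk, ambiguity = ambiguity, G = risk + ambiguity)
}

random_simple_model <- function() {
  build_simple_model(
    d_counts = stats::runif(2, 0.2, 10),
    rho_agent = stats::runif(1, 0.05, 0.95),
    cue_strength = stats::runif(1, 2, 60),
    reward = stats::runif(1, 0.5, 8),
    loss = stats::runif(1, 0.5, 8),
    q_hit = stats::runif(1, 0.6, 1),
    gamma = stats::runif(1, 0.5, 20)
  )
}

random_tradeoff_model <- function() {
  r_early <- stats::runif(1, 1, 8)
  build_tradeoff_model(
    d_counts = stats::runif(2, 0.2, 10),
    rho_agent = stats::runif(1, 0.05, 0.95),
    cue_strength = stats::runif(1, 2, 60),
    r_early = r_early,
    r_late = r_early * stats::runif(1, 0.2, 0.9),
    loss = stats::runif(1, 0.5, 8),
    q_hit = stats::runif(1, 0.6, 1)
  )
}

# Observations consistent with a policy rollout: a cue at the cue stage (when
# visited) and feedback at the outcome; truncated at a random horizon.
random_observations <- function(model, policy) {
  actions <- model$policies[policy, ]
  obs <- matrix(NA_integer_, length(model$modalities), model$horizon,
                dimnames = list(names(model$modalities), NULL))
  obs[, 1L] <- 1L  # null, null at the start stage
  upto <- sample(1:3, 1L)
  stage <- "start"
  for (tau in 2:model$horizon) {
    stage_idx <- which(model$B$stage[, match(stage, model$labels$stage),
                                     actions[tau - 1L]] == 1)
    stage <- model$labels$stage[stage_idx]
    if (tau > upto) next
    if (stage == "observing") {
      obs["cue", tau] <- sample(2:3, 1L)
      obs["feedback", tau] <- 1L
    } else {
      obs["cue", tau] <- 1L
      fb <- model$modalities$feedback
      emitted <- which(rowSums(model$A$feedback[, , stage_idx, drop = FALSE] > 0) > 0)
      emitted <- setdiff(emitted, 1L)
      obs["feedback", tau] <- if (length(emitted)) sample(rep(emitted, 2), 1L) else 1L
    }
  }
  obs
}
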
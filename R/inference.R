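# Belief updating, free energies, policy evaluation and learning.
#
# Given a policy, the within-trial model is a three-timepoint chain over the
# joint (context x stage) state. infer_states runs iterated sum-product
# message passing (forward/backward) on that chain, a fixed-point scheme that
# is exact on these tree-structured models: converged marginals equal the
# brute-force Bayes posterior over the full joint.

# Map observation labels to an index matrix (modalities x timepoints).
.obs_matrix <- function(model, horizon = model$horizon) {
  m <- matrix(NA_integer_, nrow = length(model$modalities), ncol = horizon,
              dimnames = list(names(model$modalities), NULL))
  m
}

# Per-timepoint joint-state evidence from the observed outcomes.
.evidence <- function(model, observations) {
  ev <- matrix(1, nrow = model$n_joint, ncol = model$horizon)
  for (m in seq_along(model$modalities)) {
    for (tau in seq_len(model$horizon)) {
      o <- observations[m, tau]
      if (!is.na(o)) ev[, tau] <- ev[, tau] * model$A_joint[[m]][o, ]
    }
  }
  ev
}

# Resolve a policy argument (row index or action-index vector).
.policy_actions <- function(model, policy) {
  if (length(policy) == 1L) {
    model$policies[policy, ]
  } else {
    as.integer(policy)
  }
}

#' Infer posteriors over hidden states under a policy
#'
#' Combines the contextual and behavioural priors, the policy's transition
#' messages, and the likelihood evidence of every observed timepoint by
#' iterated forward/backward message passing on the joint-state chain, until
#' the largest absolute belief change falls below `tol` (default `1e-6`) or
#' `max_iter` sweeps (default 64). On these models the converged marginals
#' equal the exact Bayes posterior; timepoints without observations carry the
#' forward predictive beliefs.
#'
#' @param model An `aip_model`.
#' @param observations Integer matrix (modalities x timepoints) of outcome
#'   indices, `NA` where nothing has been observed; see [observation_matrix()].
#' @param policy Policy row index in `model$policies`, or a vector of action
#'   indices (one per transition).
#' @param tol,max_iter Convergence tolerance and sweep cap. Non-convergence
#'   returns the best iterate with `converged = FALSE`, with a warning.
#' @return An `aip_posteriors` list: `joint` (joint-state marginals per
#'   timepoint), `context` and `stage` factor marginals, `log_evidence` of the
#'   observations under the policy, iteration count and convergence flag.
#' @export
infer_states <- function(model, observations, policy, tol = 1e-6,
                         max_iter = 64L) {
  stopifnot(inherits(model, "aip_model"))
  if (!is.matrix(observations) || nrow(observations) != length(model$modalities) ||
      ncol(observations) != model$horizon) {
    stop("observations must be a modalities x horizon index matrix")
  }
  actions <- .policy_actions(model, policy)
  horizon <- model$horizon
  B <- lapply(actions, function(a) model$B_joint[[a]])
  ev <- .evidence(model, observations)

  n <- model$n_joint
  q <- matrix(1 / n, n, horizon)
  n_iter <- 0L
  converged <- FALSE
  logZ <- NA_real_
  repeat {
    n_iter <- n_iter + 1L
    f <- matrix(0, n, horizon)
    z <- numeric(horizon)
    msg <- model$D_joint
    for (tau in seq_len(horizon)) {
      if (tau > 1L) msg <- B[[tau - 1L]] %*% f[, tau - 1L]
      a <- as.vector(msg) * ev[, tau]
      z[tau] <- sum(a)
      if (z[tau] <= 0) stop("observations have zero probability under the model")
      f[, tau] <- a / z[tau]
    }
    b <- matrix(1, n, horizon)
    for (tau in rev(seq_len(horizon - 1L))) {
      b[, tau] <- crossprod(B[[tau]], b[, tau + 1L] * ev[, tau + 1L])
    }
    q_new <- f * b
    q_new <- sweep(q_new, 2L, colSums(q_new), "/")
    delta <- max(abs(q_new - q))
    q <- q_new
    logZ <- sum(log(z))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= max_iter) break
  }
  if (!converged) {
    warning("infer_states: belief updating did not converge within max_iter")
  }
  n_ctx <- length(model$labels$context)
  by_factor <- function(qt) {
    m <- matrix(qt, nrow = n_ctx)
    list(context = rowSums(m), stage = colSums(m))
  }
  fac <- apply(q, 2L, by_factor)
  structure(
    list(
      joint = q,
      context = vapply(fac, `[[`, numeric(n_ctx), "context"),
      stage = vapply(fac, `[[`, numeric(model$n_joint / n_ctx), "stage"),
      log_evidence = logZ,
      n_iter = n_iter,
      converged = converged,
      actions = actions
    ),
    class = "aip_posteriors"
  )
}

#' Observation index matrix helper
#'
#' Builds the (modalities x timepoints) observation matrix consumed by
#' [infer_states()], filled with `NA`, optionally setting labelled outcomes.
#'
#' @param model An `aip_model`.
#' @param ... Named timepoint entries, e.g. `cue = c(NA, "cue_changeup", NA)`.
#' @return Integer matrix with one row per modality.
#' @export
observation_matrix <- function(model, ...) {
  obs <- .obs_matrix(model)
  fill <- list(...)
  for (m in names(fill)) {
    labs <- fill[[m]]
    idx <- match(labs, model$modalities[[m]])
    if (any(!is.na(labs) & is.na(idx))) {
      stop(sprintf("unknown outcome label for modality '%s'", m))
    }
    obs[m, seq_along(idx)] <- idx
  }
  obs
}

#' Variational free energy of posterior beliefs
#'
#' Evaluates the discrete free-energy functional
#' `sum_tau q_tau . (ln q_tau - ln m_tau) - sum_observed q_tau . ln P(o_tau | s_tau)`
#' where `m_1` is the prior D and `m_tau` the one-step forward prediction
#' `B q_{tau-1}` (the empirical prior). It upper-bounds the surprisal of the
#' observations under the policy; at the converged posteriors it is the
#' tightest value the functional attains, so free energy from converged
#' posteriors never exceeds free energy evaluated at prior beliefs.
#'
#' @inheritParams infer_states
#' @param posteriors An `aip_posteriors` object for the same observations and
#'   policy (any normalized beliefs may be supplied to probe the functional).
#' @return Scalar free energy in nats.
#' @export
variational_free_energy <- function(model, posteriors, observations, policy) {
  actions <- .policy_actions(model, policy)
  q <- posteriors$joint
  if (nrow(q) != model$n_joint || ncol(q) != model$horizon) {
    stop("posteriors do not match the model dimensions")
  }
  ev <- .evidence(model, observations)
  f <- 0
  for (tau in seq_len(model$horizon)) {
    m <- if (tau == 1L) model$D_joint
         else as.vector(model$B_joint[[actions[tau - 1L]]] %*% q[, tau - 1L])
    qt <- q[, tau]
    f <- f + sum(qt * (.logp(qt) - .logp(m))) - sum(qt * .logp(ev[, tau]))
  }
  f
}

#' Expected free energy of a policy
#'
#' For every timepoint after `from_t`, accumulates over modalities the risk
#' (KL divergence from the predicted outcome distribution to the preference
#' distribution `softmax(C)`), the ambiguity (expected conditional entropy of
#' the likelihood mapping under the predicted states), and, when cue learning
#' is enabled in `dirichlet`, the novelty (expected information gain about
#' the cue-likelihood Dirichlet counts), with `G = risk + ambiguity - novelty`.
#'
#' @inheritParams infer_states
#' @param posteriors `aip_posteriors` holding predictive beliefs for future
#'   timepoints under this policy.
#' @param dirichlet Optional `aip_dirichlet`; the novelty term is zero unless
#'   `dirichlet$learn_cue` is `TRUE`.
#' @param from_t Current timepoint; risk/ambiguity/novelty are accumulated
#'   over timepoints `from_t + 1, ..., horizon`.
#' @return An `aip_efe` list with components `G`, `risk`, `ambiguity`,
#'   `novelty`.
#' @export
expected_free_energy <- function(model, posteriors, policy, dirichlet = NULL,
                                 from_t = 1L) {
  q <- posteriors$joint
  risk <- 0
  ambiguity <- 0
  novelty <- 0
  learn_cue <- !is.null(dirichlet) && isTRUE(dirichlet$learn_cue)
  W <- NULL
  if (learn_cue) {
    a <- dirichlet$a_counts
    Wm <- matrix(0, nrow(a), ncol(a))
    pos <- a > 0
    Wm[pos] <- 0.5 * (1 / a[pos] -
                        1 / rep(colSums(a), each = nrow(a))[pos])
    W <- array(0, dim = dim(model$A$cue))
    W[, , match("observing", model$labels$stage)] <- Wm
  }
  taus <- seq_len(model$horizon)
  taus <- taus[taus > from_t]
  for (tau in taus) {
    qt <- q[, tau]
    for (m in seq_along(model$modalities)) {
      A <- model$A_joint[[m]]
      o_pred <- as.vector(A %*% qt)
      cdist <- softmax(model$C[[names(model$modalities)[m]]][, tau])
      risk <- risk + .kl_div(o_pred, cdist)
      colH <- -colSums(A * .logp(A) * (A > 0))
      ambiguity <- ambiguity + sum(qt * colH)
    }
    if (learn_cue) {
      Wj <- matrix(W, nrow = dim(W)[1L])
      A <- model$A_joint[["cue"]]
      novelty <- novelty + sum(qt * colSums(A * Wj))
    }
  }
  structure(list(G = risk + ambiguity - novelty, risk = risk,
                 ambiguity = ambiguity, novelty = novelty),
            class = "aip_efe")
}

#' Posterior over policies from expected free energy
#'
#' `softmax(ln habits - gamma * G)`: policy precision `gamma` sharpens the
#' posterior around the lowest-G policy; `gamma = 0` returns the habit prior
#' (uniform by default).
#'
#' @param G Numeric vector of finite expected free energies (or an `aip_efe`
#'   list per policy via `sapply`).
#' @param gamma Nonnegative policy precision.
#' @param habits Optional prior over policies; defaults to uniform.
#' @return Normalized probability vector over policies.
#' @export
policy_posterior <- function(G, gamma, habits = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop("gamma must be a nonnegative scalar")
  }
  if (!all(is.finite(G))) stop("G values must be finite")
  if (is.null(habits)) habits <- rep(1 / length(G), length(G))
  .check_dist(habits, "habits")
  softmax(.logp(habits) - gamma * G)
}

#' Select the next action from the policy posterior
#'
#' Marginalises the policy posterior onto the action taken at transition `t`,
#' then samples from that marginal (default) or takes its argmax (ties broken
#' by the lowest action index). The probability of the chosen action is
#' returned alongside it.
#'
#' @param policy_post Normalized posterior over the rows of `policies`.
#' @param policies Integer policy matrix (policies x transitions) of action
#'   indices.
#' @param t Transition index at which to act.
#' @param mode `"sample"` (uses the current RNG state) or `"argmax"`.
#' @param seed Optional integer seed applied before sampling.
#' @return List with `action` (index), `prob` (its marginal probability), and
#'   `action_probs` (named marginal over all action indices at `t`).
#' @export
select_action <- function(policy_post, policies, t = 1L,
                          mode = c("sample", "argmax"), seed = NULL) {
  mode <- match.arg(mode)
  .check_dist(policy_post, "policy posterior", tol = 1e-8)
  acts <- policies[, t]
  p_act <- tapply(policy_post, acts, sum)
  action_ids <- as.integer(names(p_act))
  p_act <- as.numeric(p_act)
  if (!is.null(seed)) set.seed(seed)
  pick <- if (mode == "argmax") {
    which.max(p_act)
  } else {
    sample.int(length(p_act), 1L, prob = p_act)
  }
  list(action = action_ids[pick], prob = p_act[pick],
       action_probs = stats::setNames(p_act, action_ids))
}

#' Update Dirichlet beliefs from a completed trial
#'
#' With context learning on, the trial-start context posterior (after all
#' observations, including the revealed outcome) is added to `d_counts`
#' scaled by the learning rate. With cue learning on, the row of `a_counts`
#' for the observed cue receives the cue-time context posterior, likewise
#' scaled. Disabled components are returned unchanged.
#'
#' @param dirichlet An `aip_dirichlet`.
#' @param trial List with `context_posterior_t1` (length-2), `cue_index`
#'   (outcome index into the cue modality, `NA` or the null outcome when no
#'   cue was seen), and `context_posterior_cue` (length-2 context posterior at
#'   the cue timepoint).
#' @return The updated `aip_dirichlet`.
#' @export
update_dirichlet <- function(dirichlet, trial) {
  stopifnot(inherits(dirichlet, "aip_dirichlet"))
  if (dirichlet$learn_context) {
    p <- trial$context_posterior_t1
    .check_dist(p, "context posterior", tol = 1e-8)
    dirichlet$d_counts <- dirichlet$d_counts + dirichlet$eta * p
  }
  if (dirichlet$learn_cue) {
    o <- trial$cue_index
    if (!is.na(o) && o != 1L) {  # index 1 is the null outcome
      p <- trial$context_posterior_cue
      .check_dist(p, "cue-time context posterior", tol = 1e-8)
      dirichlet$a_counts[o, ] <- dirichlet$a_counts[o, ] + dirichlet$eta * p
    }
  }
  dirichlet
}
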
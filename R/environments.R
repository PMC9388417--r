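# The generative process: true trial sequences, cue emission with
# configurable congruency, feedback delivery, and the registry of
# experimental conditions and batteries.

#' Specify a generative process (the environment's ground truth)
#'
#' @param p_changeup True probability of a change-up ball per trial (ignored
#'   when a `schedule` is given).
#' @param rho_true True cue reliability in `[0, 1]`.
#' @param cue_congruent If `FALSE` the cue indicates the opposite ball (with
#'   reliability `rho_true`).
#' @param context_congruent Whether the agent's initial contextual counts
#'   favour the true majority ball (used by the condition registry when
#'   pairing agents with environments).
#' @param cue_forced Optional fixed cue label (`"cue_normal"` or
#'   `"cue_changeup"`) emitted on every trial regardless of the ball.
#' @param q_hit Probability that a correct commitment yields positive
#'   feedback.
#' @param schedule Optional volatility schedule: data frame with columns
#'   `length` (positive block lengths) and `p_changeup`, cycled across trials.
#' @param scenario `"simple"` or `"tradeoff"`.
#' @return An `aip_env` specification.
#' @export
environment_spec <- function(p_changeup = 0.5, rho_true = 0.8,
                             cue_congruent = TRUE, context_congruent = TRUE,
                             cue_forced = NULL, q_hit = 1, schedule = NULL,
                             scenario = c("simple", "tradeoff")) {
  scenario <- match.arg(scenario)
  probs <- c(p_changeup = p_changeup, rho_true = rho_true, q_hit = q_hit)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("p_changeup, rho_true and q_hit must lie in [0, 1]")
  }
  if (!is.null(schedule)) {
    schedule <- as.data.frame(schedule)
    if (!all(c("length", "p_changeup") %in% names(schedule))) {
      stop("schedule needs columns 'length' and 'p_changeup'")
    }
    if (any(schedule$length < 1) || any(schedule$p_changeup < 0) ||
        any(schedule$p_changeup > 1)) {
      stop("schedule block lengths must be positive and probabilities in [0, 1]")
    }
  }
  if (!is.null(cue_forced) &&
      !cue_forced %in% c("cue_normal", "cue_changeup")) {
    stop("cue_forced must be 'cue_normal' or 'cue_changeup'")
  }
  structure(
    list(p_changeup = p_changeup, rho_true = rho_true,
         cue_congruent = isTRUE(cue_congruent),
         context_congruent = isTRUE(context_congruent),
         cue_forced = cue_forced, q_hit = q_hit, schedule = schedule,
         scenario = scenario),
    class = "aip_env"
  )
}

#' Generate a true trial sequence of ball labels
#'
#' Independent draws at `p_changeup`, or block-wise draws following the
#' volatility schedule (blocks cycled until `n_trials` is reached). Seeded
#' draws are bit-reproducible.
#'
#' @param spec An `aip_env` specification.
#' @param n_trials Number of trials (at least 1).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return Character vector of `"normal"`/`"changeup"` with attributes
#'   `p_trial` (scheduled per-trial probability), `block` (block index) and
#'   `realised_marginal` (observed change-up fraction).
#' @export
generate_trial_sequence <- function(spec, n_trials, seed = NULL) {
  stopifnot(inherits(spec, "aip_env"))
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spec$schedule)) {
    if (is.null(spec$p_changeup)) {
      stop("empty schedule with no base probability")
    }
    p <- rep(spec$p_changeup, n_trials)
    block <- rep(1L, n_trials)
  } else {
    lens <- spec$schedule$length
    ps <- spec$schedule$p_changeup
    reps <- ceiling(n_trials / sum(lens))
    p <- rep(rep(ps, times = lens), reps)[seq_len(n_trials)]
    block <- rep(rep(seq_along(lens), times = lens), reps)[seq_len(n_trials)]
    block <- block + rep((seq_len(reps) - 1L) * length(lens),
                         each = sum(lens))[seq_len(n_trials)]
  }
  balls <- ifelse(stats::runif(n_trials) < p, "changeup", "normal")
  attr(balls, "p_trial") <- p
  attr(balls, "block") <- block
  attr(balls, "realised_marginal") <- mean(balls == "changeup")
  balls
}

# Deterministic behavioural-stage dynamics of the generative process,
# mirroring the agent's B tables. Errors on actions after commitment.
.env_stage_step <- function(scenario, stage, action) {
  if (scenario == "simple") {
    absorbing <- c("committed_normal", "committed_changeup")
    if (stage %in% absorbing) {
      if (action != "wait") stop("action after commitment (absorbing stage)")
      return(stage)
    }
    switch(action,
      wait = "observing",
      commit_normal = "committed_normal",
      commit_changeup = "committed_changeup",
      stop(sprintf("unknown action '%s'", action))
    )
  } else {
    if (stage %in% c("early_normal", "early_changeup")) {
      if (!action %in% c("wait")) stop("action after commitment (absorbing stage)")
      return(sub("^early", "early_outcome", stage))
    }
    absorbing <- c("early_outcome_normal", "early_outcome_changeup",
                   "late_normal", "late_changeup")
    if (stage %in% absorbing) {
      if (action != "wait") stop("action after commitment (absorbing stage)")
      return(stage)
    }
    switch(action,
      wait = "observing",
      early_normal = "early_normal",
      early_changeup = "early_changeup",
      late_normal = "late_normal",
      late_changeup = "late_changeup",
      stop(sprintf("unknown action '%s'", action))
    )
  }
}

#' Emit the environment's observations for one timepoint
#'
#' The cue is emitted while the observer is in the watching stage, pointing
#' at the true ball with reliability `rho_true` (direction flipped when
#' `cue_congruent` is `FALSE`, overridden entirely by `cue_forced`).
#' Feedback is emitted once the observer occupies a commitment-outcome stage,
#' tagged early/late in the trade-off scenario. All other stages emit the
#' null outcome.
#'
#' @param spec An `aip_env` specification.
#' @param ball True ball label for the trial.
#' @param stage The observer's current behavioural stage label.
#' @return Named character vector with elements `cue` and `feedback`.
#' @export
step_environment <- function(spec, ball, stage) {
  stopifnot(inherits(spec, "aip_env"), ball %in% CONTEXT_LABELS)
  cue <- "null"
  feedback <- "null"
  if (stage == "observing") {
    if (!is.null(spec$cue_forced)) {
      cue <- spec$cue_forced
    } else {
      target <- if (spec$cue_congruent) ball else setdiff(CONTEXT_LABELS, ball)
      other <- setdiff(CONTEXT_LABELS, target)
      hit <- stats::runif(1L) < spec$rho_true
      cue <- paste0("cue_", if (hit) target else other)
    }
  }
  commit <- switch(stage,
    committed_normal = c("normal", "correct"),
    committed_changeup = c("changeup", "correct"),
    early_outcome_normal = c("normal", "early_correct"),
    early_outcome_changeup = c("changeup", "early_correct"),
    late_normal = c("normal", "late_correct"),
    late_changeup = c("changeup", "late_correct"),
    NULL
  )
  if (!is.null(commit)) {
    if (commit[1L] == ball) {
      hit <- spec$q_hit == 1 || stats::runif(1L) < spec$q_hit
      feedback <- if (hit) commit[2L] else "incorrect"
    } else {
      feedback <- "incorrect"
    }
  }
  c(cue = cue, feedback = feedback)
}

# ---------------------------------------------------------------------------
# Condition registry

.batteries <- list(
  learning_curves = c("learning_off", "learning_context", "learning_cue",
                      "learning_context_reversal", "learning_cue_reversal"),
  single_trial = c("single_strong_prior_weak_cue",
                   "single_weak_prior_precise_cue"),
  congruency = c("congruency_both_congruent", "congruency_cue_incongruent",
                 "congruency_context_incongruent",
                 "congruency_both_incongruent"),
  precision_conflict = c("precision_strong_cue", "precision_strong_context"),
  policy_precision = c("policy_precision_gamma16", "policy_precision_gamma4",
                       "policy_precision_gamma2", "policy_precision_gamma1"),
  reward_sweep = c("reward_low", "reward_medium", "reward_high"),
  volatility = c("volatility_stable", "volatility_volatile")
)

#' List experiment batteries and their conditions
#'
#' @return Named list mapping battery names to condition-name vectors.
#' @export
list_batteries <- function() .batteries

#' List all registered condition names
#' @return Character vector.
#' @export
list_conditions <- function() unname(unlist(.batteries))

# Base agent configuration; condition entries override fields.
.agent_defaults <- list(
  d_counts = c(1, 1), rho_agent = 0.8, cue_strength = 10,
  reward = 4, loss = 4, r_early = 4, r_late = 3,
  q_hit = 1, gamma = 16, learn_context = FALSE, learn_cue = FALSE, eta = 1
)

.condition_table <- function() {
  flat_cue <- list(rho_agent = 0.5, cue_strength = 2)
  reversal <- data.frame(length = c(25, 25), p_changeup = c(0.2, 0.8))
  volatile <- data.frame(length = c(10, 10), p_changeup = c(0.8, 0.2))
  list(
    learning_off = list(
      battery = "learning_curves", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8),
      agent = flat_cue,
      n_observers = 50, n_trials = 50
    ),
    learning_context = list(
      battery = "learning_curves", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8),
      agent = c(flat_cue, list(learn_context = TRUE)),
      n_observers = 50, n_trials = 50
    ),
    learning_cue = list(
      battery = "learning_curves", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8),
      agent = c(flat_cue, list(learn_cue = TRUE)),
      n_observers = 50, n_trials = 50
    ),
    learning_context_reversal = list(
      battery = "learning_curves", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8, schedule = reversal),
      agent = c(flat_cue, list(learn_context = TRUE)),
      n_observers = 50, n_trials = 50
    ),
    learning_cue_reversal = list(
      battery = "learning_curves", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8, schedule = reversal),
      agent = c(flat_cue, list(learn_cue = TRUE)),
      n_observers = 50, n_trials = 50
    ),
    single_strong_prior_weak_cue = list(
      battery = "single_trial", scenario = "simple",
      env = list(p_changeup = 0.5, cue_forced = "cue_changeup"),
      agent = list(d_counts = c(40, 10), rho_agent = 0.6, cue_strength = 50),
      n_observers = 1, n_trials = 1, mode = "argmax"
    ),
    single_weak_prior_precise_cue = list(
      battery = "single_trial", scenario = "simple",
      env = list(p_changeup = 0.5, cue_forced = "cue_changeup"),
      agent = list(d_counts = c(6, 4), rho_agent = 0.9, cue_strength = 50),
      n_observers = 1, n_trials = 1, mode = "argmax"
    ),
    congruency_both_congruent = list(
      battery = "congruency", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8, cue_congruent = TRUE,
                 context_congruent = TRUE),
      agent = list(d_counts = c(8, 2), rho_agent = 0.9, cue_strength = 15,
                   learn_context = TRUE, learn_cue = TRUE),
      n_observers = 50, n_trials = 100
    ),
    congruency_cue_incongruent = list(
      battery = "congruency", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8, cue_congruent = FALSE,
                 context_congruent = TRUE),
      agent = list(d_counts = c(8, 2), rho_agent = 0.9, cue_strength = 15,
                   learn_context = TRUE, learn_cue = TRUE),
      n_observers = 50, n_trials = 100
    ),
    congruency_context_incongruent = list(
      battery = "congruency", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8, cue_congruent = TRUE,
                 context_congruent = FALSE),
      agent = list(d_counts = c(2, 8), rho_agent = 0.7, cue_strength = 15,
                   learn_context = TRUE, learn_cue = TRUE),
      n_observers = 50, n_trials = 100
    ),
    congruency_both_incongruent = list(
      battery = "congruency", scenario = "simple",
      env = list(p_changeup = 0.2, rho_true = 0.8, cue_congruent = FALSE,
                 context_congruent = FALSE),
      agent = list(d_counts = c(2, 8), rho_agent = 0.9, cue_strength = 15,
                   learn_context = TRUE, learn_cue = TRUE),
      n_observers = 50, n_trials = 100
    ),
    precision_strong_cue = list(
      battery = "precision_conflict", scenario = "simple",
      env = list(p_changeup = 0.5, cue_forced = "cue_changeup"),
      agent = list(d_counts = c(4, 1), rho_agent = 0.8, cue_strength = 50,
                   learn_context = TRUE, learn_cue = TRUE),
      n_observers = 50, n_trials = 50
    ),
    precision_strong_context = list(
      battery = "precision_conflict", scenario = "simple",
      env = list(p_changeup = 0.5, cue_forced = "cue_changeup"),
      agent = list(d_counts = c(40, 10), rho_agent = 0.8, cue_strength = 5,
                   learn_context = TRUE, learn_cue = TRUE),
      n_observers = 50, n_trials = 50
    ),
    policy_precision_gamma16 = list(
      battery = "policy_precision", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 0.8, scenario = "tradeoff"),
      agent = list(d_counts = c(40, 10), rho_agent = 0.8, cue_strength = 50,
                   gamma = 16),
      n_observers = 50, n_trials = 50
    ),
    policy_precision_gamma4 = list(
      battery = "policy_precision", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 0.8, scenario = "tradeoff"),
      agent = list(d_counts = c(40, 10), rho_agent = 0.8, cue_strength = 50,
                   gamma = 4),
      n_observers = 50, n_trials = 50
    ),
    policy_precision_gamma2 = list(
      battery = "policy_precision", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 0.8, scenario = "tradeoff"),
      agent = list(d_counts = c(40, 10), rho_agent = 0.8, cue_strength = 50,
                   gamma = 2),
      n_observers = 50, n_trials = 50
    ),
    policy_precision_gamma1 = list(
      battery = "policy_precision", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 0.8, scenario = "tradeoff"),
      agent = list(d_counts = c(40, 10), rho_agent = 0.8, cue_strength = 50,
                   gamma = 1),
      n_observers = 50, n_trials = 50
    ),
    reward_low = list(
      battery = "reward_sweep", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 1, scenario = "tradeoff"),
      agent = list(d_counts = c(5, 5), rho_agent = 1, cue_strength = 50,
                   r_early = 1, r_late = 0.75, learn_context = TRUE),
      n_observers = 50, n_trials = 60
    ),
    reward_medium = list(
      battery = "reward_sweep", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 1, scenario = "tradeoff"),
      agent = list(d_counts = c(5, 5), rho_agent = 1, cue_strength = 50,
                   r_early = 4, r_late = 3, learn_context = TRUE),
      n_observers = 50, n_trials = 60
    ),
    reward_high = list(
      battery = "reward_sweep", scenario = "tradeoff",
      env = list(p_changeup = 0.2, rho_true = 1, scenario = "tradeoff"),
      agent = list(d_counts = c(5, 5), rho_agent = 1, cue_strength = 50,
                   r_early = 8, r_late = 6, learn_context = TRUE),
      n_observers = 50, n_trials = 60
    ),
    volatility_stable = list(
      battery = "volatility", scenario = "hierarchical",
      env = list(p_changeup = 0.5),
      agent = list(),
      hierarchical = list(persistence = 0.9, window = 10,
                          thresholds = c(0.25, 0.75), emission_acc = 0.8),
      n_observers = 50, n_trials = 100
    ),
    volatility_volatile = list(
      battery = "volatility", scenario = "hierarchical",
      env = list(p_changeup = 0.5, schedule = volatile),
      agent = list(),
      hierarchical = list(persistence = 0.9, window = 10,
                          thresholds = c(0.25, 0.75), emission_acc = 0.8),
      n_observers = 50, n_trials = 100
    )
  )
}

#' Build a fully specified experimental condition
#'
#' Returns the environment specification and agent configuration for one of
#' the registered condition names (see [list_conditions()]), optionally with
#' named overrides of scenario parameters.
#'
#' @param name Condition name from the registry.
#' @param overrides Named list of parameter overrides; names must match
#'   existing agent fields (`gamma`, `eta`, `rho_agent`, ...), environment
#'   fields (`p_changeup`, `rho_true`, ...), or `n_observers`/`n_trials`/
#'   `mode`.
#' @return An `aip_condition` list with elements `name`, `battery`,
#'   `scenario`, `env` (an `aip_env`), `agent`, `n_observers`, `n_trials`,
#'   `mode`, and `hierarchical` (volatility conditions only).
#' @export
make_condition <- function(name, overrides = list()) {
  tab <- .condition_table()
  if (!name %in% names(tab)) {
    stop(sprintf("unknown condition '%s'; see list_conditions()", name))
  }
  entry <- tab[[name]]
  agent <- utils::modifyList(.agent_defaults, entry$agent)
  env_args <- entry$env
  if (entry$scenario == "tradeoff") env_args$scenario <- "tradeoff"
  if (entry$scenario == "hierarchical") env_args$scenario <- NULL
  mode <- if (is.null(entry$mode)) "sample" else entry$mode
  n_observers <- entry$n_observers
  n_trials <- entry$n_trials
  hier <- entry$hierarchical

  for (key in names(overrides)) {
    val <- overrides[[key]]
    if (key %in% names(agent)) {
      agent[[key]] <- val
    } else if (key %in% c("p_changeup", "rho_true", "cue_congruent",
                          "context_congruent", "cue_forced", "q_hit")) {
      env_args[[key]] <- val
    } else if (key == "n_observers") {
      n_observers <- val
    } else if (key == "n_trials") {
      n_trials <- val
    } else if (key == "mode") {
      mode <- val
    } else if (!is.null(hier) && key %in% names(hier)) {
      hier[[key]] <- val
    } else {
      stop(sprintf("unknown override '%s'", key))
    }
  }
  env <- do.call(environment_spec, env_args)
  structure(
    list(name = name, battery = entry$battery, scenario = entry$scenario,
         env = env, agent = agent, n_observers = n_observers,
         n_trials = n_trials, mode = mode, hierarchical = hier),
    class = "aip_condition"
  )
}

# Build the agent's generative model + Dirichlet beliefs for a condition.
.condition_agent <- function(condition) {
  a <- condition$agent
  a_counts <- .cue_counts(a$rho_agent, a$cue_strength)
  if (condition$scenario == "tradeoff") {
    model <- build_tradeoff_model(
      d_counts = a$d_counts, a_counts = a_counts,
      r_early = a$r_early, r_late = a$r_late, loss = a$loss,
      q_hit = a$q_hit, gamma = a$gamma
    )
  } else {
    model <- build_simple_model(
      d_counts = a$d_counts, a_counts = a_counts,
      reward = a$reward, loss = a$loss, q_hit = a$q_hit, gamma = a$gamma
    )
  }
  dirichlet <- dirichlet_beliefs(
    d_counts = a$d_counts, a_counts = a_counts,
    learn_context = a$learn_context, learn_cue = a$learn_cue, eta = a$eta
  )
  list(model = model, dirichlet = dirichlet)
}
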
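# Batch runners: the within-trial perception-action loop, seeded observers,
# condition batteries, and tidy summaries.

# Policies whose first `t` actions match the actions already taken.
.consistent_policies <- function(policies, taken) {
  if (!length(taken)) return(seq_len(nrow(policies)))
  keep <- rep(TRUE, nrow(policies))
  for (j in seq_along(taken)) keep <- keep & policies[, j] == taken[j]
  which(keep)
}

#' Run a single anticipation trial
#'
#' Executes the timepoint loop: infer states under each still-viable policy,
#' evaluate expected free energy over the remaining timepoints, form the
#' policy posterior, select an action, advance the environment and receive
#' its observation, and finally (after the outcome) update the Dirichlet
#' beliefs. Randomness (action sampling, cue emission) uses the current RNG
#' state, which callers seed per observer.
#'
#' @param model An `aip_model`, already refreshed against `dirichlet`.
#' @param dirichlet An `aip_dirichlet` (learning state).
#' @param env An `aip_env` whose scenario matches the model.
#' @param ball True ball label for this trial.
#' @param mode Action selection: `"sample"` or `"argmax"`.
#' @return An `aip_trial` list: the observation labels, per-timepoint context
#'   posteriors, initial expected-free-energy table over all policies, chosen
#'   actions with their probabilities, commitment and success, variational
#'   free energy of the realized policy, and the updated `dirichlet`.
#' @export
run_trial <- function(model, dirichlet, env, ball,
                      mode = c("sample", "argmax")) {
  mode <- match.arg(mode)
  horizon <- model$horizon
  obs <- .obs_matrix(model)
  stage <- "start"
  emis <- step_environment(env, ball, stage)
  obs["cue", 1L] <- match(emis[["cue"]], model$modalities$cue)
  obs["feedback", 1L] <- match(emis[["feedback"]], model$modalities$feedback)

  taken <- integer(0)
  probs <- numeric(0)
  efe_t1 <- NULL
  for (t in seq_len(horizon - 1L)) {
    active <- .consistent_policies(model$policies, taken)
    G <- numeric(length(active))
    risk <- numeric(length(active))
    amb <- numeric(length(active))
    nov <- numeric(length(active))
    for (i in seq_along(active)) {
      post <- infer_states(model, obs, active[i])
      rep_i <- expected_free_energy(model, post, active[i], dirichlet,
                                    from_t = t)
      G[i] <- rep_i$G
      risk[i] <- rep_i$risk
      amb[i] <- rep_i$ambiguity
      nov[i] <- rep_i$novelty
    }
    if (t == 1L) {
      efe_t1 <- data.frame(policy = model$policy_labels[active],
                           G = G, risk = risk, ambiguity = amb, novelty = nov)
    }
    habits <- model$habits[active]
    q_pi <- policy_posterior(G, model$gamma, habits / sum(habits))
    sel <- select_action(q_pi, model$policies[active, , drop = FALSE],
                         t = t, mode = mode)
    taken <- c(taken, sel$action)
    probs <- c(probs, sel$prob)
    stage <- .env_stage_step(env$scenario, stage, model$actions[sel$action])
    emis <- step_environment(env, ball, stage)
    obs["cue", t + 1L] <- match(emis[["cue"]], model$modalities$cue)
    obs["feedback", t + 1L] <- match(emis[["feedback"]], model$modalities$feedback)
  }
  realized <- .consistent_policies(model$policies, taken)[1L]
  post <- infer_states(model, obs, realized)
  fe <- variational_free_energy(model, post, obs, realized)

  fb <- model$modalities$feedback[obs["feedback", horizon]]
  success <- fb %in% c("correct", "early_correct", "late_correct")
  committed <- if (grepl("changeup", stage)) "changeup" else "normal"
  timing <- if (model$scenario == "tradeoff") {
    if (grepl("^early", stage)) "early" else "late"
  } else NA_character_
  cue_idx <- obs["cue", 2L]
  dirichlet <- update_dirichlet(dirichlet, list(
    context_posterior_t1 = post$context[, 1L],
    cue_index = cue_idx,
    context_posterior_cue = post$context[, 2L]
  ))
  structure(
    list(
      ball = ball,
      cue = model$modalities$cue[cue_idx],
      feedback = fb,
      actions = model$actions[taken],
      action_probs = probs,
      committed = committed,
      timing = timing,
      success = success,
      context_posterior = post$context,
      efe = efe_t1,
      policy = model$policy_labels[realized],
      free_energy = fe,
      converged = post$converged,
      dirichlet = dirichlet
    ),
    class = "aip_trial"
  )
}

#' Run a batch of seeded observers through a condition
#'
#' Each observer receives their own seed (derived from `base_seed`), their
#' own trial sequence, and fresh Dirichlet beliefs; trials update beliefs
#' sequentially. Per-trial summaries aggregate across observers with
#' normal-approximation 95% confidence intervals.
#'
#' @param condition An `aip_condition` from [make_condition()], or a
#'   condition name.
#' @param n_observers,n_trials Optional overrides of the condition's sizes.
#' @param base_seed Integer base seed; observer `i` uses `base_seed + i - 1`.
#' @param mode Optional override of the condition's action-selection mode.
#' @return An `aip_experiment` list with `condition` metadata, the tidy
#'   per-trial `trials` data frame, the per-trial `summary` (mean proportion
#'   of normal anticipations, CI bounds, mean success), `beliefs` (the
#'   across-observer Beta summary of final context counts over p(change-up)),
#'   and `totals` (success and free-energy aggregates).
#' @export
run_batch <- function(condition, n_observers = NULL, n_trials = NULL,
                      base_seed = 1L, mode = NULL) {
  if (is.character(condition)) condition <- make_condition(condition)
  stopifnot(inherits(condition, "aip_condition"))
  if (condition$scenario == "hierarchical") {
    return(.run_batch_hierarchical(condition, n_observers, n_trials, base_seed))
  }
  if (is.null(n_observers)) n_observers <- condition$n_observers
  if (is.null(n_trials)) n_trials <- condition$n_trials
  if (is.null(mode)) mode <- condition$mode
  if (n_observers < 1 || n_trials < 1) stop("need at least one observer and trial")

  rows <- vector("list", n_observers)
  d_final <- matrix(NA_real_, n_observers, 2L)
  for (o in seq_len(n_observers)) {
    set.seed(base_seed + o - 1L)
    agent <- .condition_agent(condition)
    model <- agent$model
    dirichlet <- agent$dirichlet
    balls <- generate_trial_sequence(condition$env, n_trials)
    obs_rows <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      model <- refresh_model(model, dirichlet)
      trial <- run_trial(model, dirichlet, condition$env, balls[tr], mode)
      dirichlet <- trial$dirichlet
      n_act <- length(trial$actions)
      obs_rows[[tr]] <- data.frame(
        observer = o, trial = tr, ball = trial$ball, cue = trial$cue,
        action = trial$actions[n_act],
        action_prob = trial$action_probs[n_act],
        first_action = trial$actions[1L],
        first_action_prob = trial$action_probs[1L],
        committed = trial$committed, timing = trial$timing,
        success = trial$success,
        posterior_changeup_t1 = trial$context_posterior[2L, 1L],
        posterior_changeup_t2 = trial$context_posterior[2L, 2L],
        posterior_changeup_t3 = trial$context_posterior[2L, 3L],
        free_energy = trial$free_energy,
        d_normal = dirichlet$d_counts[1L],
        d_changeup = dirichlet$d_counts[2L]
      )
    }
    rows[[o]] <- do.call(rbind, obs_rows)
    d_final[o, ] <- dirichlet$d_counts
  }
  trials <- do.call(rbind, rows)
  summary <- .summarize_trials(trials, n_observers)
  beliefs <- beta_summary(cbind(d_final[, 2L], d_final[, 1L]))
  res <- structure(
    list(
      condition = condition,
      n_observers = n_observers, n_trials = n_trials, base_seed = base_seed,
      trials = trials, summary = summary, beliefs = beliefs,
      totals = list(
        mean_success = mean(trials$success),
        total_free_energy = sum(trials$free_energy),
        mean_free_energy = mean(trials$free_energy)
      )
    ),
    class = "aip_experiment"
  )
  attr(res, "ci_degenerate") <- n_observers == 1L
  res
}

# Across-observer per-trial means with normal-approximation 95% CIs
# (width 0 by convention when there is a single observer).
.summarize_trials <- function(trials, n_observers) {
  agg <- function(x) tapply(x, trials$trial, mean)
  prop_normal <- agg(trials$committed == "normal")
  success <- agg(trials$success)
  fe <- agg(trials$free_energy)
  if (n_observers > 1L) {
    sd_normal <- tapply(trials$committed == "normal", trials$trial, stats::sd)
    half <- 1.96 * sd_normal / sqrt(n_observers)
  } else {
    half <- 0
  }
  data.frame(
    trial = as.integer(names(prop_normal)),
    prop_normal = as.numeric(prop_normal),
    ci_lower = pmax(0, as.numeric(prop_normal - half)),
    ci_upper = pmin(1, as.numeric(prop_normal + half)),
    success = as.numeric(success),
    free_energy = as.numeric(fe),
    row.names = NULL
  )
}

.run_batch_hierarchical <- function(condition, n_observers, n_trials,
                                    base_seed) {
  if (is.null(n_observers)) n_observers <- condition$n_observers
  if (is.null(n_trials)) n_trials <- condition$n_trials
  h <- condition$hierarchical
  hmodel <- build_hierarchical_model(
    persistence = h$persistence, window = h$window,
    thresholds = h$thresholds, emission_acc = h$emission_acc
  )
  rows <- vector("list", n_observers)
  for (o in seq_len(n_observers)) {
    set.seed(base_seed + o - 1L)
    balls <- generate_trial_sequence(condition$env, n_trials)
    fit <- run_hierarchical(hmodel, balls)
    rows[[o]] <- data.frame(
      observer = o,
      higher_free_energy = fit$higher_free_energy,
      higher_complexity = fit$higher_complexity,
      lower_free_energy = fit$lower_free_energy,
      lower_belief = fit$lower_belief,
      realised_marginal = attr(balls, "realised_marginal")
    )
  }
  observers <- do.call(rbind, rows)
  structure(
    list(
      condition = condition,
      n_observers = n_observers, n_trials = n_trials, base_seed = base_seed,
      observers = observers,
      totals = list(
        mean_higher_free_energy = mean(observers$higher_free_energy),
        mean_higher_complexity = mean(observers$higher_complexity),
        mean_lower_free_energy = mean(observers$lower_free_energy),
        mean_lower_belief = mean(observers$lower_belief)
      )
    ),
    class = c("aip_hier_experiment", "aip_experiment")
  )
}

#' Run a named battery of conditions
#'
#' Batteries group the conditions of one simulated experiment (learning
#' curves, single-trial belief traces, congruency grid, precision conflict,
#' policy-precision sweep, reward sweep, volatility comparison) and run each
#' at its registered observer/trial counts.
#'
#' @param battery Battery name; see [list_batteries()].
#' @param base_seed Integer base seed shared by all conditions (observers are
#'   paired across conditions).
#' @param n_observers,n_trials,mode Optional overrides applied to every
#'   condition.
#' @param overrides Named list of scenario-parameter overrides passed to
#'   [make_condition()].
#' @return An `aip_battery`: named list of `aip_experiment` results with
#'   attributes `battery` and `base_seed`.
#' @export
run_battery <- function(battery, base_seed = 1L, n_observers = NULL,
                        n_trials = NULL, mode = NULL, overrides = list()) {
  if (!battery %in% names(.batteries)) {
    stop(sprintf("unknown battery '%s'; see list_batteries()", battery))
  }
  results <- lapply(.batteries[[battery]], function(nm) {
    run_batch(make_condition(nm, overrides), n_observers = n_observers,
              n_trials = n_trials, base_seed = base_seed, mode = mode)
  })
  names(results) <- .batteries[[battery]]
  structure(results, class = "aip_battery", battery = battery,
            base_seed = base_seed)
}

#' Summarize Dirichlet context counts as Beta distributions
#'
#' Maps two-category counts to `Beta(alpha, beta)` per observer (`alpha` from
#' the first column) and reports the across-observer mean parameters together
#' with an evaluable density grid on `[0, 1]`.
#'
#' @param counts Numeric length-2 vector or a matrix with one row per
#'   observer and two columns.
#' @param grid_n Number of density grid points.
#' @return List with `alpha`, `beta` (per observer), `mean_alpha`,
#'   `mean_beta`, `mode` of the mean-parameter Beta (when defined), and a
#'   `density` data frame (`x`, `y`).
#' @export
beta_summary <- function(counts, grid_n = 201L) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  if (ncol(counts) != 2L) stop("counts must have exactly 2 categories")
  alpha <- counts[, 1L]
  beta <- counts[, 2L]
  ma <- mean(alpha)
  mb <- mean(beta)
  mode <- if (ma > 1 && mb > 1) (ma - 1) / (ma + mb - 2) else NA_real_
  x <- seq(0, 1, length.out = grid_n)
  list(
    alpha = alpha, beta = beta, mean_alpha = ma, mean_beta = mb, mode = mode,
    density = data.frame(x = x, y = stats::dbeta(x, ma, mb))
  )
}

#' Write battery results as tidy CSV files plus a JSON summary
#'
#' One CSV per condition under `dir/<battery>/<condition>.csv` and a
#' pretty-printed, key-sorted `summary.json` for the battery.
#'
#' @param results An `aip_battery` from [run_battery()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_battery <- function(results, dir) {
  stopifnot(inherits(results, "aip_battery"))
  battery <- attr(results, "battery")
  out_dir <- file.path(dir, battery)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summary <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    path <- file.path(out_dir, paste0(nm, ".csv"))
    tab <- if (inherits(res, "aip_hier_experiment")) res$observers else res$trials
    utils::write.csv(tab, path, row.names = FALSE)
    paths <- c(paths, path)
    summary[[nm]] <- res$totals
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary[order(names(summary))], summary_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, summary_path))
}

#' @export
print.aip_experiment <- function(x, ...) {
  cat(sprintf("<aip_experiment: %s> %d observers x %d trials (seed %d)\n",
              x$condition$name, x$n_observers, x$n_trials, x$base_seed))
  if (inherits(x, "aip_hier_experiment")) {
    cat(sprintf("  higher-level free energy: %.2f (complexity %.2f)\n",
                x$totals$mean_higher_free_energy,
                x$totals$mean_higher_complexity))
    cat(sprintf("  lower-level belief p(changeup): %.3f\n",
                x$totals$mean_lower_belief))
  } else {
    cat(sprintf("  mean success: %.3f, mean free energy: %.3f\n",
                x$totals$mean_success, x$totals$mean_free_energy))
  }
  invisible(x)
}
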
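# Generative-model builders for the anticipation scenarios.
#
# Hidden states factorize into `context` (which ball is coming: normal vs
# change-up; uncontrollable, fixed within a trial) and `stage` (the observer's
# behavioural stage; controllable). Observations arrive through two
# modalities: an early sensory `cue` (informative only while the observer is
# in the watching stage) and `feedback` about the anticipatory action
# (emitted once, after commitment). Three timepoints per trial: start,
# cue, outcome.

CONTEXT_LABELS <- c("normal", "changeup")
CUE_LABELS <- c("null", "cue_normal", "cue_changeup")

# Flatten factor dimensions into the joint state index (context varies
# fastest: joint = (stage - 1) * n_context + context).
.joint_cache <- function(model) {
  n_ctx <- length(model$labels$context)
  n_stage <- length(model$labels$stage)
  model$n_joint <- n_ctx * n_stage
  model$A_joint <- lapply(model$A, function(a) {
    matrix(a, nrow = dim(a)[1L])
  })
  Bc <- model$B$context[, , 1L]
  model$B_joint <- lapply(seq_along(model$actions), function(a) {
    kronecker(model$B$stage[, , a], Bc)
  })
  model$D_joint <- as.vector(outer(model$D$context, model$D$stage))
  model
}

.new_model <- function(scenario, labels, modalities, A, B, C, D, actions,
                       policies, policy_labels, gamma, habits = NULL,
                       a_counts = NULL, params = list()) {
  if (is.null(habits)) habits <- rep(1 / nrow(policies), nrow(policies))
  model <- structure(
    list(
      scenario = scenario,
      labels = labels,
      modalities = modalities,
      A = A, B = B, C = C, D = D,
      actions = actions,
      policies = policies,
      policy_labels = policy_labels,
      horizon = ncol(policies) + 1L,
      gamma = gamma,
      habits = habits,
      a_counts = a_counts,
      params = params
    ),
    class = "aip_model"
  )
  model <- .joint_cache(model)
  validate_model(model)
  model
}

#' Validate a generative model
#'
#' Checks dimensional consistency of A, B, C and D, that every conditional
#' column is a categorical distribution, that uncontrollable factors carry a
#' single transition table, that all policies share one horizon, and that
#' habit weights form a distribution.
#'
#' @param model An object built by [build_simple_model()] or
#'   [build_tradeoff_model()].
#' @return The model, invisibly; errors describe the first violated check.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "aip_model"))
  n_ctx <- length(model$labels$context)
  n_stage <- length(model$labels$stage)
  for (f in names(model$D)) {
    .check_dist(model$D[[f]], sprintf("D[%s]", f))
  }
  for (m in names(model$A)) {
    a <- model$A[[m]]
    if (!all(dim(a) == c(length(model$modalities[[m]]), n_ctx, n_stage))) {
      stop(sprintf("A[%s] has inconsistent dimensions", m))
    }
    cols <- matrix(a, nrow = dim(a)[1L])
    for (j in seq_len(ncol(cols))) {
      .check_dist(cols[, j], sprintf("A[%s] column %d", m, j))
    }
  }
  if (dim(model$B$context)[3L] != 1L) {
    stop("uncontrollable context factor must have exactly one transition table")
  }
  for (f in names(model$B)) {
    b <- model$B[[f]]
    for (a in seq_len(dim(b)[3L])) {
      for (j in seq_len(ncol(b[, , a]))) {
        .check_dist(b[, j, a], sprintf("B[%s] action %d column %d", f, a, j))
      }
    }
  }
  for (m in names(model$C)) {
    cm <- model$C[[m]]
    if (!all(is.finite(cm))) stop(sprintf("C[%s] has non-finite entries", m))
    if (nrow(cm) != length(model$modalities[[m]]) || ncol(cm) != model$horizon) {
      stop(sprintf("C[%s] has inconsistent dimensions", m))
    }
  }
  if (any(model$policies < 1L) || any(model$policies > length(model$actions))) {
    stop("policy action indices out of range")
  }
  .check_dist(model$habits, "habit weights")
  if (!is.numeric(model$gamma) || model$gamma < 0) {
    stop("gamma must be a nonnegative real")
  }
  invisible(model)
}

# Cue likelihood columns for the watching stage, from Dirichlet counts.
.cue_counts <- function(rho_agent, cue_strength) {
  if (!is.finite(rho_agent) || rho_agent < 0 || rho_agent > 1) {
    stop("rho_agent (believed cue reliability) must lie in [0, 1]")
  }
  counts <- rbind(
    null = c(0, 0),
    cue_normal = cue_strength * c(rho_agent, 1 - rho_agent),
    cue_changeup = cue_strength * c(1 - rho_agent, rho_agent)
  )
  colnames(counts) <- CONTEXT_LABELS
  counts
}

#' Build the simple anticipation scenario model
#'
#' Two hidden-state factors: the ball context (`normal`, `changeup`; identity
#' dynamics, the ball is fixed within a trial) and the behavioural stage
#' (`start`, `observing`, `committed_normal`, `committed_changeup`;
#' controllable). The cue modality is informative only in the `observing`
#' stage with believed reliability derived from the cue Dirichlet counts;
#' feedback (`correct`/`incorrect`) is emitted only in committed stages.
#' There are two policies: wait then commit to the normal ball, or wait then
#' commit to the change-up.
#'
#' @param d_counts Length-2 positive Dirichlet counts over context
#'   (`normal`, `changeup`); their normalisation is the contextual prior D and
#'   their magnitude is its precision.
#' @param rho_agent Believed cue reliability in `[0, 1]`; used with
#'   `cue_strength` to seed the cue-likelihood counts when `a_counts` is not
#'   given.
#' @param cue_strength Total Dirichlet count mass per cue-likelihood column.
#' @param a_counts Optional explicit 3 x 2 cue count matrix (rows
#'   `null`, `cue_normal`, `cue_changeup`; columns context) overriding
#'   `rho_agent`/`cue_strength`.
#' @param reward,loss Finite utilities (log-preference units) on `correct`
#'   and `incorrect` feedback; `null` feedback has utility 0.
#' @param q_hit Probability that a correct commitment yields `correct`
#'   feedback (1 = deterministic feedback).
#' @param gamma Policy precision (inverse temperature on expected free
#'   energy), nonnegative.
#' @param habits Optional prior over the two policies (defaults to uniform).
#' @return An `aip_model` object.
#' @examples
#' m <- build_simple_model(d_counts = c(8, 2), rho_agent = 0.8)
#' m$policy_labels
#' @export
build_simple_model <- function(d_counts = c(1, 1), rho_agent = 0.8,
                               cue_strength = 10, a_counts = NULL,
                               reward = 4, loss = 4, q_hit = 1,
                               gamma = 16, habits = NULL) {
  if (!all(is.finite(c(reward, loss)))) stop("utilities must be finite")
  if (length(d_counts) != 2L || any(d_counts <= 0)) {
    stop("d_counts must be two positive counts")
  }
  if (is.null(a_counts)) a_counts <- .cue_counts(rho_agent, cue_strength)
  stage <- c("start", "observing", "committed_normal", "committed_changeup")
  labels <- list(context = CONTEXT_LABELS, stage = stage)
  modalities <- list(
    cue = CUE_LABELS,
    feedback = c("null", "correct", "incorrect")
  )

  A_cue <- array(0, c(3, 2, 4), dimnames = list(CUE_LABELS, CONTEXT_LABELS, stage))
  A_cue[1L, , c(1L, 3L, 4L)] <- 1
  A_cue[, , 2L] <- normalize_counts(a_counts)
  A_fb <- array(0, c(3, 2, 4),
                dimnames = list(modalities$feedback, CONTEXT_LABELS, stage))
  A_fb[1L, , 1:2] <- 1
  A_fb[2L, "normal", 3L] <- q_hit       # committed normal, ball normal
  A_fb[3L, "normal", 3L] <- 1 - q_hit
  A_fb[3L, "changeup", 3L] <- 1
  A_fb[2L, "changeup", 4L] <- q_hit
  A_fb[3L, "changeup", 4L] <- 1 - q_hit
  A_fb[3L, "normal", 4L] <- 1

  B_ctx <- array(diag(2), c(2, 2, 1))
  actions <- c("wait", "commit_normal", "commit_changeup")
  B_stage <- array(0, c(4, 4, 3), dimnames = list(stage, stage, actions))
  B_stage[, , "wait"] <- cbind(c(0, 1, 0, 0), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1))
  B_stage[, , "commit_normal"] <- cbind(c(0, 0, 1, 0), c(0, 0, 1, 0),
                                        c(0, 0, 1, 0), c(0, 0, 0, 1))
  B_stage[, , "commit_changeup"] <- cbind(c(0, 0, 0, 1), c(0, 0, 0, 1),
                                          c(0, 0, 1, 0), c(0, 0, 0, 1))

  C <- list(
    cue = matrix(0, 3, 3, dimnames = list(CUE_LABELS, NULL)),
    feedback = matrix(c(0, reward, -loss), 3, 3,
                      dimnames = list(modalities$feedback, NULL))
  )
  D <- list(context = as.vector(normalize_counts(d_counts)),
            stage = c(1, 0, 0, 0))
  policies <- rbind(c(1L, 2L), c(1L, 3L))

  .new_model(
    scenario = "simple", labels = labels, modalities = modalities,
    A = list(cue = A_cue, feedback = A_fb),
    B = list(context = B_ctx, stage = B_stage),
    C = C, D = D, actions = actions, policies = policies,
    policy_labels = c("anticipate_normal", "anticipate_changeup"),
    gamma = gamma, habits = habits, a_counts = a_counts,
    params = list(d_counts = d_counts, reward = reward, loss = loss,
                  q_hit = q_hit)
  )
}

#' Build the reward/information trade-off scenario model
#'
#' As the simple scenario, but committing can happen early (before the cue,
#' for a higher reward) or late (after observing the cue, for a reduced
#' reward). The behavioural stage distinguishes pending early commitments,
#' their outcome stage, and late commitments, so that feedback is emitted
#' exactly once per trial. Four policies: commit early to either ball, or
#' wait and commit late to either ball. The cue is only observable on the
#' wait branch, before the late commitment.
#'
#' @inheritParams build_simple_model
#' @param r_early Reward (log-preference units) for a correct early
#'   commitment; must exceed `r_late`.
#' @param r_late Reward for a correct late commitment, positive and strictly
#'   below `r_early` (waiting for the cue costs outcome value).
#' @param loss Penalty magnitude for an incorrect commitment.
#' @return An `aip_model` object with 4 policies of 2 transitions.
#' @examples
#' m <- build_tradeoff_model(r_early = 4, r_late = 3)
#' m$policy_labels
#' @export
build_tradeoff_model <- function(d_counts = c(1, 1), rho_agent = 1,
                                 cue_strength = 50, a_counts = NULL,
                                 r_early = 4, r_late = 3, loss = 4,
                                 q_hit = 1, gamma = 16, habits = NULL) {
  if (!all(is.finite(c(r_early, r_late, loss)))) stop("utilities must be finite")
  if (r_late >= r_early) {
    stop("degenerate trade-off: r_late must be strictly below r_early")
  }
  if (r_late <= 0) stop("r_late must be positive")
  if (length(d_counts) != 2L || any(d_counts <= 0)) {
    stop("d_counts must be two positive counts")
  }
  if (is.null(a_counts)) a_counts <- .cue_counts(rho_agent, cue_strength)
  stage <- c("start", "observing", "early_normal", "early_changeup",
             "early_outcome_normal", "early_outcome_changeup",
             "late_normal", "late_changeup")
  labels <- list(context = CONTEXT_LABELS, stage = stage)
  fb_labels <- c("null", "early_correct", "late_correct", "incorrect")
  modalities <- list(cue = CUE_LABELS, feedback = fb_labels)

  A_cue <- array(0, c(3, 2, 8), dimnames = list(CUE_LABELS, CONTEXT_LABELS, stage))
  A_cue[1L, , setdiff(seq_len(8L), 2L)] <- 1
  A_cue[, , 2L] <- normalize_counts(a_counts)
  A_fb <- array(0, c(4, 2, 8), dimnames = list(fb_labels, CONTEXT_LABELS, stage))
  A_fb[1L, , 1:4] <- 1   # nothing yet in start/observing/pending stages
  fill_fb <- function(stage_idx, committed, slot) {
    match_ctx <- committed
    other <- setdiff(CONTEXT_LABELS, committed)
    A_fb[slot, match_ctx, stage_idx] <<- q_hit
    A_fb["incorrect", match_ctx, stage_idx] <<- 1 - q_hit
    A_fb["incorrect", other, stage_idx] <<- 1
  }
  fill_fb(5L, "normal", "early_correct")
  fill_fb(6L, "changeup", "early_correct")
  fill_fb(7L, "normal", "late_correct")
  fill_fb(8L, "changeup", "late_correct")

  B_ctx <- array(diag(2), c(2, 2, 1))
  actions <- c("wait", "early_normal", "early_changeup",
               "late_normal", "late_changeup")
  B_stage <- array(0, c(8, 8, 5), dimnames = list(stage, stage, actions))
  for (a in seq_len(5L)) {
    # pending early commitments progress to their outcome stage regardless of
    # action; outcome and late stages are absorbing
    B_stage[5L, 3L, a] <- 1
    B_stage[6L, 4L, a] <- 1
    for (s in 5:8) B_stage[s, s, a] <- 1
  }
  from <- c(1L, 2L)  # stages an action can still steer
  B_stage[2L, from, "wait"] <- 1
  B_stage[3L, from, "early_normal"] <- 1
  B_stage[4L, from, "early_changeup"] <- 1
  B_stage[7L, from, "late_normal"] <- 1
  B_stage[8L, from, "late_changeup"] <- 1

  C <- list(
    cue = matrix(0, 3, 3, dimnames = list(CUE_LABELS, NULL)),
    feedback = matrix(c(0, r_early, r_late, -loss), 4, 3,
                      dimnames = list(fb_labels, NULL))
  )
  D <- list(context = as.vector(normalize_counts(d_counts)),
            stage = c(1, rep(0, 7)))
  policies <- rbind(
    c(2L, 1L),  # commit early to normal, then progression
    c(3L, 1L),
    c(1L, 4L),  # wait, then commit late to normal
    c(1L, 5L)
  )

  .new_model(
    scenario = "tradeoff", labels = labels, modalities = modalities,
    A = list(cue = A_cue, feedback = A_fb),
    B = list(context = B_ctx, stage = B_stage),
    C = C, D = D, actions = actions, policies = policies,
    policy_labels = c("early_normal", "early_changeup",
                      "wait_late_normal", "wait_late_changeup"),
    gamma = gamma, habits = habits, a_counts = a_counts,
    params = list(d_counts = d_counts, r_early = r_early, r_late = r_late,
                  loss = loss, q_hit = q_hit)
  )
}

#' Dirichlet beliefs over learnable model elements
#'
#' Concentration counts shadowing the contextual prior D (`d_counts`) and the
#' cue-likelihood columns of A (`a_counts`), with per-component learning
#' toggles and a learning rate.
#'
#' @param d_counts Length-2 positive counts over context.
#' @param a_counts 3 x 2 cue count matrix (rows `null`, `cue_normal`,
#'   `cue_changeup`; columns context); the `null` row is structurally zero.
#' @param learn_context,learn_cue Logical learning toggles.
#' @param eta Positive learning rate applied to posterior-weighted count
#'   increments.
#' @return An `aip_dirichlet` object.
#' @export
dirichlet_beliefs <- function(d_counts = c(1, 1),
                              a_counts = .cue_counts(0.5, 2),
                              learn_context = FALSE, learn_cue = FALSE,
                              eta = 1) {
  if (eta <= 0) stop("eta must be positive")
  if (any(d_counts <= 0)) stop("d_counts must be strictly positive")
  if (any(a_counts < 0) || any(colSums(a_counts) <= 0)) {
    stop("a_counts columns must be nonnegative with positive mass")
  }
  structure(
    list(d_counts = as.vector(d_counts), a_counts = a_counts,
         learn_context = isTRUE(learn_context), learn_cue = isTRUE(learn_cue),
         eta = eta),
    class = "aip_dirichlet"
  )
}

#' Refresh a model's beliefs from Dirichlet counts
#'
#' Replaces the contextual prior D and the cue-likelihood columns of the
#' watching stage with the normalized Dirichlet counts, and recomputes the
#' cached joint-state tables.
#'
#' @param model An `aip_model`.
#' @param dirichlet An `aip_dirichlet` from [dirichlet_beliefs()].
#' @return The updated model.
#' @export
refresh_model <- function(model, dirichlet) {
  stopifnot(inherits(model, "aip_model"), inherits(dirichlet, "aip_dirichlet"))
  model$D$context <- as.vector(normalize_counts(dirichlet$d_counts))
  obs_stage <- match("observing", model$labels$stage)
  model$A$cue[, , obs_stage] <- normalize_counts(dirichlet$a_counts)
  model$a_counts <- dirichlet$a_counts
  model$params$d_counts <- dirichlet$d_counts
  .joint_cache(model)
}

#' @export
print.aip_model <- function(x, ...) {
  cat(sprintf("<aip_model: %s scenario>\n", x$scenario))
  cat(sprintf("  states   : context (%d) x stage (%d)\n",
              length(x$labels$context), length(x$labels$stage)))
  cat(sprintf("  policies : %s\n", paste(x$policy_labels, collapse = ", ")))
  cat(sprintf("  horizon  : %d timepoints, gamma = %g\n", x$horizon, x$gamma))
  cat(sprintf("  prior D  : p(changeup) = %.3f\n", x$D$context[2L]))
  invisible(x)
}

#' @export
print.aip_dirichlet <- function(x, ...) {
  cat("<aip_dirichlet>\n")
  cat(sprintf("  d_counts: (%s)  learn_context = %s\n",
              paste(signif(x$d_counts, 4), collapse = ", "), x$learn_context))
  cat(sprintf("  a column mass: (%s)  learn_cue = %s, eta = %g\n",
              paste(signif(colSums(x$a_counts), 4), collapse = ", "),
              x$learn_cue, x$eta))
  invisible(x)
}
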
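# Across-trial hierarchical model for contextual volatility.
#
# The lower level tracks the marginal probability of a change-up ball with
# Dirichlet counts updated every trial. The higher level is a hidden Markov
# model over context *regimes* whose transition table encodes an expectation
# of stability (regime persistence). Its observations are summaries of
# non-overlapping windows of trials (the realised change-up fraction,
# discretized); with `window = 1` it observes raw ball identities. The
# higher-level variational free energy of each belief update equals the
# surprisal of the window summary under the regime-filtered predictive, and
# splits into complexity (belief shift) minus accuracy.

#' Build a hierarchical regime model over trial-order volatility
#'
#' @param regimes Character labels of the context regimes.
#' @param emissions Matrix of per-regime emission probabilities (observation
#'   categories x regimes, columns summing to 1). When `NULL`, a default with
#'   `emission_acc` on the matching category and the remainder split evenly
#'   is used (requires as many categories as regimes).
#' @param persistence Believed per-step probability that the regime persists,
#'   in `(0, 1]`; the complement is split evenly across the other regimes.
#' @param window Number of trials summarized into one higher-level
#'   observation. `window = 1` observes ball identities directly (categories
#'   `normal`, `changeup`).
#' @param thresholds Length-2 cut points on the windowed change-up fraction
#'   separating the low / balanced / high observation categories (used when
#'   `window > 1`).
#' @param emission_acc Probability mass on the matching category in the
#'   default emission table.
#' @return An `aip_hier_model` object.
#' @export
build_hierarchical_model <- function(regimes = c("mostly_normal", "balanced",
                                                 "mostly_changeup"),
                                     emissions = NULL, persistence = 0.9,
                                     window = 10, thresholds = c(0.25, 0.75),
                                     emission_acc = 0.8) {
  if (!is.numeric(persistence) || persistence <= 0 || persistence > 1) {
    stop("persistence must lie in (0, 1]")
  }
  if (window < 1) stop("window must be at least 1")
  n_reg <- length(regimes)
  if (n_reg < 2) stop("need at least two regimes")
  categories <- if (window == 1) CONTEXT_LABELS else
    c("low_changeup", "balanced", "high_changeup")[seq_len(3)]
  if (is.null(emissions)) {
    if (window == 1) {
      stop("with window = 1 an explicit emissions matrix is required")
    }
    if (n_reg != length(categories)) {
      stop("default emissions require one regime per observation category")
    }
    emissions <- matrix((1 - emission_acc) / (n_reg - 1), n_reg, n_reg)
    diag(emissions) <- emission_acc
    dimnames(emissions) <- list(categories, regimes)
  } else {
    emissions <- as.matrix(emissions)
    if (ncol(emissions) != n_reg) stop("emissions must have one column per regime")
    for (j in seq_len(n_reg)) .check_dist(emissions[, j], "emission column")
    if (window == 1 && nrow(emissions) != 2L) {
      stop("with window = 1 emissions must have one row per ball type")
    }
    categories <- if (!is.null(rownames(emissions))) rownames(emissions)
                  else categories[seq_len(nrow(emissions))]
  }
  transition <- matrix((1 - persistence) / (n_reg - 1), n_reg, n_reg)
  diag(transition) <- persistence
  structure(
    list(regimes = regimes, categories = categories, emissions = emissions,
         transition = transition, persistence = persistence, window = window,
         thresholds = thresholds),
    class = "aip_hier_model"
  )
}

# Discretize a ball sequence into higher-level observation categories.
.window_categories <- function(hmodel, balls) {
  if (hmodel$window == 1) {
    return(match(balls, CONTEXT_LABELS))
  }
  n_win <- floor(length(balls) / hmodel$window)
  if (n_win < 1) stop("sequence shorter than one window")
  idx <- matrix(seq_len(n_win * hmodel$window), nrow = hmodel$window)
  frac <- colMeans(matrix(balls[idx] == "changeup", nrow = hmodel$window))
  findInterval(frac, hmodel$thresholds, left.open = TRUE) + 1L
}

#' Run hierarchical inference over a trial sequence
#'
#' Filters the regime-level hidden Markov model across window summaries of
#' the ball sequence and tracks the lower-level Dirichlet belief about
#' p(change-up) trial by trial. Per higher-level update, the variational free
#' energy (equal to the surprisal of the summary under the predictive),
#' its complexity part (KL from the propagated prior to the posterior) and
#' accuracy part are recorded.
#'
#' @param hmodel An `aip_hier_model`.
#' @param balls Character vector of `"normal"`/`"changeup"` trial outcomes.
#' @param lower_counts Initial lower-level Dirichlet counts over
#'   (`normal`, `changeup`).
#' @return An `aip_hier_fit` list: `ticks` data frame (one row per
#'   higher-level update: observed category, free energy, complexity,
#'   accuracy, regime posteriors), `trials` data frame (per-trial lower-level
#'   predictive surprisal), `higher_free_energy` and `higher_complexity`
#'   totals, `lower_free_energy` total, and `lower_belief` (final normalized
#'   p(change-up)).
#' @export
run_hierarchical <- function(hmodel, balls, lower_counts = c(1, 1)) {
  stopifnot(inherits(hmodel, "aip_hier_model"))
  obs <- .window_categories(hmodel, balls)
  n_reg <- length(hmodel$regimes)
  q <- rep(1 / n_reg, n_reg)
  ticks <- data.frame(tick = seq_along(obs), category = hmodel$categories[obs],
                      free_energy = NA_real_, complexity = NA_real_,
                      accuracy = NA_real_)
  post <- matrix(NA_real_, length(obs), n_reg,
                 dimnames = list(NULL, hmodel$regimes))
  for (k in seq_along(obs)) {
    pred <- as.vector(hmodel$transition %*% q)
    lik <- hmodel$emissions[obs[k], ]
    joint <- pred * lik
    z <- sum(joint)
    if (z <= 0) stop("observation has zero probability under every regime")
    q <- joint / z
    accuracy <- sum(q * .logp(lik))
    ticks$free_energy[k] <- -log(z)
    ticks$complexity[k] <- .kl_div(q, pred)
    ticks$accuracy[k] <- accuracy
    post[k, ] <- q
  }
  counts <- lower_counts
  lower_surprisal <- numeric(length(balls))
  for (t in seq_along(balls)) {
    p_cu <- counts[2L] / sum(counts)
    is_cu <- balls[t] == "changeup"
    lower_surprisal[t] <- -log(if (is_cu) p_cu else 1 - p_cu)
    counts[if (is_cu) 2L else 1L] <- counts[if (is_cu) 2L else 1L] + 1
  }
  structure(
    list(
      ticks = cbind(ticks, as.data.frame(post)),
      trials = data.frame(trial = seq_along(balls), ball = balls,
                          surprisal = lower_surprisal),
      higher_free_energy = sum(ticks$free_energy),
      higher_complexity = sum(ticks$complexity),
      lower_free_energy = sum(lower_surprisal),
      lower_belief = counts[2L] / sum(counts),
      lower_counts = counts
    ),
    class = "aip_hier_fit"
  )
}
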
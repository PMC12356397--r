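#' Parameters of the QUEST adaptive staircase
#'
#' QUEST maintains a discretised posterior over the log10 threshold of a
#' Weibull psychometric function and places every trial at the current
#' posterior mean.  The intensity variable throughout is the log10 of the
#' letter luminance increment above the fixed grey background, not absolute
#' luminance.
#'
#' Defaults follow common QUEST practice for a 6-alternative forced choice
#' letter task: Weibull slope `beta = 3.5`, lapse `delta = 0.01`, guess rate
#' `gamma = 1/6`, target proportion correct 0.70, and a 201-point grid
#' spanning `prior_mean +/- 2.5` log10 units under a Gaussian prior with
#' SD 1.
#'
#' @param beta Weibull slope.
#' @param delta lapse probability.
#' @param gamma guess rate (1/6 for 6AFC).
#' @param target_p proportion correct aimed for; must satisfy
#'   `gamma < target_p < 1 - delta`.
#' @param prior_mean,prior_sd Gaussian prior over the log10 threshold.
#' @param grid optional explicit strictly increasing grid of candidate log10
#'   thresholds; by default `n_grid` points spanning
#'   `prior_mean +/- grid_span`.
#' @param n_grid,grid_span grid resolution and half-width (ignored when
#'   `grid` is given).
#' @return Object of class `quest_params`.
#' @export
quest_params <- function(beta = 3.5, delta = 0.01, gamma = 1 / 6,
                         target_p = 0.70, prior_mean = 1.0, prior_sd = 1.0,
                         grid = NULL, n_grid = 201L, grid_span = 2.5) {
  stopifnot(beta > 0, delta >= 0, delta < 1, gamma > 0, gamma < 1,
            prior_sd > 0)
  if (!(gamma < target_p && target_p < 1 - delta)) {
    stop("need gamma < target_p < 1 - delta")
  }
  if (is.null(grid)) {
    grid <- seq(prior_mean - grid_span, prior_mean + grid_span,
                length.out = as.integer(n_grid))
  }
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing with length >= 2")
  }
  structure(
    list(beta = beta, delta = delta, gamma = gamma, target_p = target_p,
         prior_mean = prior_mean, prior_sd = prior_sd, grid = grid),
    class = "quest_params"
  )
}

#' Initialise a QUEST state
#'
#' The posterior starts as the discretised Gaussian prior over the grid.
#'
#' @param params a [quest_params()] object.
#' @return Object of class `quest_state`: list with `params`,
#'   `log_posterior` (normalised so the exponentiated values sum to 1) and
#'   `history` (data frame of tested intensities and outcomes).
#' @export
quest_init <- function(params = quest_params()) {
  stopifnot(inherits(params, "quest_params"))
  lp <- stats::dnorm(params$grid, params$prior_mean, params$prior_sd,
                     log = TRUE)
  structure(
    list(params = params,
         log_posterior = .quest_normalise(lp),
         history = data.frame(intensity = numeric(0),
                              correct = logical(0))),
    class = "quest_state"
  )
}

.quest_normalise <- function(lp) {
  m <- max(lp)
  lp - (m + log(sum(exp(lp - m))))
}

#' Weibull psychometric function used by QUEST
#'
#' Probability of a correct response at log10 intensity `log_intensity` for
#' an observer with log10 threshold `log_threshold`:
#' `p = delta * gamma + (1 - delta) * (1 - (1 - gamma) *
#'  exp(-10 ^ (beta * (log_intensity - log_threshold))))`.
#' The function is monotone nondecreasing in intensity, bounded below by the
#' guess rate `gamma` and above by `1 - delta * (1 - gamma)`.
#'
#' @param log_intensity log10 stimulus intensity (scalar).
#' @param log_threshold log10 threshold (may be a vector, e.g. the grid).
#' @param params a [quest_params()] object.
#' @return Probability correct, same length as `log_threshold`.
#' @export
quest_likelihood <- function(log_intensity, log_threshold,
                             params = quest_params()) {
  stopifnot(inherits(params, "quest_params"))
  b <- params$beta; d <- params$delta; g <- params$gamma
  d * g + (1 - d) *
    (1 - (1 - g) * exp(-10 ^ (b * (log_intensity - log_threshold))))
}

#' Bayesian update of the QUEST posterior after one trial
#'
#' @param state a `quest_state`.
#' @param tested_log_intensity log10 intensity the trial was run at.
#' @param correct logical outcome.
#' @return Updated `quest_state`.  Updates commute: any permutation of a
#'   fixed trial history yields the same posterior.
#' @export
quest_update <- function(state, tested_log_intensity, correct) {
  stopifnot(inherits(state, "quest_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  p <- quest_likelihood(tested_log_intensity, state$params$grid,
                        state$params)
  lik <- if (correct) p else 1 - p
  state$log_posterior <- .quest_normalise(
    state$log_posterior + log(pmax(lik, .Machine$double.xmin)))
  state$history <- rbind(
    state$history,
    data.frame(intensity = tested_log_intensity, correct = correct))
  state
}

#' Placement rule: intensity for the next trial
#'
#' Returns the posterior-mean log10 threshold, clamped to the grid range.
#'
#' @param state a `quest_state`.
#' @return log10 intensity for the next trial.
#' @export
quest_next_intensity <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  g <- state$params$grid
  est <- sum(g * exp(state$log_posterior))
  min(max(est, g[1L]), g[length(g)])
}

#' Threshold estimate and implied letter increment
#'
#' @param state a `quest_state`.
#' @return List with `log_threshold` (posterior mean, log10 units) and
#'   `increment` (`10 ^ log_threshold`, grey-level units).
#' @export
quest_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  est <- sum(state$params$grid * exp(state$log_posterior))
  list(log_threshold = est, increment = 10 ^ est)
}

#' Run a full QUEST titration against a responder
#'
#' Drives the staircase for `n_trials` trials: each trial is placed at the
#' current posterior mean (optionally capped, e.g. by display headroom), the
#' responder is queried, and the posterior updated.
#'
#' @param respond function of one argument (log10 intensity) returning a
#'   single logical: was the response correct?
#' @param n_trials number of staircase trials (default 50).
#' @param params a [quest_params()] object.
#' @param intensity_cap optional maximum log10 intensity to present.
#' @return List with the final `state`, `estimate` (see [quest_estimate()])
#'   and `trials` (data frame: trial, intensity, correct, running estimate).
#' @export
run_quest_titration <- function(respond, n_trials = 50L,
                                params = quest_params(),
                                intensity_cap = NULL) {
  stopifnot(is.function(respond))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("'n_trials' must be >= 1")
  state <- quest_init(params)
  log <- data.frame(trial = integer(0), intensity = numeric(0),
                    correct = logical(0), estimate = numeric(0))
  for (i in seq_len(n_trials)) {
    x <- quest_next_intensity(state)
    if (!is.null(intensity_cap)) x <- min(x, intensity_cap)
    ok <- isTRUE(respond(x))
    state <- quest_update(state, x, ok)
    log <- rbind(log, data.frame(
      trial = i, intensity = x, correct = ok,
      estimate = quest_estimate(state)$log_threshold))
  }
  list(state = state, estimate = quest_estimate(state), trials = log)
}

#' Simulated responder with a known Weibull psychometric function
#'
#' Factory for the graded observer used to validate QUEST convergence: the
#' probability of a correct response at intensity `x` is
#' `quest_likelihood(x, log_threshold, params)`.
#'
#' @param log_threshold true log10 threshold.
#' @param params a [quest_params()] object (slope/lapse/guess of the truth).
#' @return Function mapping log10 intensity to a logical response (draws
#'   from the global RNG).
#' @export
weibull_responder <- function(log_threshold, params = quest_params()) {
  force(log_threshold); force(params)
  function(x) stats::runif(1L) < quest_likelihood(x, log_threshold, params)
}

#' Seeded demonstration titration
#'
#' Runs one QUEST titration against a [weibull_responder()] whose true
#' threshold equals the prior mean, followed by fixed-intensity probe trials
#' at the final estimate.
#'
#' @param seed integer RNG seed.
#' @param n_trials staircase trials (default 50).
#' @param n_probe probe trials at the titrated intensity (default 200).
#' @param true_log_threshold true threshold; defaults to the prior mean.
#' @param params a [quest_params()] object.
#' @return List with `trials` (the staircase table), `estimate`,
#'   `probe_accuracy` (proportion correct over the probe trials).
#' @export
quest_demo <- function(seed = 1L, n_trials = 50L, n_probe = 200L,
                       true_log_threshold = NULL,
                       params = quest_params()) {
  set.seed(as.integer(seed))
  if (is.null(true_log_threshold)) true_log_threshold <- params$prior_mean
  resp <- weibull_responder(true_log_threshold, params)
  fit <- run_quest_titration(resp, n_trials = n_trials, params = params)
  est <- fit$estimate$log_threshold
  p <- quest_likelihood(est, true_log_threshold, params)
  acc <- mean(stats::runif(n_probe) < p)
  list(trials = fit$trials, estimate = fit$estimate, probe_accuracy = acc,
       true_log_threshold = true_log_threshold)
}
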
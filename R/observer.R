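#' Parameters of the synthetic observer
#'
#' The synthetic participant is the package's generative model of the
#' behaviour the analysis assumes.  Its mechanism is: (1) a hard
#' transduction threshold `theta` on pixel contrast -- only pixels whose
#' deviation from background exceeds `theta` reach the percept, which is why
#' adding pixel noise can reveal a subthreshold letter (stochastic
#' resonance); (2) template matching of the percept against the six letter
#' bitmaps; (3) a prior-weighted decision with zero-mean Gaussian late noise
#' on the six letter evidences; (4) a lapse process responding uniformly at
#' random.
#'
#' @param theta internal transduction threshold (grey-level units, >= 0).
#' @param prior_weight additive log-prior strength `w` on category evidence
#'   (>= 0); the decision maximises
#'   `evidence + w * log(letter prior) + noise`.
#' @param lapse probability of a uniformly random letter response.
#' @param evidence_noise SD of the zero-mean Gaussian late (decision) noise
#'   added independently to each letter's evidence.  This internal noise is
#'   what limits the observer at high external noise and makes behaviour
#'   graded near threshold.
#' @param n_frames_integrated number of stimulus frames averaged into the
#'   percept per trial (default 6).
#' @param category_prior probability the observer assigns to the frequent
#'   letter category (`0.5 <= category_prior < 1`), split equally over its
#'   three letters.
#' @param rng_seed optional integer seed used by [simulate_participant()].
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(theta = 40, prior_weight = 0.10, lapse = 0.05,
                            evidence_noise = 0.12,
                            n_frames_integrated = 6L,
                            category_prior = 0.8, rng_seed = NULL) {
  stopifnot(theta >= 0, prior_weight >= 0, lapse >= 0, lapse <= 1,
            evidence_noise >= 0, n_frames_integrated >= 1,
            category_prior >= 0.5, category_prior < 1)
  structure(
    list(theta = theta, prior_weight = prior_weight, lapse = lapse,
         evidence_noise = evidence_noise,
         n_frames_integrated = as.integer(n_frames_integrated),
         category_prior = category_prior, rng_seed = rng_seed),
    class = "observer_params"
  )
}

#' Draw a heterogeneous cohort of synthetic observers
#'
#' Participant-level parameters are drawn around the defaults: transduction
#' thresholds `theta ~ N(theta_mean, theta_sd)` (truncated at
#' `theta_mean / 2`) and prior weights `w ~ N(w_mean, w_sd)` (truncated at
#' `w_min`), with per-participant substream seeds derived from `seed`.
#'
#' @param n cohort size.
#' @param seed root seed.
#' @param theta_mean,theta_sd cohort distribution of `theta`.
#' @param w_mean,w_sd,w_min cohort distribution of the prior weight.
#' @param ... further arguments passed to [observer_params()] (shared by all
#'   participants).
#' @return List of `n` `observer_params` objects.
#' @export
observer_cohort <- function(n = 22L, seed = 1L, theta_mean = 40,
                            theta_sd = 2, w_mean = 0.10, w_sd = 0.02,
                            w_min = 0.04, ...) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  set.seed(substream_seed(seed, "cohort"))
  thetas <- pmax(stats::rnorm(n, theta_mean, theta_sd), theta_mean / 2)
  ws <- pmax(stats::rnorm(n, w_mean, w_sd), w_min)
  lapply(seq_len(n), function(i) {
    observer_params(theta = thetas[i], prior_weight = ws[i],
                    rng_seed = substream_seed(seed, "participant", i), ...)
  })
}

#' Threshold transduction of a stimulus
#'
#' Per frame, a pixel reaches the percept iff its deviation from background
#' exceeds `theta`, contributing that deviation; the percept map is the mean
#' over frames of the passed contributions (zero elsewhere).  This hard
#' nonlinearity is the stochastic-resonance mechanism: a subthreshold letter
#' (increment < theta) is invisible at sigma = 0 but is pushed across the
#' threshold on letter pixels by moderate noise.
#'
#' @param frames a `stimulus_frames` object (see [compose_trial_frames()]).
#' @param theta transduction threshold (grey-level units).
#' @return Numeric percept matrix, same size as one frame.
#' @export
transduce <- function(frames, theta) {
  stopifnot(inherits(frames, "stimulus_frames"), theta >= 0)
  d <- dim(frames$frames)
  s <- matrix(frames$frames, d[1L] * d[2L], d[3L]) - frames$background
  matrix(rowMeans(s * (s > theta)), d[1L], d[2L])
}

#' Letter evidence by normalized cross-correlation
#'
#' Evidence for each letter is the Pearson correlation between the percept
#' map and that letter's field-embedded template.  A percept with no spatial
#' variation (in particular the all-zero map of an invisible stimulus)
#' yields zero evidence for every letter.
#'
#' @param percept percept matrix from [transduce()] (or any numeric matrix
#'   with `field^2` pixels).
#' @param templates template pixel matrix from [template_matrix()], or a
#'   list of templates accepted by it.
#' @return Named numeric vector of 6 evidences in canonical letter order.
#' @export
letter_evidence <- function(percept, templates = template_matrix()) {
  if (is.list(templates)) templates <- template_matrix(templates)
  p <- as.numeric(percept)
  stopifnot(length(p) == nrow(templates))
  tc <- scale(templates, center = TRUE, scale = FALSE)
  tn <- sqrt(colSums(tc ^ 2))
  pc <- p - mean(p)
  pn <- sqrt(sum(pc ^ 2))
  if (pn < 1e-12) {
    ev <- rep(0, ncol(templates))
  } else {
    ev <- as.vector(crossprod(tc, pc)) / (pn * tn)
  }
  names(ev) <- colnames(templates)
  ev
}

#' Prior-weighted decision rule
#'
#' With probability `lapse` the observer responds with a uniformly random
#' letter.  Otherwise it responds with the letter maximising
#' `evidence + prior_weight * log(letter prior) + e`, where the frequent
#' category's probability `category_prior` is split equally over its three
#' letters and `e` is iid `N(0, evidence_noise^2)` late noise.  Exact ties
#' are broken uniformly at random.
#'
#' @param evidence named evidence vector over the six letters (canonical
#'   order, as from [letter_evidence()]).
#' @param frequent_category `"consonant"` or `"vowel"`.
#' @param params an [observer_params()] object.
#' @return A single response letter.
#' @export
decide <- function(evidence, frequent_category = "consonant",
                   params = observer_params()) {
  stopifnot(length(evidence) == 6L,
            frequent_category %in% c("consonant", "vowel"),
            inherits(params, "observer_params"))
  letters6 <- letter_set()
  if (!is.null(names(evidence))) evidence <- evidence[letters6]
  if (stats::runif(1L) < params$lapse) {
    return(sample(letters6, 1L))
  }
  cp <- params$category_prior
  prior <- ifelse(letter_category(letters6) == frequent_category,
                  cp / 3, (1 - cp) / 3)
  score <- as.numeric(evidence) + params$prior_weight * log(prior)
  if (params$evidence_noise > 0) {
    score <- score + stats::rnorm(6L, 0, params$evidence_noise)
  }
  top <- which(score == max(score))
  letters6[if (length(top) > 1L) sample(top, 1L) else top]
}

# Fast percept path: identical draws and arithmetic to
# compose_trial_frames() + transduce() (column k of the noise matrix is
# frame k), without materialising the frames array.
.trial_percept <- function(mask_vec, increment, sigma, theta,
                           n_frames, background) {
  sig <- background + increment * mask_vec
  if (sigma > 0) {
    s <- sig + matrix(stats::rnorm(length(mask_vec) * n_frames, 0, sigma),
                      length(mask_vec), n_frames)
  } else {
    s <- matrix(sig, length(mask_vec), 1L)
  }
  s <- pmin(pmax(s, 0), 255) - background
  rowMeans(s * (s > theta))
}

#' Simulate a synthetic participant through a trial schedule
#'
#' For every scheduled trial: composes the noisy frames, transduces them
#' through the observer's threshold nonlinearity, computes letter evidence,
#' and applies the prior-weighted decision rule.  Deterministic given the
#' seed.
#'
#' @param design an experiment design from [build_design()], or any data
#'   frame with columns `block`, `trial_index`, `sigma`, `letter_shown` (an
#'   optional `increment` column overrides the titrated increment row-wise,
#'   e.g. for the practice block).
#' @param params an [observer_params()] object.
#' @param increment titrated letter increment (grey-level units, > 0) used
#'   for rows without their own increment.
#' @param participant_id identifier written into the records.
#' @param frequent_category category the observer's prior favours.
#' @param templates list from [letter_templates()] (rendered once and
#'   reused); its masks define both the stimuli and the matching templates.
#' @param background background grey level.
#' @param seed RNG seed; defaults to `params$rng_seed`.
#' @return Data frame of trial records with columns `participant_id`,
#'   `block`, `trial_index`, `sigma`, `letter_shown`, `category_shown`,
#'   `response_letter`, `response_category`, `correct_category`,
#'   `increment`.
#' @export
simulate_participant <- function(design, params, increment,
                                 participant_id = "p01",
                                 frequent_category = "consonant",
                                 templates = letter_templates(),
                                 background = 127, seed = NULL) {
  sched <- if (is.data.frame(design)) design else design$schedule
  stopifnot(all(c("block", "trial_index", "sigma", "letter_shown") %in%
                  names(sched)),
            inherits(params, "observer_params"))
  if (missing(increment) || is.null(increment)) increment <- NA_real_
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  } else if (!is.null(params$rng_seed)) {
    set.seed(as.integer(params$rng_seed))
  }
  tm <- template_matrix(templates)
  tc <- scale(tm, center = TRUE, scale = FALSE)
  tn <- sqrt(colSums(tc ^ 2))
  letters6 <- letter_set()
  n <- nrow(sched)
  resp <- character(n)
  incr_col <- if ("increment" %in% names(sched)) sched$increment
              else rep(NA_real_, n)
  incr_used <- ifelse(is.na(incr_col), increment, incr_col)
  if (anyNA(incr_used) || any(incr_used <= 0)) {
    stop("every trial needs a positive increment (argument or column)")
  }
  nf <- params$n_frames_integrated
  for (i in seq_len(n)) {
    p <- .trial_percept(tm[, sched$letter_shown[i]], incr_used[i],
                        sched$sigma[i], params$theta, nf, background)
    pc <- p - mean(p)
    pn <- sqrt(sum(pc ^ 2))
    ev <- if (pn < 1e-12) stats::setNames(numeric(6L), letters6)
          else stats::setNames(as.vector(crossprod(tc, pc)) / (pn * tn),
                               letters6)
    resp[i] <- decide(ev, frequent_category, params)
  }
  data.frame(
    participant_id = participant_id,
    block = sched$block,
    trial_index = sched$trial_index,
    sigma = sched$sigma,
    letter_shown = sched$letter_shown,
    category_shown = letter_category(sched$letter_shown),
    response_letter = resp,
    response_category = letter_category(resp),
    correct_category =
      letter_category(sched$letter_shown) == letter_category(resp),
    increment = incr_used,
    stringsAsFactors = FALSE
  )
}
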
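#' Tally 2AFC category outcomes from 6AFC letter responses
#'
#' The 6-alternative letter task is folded into a 2-alternative category
#' task: a hit is responding with a rare-category letter when a rare letter
#' was shown; a miss is responding frequent to a rare letter; a correct
#' rejection is responding frequent to a frequent letter; a false alarm is
#' responding rare to a frequent letter.
#'
#' @param trials data frame of trial records with columns
#'   `category_shown` and `response_category` (or `letter_shown` /
#'   `response_letter`, from which categories are derived).
#' @param rare_category `"consonant"` or `"vowel"`.
#' @return Object of class `sdt_counts`: list with integers `H`, `M`, `FA`,
#'   `CR`.  Invariants: `H + M` equals the number of rare-category trials
#'   and `FA + CR` the number of frequent-category trials.
#' @export
classify_responses <- function(trials, rare_category) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L,
            rare_category %in% c("consonant", "vowel"))
  shown <- if ("category_shown" %in% names(trials)) trials$category_shown
           else letter_category(trials$letter_shown)
  resp <- if ("response_category" %in% names(trials)) trials$response_category
          else letter_category(trials$response_letter)
  ok <- c("consonant", "vowel")
  if (!all(shown %in% ok) || !all(resp %in% ok)) {
    stop("invalid record: category outside {consonant, vowel}")
  }
  rare_shown <- shown == rare_category
  rare_resp <- resp == rare_category
  structure(
    list(H = sum(rare_shown & rare_resp),
         M = sum(rare_shown & !rare_resp),
         FA = sum(!rare_shown & rare_resp),
         CR = sum(!rare_shown & !rare_resp)),
    class = "sdt_counts"
  )
}

#' Accuracy from SDT counts
#'
#' `(H + CR) / (H + M + CR + FA)`.
#'
#' @param counts an `sdt_counts` object (or list with H, M, FA, CR).
#' @return Proportion correct.
#' @export
sdt_accuracy <- function(counts) {
  tot <- counts$H + counts$M + counts$FA + counts$CR
  if (tot <= 0) stop("cannot compute accuracy from zero trials")
  (counts$H + counts$CR) / tot
}

#' Hit and false-alarm rates with extreme-rate correction
#'
#' Raw rates are `HR = H / (H + M)` and `FAR = FA / (CR + FA)`.  A rate of
#' exactly 0 or 1 would make the normal quantile infinite, so it is replaced
#' by `1 / (2N)` or `1 - 1 / (2N)` respectively, where `N` is that rate's
#' own trial count (the standard log-linear-free clipping remedy).
#'
#' @param counts an `sdt_counts` object.
#' @return List with `HR`, `FAR`, `correction_applied` (logical).
#' @export
sdt_rates <- function(counts) {
  n_rare <- counts$H + counts$M
  n_freq <- counts$FA + counts$CR
  if (n_rare <= 0 || n_freq <= 0) {
    stop("both rare and frequent trials are required to form rates")
  }
  clip <- function(r, n) {
    if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
  }
  hr_raw <- counts$H / n_rare
  far_raw <- counts$FA / n_freq
  hr <- clip(hr_raw, n_rare)
  far <- clip(far_raw, n_freq)
  list(HR = hr, FAR = far,
       correction_applied = (hr != hr_raw) || (far != far_raw))
}

#' Sensitivity d'
#'
#' `d' = z(HR) - z(FAR)` with `z` the standard-normal quantile function.
#' Rates must lie strictly inside (0, 1); see [sdt_rates()] for the
#' correction of extreme rates.
#'
#' @param HR,FAR hit and false-alarm rates in (0, 1).
#' @return d' (dimensionless, in SD units of the evidence axis).
#' @export
dprime <- function(HR, FAR) {
  .check_rates(HR, FAR)
  stats::qnorm(HR) - stats::qnorm(FAR)
}

#' Response criterion c
#'
#' `c = -(z(HR) + z(FAR)) / 2`.  Positive values indicate a bias toward the
#' frequent category, i.e. under-responding "rare".
#'
#' @inheritParams dprime
#' @return Criterion (same units as d').
#' @export
criterion <- function(HR, FAR) {
  .check_rates(HR, FAR)
  -(stats::qnorm(HR) + stats::qnorm(FAR)) / 2
}

.check_rates <- function(HR, FAR) {
  if (any(c(HR, FAR) <= 0) || any(c(HR, FAR) >= 1)) {
    stop("rates must lie strictly in (0, 1); apply sdt_rates() correction")
  }
}

#' Per-participant, per-noise-level SDT summary
#'
#' Pools the supplied trials (canonically blocks 4 and 5, so the zero-noise
#' rows from both blocks form the baseline) and computes one row per
#' participant x sigma: counts, accuracy, corrected rates, d' and
#' criterion.
#'
#' @param trials trial records (see [simulate_participant()] /
#'   [read_trial_log()]), already restricted to the blocks of interest.
#' @param rare_category the rare letter category for these participants
#'   (scalar, or named vector keyed by participant id when the flipped
#'   base-rate direction differs between participants).
#' @return Data frame with columns `participant_id`, `sigma`, `n_rare`,
#'   `n_frequent`, `H`, `M`, `FA`, `CR`, `accuracy`, `HR`, `FAR`, `dprime`,
#'   `criterion`, `correction_applied`, ordered by participant then sigma.
#' @export
sdt_summarize <- function(trials, rare_category = "vowel") {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L)
  ids <- unique(trials$participant_id)
  rare_for <- function(id) {
    if (length(rare_category) == 1L && is.null(names(rare_category))) {
      rare_category
    } else {
      if (!id %in% names(rare_category)) {
        stop("no rare_category entry for participant ", id)
      }
      unname(rare_category[[id]])
    }
  }
  out <- list()
  for (id in ids) {
    sub <- trials[trials$participant_id == id, , drop = FALSE]
    for (s in sort(unique(sub$sigma))) {
      cell <- sub[sub$sigma == s, , drop = FALSE]
      cnt <- classify_responses(cell, rare_for(id))
      if (cnt$H + cnt$M == 0L || cnt$FA + cnt$CR == 0L) {
        warning("participant ", id, ", sigma ", s,
                ": missing a category; row omitted")
        next
      }
      r <- sdt_rates(cnt)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = id, sigma = s,
        n_rare = cnt$H + cnt$M, n_frequent = cnt$FA + cnt$CR,
        H = cnt$H, M = cnt$M, FA = cnt$FA, CR = cnt$CR,
        accuracy = sdt_accuracy(cnt),
        HR = r$HR, FAR = r$FAR,
        dprime = dprime(r$HR, r$FAR),
        criterion = criterion(r$HR, r$FAR),
        correction_applied = r$correction_applied,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
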
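#' Build the experiment design (Table-of-blocks structure)
#'
#' Constructs the block ladder of the paradigm: an 18-trial practice block
#' (6 letters x 3 repetitions, zero noise), a 50-trial QUEST titration
#' block, two 48-trial zero-noise base-rate blocks (block2 uninformed,
#' consonant-frequent; block3 informed, frequent category set by the
#' participant's observed bias), and two 240-trial noise blocks (block4,
#' block5) crossing the noise ladder with the 80/20 base rate.
#'
#' Two counting conventions are applied exactly:
#' \itemize{
#'   \item 48-trial blocks cannot realise 80/20 with equal per-letter
#'     counts, so they use 39 frequent (13 per letter) / 9 rare (3 per
#'     letter), an effective 81.25/18.75 split.
#'   \item The 240-trial blocks comprise eight 30-trial noise-condition
#'     slots over the 7-level ladder, the zero-noise condition occupying two
#'     slots; each slot is an exact 24/6 (8 and 2 per letter) split.
#' }
#' Shuffling is seeded per block via [substream_seed()], so letter counts
#' are deterministic and only order is random; block5 repeats block4's
#' composition with a fresh shuffle.
#'
#' @param config optional list overriding `sigma_min`, `sigma_max`,
#'   `n_nonzero`, `trials_per_slot` (default 30; must be divisible by 15),
#'   `n_quest_trials`, `practice_reps`.
#' @param seed root seed for the schedule shuffles.
#' @param frequent_category category presented frequently from block3 on
#'   (block2 is always consonant-frequent; the flip is applied by
#'   [run_simulate()] after [assign_frequent_category()]).
#' @return Object of class `experiment_design`: list with `blocks` (one row
#'   per block: label, n_trials, base_rate, informed), `frequent_category`,
#'   `sigmas` (the noise ladder) and `schedule` (one row per trial: block,
#'   trial_index, sigma, letter_shown).
#' @export
build_design <- function(config = NULL, seed = 1L,
                         frequent_category = "consonant") {
  defaults <- list(sigma_min = 0.25, sigma_max = 64, n_nonzero = 6L,
                   trials_per_slot = 30L, n_quest_trials = 50L,
                   practice_reps = 3L)
  if (!is.null(config)) {
    bad <- setdiff(names(config), names(defaults))
    if (length(bad) > 0L) {
      stop("unknown design config key(s): ", paste(bad, collapse = ", "))
    }
    defaults[names(config)] <- config
  }
  cfg <- defaults
  stopifnot(frequent_category %in% c("consonant", "vowel"))
  tps <- as.integer(cfg$trials_per_slot)
  if (tps < 15L || tps %% 15L != 0L) {
    stop("'trials_per_slot' must be a positive multiple of 15 ",
         "(exact 80/20 split with equal per-letter counts)")
  }
  sigmas <- make_noise_ladder(cfg$sigma_min, cfg$sigma_max, cfg$n_nonzero)

  freq_letters <- function(cat) letter_set()[letter_category(letter_set()) == cat]
  rare_of <- function(cat) setdiff(c("consonant", "vowel"), cat)

  balanced <- function(n_freq, n_rare, cat) {
    fl <- freq_letters(cat)
    rl <- freq_letters(rare_of(cat))
    if (n_freq %% 3L != 0L || n_rare %% 3L != 0L) {
      stop("per-category trial counts must divide equally over 3 letters")
    }
    c(rep(fl, each = n_freq / 3L), rep(rl, each = n_rare / 3L))
  }

  shuffle <- function(x, label) {
    set.seed(substream_seed(seed, "design", label))
    sample(x)
  }

  # practice: 6 letters x practice_reps, zero noise
  practice <- shuffle(rep(letter_set(), cfg$practice_reps), "practice")
  # quest: one random letter per trial
  set.seed(substream_seed(seed, "design", "quest"))
  quest <- sample(letter_set(), cfg$n_quest_trials, replace = TRUE)
  # 48-trial base-rate blocks: 39/9 equal-per-letter split
  b2 <- shuffle(balanced(39L, 9L, "consonant"), "block2")
  b3 <- shuffle(balanced(39L, 9L, frequent_category), "block3")

  # noise blocks: 8 slots of trials_per_slot, zero-noise twice
  slot_weights <- c(2L, rep(1L, length(sigmas) - 1L))
  noise_block <- function(label) {
    rows <- do.call(rbind, lapply(seq_along(sigmas), function(k) {
      n <- slot_weights[k] * tps
      data.frame(
        sigma = sigmas[k],
        letter_shown = balanced(n * 4L / 5L, n / 5L, frequent_category),
        stringsAsFactors = FALSE)
    }))
    set.seed(substream_seed(seed, "design", label))
    rows[sample(nrow(rows)), , drop = FALSE]
  }
  b4 <- noise_block("block4")
  b5 <- noise_block("block5")

  zero_block <- function(label, letters) {
    data.frame(block = label,
               trial_index = seq_along(letters),
               sigma = 0,
               letter_shown = letters,
               stringsAsFactors = FALSE)
  }
  sched <- rbind(
    zero_block("practice", practice),
    zero_block("quest", quest),
    zero_block("block2", b2),
    zero_block("block3", b3),
    data.frame(block = "block4", trial_index = seq_len(nrow(b4)),
               sigma = b4$sigma, letter_shown = b4$letter_shown,
               stringsAsFactors = FALSE),
    data.frame(block = "block5", trial_index = seq_len(nrow(b5)),
               sigma = b5$sigma, letter_shown = b5$letter_shown,
               stringsAsFactors = FALSE)
  )
  rownames(sched) <- NULL
  blocks <- data.frame(
    label = c("practice", "quest", "block2", "block3", "block4", "block5"),
    n_trials = c(length(practice), length(quest), 48L, 48L,
                 nrow(b4), nrow(b5)),
    base_rate = c(0.5, 0.5, 39 / 48, 39 / 48, 0.8, 0.8),
    informed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  structure(
    list(blocks = blocks, frequent_category = frequent_category,
         sigmas = sigmas, schedule = sched),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design:", nrow(x$schedule), "trials,",
      length(x$sigmas), "noise levels, frequent =",
      x$frequent_category, ">\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Determine the participant's preferred letter category
#'
#' After the uninformed base-rate block (block2), the participant's
#' criterion (computed with vowel as the "rare" category) decides which
#' category they over-respond with: a positive criterion means
#' under-responding vowel, i.e. a consonant preference.  Subsequent blocks
#' make that category the frequent one.  A criterion of exactly zero falls
#' back to the presented frequent category (consonant).
#'
#' @param block2_records trial records of block2.
#' @return `"consonant"` or `"vowel"`.
#' @export
assign_frequent_category <- function(block2_records) {
  if (is.null(block2_records) || nrow(block2_records) == 0L) {
    stop("block2 records are empty")
  }
  counts <- classify_responses(block2_records, rare_category = "vowel")
  r <- sdt_rates(counts)
  c_hat <- criterion(r$HR, r$FAR)
  if (c_hat < 0) "vowel" else "consonant"
}

#' QUEST rerun rule
#'
#' The titration targets 70% correct; if the 6AFC letter-exact accuracy in
#' block2 is not within +/- 10 percentage points of that level, the QUEST
#' block is run again.  The boundary is inclusive: accuracies of exactly
#' 0.60 or 0.80 do not trigger a rerun.
#'
#' @param block2_accuracy proportion correct in `[0, 1]`.
#' @return `TRUE` if QUEST must be rerun.
#' @export
quest_rerun_rule <- function(block2_accuracy) {
  stopifnot(is.numeric(block2_accuracy), length(block2_accuracy) == 1L,
            block2_accuracy >= 0, block2_accuracy <= 1)
  abs(block2_accuracy - 0.70) > 0.10 + 1e-9
}

#' Participant exclusion rule
#'
#' Participants who do not show a bias (of any size) toward the frequent
#' stimuli in the informed base-rate block (block3) are excluded: exclude
#' iff the block3 criterion is <= 0.
#'
#' @param block3_criterion criterion value computed on block3.
#' @return `"include"` or `"exclude"`.
#' @export
exclusion_rule <- function(block3_criterion) {
  stopifnot(is.numeric(block3_criterion), length(block3_criterion) == 1L,
            is.finite(block3_criterion))
  if (block3_criterion > 0) "include" else "exclude"
}
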
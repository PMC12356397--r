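test_that("the block ladder realises the printed trial counts", {
  d <- build_design(seed = 1)
  counts <- table(d$schedule$block)
  expect_identical(as.integer(counts[d$blocks$label]),
                   as.integer(c(18, 50, 48, 48, 240, 240)))
  # blocks 4+5 give 60 trials per nonzero noise level, 120 at zero
  b45 <- d$schedule[d$schedule$block %in% c("block4", "block5"), ]
  per_sigma <- table(b45$sigma)
  nz <- setdiff(sort(unique(b45$sigma)), 0)
  expect_identical(length(nz), 6L)
  expect_true(all(per_sigma[as.character(nz)] == 60L))
  expect_identical(unname(per_sigma["0"]), 120L)
})

test_that("base-rate blocks use exact equal-per-letter splits", {
  d <- build_design(seed = 3)
  b2 <- d$schedule[d$schedule$block == "block2", ]
  tab <- table(b2$letter_shown)
  expect_true(all(tab[c("C", "B", "H")] == 13L))
  expect_true(all(tab[c("O", "E", "U")] == 3L))
  # per noise condition in block4: 24 frequent / 6 rare, equal per letter
  b4 <- d$schedule[d$schedule$block == "block4", ]
  for (s in setdiff(unique(b4$sigma), 0)) {
    tab_s <- table(b4$letter_shown[b4$sigma == s])
    expect_true(all(tab_s[c("C", "B", "H")] == 8L))
    expect_true(all(tab_s[c("O", "E", "U")] == 2L))
  }
  tab_0 <- table(b4$letter_shown[b4$sigma == 0])
  expect_true(all(tab_0[c("C", "B", "H")] == 16L))
  expect_true(all(tab_0[c("O", "E", "U")] == 4L))
})

test_that("shuffling is seed-stable and changes only order", {
  a <- build_design(seed = 10)
  b <- build_design(seed = 10)
  c <- build_design(seed = 11)
  expect_identical(a$schedule, b$schedule)
  expect_false(identical(a$schedule$letter_shown, c$schedule$letter_shown))
  # outside the randomly drawn QUEST block, composition is seed-invariant
  fixed <- function(d) table(
    d$schedule$letter_shown[d$schedule$block != "quest"],
    d$schedule$block[d$schedule$block != "quest"])
  expect_identical(fixed(a), fixed(c))
})

test_that("the base-rate flip reaches blocks 3-5 but never block 2", {
  d <- build_design(seed = 2, frequent_category = "vowel")
  cat_of <- function(b) letter_category(
    d$schedule$letter_shown[d$schedule$block == b])
  expect_identical(sum(cat_of("block2") == "consonant"), 39L)
  expect_identical(sum(cat_of("block3") == "vowel"), 39L)
  expect_identical(sum(cat_of("block4") == "vowel"), 192L)
  expect_identical(sum(cat_of("block5") == "vowel"), 192L)
})

test_that("design rejects unrealisable configurations", {
  expect_error(build_design(list(trials_per_slot = 20L)), "multiple of 15")
  expect_error(build_design(list(nonsense = 1)), "unknown design config")
})

test_that("bias assignment follows the criterion sign on block2", {
  mk <- function(shown, resp) {
    data.frame(block = "block2", trial_index = seq_along(shown),
               sigma = 0, letter_shown = shown,
               category_shown = letter_category(shown),
               response_letter = resp,
               response_category = letter_category(resp),
               stringsAsFactors = FALSE)
  }
  shown <- c(rep("C", 13), rep("B", 13), rep("H", 13),
             rep("O", 3), rep("E", 3), rep("U", 3))
  expect_identical(assign_frequent_category(mk(shown, rep("C", 48))),
                   "consonant")
  expect_identical(assign_frequent_category(mk(shown, rep("O", 48))),
                   "vowel")
  # perfectly accurate responding mirrors the 80/20 presentation rates:
  # the corrected criterion is positive, so consonant is preferred
  expect_identical(assign_frequent_category(mk(shown, shown)), "consonant")
  expect_error(assign_frequent_category(mk(shown, shown)[0, ]), "empty")
})

test_that("the QUEST rerun boundary is inclusive at 70 +/- 10", {
  expect_false(quest_rerun_rule(0.70))
  expect_true(quest_rerun_rule(0.59))
  expect_false(quest_rerun_rule(0.80))
  expect_false(quest_rerun_rule(0.60))
  expect_true(quest_rerun_rule(0.81))
  expect_true(quest_rerun_rule(0.20))
})

test_that("participants without a frequent-category bias are excluded", {
  expect_identical(exclusion_rule(0.52), "include")
  expect_identical(exclusion_rule(0), "exclude")
  expect_identical(exclusion_rule(-0.3), "exclude")
  expect_identical(exclusion_rule(1e-6), "include")
})
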
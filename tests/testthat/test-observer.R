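test_that("transduction passes only suprathreshold contrast", {
  tpl <- render_letter_template("E", 20)
  fr0 <- compose_trial_frames(tpl, 20, 0, n_frames = 2, field = 40)
  m <- embed_mask(tpl$mask, 40)
  # theta = 0: percept proportional to the letter mask
  pc <- transduce(fr0, 0)
  expect_equal(pc, 20 * m, ignore_attr = TRUE)
  # subthreshold letter, no noise: invisible
  expect_true(all(transduce(fr0, 25) == 0))
})

test_that("noise lifts a subthreshold letter into the percept (SR mechanism)", {
  tpl <- render_letter_template("E", 20)
  fr <- compose_trial_frames(tpl, 20, 15, n_frames = 1000, field = 40,
                             seed = 42)
  pc <- transduce(fr, 40)  # theta 40 > increment 20
  m <- embed_mask(tpl$mask, 40)
  expect_gt(mean(pc[m == 1]), mean(pc[m == 0]))
})

test_that("letter evidence is a normalized template match", {
  tpls <- letter_templates(20, 40)
  tm <- template_matrix(tpls)
  ev <- letter_evidence(tpls[["E"]]$mask, tm)
  expect_identical(names(which.max(ev)), "E")
  expect_equal(max(ev), 1, tolerance = 1e-12)
  # zero map carries no evidence
  expect_true(all(letter_evidence(matrix(0, 40, 40), tm) == 0))
  # mixtures favour the dominant component
  mix <- 0.7 * tpls[["B"]]$mask + 0.3 * tpls[["E"]]$mask
  evm <- letter_evidence(mix, tm)
  expect_gt(evm[["B"]], evm[["E"]])
})

test_that("decision rule weighs prior against evidence", {
  zero_ev <- setNames(numeric(6), letter_set())
  biased <- observer_params(prior_weight = 1, lapse = 0, evidence_noise = 0)
  set.seed(1)
  resps <- replicate(50, decide(zero_ev, "consonant", biased))
  expect_true(all(letter_category(resps) == "consonant"))
  # w = 0: pure argmax
  ev <- setNames(c(0.1, 0.2, 0.9, 0.3, 0.1, 0), letter_set())
  neutral <- observer_params(prior_weight = 0, lapse = 0,
                             evidence_noise = 0)
  expect_identical(decide(ev, "consonant", neutral), "H")
  # scanning the evidence scale finds a prior-to-evidence crossover
  rare_ev <- setNames(c(0, 0, 0, 0.1, 0, 0), letter_set())  # favours 'O'
  w1 <- observer_params(prior_weight = 1, lapse = 0, evidence_noise = 0)
  resp_at <- function(k) decide(rare_ev * k, "consonant", w1)
  expect_identical(letter_category(resp_at(0.1)), "consonant")
  expect_identical(resp_at(20), "O")
  flips <- vapply(seq(0.1, 20, length.out = 40),
                  function(k) resp_at(k) == "O", logical(1))
  expect_true(any(!flips) && any(flips))
  expect_true(all(diff(flips) >= 0))  # single crossover
})

test_that("full lapse yields chance category accuracy on balanced trials", {
  sch <- balanced_schedule(120, sigma = 0, seed = 2)
  tr <- simulate_participant(sch, observer_params(lapse = 1), 39, seed = 7)
  expect_lt(abs(mean(tr$correct_category) - 0.5), 3 * sqrt(0.25 / 120))
})

test_that("subthreshold observers show stochastic resonance and bias relief", {
  pars <- observer_params()  # theta 40
  inc <- 39                  # subthreshold: theta > increment
  run_at <- function(sigma, seed) {
    sch <- biased_schedule(60, sigma = sigma, seed = seed)
    simulate_participant(sch, pars, inc, seed = seed + 1000)
  }
  base <- run_at(0, 3)
  star <- run_at(6.96, 3)
  acc0 <- mean(base$correct_category)
  acc_star <- mean(star$correct_category)
  expect_gte(acc_star - acc0, 0.10)
  # criterion at the resonant level is below the zero-noise criterion
  crit_of <- function(tr) {
    r <- sdt_rates(classify_responses(tr, "vowel"))
    criterion(r$HR, r$FAR)
  }
  expect_lt(crit_of(star), crit_of(base))
  expect_gt(crit_of(base), 0)
})

test_that("with no transduction threshold accuracy does not increase with noise", {
  pars <- observer_params(theta = 0)
  accs <- vapply(c(0, 2.3, 6.96, 21.11, 64), function(sg) {
    mean(vapply(1:3, function(s) {
      sch <- balanced_schedule(60, sigma = sg, seed = s)
      mean(simulate_participant(sch, pars, 39,
                                seed = s + 200)$correct_category)
    }, numeric(1)))
  }, numeric(1))
  # non-increasing trend up to Monte-Carlo error
  expect_true(all(diff(accs) <= 0.03))
  expect_gt(accs[1], accs[length(accs)])
})

test_that("prior-driven bias emerges for zero-information stimuli", {
  # letter far below threshold at sigma = 0: the percept is empty, so only
  # the category prior drives responding
  pars <- observer_params(prior_weight = 0.2)
  sch <- biased_schedule(60, sigma = 0, seed = 5)
  tr <- simulate_participant(sch, pars, 20, seed = 11)
  r <- sdt_rates(classify_responses(tr, "vowel"))
  expect_gt(criterion(r$HR, r$FAR), 0)
})

test_that("without a category prior the mean criterion vanishes on balanced trials", {
  cs <- vapply(1:8, function(s) {
    sch <- balanced_schedule(120, sigma = 6.96, seed = s)
    tr <- simulate_participant(sch, observer_params(prior_weight = 0), 39,
                               seed = s + 300)
    r <- sdt_rates(classify_responses(tr, "vowel"))
    criterion(r$HR, r$FAR)
  }, numeric(1))
  expect_lt(abs(mean(cs)), 0.15)
})

test_that("identical seeds give identical trial logs", {
  sch <- biased_schedule(30, sigma = 2.3, seed = 4)
  a <- simulate_participant(sch, observer_params(), 39, seed = 123)
  b <- simulate_participant(sch, observer_params(), 39, seed = 123)
  expect_identical(a, b)
})
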
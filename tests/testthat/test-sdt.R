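# build a trial frame from shown/responded category vectors
cat_trials <- function(shown, resp) {
  pick <- function(cat) ifelse(cat == "vowel", "O", "C")
  data.frame(block = "block4", trial_index = seq_along(shown), sigma = 0,
             letter_shown = pick(shown), category_shown = shown,
             response_letter = pick(resp), response_category = resp,
             stringsAsFactors = FALSE)
}

test_that("responses are tallied into H/M/FA/CR by category", {
  shown <- c(rep("vowel", 10), rep("consonant", 40))
  cnt <- classify_responses(cat_trials(shown, shown), "vowel")
  expect_identical(unclass(cnt)[c("H", "M", "FA", "CR")],
                   list(H = 10L, M = 0L, FA = 0L, CR = 40L))
  # maximal conservative bias: everything answered frequent
  cnt2 <- classify_responses(cat_trials(shown, rep("consonant", 50)),
                             "vowel")
  expect_identical(unclass(cnt2)[c("H", "M", "FA", "CR")],
                   list(H = 0L, M = 10L, FA = 0L, CR = 40L))
  # mixed log: 12 rare (9 correct), 36 frequent (7 errors)
  shown3 <- c(rep("vowel", 12), rep("consonant", 36))
  resp3 <- c(rep("vowel", 9), rep("consonant", 3),
             rep("vowel", 7), rep("consonant", 29))
  cnt3 <- classify_responses(cat_trials(shown3, resp3), "vowel")
  expect_identical(unclass(cnt3)[c("H", "M", "FA", "CR")],
                   list(H = 9L, M = 3L, FA = 7L, CR = 29L))
  # counts partition the trials by presented category
  expect_identical(cnt3$H + cnt3$M, 12L)
  expect_identical(cnt3$FA + cnt3$CR, 36L)
})

test_that("records with letters outside the set are rejected", {
  bad <- data.frame(letter_shown = "Z", response_letter = "C")
  expect_error(classify_responses(bad, "vowel"), "unknown letter")
})

test_that("accuracy is (H+CR)/total", {
  expect_equal(sdt_accuracy(list(H = 10, M = 0, FA = 0, CR = 40)), 1)
  expect_equal(sdt_accuracy(list(H = 0, M = 10, FA = 40, CR = 0)), 0)
  expect_equal(sdt_accuracy(list(H = 9, M = 3, FA = 7, CR = 29)), 38 / 48)
  expect_error(sdt_accuracy(list(H = 0, M = 0, FA = 0, CR = 0)), "zero")
})

test_that("rates apply the 1/(2N) extreme-rate correction", {
  r <- sdt_rates(list(H = 9, M = 3, FA = 7, CR = 29))
  expect_equal(r$HR, 0.75)
  expect_false(r$correction_applied)
  r2 <- sdt_rates(list(H = 12, M = 0, FA = 3, CR = 33))
  expect_equal(r2$HR, 1 - 1 / 24)
  expect_true(r2$correction_applied)
  r3 <- sdt_rates(list(H = 6, M = 6, FA = 0, CR = 36))
  expect_equal(r3$FAR, 1 / 72)
  expect_true(r3$correction_applied)
  expect_error(sdt_rates(list(H = 0, M = 0, FA = 3, CR = 33)), "required")
})

test_that("d-prime and criterion match a bisection-on-erf oracle", {
  skip_if_not_installed("pracma")
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.8413447, 0.1586553), 2, tolerance = 1e-4)
  expect_equal(criterion(0.5, 0.5), 0)
  expect_equal(criterion(0.8413447, 0.1586553), 0, tolerance = 1e-6)
  # independent high-precision inverse-normal via bisection on erf
  z_hr <- qnorm_bisect(0.75)
  z_far <- qnorm_bisect(0.1944)
  expect_equal(dprime(0.75, 0.1944), z_hr - z_far, tolerance = 1e-9)
  expect_equal(dprime(0.75, 0.1944), 1.536, tolerance = 1e-3)
  expect_equal(criterion(0.75, 0.1944), -(z_hr + z_far) / 2,
               tolerance = 1e-9)
  expect_equal(criterion(0.75, 0.1944), 0.0937, tolerance = 1e-3)
  expect_error(dprime(1, 0.5), "strictly")
  expect_error(criterion(0.5, 0), "strictly")
})

test_that("d-prime and criterion reconstruct the corrected rates", {
  set.seed(8)
  for (i in 1:50) {
    hr <- runif(1, 0.02, 0.98)
    far <- runif(1, 0.02, 0.98)
    d <- dprime(hr, far)
    c0 <- criterion(hr, far)
    expect_equal(qnorm(hr), d / 2 - c0, tolerance = 1e-12)
    expect_equal(qnorm(far), -d / 2 - c0, tolerance = 1e-12)
  }
})

test_that("relabelling the rare category preserves accuracy and d', flips c", {
  shown <- c(rep("vowel", 12), rep("consonant", 36))
  resp <- c(rep("vowel", 9), rep("consonant", 3),
            rep("vowel", 7), rep("consonant", 29))
  tr <- cat_trials(shown, resp)
  as_rare <- function(rc) {
    cnt <- classify_responses(tr, rc)
    r <- sdt_rates(cnt)
    c(acc = sdt_accuracy(cnt), d = dprime(r$HR, r$FAR),
      c = criterion(r$HR, r$FAR))
  }
  v <- as_rare("vowel"); k <- as_rare("consonant")
  expect_equal(v[["acc"]], k[["acc"]])
  expect_equal(v[["d"]], k[["d"]], tolerance = 1e-12)
  expect_equal(v[["c"]], -k[["c"]], tolerance = 1e-12)
})

test_that("summaries match hand counts and pool duplicated logs identically", {
  shown <- c(rep("vowel", 12), rep("consonant", 36))
  resp <- c(rep("vowel", 9), rep("consonant", 3),
            rep("vowel", 7), rep("consonant", 29))
  tr0 <- cat_trials(shown, resp); tr0$sigma <- 0
  resp_hi <- c(rep("vowel", 11), "consonant",
               rep("consonant", 34), rep("vowel", 2))
  tr1 <- cat_trials(shown, resp_hi); tr1$sigma <- 2.3
  tr <- rbind(tr0, tr1)
  tr$participant_id <- "p01"
  s <- sdt_summarize(tr, "vowel")
  expect_identical(nrow(s), 2L)
  row0 <- s[s$sigma == 0, ]
  expect_identical(c(row0$H, row0$M, row0$FA, row0$CR), c(9L, 3L, 7L, 29L))
  expect_equal(row0$accuracy, 38 / 48)
  expect_equal(row0$HR, 0.75)
  expect_equal(row0$dprime, dprime(0.75, 7 / 36))
  # duplicating every trial leaves all rates identical
  s2 <- sdt_summarize(rbind(tr, tr), "vowel")
  expect_equal(s2[, c("accuracy", "HR", "FAR", "dprime", "criterion")],
               s[, c("accuracy", "HR", "FAR", "dprime", "criterion")])
  # a log with only zero-noise trials gives a single row
  tr_only0 <- tr[tr$sigma == 0, ]
  expect_identical(nrow(sdt_summarize(tr_only0, "vowel")), 1L)
})

test_that("cells missing a presented category are dropped with a warning", {
  tr <- cat_trials(rep("consonant", 10), rep("consonant", 10))
  tr$sigma <- 64
  tr$participant_id <- "p01"
  expect_warning(out <- sdt_summarize(tr, "vowel"), "omitted")
  expect_null(out)
})
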
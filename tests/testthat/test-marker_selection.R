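test_that("IHC binarization follows the >10% at >=moderate-intensity rule", {
  expect_equal(as.character(binarize_ihc(15, 2)), "positive")
  expect_equal(as.character(binarize_ihc(5, 3)), "negative")   # extent too low
  expect_equal(as.character(binarize_ihc(50, 1)), "negative")  # too weak
  expect_equal(as.character(binarize_ihc(10, 3)), "negative")  # strictly > 10
  expect_equal(as.character(binarize_ihc(c(20, 80), c(2, 0))),
               c("positive", "negative"))
  expect_error(binarize_ihc(120, 2), "percent_stained")
  expect_error(binarize_ihc(50, 5), "intensity")
})

test_that("weighted stump error matches direct counting and orientation logic", {
  calls <- c("+", "+", "-", "-")
  resp <- c("NR", "NR", "NR", "R")
  e <- weighted_stump_error(calls, resp, rep(0.25, 4), orientation = "pos_NR")
  expect_equal(as.numeric(e), 0.25)   # one miss: sample 3 (negative but NR)

  # marker identical to response
  expect_equal(as.numeric(weighted_stump_error(
    c("+", "+", "-"), c("NR", "NR", "R"))), 0)
  # independent marker, balanced classes, equal weights
  expect_equal(as.numeric(weighted_stump_error(
    c("+", "-", "+", "-"), c("NR", "NR", "R", "R"), orientation = "pos_NR")),
    0.5)
  expect_error(weighted_stump_error(calls, resp, rep(0, 4)), "weights")

  # equal weights: error equals 1 - best accuracy by direct counting
  set.seed(31)
  for (i in 1:40) {
    n <- sample(6:20, 1)
    calls_i <- sample(c("positive", "negative"), n, replace = TRUE)
    resp_i <- sample(c("R", "NR"), n, replace = TRUE)
    acc_pos_nr <- mean((calls_i == "positive") == (resp_i == "NR"))
    best <- weighted_stump_error(calls_i, resp_i)
    expect_equal(as.numeric(best),
                 1 - max(acc_pos_nr, 1 - acc_pos_nr), tolerance = 1e-12)
  }
})

test_that("a perfectly predictive marker is selected first and weights stay a distribution", {
  set.seed(5)
  n <- 40
  resp <- rep(c("R", "NR"), each = n / 2)
  markers <- list(perfect = ifelse(resp == "NR", "positive", "negative"))
  for (j in 1:4) {
    markers[[paste0("noise", j)]] <-
      sample(c("positive", "negative"), n, replace = TRUE)
  }
  ch <- make_cohort(n, markers, resp)
  sel <- select_pair_adaboost(ch)
  expect_identical(sel$first_marker, "perfect")
  expect_identical(sel$first_orientation, "pos_NR")
  expect_true(all(sel$weights_round2 >= 0))
  expect_equal(sum(sel$weights_round2), 1, tolerance = 1e-12)
  expect_error(select_pair_adaboost(ch, markers = "perfect"), "2 markers")
})

test_that("two complementary planted markers beat six noise markers, matching a brute-force oracle", {
  # m1 resolves the even-index half, m2 the samples m1 gets wrong
  set.seed(17)
  n <- 40
  resp <- sample(rep(c("R", "NR"), each = n / 2))
  is_nr <- resp == "NR"
  m1 <- ifelse(is_nr, "positive", "negative")
  flip <- sample(which(is_nr), 6)            # m1 errs on 6 NR samples
  m1[flip] <- "negative"
  m2 <- ifelse(seq_len(n) %in% flip, "positive",
               ifelse(runif(n) < 0.5, "positive", "negative"))
  markers <- list(planted1 = m1, planted2 = m2)
  for (j in 1:6) {
    markers[[paste0("noise", j)]] <-
      sample(c("positive", "negative"), n, replace = TRUE)
  }
  ch <- make_cohort(n, markers, resp)
  sel <- select_pair_adaboost(ch)

  # independent oracle: round 1 by direct counting, then the textbook
  # reweighting, then round 2 by direct weighted counting
  stump_err <- function(calls, w) {
    e_nr <- sum(w[(calls == "positive") != is_nr])
    min(e_nr, sum(w) - e_nr)
  }
  w <- rep(1 / n, n)
  errs1 <- vapply(markers, stump_err, numeric(1), w = w)
  first <- names(which.min(errs1))
  e1 <- errs1[[first]]
  pred_nr <- markers[[first]] == "positive"
  if (sum(w[pred_nr != is_nr]) > sum(w[pred_nr == is_nr])) pred_nr <- !pred_nr
  miss <- pred_nr != is_nr
  w2 <- w * exp(0.5 * log((1 - e1) / e1) * miss)
  w2 <- w2 / sum(w2)
  errs2 <- vapply(markers, stump_err, numeric(1), w = w2)
  second <- names(which.min(errs2[setdiff(names(markers), first)]))

  expect_identical(sel$first_marker, first)
  expect_identical(sel$first_marker, "planted1")
  expect_identical(sel$second_marker, second)
  expect_identical(sel$second_marker, "planted2")
  expect_equal(unname(sel$round1_errors), unname(errs1), tolerance = 1e-12)
  expect_equal(unname(sel$round2_errors), unname(errs2), tolerance = 1e-12)
})

test_that("selection is invariant to marker column order", {
  sim <- simulate_cohort(cohort_spec(seed = 23L))
  sel <- select_pair_adaboost(sim$cohort)
  shuffled_markers <- rev(marker_names(sim$cohort))
  sel2 <- select_pair_adaboost(sim$cohort, markers = shuffled_markers)
  expect_identical(sel$first_marker, sel2$first_marker)
  expect_identical(sel$second_marker, sel2$second_marker)
  expect_identical(sel$first_orientation, sel2$first_orientation)
})

test_that("missing marker calls exclude patients and are counted", {
  set.seed(2)
  n <- 30
  resp <- rep(c("R", "NR"), 15)
  markers <- list(a = ifelse(resp == "NR", "positive", "negative"),
                  b = sample(c("positive", "negative"), n, replace = TRUE))
  markers$b[c(3, 7)] <- NA
  ch <- make_cohort(n, markers, resp)
  sel <- select_pair_adaboost(ch)
  expect_equal(sel$n_excluded, 2L)
  expect_error(select_pair_adaboost(
    make_cohort(4, list(a = rep("positive", 4), b = rep("negative", 4)),
                c("R", "R", "NR", "NR"))),
    "constant")
})

test_that("stability is 1 for a dominant pair and reproducible under a fixed seed", {
  spec <- cohort_spec(
    n_patients = 40,
    marker_model = c(list(GDPD3 = c(0.97, 0.03), SPRED1 = c(0.03, 0.97)),
                     default_marker_model()[3:8]),
    seed = 41L)
  sim <- simulate_cohort(spec)
  cfg <- boost_config(n_repeats = 10, n_folds = 10, seed = 7L)
  st <- stability_cv(sim$cohort, cfg = cfg)
  expect_identical(st$reference_pair, c("GDPD3", "SPRED1"))
  expect_equal(st$stability, 1.0)
  expect_equal(st$n_fits, 100L)
  st2 <- stability_cv(sim$cohort, cfg = cfg)
  expect_identical(st$stability, st2$stability)

  # pure-noise markers cannot be this stable
  noise_spec <- cohort_spec(
    n_patients = 40,
    marker_model = list(m1 = c(0.5, 0.5), m2 = c(0.5, 0.5),
                        m3 = c(0.5, 0.5), m4 = c(0.5, 0.5)),
    seed = 19L)
  noise <- simulate_cohort(noise_spec)
  st_noise <- stability_cv(noise$cohort, cfg = cfg)
  expect_lt(st_noise$stability, st$stability)
})
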
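test_that("gamma handles perfect, balanced, and tabulated associations", {
  x <- c(1, 2, 3, 4, 5)
  g <- goodman_kruskal_gamma(x, x)
  expect_equal(g$gamma, 1.0)
  expect_equal(g$discordant, 0)

  # 2x2 rows (low, high) x cols (R, NR) = [[14, 5], [2, 16]]
  strat <- rep(c("low", "high"), c(19, 18))
  resp <- c(rep(c("R", "NR"), c(14, 5)), rep(c("R", "NR"), c(2, 16)))
  g2 <- goodman_kruskal_gamma(factor(strat, levels = c("low", "high")),
                              factor(resp, levels = c("R", "NR")))
  expect_equal(g2$concordant, 14 * 16)
  expect_equal(g2$discordant, 5 * 2)
  expect_equal(g2$gamma, 214 / 234, tolerance = 1e-12)

  # balanced independent table
  xb <- rep(c("lo", "hi"), each = 20)
  yb <- rep(rep(c("R", "NR"), each = 10), 2)
  expect_equal(goodman_kruskal_gamma(xb, yb)$gamma, 0)

  # all pairs tied on one variable: undefined, flagged, no exception
  und <- goodman_kruskal_gamma(rep(1, 5), c(1, 2, 3, 2, 1))
  expect_true(und$undefined)
  expect_true(is.na(und$gamma))
})

test_that("gamma agrees with O(n^2) pair enumeration on random ordinal data", {
  set.seed(29)
  for (i in 1:60) {
    n <- sample(5:25, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    o <- oracle_gamma(x, y)
    g <- goodman_kruskal_gamma(x, y)
    expect_equal(g$concordant, o$C)
    expect_equal(g$discordant, o$D)
    if (!g$undefined) expect_equal(g$gamma, o$gamma, tolerance = 1e-12)
  }
})

test_that("gamma permutation p-value agrees with the asymptotic one on clear effects", {
  set.seed(8)
  x <- rep(1:2, each = 25)
  y <- ifelse(runif(50) < ifelse(x == 2, 0.8, 0.2), 2, 1)
  pa <- goodman_kruskal_gamma(x, y, p_method = "asymptotic")
  pp <- goodman_kruskal_gamma(x, y, p_method = "permutation",
                              n_perm = 4000, seed = 3)
  expect_equal(pa$gamma, pp$gamma)
  expect_lt(pa$p_value, 0.01)
  expect_lt(pp$p_value, 0.01)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  # zero margin: degenerate
  pz <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))
  expect_equal(as.numeric(pz), 1.0)
  expect_true(attr(pz, "degenerate"))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")

  set.seed(37)
  for (i in 1:80) {
    tab <- matrix(rpois(4, sample(2:8, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                 tolerance = 1e-9)
    # symmetric under simultaneous row and column swaps
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(tab[2:1, 2:1]),
                 tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches the hand formula and external reference", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1.0)

  # cross-table [[4,1],[1,4]]: p_o = 0.8, p_e = 0.5, kappa = 0.6
  r1 <- rep(c("x", "y"), each = 5)
  r2 <- c(rep("x", 4), "y", "x", rep("y", 4))
  k <- cohens_kappa(r1, r2)
  expect_equal(k$observed_agreement, 0.8)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.6, tolerance = 1e-12)

  set.seed(41)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    a <- sample(letters[1:3], n, replace = TRUE)
    b <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(cohens_kappa(a, b)$kappa, oracle_kappa(a, b),
                 tolerance = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE)) {
      tab <- table(factor(a, levels = letters[1:3]),
                   factor(b, levels = letters[1:3]))
      expect_equal(cohens_kappa(a, b)$kappa,
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-9)
    }
    # invariant under category relabeling applied to both raters
    relab <- c(a = "z", b = "q", c = "m")
    expect_equal(cohens_kappa(relab[a], relab[b])$kappa,
                 cohens_kappa(a, b)$kappa, tolerance = 1e-12)
  }

  # shuffled rater ~ chance agreement
  set.seed(6)
  big <- sample(letters[1:2], 4000, replace = TRUE)
  expect_lt(abs(cohens_kappa(big, sample(big))$kappa), 0.05)

  kd <- cohens_kappa(rep("a", 4), rep("a", 4))
  expect_equal(kd$kappa, 1.0)
  expect_true(kd$degenerate)
})

test_that("Kruskal-Wallis behaves across degenerate, two-group, and separated cases", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3))), 1.0)
  pd <- kruskal_wallis(list(rep(2, 4), rep(2, 5)))
  expect_equal(as.numeric(pd), 1.0)

  # two groups: equals the normal-approximation Mann-Whitney p
  set.seed(12)
  a <- rnorm(30); b <- rnorm(30, 0.8)
  p_kw <- kruskal_wallis(list(a, b))
  p_mw <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_kw, p_mw, tolerance = 1e-6)

  p3 <- kruskal_wallis(list(rnorm(10), rnorm(10, 3), rnorm(10, 6)))
  expect_lt(p3, 0.001)
  expect_error(kruskal_wallis(list(1:3)), "2")
})

test_that("logistic regression recovers planted odds ratios and flags separation", {
  set.seed(91)
  n <- 2000
  x1 <- runif(n) < 0.5
  x2 <- runif(n) < 0.5
  eta <- -1.4 + log(4) * x1 + log(4) * x2
  resp <- ifelse(runif(n) < plogis(eta), "NR", "R")
  ch <- make_cohort(n, list(M1 = ifelse(x1, "positive", "negative"),
                            M2 = ifelse(x2, "positive", "negative")),
                    resp)
  fit <- logistic_multivariate(ch, list(pred_marker_pos("M1"),
                                        pred_marker_pos("M2")))
  expect_false(fit$separation)
  expect_true(fit$converged)
  est <- fit$coefficients$estimate
  expect_true(all(abs(est - log(4)) < 0.2 * log(4)))
  expect_true(all(fit$coefficients$p_value < 1e-4))

  # null predictor: coefficient near zero, p not small
  x0 <- runif(n) < 0.5
  ch0 <- make_cohort(n, list(M0 = ifelse(x0, "positive", "negative"),
                             MX = sample(c("positive", "negative"), n, TRUE)),
                     sample(c("R", "NR"), n, replace = TRUE))
  fit0 <- logistic_multivariate(ch0, list(pred_marker_pos("M0")))
  # within 4 standard errors of zero (~0.36 at this n)
  expect_lt(abs(fit0$coefficients$estimate[1]),
            4 * fit0$coefficients$std_error[1])

  # predictor identical to outcome: separation flagged, estimates suppressed
  resp_s <- rep(c("R", "NR"), each = 20)
  chs <- make_cohort(40, list(S = ifelse(resp_s == "NR", "positive",
                                         "negative"),
                              T2 = sample(c("positive", "negative"), 40, TRUE)),
                     resp_s)
  fits <- logistic_multivariate(chs, list(pred_marker_pos("S"),
                                          pred_marker_pos("T2")))
  expect_true(fits$separation)
  expect_true(all(is.na(fits$coefficients$estimate)))
})
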
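# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: AUC and gamma enumerate all
# observation pairs, Fisher enumerates the hypergeometric support, kappa is
# recomputed from raw agreement counting, and the tree oracle enumerates
# depth <= 2 topologies on the predictor-pattern cells.

oracle_auc <- function(values, response) {
  a <- values[response == "NR"]
  b <- values[response == "R"]
  tot <- 0
  for (x in a) for (y in b) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(a) * length(b))
}

oracle_gamma <- function(x, y) {
  xi <- as.integer(factor(x, levels = sort(unique(x))))
  yi <- as.integer(factor(y, levels = sort(unique(y))))
  n <- length(xi)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(xi[i] - xi[j]) * sign(yi[i] - yi[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  list(C = C, D = D, gamma = if (C + D == 0) NA_real_ else (C - D) / (C + D))
}

# two-sided Fisher by direct enumeration of all 2x2 tables with the observed
# margins, summing probabilities <= the observed table's
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- vapply(support, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_kappa <- function(r1, r2) {
  r1 <- as.character(r1); r2 <- as.character(r2)
  cats <- unique(c(r1, r2))
  p_o <- mean(r1 == r2)
  p_e <- 0
  for (cat in cats) p_e <- p_e + mean(r1 == cat) * mean(r2 == cat)
  (p_o - p_e) / (1 - p_e)
}

# Oracle for the tree search: works on the <= 8 cells defined by the joint
# predictor pattern; enumerates root/left/right predicate choices directly
# and returns the minimal total Gini (sum over leaves of n * 2p(1-p)).
oracle_tree_min_gini <- function(pv, is_nr) {
  m <- ncol(pv)
  gini_of <- function(split_list) {
    # split_list: list of logical vectors (leaf membership)
    tot <- 0
    for (members in split_list) {
      n_l <- sum(members)
      if (n_l == 0) next
      p <- sum(is_nr[members]) / n_l
      tot <- tot + n_l * 2 * p * (1 - p)
    }
    tot
  }
  best <- Inf
  for (r in seq_len(m)) {
    root <- pv[, r]
    kid_opts <- c(NA, setdiff(seq_len(m), r))
    for (lq in kid_opts) for (rq in kid_opts) {
      left_side <- !root
      right_side <- root
      leaves <- list()
      if (is.na(lq)) {
        leaves <- c(leaves, list(left_side))
      } else {
        leaves <- c(leaves, list(left_side & !pv[, lq]),
                    list(left_side & pv[, lq]))
      }
      if (is.na(rq)) {
        leaves <- c(leaves, list(right_side))
      } else {
        leaves <- c(leaves, list(right_side & !pv[, rq]),
                    list(right_side & pv[, rq]))
      }
      best <- min(best, gini_of(leaves))
    }
  }
  best
}

# quick builder for small cohort tables in tests
make_cohort <- function(n, markers, response, age = NULL, ct = NULL) {
  df <- data.frame(patient_id = sprintf("t%03d", seq_len(n)),
                   age = if (is.null(age)) rep(60, n) else age,
                   cT = if (is.null(ct)) rep(2L, n) else ct,
                   stringsAsFactors = FALSE)
  for (m in names(markers)) df[[m]] <- markers[[m]]
  df$response <- response
  cohort_table(df)
}
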
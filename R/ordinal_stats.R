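#' Goodman-Kruskal gamma for two ordinal variables
#'
#' Rank association from concordant and discordant observation pairs, the
#' statistic used to score how well an ordered risk stratification tracks
#' the ordered outcome. For every pair of observations, the pair is
#' concordant when both variables move in the same direction and discordant
#' when they move in opposite directions; pairs tied on either variable are
#' ignored. gamma = (C - D) / (C + D). The default p-value is the asymptotic
#' two-sided z-test z = gamma * sqrt((C + D) / (n (1 - gamma^2))); for small
#' samples a permutation p-value (label permutations of `y`) is available
#' and recommended.
#'
#' @param x,y equal-length ordinal variables (ordered factors, or values
#'   whose natural sort order is the level ordering).
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"` (default
#'   1e4; all of them contribute to a one-add smoothed p).
#' @param seed seed for the permutation p-value.
#' @return A `gamma_result`: list with `gamma`, `concordant`, `discordant`,
#'   `p_value`, `method`, and `undefined` (TRUE when C + D = 0, in which
#'   case `gamma` and `p_value` are NA).
#' @export
goodman_kruskal_gamma <- function(x, y,
                                  p_method = c("asymptotic", "permutation"),
                                  n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  xi <- as.integer(if (is.factor(x)) x else factor(x, levels = sort(unique(x))))
  yi <- as.integer(if (is.factor(y)) y else factor(y, levels = sort(unique(y))))
  if (anyNA(xi) || anyNA(yi)) stop("missing values not allowed", call. = FALSE)

  cd <- concordance_counts(xi, yi)
  C <- cd[["C"]]; D <- cd[["D"]]
  if (C + D == 0) {
    return(structure(list(gamma = NA_real_, concordant = C, discordant = D,
                          p_value = NA_real_, method = p_method,
                          undefined = TRUE),
                     class = "gamma_result"))
  }
  g <- (C - D) / (C + D)
  n <- length(xi)
  p <- if (p_method == "asymptotic") {
    if (abs(g) >= 1) {
      0   # perfect ordering: z diverges
    } else {
      z <- g * sqrt((C + D) / (n * (1 - g^2)))
      2 * stats::pnorm(-abs(z))
    }
  } else {
    set.seed(seed)
    g_null <- replicate(n_perm, {
      cdp <- concordance_counts(xi, sample(yi))
      if (cdp[["C"]] + cdp[["D"]] == 0) 0
      else (cdp[["C"]] - cdp[["D"]]) / (cdp[["C"]] + cdp[["D"]])
    })
    (1 + sum(abs(g_null) >= abs(g) - 1e-12)) / (n_perm + 1)
  }
  structure(list(gamma = g, concordant = C, discordant = D, p_value = p,
                 method = p_method, undefined = FALSE),
            class = "gamma_result")
}

# Concordant / discordant pair counts from the cross-table (O(r c) cells
# rather than O(n^2) pairs): a cell (i, j) is concordant with every cell
# strictly below-right, discordant with every cell strictly below-left.
concordance_counts <- function(xi, yi) {
  tab <- table(xi, yi)
  r <- nrow(tab); cn <- ncol(tab)
  C <- 0; D <- 0
  for (i in seq_len(r)) for (j in seq_len(cn)) {
    nij <- tab[i, j]
    if (nij == 0) next
    if (i < r && j < cn) C <- C + nij * sum(tab[(i + 1):r, (j + 1):cn])
    if (i < r && j > 1)  D <- D + nij * sum(tab[(i + 1):r, 1:(j - 1)])
  }
  c(C = C, D = D)
}

#' @export
print.gamma_result <- function(x, ...) {
  if (x$undefined) {
    cat("Goodman-Kruskal gamma: undefined (no untied pairs)\n")
  } else {
    cat(sprintf("Goodman-Kruskal gamma = %.4f (C = %d, D = %d), p = %.4g [%s]\n",
                x$gamma, x$concordant, x$discordant, x$p_value, x$method))
  }
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sum of hypergeometric probabilities (margins fixed) of every table no
#' more probable than the observed one — the probability-ordering convention
#' of mainstream statistical software. A table with a zero margin is
#' degenerate: p = 1 with a `"degenerate"` attribute.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with observed
#' agreement p_o and expected agreement p_e from the product of the raters'
#' marginal distributions. When both raters are constant and identical
#' (p_e = 1) kappa is returned as 1 with a `degenerate` flag.
#'
#' @param rater1,rater2 equal-length categorical ratings over a shared
#'   category set.
#' @return A `kappa_result`: list with `kappa`, `observed_agreement`,
#'   `expected_agreement`, `degenerate`.
#' @export
cohens_kappa <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2), length(rater1) >= 1L)
  lev <- sort(unique(c(as.character(rater1), as.character(rater2))))
  r1 <- factor(as.character(rater1), levels = lev)
  r2 <- factor(as.character(rater2), levels = lev)
  tab <- table(r1, r2) / length(r1)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) {
    return(structure(list(kappa = 1, observed_agreement = p_o,
                          expected_agreement = p_e, degenerate = TRUE),
                     class = "kappa_result"))
  }
  structure(list(kappa = (p_o - p_e) / (1 - p_e), observed_agreement = p_o,
                 expected_agreement = p_e, degenerate = FALSE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (observed %.3f, expected %.3f)\n",
              x$kappa, x$observed_agreement, x$expected_agreement))
  invisible(x)
}

#' Kruskal-Wallis test over groups
#'
#' Rank-based H test with tie correction (chi-squared p-value), as used to
#' compare medians across cohorts. All-tied input returns p = 1.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) > 0L))
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) return(structure(1, degenerate = TRUE))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  stats::kruskal.test(vals, g)$p.value
}

#' Multivariable logistic regression of NAC resistance
#'
#' Maximum-likelihood fit of the NR indicator on a set of binary predicates,
#' with Wald p-values and explicit convergence / separation diagnostics.
#' Perfect (or quasi-perfect) separation is detected from degenerate fitted
#' probabilities; when flagged, coefficients are suppressed (NA) because the
#' MLE does not exist.
#'
#' @param cohort a [cohort_table()].
#' @param predictors list of predicates ([pred_marker_pos()] etc.).
#' @return List with `coefficients` (data frame: term, estimate, std_error,
#'   p_value), `converged`, `separation`, `n` (complete cases used).
#' @export
logistic_multivariate <- function(cohort, predictors) {
  pnames <- vapply(predictors, `[[`, character(1), "name")
  pv <- vapply(predictors, eval_predicate, logical(nrow(cohort)),
               cohort = cohort)
  pv <- matrix(pv, ncol = length(predictors), dimnames = list(NULL, pnames))
  df <- data.frame(.nr = as.integer(cohort$response == "NR"), pv)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(predictors) + 2L) {
    stop("too few complete cases for the model", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(.nr ~ ., data = df, family = stats::binomial()))
  mu <- stats::fitted(fit)
  eps <- 1e-8
  separation <- all(mu[df$.nr == 1] > 1 - eps) && all(mu[df$.nr == 0] < eps) ||
    any(abs(stats::coef(fit)[-1L]) > 15)
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1L]
  coefs <- data.frame(term = terms,
                      estimate = sm[-1L, 1L],
                      std_error = sm[-1L, 2L],
                      p_value = sm[-1L, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (separation) coefs[, c("estimate", "std_error", "p_value")] <- NA_real_
  list(coefficients = coefs, converged = fit$converged,
       separation = separation, n = nrow(df))
}
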
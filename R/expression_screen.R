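#' Configuration for the expression target screen
#'
#' Captures the parameters of the discovery screen: the signal-window filter
#' (group mean below `low_threshold` in one response class and above
#' `high_threshold` in the other, MAS 5.0-style arbitrary units), the
#' groupwise p-value cutoff, the permutation-estimated FDR cutoff, and the
#' number of label permutations.
#'
#' @param low_threshold signal units; a gene passes only if one group mean
#'   falls below this (default 300).
#' @param high_threshold signal units; the other group mean must exceed this
#'   (default 500).
#' @param p_cutoff groupwise p-value cutoff (default 0.005).
#' @param fdr_cutoff permutation FDR cutoff (default 0.10).
#' @param n_permutations number of random label permutations (default 200).
#' @param seed integer seed for the permutations.
#' @param test groupwise test: `"wilcoxon"` (two-sided Mann-Whitney, the
#'   default, consistent with the AUC ranking) or `"welch"` (Welch t-test).
#' @return A `screen_config` list.
#' @export
screen_config <- function(low_threshold = 300, high_threshold = 500,
                          p_cutoff = 0.005, fdr_cutoff = 0.10,
                          n_permutations = 200L, seed = 1L,
                          test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  stopifnot(low_threshold < high_threshold,
            p_cutoff > 0, p_cutoff < 1,
            fdr_cutoff > 0, fdr_cutoff < 1)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  structure(list(low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 p_cutoff = p_cutoff, fdr_cutoff = fdr_cutoff,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 test = test),
            class = "screen_config")
}

# Group means per gene; returns a 2-column matrix (mean_R, mean_NR).
group_means <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  r <- x$response == "R"
  if (!any(r) || all(r)) {
    stop("both response classes must be present", call. = FALSE)
  }
  cbind(mean_R = rowMeans(x$signal[, r, drop = FALSE]),
        mean_NR = rowMeans(x$signal[, !r, drop = FALSE]))
}

#' Signal-window filter for large expression changes
#'
#' A gene passes when its mean signal is below `low_threshold` in one
#' response group and above `high_threshold` in the other, in either
#' direction. With the default 300/500 window this is the coarse filter that
#' reduces tens of thousands of probes to a few hundred robustly changed
#' targets before any statistical testing.
#'
#' @param x an [expression_matrix()].
#' @param cfg a [screen_config()].
#' @return Character vector of passing gene ids.
#' @export
filter_by_signal <- function(x, cfg = screen_config()) {
  m <- group_means(x)
  pass <- (m[, "mean_R"] < cfg$low_threshold & m[, "mean_NR"] > cfg$high_threshold) |
          (m[, "mean_NR"] < cfg$low_threshold & m[, "mean_R"] > cfg$high_threshold)
  rownames(x$signal)[pass]
}

#' Per-gene AUC for resistance discrimination
#'
#' Area under the receiver-operator curve of the rule "higher signal implies
#' NAC resistance": the probability that a randomly chosen NR sample has a
#' higher value than a randomly chosen R sample, with ties counted 1/2
#' (midranks). Equals U / (n_R * n_NR) where U is the Mann-Whitney statistic.
#'
#' @param values numeric per-sample signals.
#' @param response per-sample labels (R/NR).
#' @return AUC in \[0, 1\]; values above 0.5 mean higher signal in NR.
#' @export
gene_auc <- function(values, response) {
  resp <- normalize_response(response)
  stopifnot(length(values) == length(resp), !anyNA(resp))
  n_nr <- sum(resp == "NR")
  n_r <- sum(resp == "R")
  if (n_nr == 0L || n_r == 0L) {
    stop("both response classes must be present", call. = FALSE)
  }
  rk <- rank(values)
  u <- sum(rk[resp == "NR"]) - n_nr * (n_nr + 1) / 2
  u / (n_nr * n_r)
}

#' Groupwise p-value for a single gene
#'
#' Two-sided Mann-Whitney test of the signal distribution between R and NR
#' samples (exact when sample sizes are small and values untied, normal
#' approximation with continuity correction otherwise). A Welch t-test is
#' available via `test = "welch"`. Degenerate all-tied input returns p = 1
#' with a `"degenerate"` attribute.
#'
#' @param values numeric per-sample signals.
#' @param response per-sample labels (R/NR); at least 2 samples per class.
#' @param test `"wilcoxon"` or `"welch"`.
#' @return p-value in \[0, 1\].
#' @export
groupwise_pvalue <- function(values, response, test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  resp <- normalize_response(response)
  stopifnot(length(values) == length(resp), !anyNA(resp))
  if (sum(resp == "NR") < 2L || sum(resp == "R") < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    return(structure(1, degenerate = TRUE))
  }
  a <- values[resp == "NR"]
  b <- values[resp == "R"]
  if (test == "welch") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # distinct constants per group: Welch undefined; treat as separated
      return(if (mean(a) == mean(b)) structure(1, degenerate = TRUE) else 0)
    }
    return(stats::t.test(a, b)$p.value)
  }
  suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))$p.value
}

# AUC matrix trick: with R the genes x samples rank matrix (per-gene
# midranks, invariant to label permutation), U for any 0/1 NR indicator v is
# R %*% v - n_nr(n_nr+1)/2 per gene. Used for fast permutation nulls.
rank_matrix <- function(signal) {
  t(apply(signal, 1L, rank))
}

auc_from_ranks <- function(rk, nr_indicator) {
  n_nr <- sum(nr_indicator)
  n_r <- length(nr_indicator) - n_nr
  u <- as.vector(rk %*% nr_indicator) - n_nr * (n_nr + 1) / 2
  u / (n_nr * n_r)
}

#' Permutation-based FDR estimates for screen scores
#'
#' Corrects the per-gene discrimination scores for multiple testing by
#' random label permutation. The score is `|AUC - 0.5|` (direction-free).
#' For a gene with observed score s, the FDR estimate is the average over
#' permutations of the number of null scores >= s, divided by the number of
#' observed scores >= s, monotone-corrected (running minimum from the most
#' to the least extreme score) so that estimates are non-increasing in the
#' score. Estimates are capped at 1.
#'
#' @param x an [expression_matrix()].
#' @param cfg a [screen_config()]; `cfg$n_permutations` label permutations
#'   are drawn uniformly at random under `cfg$seed`.
#' @param genes optional subset of gene ids over which to estimate (e.g. the
#'   signal-filter survivors); defaults to all genes.
#' @return Named numeric vector of per-gene FDR estimates over `genes`.
#' @export
permutation_fdr <- function(x, cfg = screen_config(), genes = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(genes)) genes <- rownames(x$signal)
  if (length(genes) == 0L) return(stats::setNames(numeric(0), character(0)))
  signal <- x$signal[genes, , drop = FALSE]
  nr <- as.numeric(x$response == "NR")
  if (sum(nr) == 0 || sum(nr) == length(nr)) {
    stop("both response classes must be present", call. = FALSE)
  }
  rk <- rank_matrix(signal)
  obs <- abs(auc_from_ranks(rk, nr) - 0.5)

  set.seed(cfg$seed)
  perm_ind <- replicate(cfg$n_permutations, sample(nr))
  null_scores <- abs(sweep(rk %*% perm_ind, 2,
                           sum(nr) * (sum(nr) + 1) / 2) /
                       (sum(nr) * (length(nr) - sum(nr))) - 0.5)

  # tail counts: for each observed score s, #observed >= s and mean #null >= s
  ord <- order(obs, decreasing = TRUE)
  n_obs_ge <- rank(-obs, ties.method = "max")
  asc <- sort(as.vector(null_scores))
  # scores are midrank AUCs, spaced >= 1/(2 n_R n_NR); 1e-9 guards ties only
  n_null_ge <- length(asc) - findInterval(obs - 1e-9, asc)
  fdr_raw <- (n_null_ge / cfg$n_permutations) / pmax(1, n_obs_ge)

  # monotone correction: non-increasing in score
  fdr_sorted <- fdr_raw[ord]
  fdr_mono <- rev(cummin(rev(fdr_sorted)))
  fdr <- numeric(length(obs))
  fdr[ord] <- pmin(1, fdr_mono)
  stats::setNames(fdr, genes)
}

#' Run the full expression target screen
#'
#' Applies the signal-window filter, computes AUC and the groupwise p-value
#' for the survivors, estimates permutation FDR over the survivors, and
#' selects genes meeting all three criteria (filter pass, p < `p_cutoff`,
#' FDR < `fdr_cutoff`). AUC ranking ties are broken by smaller p-value, then
#' lexicographic gene id.
#'
#' @param x an [expression_matrix()].
#' @param cfg a [screen_config()].
#' @return A `screen_result`: a data frame with one row per gene (`gene_id`,
#'   `mean_R`, `mean_NR`, `auc`, `p_value`, `fdr`, `passed_filter`,
#'   `selected`; statistics are NA for genes failing the filter), ordered by
#'   decreasing discrimination among survivors, with attributes `n_selected`
#'   and `signature_fdr` (mean FDR over the selected set, the
#'   signature-level summary).
#' @export
screen_targets <- function(x, cfg = screen_config()) {
  m <- group_means(x)
  gene_ids <- rownames(x$signal)
  survivors <- filter_by_signal(x, cfg)
  res <- data.frame(gene_id = gene_ids,
                    mean_R = m[, "mean_R"], mean_NR = m[, "mean_NR"],
                    auc = NA_real_, p_value = NA_real_, fdr = NA_real_,
                    passed_filter = gene_ids %in% survivors,
                    selected = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (length(survivors) > 0L) {
    idx <- match(survivors, gene_ids)
    res$auc[idx] <- apply(x$signal[survivors, , drop = FALSE], 1L,
                          gene_auc, response = x$response)
    res$p_value[idx] <- apply(x$signal[survivors, , drop = FALSE], 1L,
                              groupwise_pvalue, response = x$response,
                              test = cfg$test)
    res$fdr[idx] <- permutation_fdr(x, cfg, genes = survivors)
    res$selected <- res$passed_filter &
      !is.na(res$p_value) & res$p_value < cfg$p_cutoff &
      !is.na(res$fdr) & res$fdr < cfg$fdr_cutoff
  }
  score <- abs(res$auc - 0.5)
  ord <- order(!res$passed_filter, -ifelse(is.na(score), -Inf, score),
               ifelse(is.na(res$p_value), Inf, res$p_value), res$gene_id,
               method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  sel_fdr <- res$fdr[res$selected]
  structure(res, n_selected = sum(res$selected),
            signature_fdr = if (length(sel_fdr)) mean(sel_fdr) else NA_real_,
            config = cfg, class = c("screen_result", "data.frame"))
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d genes, %d passed filter, %d selected\n",
              nrow(x), sum(x$passed_filter), attr(x, "n_selected")))
  if (attr(x, "n_selected") > 0) {
    cat(sprintf("signature-level FDR (mean over selected): %.3f\n",
                attr(x, "signature_fdr")))
  }
  NextMethod()
  invisible(x)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (handles ties exactly); used when choose(n, n_a) is small.
mw_exact_perm_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  n_a <- length(a)
  rk <- rank(vals)
  mu <- n_a * (n - n_a) / 2
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  u_all <- colSums(matrix(rk[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

#' Compare two collections of univariate AUCs
#'
#' Two-sided Mann-Whitney comparison of two sets of per-gene AUCs (e.g. a
#' new signature versus a previously reported one), with the medians of
#' both. Small inputs use an exact permutation enumeration (valid under
#' ties); larger ones the usual Mann-Whitney test.
#'
#' @param aucs_a,aucs_b non-empty numeric vectors of AUCs.
#' @return List with `median_a`, `median_b`, `p_value`.
#' @export
compare_signature_aucs <- function(aucs_a, aucs_b) {
  if (length(aucs_a) == 0L || length(aucs_b) == 0L) {
    stop("both AUC collections must be non-empty", call. = FALSE)
  }
  n <- length(aucs_a) + length(aucs_b)
  p <- if (choose(n, length(aucs_a)) <= 1e5) {
    mw_exact_perm_p(aucs_a, aucs_b)
  } else {
    suppressWarnings(stats::wilcox.test(aucs_a, aucs_b,
                                        alternative = "two.sided"))$p.value
  }
  list(median_a = stats::median(aucs_a), median_b = stats::median(aucs_b),
       p_value = p)
}
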
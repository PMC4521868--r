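#' Configuration for boosting-based marker-pair selection
#'
#' @param n_repeats number of repeated cross-validation rounds (default 100).
#' @param n_folds folds per round (default 10).
#' @param seed integer seed for fold assignment.
#' @param epsilon_clip weighted errors are clipped to
#'   `[epsilon_clip, 1 - epsilon_clip]` before the boosting weight update so
#'   a perfect stump does not produce an infinite vote.
#' @return A `boost_config` list.
#' @export
boost_config <- function(n_repeats = 100L, n_folds = 10L, seed = 1L,
                         epsilon_clip = 1e-6) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L,
            epsilon_clip > 0, epsilon_clip < 0.5)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 epsilon_clip = epsilon_clip),
            class = "boost_config")
}

#' Binarize an immunohistochemistry score
#'
#' Standard TMA scoring rule: a sample is called positive when more than 10%
#' of tumor cells show at least moderate staining (intensity 2 on the 0-3
#' scale); anything weaker or less extensive is negative.
#'
#' @param percent_stained percent of cells stained, in \[0, 100\].
#' @param intensity staining intensity, integer 0-3.
#' @return Factor with levels `negative`, `positive` (vectorized).
#' @export
binarize_ihc <- function(percent_stained, intensity) {
  if (any(percent_stained < 0 | percent_stained > 100, na.rm = TRUE)) {
    stop("percent_stained must be in [0, 100]", call. = FALSE)
  }
  if (any(!intensity %in% 0:3, na.rm = TRUE)) {
    stop("intensity must be an integer in 0..3", call. = FALSE)
  }
  pos <- percent_stained > 10 & intensity >= 2
  factor(ifelse(pos, "positive", "negative"),
         levels = c("negative", "positive"))
}

# Predicted NR indicator for a marker call under an orientation.
# "pos_NR": positive call predicts resistance; "pos_R": positive predicts
# response.
stump_predict_nr <- function(calls, orientation) {
  pos <- calls == "positive"
  if (orientation == "pos_NR") pos else !pos
}

#' Weighted misclassification error of a one-marker decision stump
#'
#' Error of the rule "predict NR iff the marker call matches `orientation`"
#' under sample weights. With `orientation` omitted, both orientations are
#' evaluated and the better one returned.
#'
#' @param calls binary marker calls (`positive`/`negative`).
#' @param response R/NR labels.
#' @param weights nonnegative sample weights summing to 1; default equal.
#' @param orientation `"pos_NR"` (positive call predicts resistance),
#'   `"pos_R"` (positive call predicts response), or NULL to pick the
#'   orientation with the smaller error.
#' @return Weighted error in \[0, 1\], with attributes `orientation` and
#'   `misclassified` (logical vector).
#' @export
weighted_stump_error <- function(calls, response, weights = NULL,
                                 orientation = NULL) {
  resp <- normalize_response(response)
  calls <- normalize_binary_call(calls)
  stopifnot(length(calls) == length(resp), !anyNA(resp), !anyNA(calls))
  n <- length(resp)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  weights <- weights / sum(weights)
  is_nr <- resp == "NR"
  one <- function(o) {
    miss <- stump_predict_nr(calls, o) != is_nr
    structure(sum(weights[miss]), orientation = o, misclassified = miss)
  }
  if (!is.null(orientation)) {
    orientation <- match.arg(orientation, c("pos_NR", "pos_R"))
    return(one(orientation))
  }
  e1 <- one("pos_NR")
  e2 <- one("pos_R")
  if (e1 <= e2) e1 else e2
}

# Marker call matrix (patients x markers, factors) from a cohort, restricted
# to complete cases over the candidate markers; returns list(calls, resp,
# n_excluded).
marker_call_frame <- function(cohort, markers) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(markers)) markers <- marker_names(cohort)
  absent <- setdiff(markers, marker_names(cohort))
  if (length(absent) > 0L) {
    stop("unknown marker(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (length(markers) < 2L) stop("need at least 2 markers", call. = FALSE)
  calls <- as.data.frame(cohort)[markers]
  complete <- stats::complete.cases(calls)
  list(calls = calls[complete, , drop = FALSE],
       resp = cohort$response[complete],
       markers = markers,
       n_excluded = sum(!complete))
}

#' Select the best marker pair by two-round adaptive boosting
#'
#' Implements the two-round AdaBoost selection over one-marker decision
#' stumps. Round 1: all samples weighted equally; every candidate marker is
#' scored by its best-orientation weighted misclassification error and the
#' minimizer is selected. Its error e1 (clipped away from 0 and 1) sets the
#' stump vote a1 = log((1 - e1) / e1) / 2, and samples the first stump
#' misclassified are up-weighted by exp(a1) and the weights renormalized.
#' Round 2: every remaining marker is rescored under the new weights and the
#' minimizer becomes the second marker. Ties are broken by the smaller
#' round-1 error, then lexicographic marker name. Patients with a missing
#' call for any candidate marker are excluded and counted.
#'
#' @param cohort a [cohort_table()].
#' @param markers candidate marker names; default all cohort markers.
#' @param cfg a [boost_config()] (only `epsilon_clip` is used here).
#' @return A `pair_selection`: list with `first_marker`,
#'   `first_orientation`, `second_marker`, `second_orientation`,
#'   `round1_errors` and `round2_errors` (named vectors over candidates),
#'   `alpha1`, and `n_excluded`.
#' @export
select_pair_adaboost <- function(cohort, markers = NULL,
                                 cfg = boost_config()) {
  mf <- marker_call_frame(cohort, markers)
  select_pair_core(mf$calls, mf$resp, cfg, n_excluded = mf$n_excluded)
}

# Core two-round selection on a calls data frame + response factor.
select_pair_core <- function(calls, resp, cfg, n_excluded = 0L) {
  markers <- names(calls)
  if (length(unique(resp)) < 2L) {
    stop("both response classes must be present", call. = FALSE)
  }
  constant <- vapply(calls, function(v) length(unique(v)) == 1L, logical(1))
  if (all(constant)) stop("all candidate markers are constant", call. = FALSE)
  n <- length(resp)
  w <- rep(1 / n, n)

  score_all <- function(weights) {
    errs <- lapply(calls, weighted_stump_error, response = resp,
                   weights = weights)
    list(err = vapply(errs, as.numeric, numeric(1)),
         orient = vapply(errs, attr, character(1), "orientation"),
         miss = lapply(errs, attr, "misclassified"))
  }

  r1 <- score_all(w)
  ord1 <- order(r1$err, markers, method = "radix")
  first <- markers[ord1[1L]]

  e1 <- min(max(r1$err[[first]], cfg$epsilon_clip), 1 - cfg$epsilon_clip)
  alpha1 <- 0.5 * log((1 - e1) / e1)
  w2 <- w * exp(alpha1 * as.numeric(r1$miss[[first]]))
  w2 <- w2 / sum(w2)

  r2 <- score_all(w2)
  rest <- setdiff(markers, first)
  # ties on round-2 error broken by smaller round-1 error, then name
  ord2 <- order(r2$err[rest], r1$err[rest], rest, method = "radix")
  second <- rest[ord2[1L]]

  structure(list(first_marker = first,
                 first_orientation = r1$orient[[first]],
                 second_marker = second,
                 second_orientation = r2$orient[[second]],
                 round1_errors = r1$err,
                 round2_errors = r2$err,
                 alpha1 = alpha1,
                 weights_round2 = w2,
                 n_excluded = n_excluded),
            class = "pair_selection")
}

#' @export
print.pair_selection <- function(x, ...) {
  o <- c(pos_NR = "positive -> NR", pos_R = "positive -> R")
  cat(sprintf("pair_selection: %s (%s, round-1 error %.3f) + %s (%s, round-2 error %.3f)\n",
              x$first_marker, o[[x$first_orientation]],
              x$round1_errors[[x$first_marker]],
              x$second_marker, o[[x$second_orientation]],
              x$round2_errors[[x$second_marker]]))
  if (x$n_excluded > 0) {
    cat(sprintf("%d patient(s) excluded for missing marker calls\n",
                x$n_excluded))
  }
  invisible(x)
}

# Stratified fold assignment: within each response class, samples are
# shuffled and dealt round-robin into n_folds folds.
stratified_folds <- function(resp, n_folds) {
  fold <- integer(length(resp))
  for (cls in levels(resp)) {
    idx <- which(resp == cls)
    if (length(idx) < n_folds && length(idx) < 2L) {
      stop("a response class has too few samples for stratified folds",
           call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validation stability of the selected marker pair
#'
#' Quantifies how reproducible the two-round boosting selection is under
#' perturbation of the cohort: over `n_repeats` random stratified `n_folds`
#' partitions, the selection is refit on each training fold (the cohort
#' minus one fold) and the stability is the fraction of all
#' `n_repeats * n_folds` fits whose unordered selected pair equals the
#' full-data pair.
#'
#' @param cohort a [cohort_table()].
#' @param markers candidate marker names; default all cohort markers.
#' @param cfg a [boost_config()].
#' @return List with `stability` (proportion in \[0, 1\]),
#'   `reference_pair` (sorted character pair from the full data), `n_fits`,
#'   and `pair_counts` (table of selected pairs across fits).
#' @export
stability_cv <- function(cohort, markers = NULL, cfg = boost_config()) {
  mf <- marker_call_frame(cohort, markers)
  n <- length(mf$resp)
  if (n < cfg$n_folds) stop("need n >= n_folds", call. = FALSE)
  full <- select_pair_core(mf$calls, mf$resp, cfg)
  ref <- sort(c(full$first_marker, full$second_marker))

  set.seed(cfg$seed)
  pairs <- character(0)
  for (rep_i in seq_len(cfg$n_repeats)) {
    fold <- stratified_folds(mf$resp, cfg$n_folds)
    for (f in seq_len(cfg$n_folds)) {
      train <- fold != f
      fit <- select_pair_core(mf$calls[train, , drop = FALSE],
                              mf$resp[train], cfg)
      pairs <- c(pairs,
                 paste(sort(c(fit$first_marker, fit$second_marker)),
                       collapse = "+"))
    }
  }
  list(stability = mean(pairs == paste(ref, collapse = "+")),
       reference_pair = ref,
       n_fits = length(pairs),
       pair_counts = sort(table(pairs), decreasing = TRUE))
}
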
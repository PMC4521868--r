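#' Configuration for the clinical risk predicates
#'
#' @param age_cutoff years; age strictly above this is a clinical risk
#'   factor (default 60).
#' @param stage_cutoff ordinal clinical T stage; stage strictly above this
#'   is a risk factor (default 2, i.e. > cT2).
#' @return A `tree_config` list.
#' @export
tree_config <- function(age_cutoff = 60, stage_cutoff = 2) {
  stopifnot(age_cutoff > 0, stage_cutoff > 0)
  structure(list(age_cutoff = age_cutoff, stage_cutoff = stage_cutoff),
            class = "tree_config")
}

#' Three-tier clinical risk stratification
#'
#' Counts the two clinical risk factors for NAC resistance — age above the
#' cutoff and clinical stage above the cutoff — and assigns each patient to
#' an ordered tier: `low` (no factor), `intermediate` (exactly one), `high`
#' (both). Patients missing age or stage get `NA` and are counted in the
#' `"n_missing"` attribute.
#'
#' @param cohort a [cohort_table()] (or data frame with `age` and `cT`).
#' @param cfg a [tree_config()].
#' @return Ordered factor (`low` < `intermediate` < `high`), one per
#'   patient, with attribute `n_missing`.
#' @export
clinical_stratify <- function(cohort, cfg = tree_config()) {
  age_rf <- cohort$age > cfg$age_cutoff
  stage_rf <- cohort$cT > cfg$stage_cutoff
  n_rf <- as.integer(age_rf) + as.integer(stage_rf)
  out <- factor(c("low", "intermediate", "high")[n_rf + 1L],
                levels = c("low", "intermediate", "high"), ordered = TRUE)
  structure(out, n_missing = sum(is.na(n_rf)))
}

# --- predicate objects -------------------------------------------------------
# A predicate is a small spec evaluable on any cohort: list(name, desc, type,
# ...params). Kept data-only so fitted models serialize to JSON.

eval_predicate <- function(pred, cohort) {
  switch(pred$type,
    marker_pos = {
      if (!pred$marker %in% names(cohort)) {
        stop("predictor field not in cohort: ", pred$marker, call. = FALSE)
      }
      cohort[[pred$marker]] == "positive"
    },
    age_gt = cohort$age > pred$cutoff,
    stage_gt = cohort$cT > pred$cutoff,
    clinical_low = cohort$age <= pred$age_cutoff &
                   cohort$cT <= pred$stage_cutoff,
    stop("unknown predicate type: ", pred$type, call. = FALSE)
  )
}

#' Predicate constructors for stratification trees
#'
#' Build the named binary predicates the trees split on. Predicates are
#' plain data (no closures) so fitted models can be serialized and applied
#' to new cohorts.
#'
#' @param marker marker column name.
#' @param cutoff threshold (years for age, ordinal stage for cT).
#' @param cfg a [tree_config()] for the composite clinical-low-risk
#'   predicate (age <= cutoff and cT <= cutoff).
#' @param name predicate name; defaults shown below.
#' @return A predicate list usable in [fit_tree()].
#' @export
pred_marker_pos <- function(marker, name = paste0(marker, "_pos")) {
  list(name = name, desc = paste0(marker, " IHC positive"),
       type = "marker_pos", marker = marker)
}

#' @rdname pred_marker_pos
#' @export
pred_age_gt <- function(cutoff = 60, name = paste0("age_gt_", cutoff)) {
  list(name = name, desc = paste0("age > ", cutoff, " years"),
       type = "age_gt", cutoff = cutoff)
}

#' @rdname pred_marker_pos
#' @export
pred_stage_gt <- function(cutoff = 2, name = paste0("stage_gt_cT", cutoff)) {
  list(name = name, desc = paste0("clinical stage > cT", cutoff),
       type = "stage_gt", cutoff = cutoff)
}

#' @rdname pred_marker_pos
#' @export
pred_clinical_low <- function(cfg = tree_config(), name = "clinical_low") {
  list(name = name,
       desc = sprintf("clinical low risk (age <= %g and cT <= %g)",
                      cfg$age_cutoff, cfg$stage_cutoff),
       type = "clinical_low", age_cutoff = cfg$age_cutoff,
       stage_cutoff = cfg$stage_cutoff)
}

# Locale-independent lexicographic comparison (radix / C ordering), so
# tie-breaking is identical on every system.
key_lt <- function(a, b) {
  a != b && order(c(a, b), method = "radix")[1L] == 1L
}

# Weighted Gini impurity of leaves: sum over leaves of n_l * 2 p_l (1 - p_l).
gini_total <- function(leaf_ids, is_nr) {
  tot <- 0
  for (l in unique(leaf_ids)) {
    in_l <- leaf_ids == l
    n_l <- sum(in_l)
    p <- sum(is_nr[in_l]) / n_l
    tot <- tot + n_l * 2 * p * (1 - p)
  }
  tot
}

# Enumerate all depth <= 2 binary tree topologies over predicate indices:
# root r, optional left child split lq (on !r side FALSE branch) and right
# child split rq. Encoded as c(root, left or NA, right or NA).
tree_topologies <- function(n_pred) {
  out <- list()
  for (r in seq_len(n_pred)) {
    others <- setdiff(seq_len(n_pred), r)
    kids <- c(NA_integer_, others)
    for (lq in kids) for (rq in kids) {
      out[[length(out) + 1L]] <- c(r, lq, rq)
    }
  }
  out
}

# Leaf id per patient for a topology given the predicate value matrix
# (logical, patients x predicates). Leaves: root FALSE side 1/2, TRUE side
# 3/4 (child-split FALSE/TRUE; unsplit sides collapse to one leaf).
topology_leaves <- function(topo, pv) {
  root <- pv[, topo[1L]]
  leaf <- integer(nrow(pv))
  if (is.na(topo[2L])) {
    leaf[!root] <- 1L
  } else {
    leaf[!root] <- ifelse(pv[!root, topo[2L]], 2L, 1L)
  }
  if (is.na(topo[3L])) {
    leaf[root] <- 3L
  } else {
    leaf[root] <- ifelse(pv[root, topo[3L]], 4L, 3L)
  }
  leaf
}

#' Fit a risk-stratification tree by exhaustive search
#'
#' Fits a binary classification tree of depth at most 2 over a small set of
#' binary predicates (at most 4; the intended use is 2-3) by exhaustively
#' enumerating every topology — each choice of root predicate and optional
#' distinct child predicates on either side — and choosing the one that
#' minimizes the total Gini impurity over leaves. Ties are broken by fewer
#' internal nodes, then by the lexicographic sequence of predicate names.
#' Leaves are then merged into `n_strata` ordered strata by ascending leaf
#' NR rate: among contiguous groupings in rate order, the one minimizing the
#' merged weighted Gini is kept. Patients with a missing value for any
#' predicate are excluded (complete-case) and counted.
#'
#' @param cohort a [cohort_table()].
#' @param predicates list of predicates from [pred_marker_pos()] and
#'   friends.
#' @param n_strata number of ordered strata; `NULL` keeps every distinct
#'   leaf as its own stratum.
#' @return A `strat_model`: list with `topology` (predicate names at root /
#'   left child / right child), `predicates`, `leaf_strata` (leaf id ->
#'   stratum label), `strata` (data frame: label, n, n_NR, nr_rate, fitted on
#'   the training cohort), `gini`, `n_excluded`.
#' @export
fit_tree <- function(cohort, predicates, n_strata = 2L) {
  stopifnot(length(predicates) >= 1L, length(predicates) <= 4L)
  pnames <- vapply(predicates, `[[`, character(1), "name")
  if (anyDuplicated(pnames)) stop("duplicate predicate names", call. = FALSE)
  pv <- vapply(predicates, eval_predicate, logical(nrow(cohort)),
               cohort = cohort)
  pv <- matrix(pv, ncol = length(predicates),
               dimnames = list(NULL, pnames))
  complete <- stats::complete.cases(pv) & !is.na(cohort$response)
  n_excluded <- sum(!complete)
  pv <- pv[complete, , drop = FALSE]
  is_nr <- cohort$response[complete] == "NR"
  if (nrow(pv) == 0L) stop("no complete cases", call. = FALSE)

  topos <- tree_topologies(length(predicates))
  best <- NULL
  for (topo in topos) {
    leaf <- topology_leaves(topo, pv)
    occupied <- sort(unique(leaf))
    g <- gini_total(leaf, is_nr)
    n_nodes <- 1L + sum(!is.na(topo[2:3]))
    key <- paste(pnames[stats::na.omit(topo)], collapse = "|")
    cand <- list(topo = topo, leaf = leaf, gini = g, n_nodes = n_nodes,
                 n_leaves = length(occupied), key = key)
    if (is.null(best) ||
        g < best$gini - 1e-12 ||
        (abs(g - best$gini) <= 1e-12 &&
         (n_nodes < best$n_nodes ||
          (n_nodes == best$n_nodes && key_lt(key, best$key))))) {
      best <- cand
    }
  }

  # leaf summary ordered by NR rate
  leaves <- sort(unique(best$leaf))
  leaf_n <- vapply(leaves, function(l) sum(best$leaf == l), numeric(1))
  leaf_nr <- vapply(leaves, function(l) sum(is_nr[best$leaf == l]), numeric(1))
  rate_ord <- order(leaf_nr / leaf_n, leaves)
  leaves <- leaves[rate_ord]; leaf_n <- leaf_n[rate_ord]
  leaf_nr <- leaf_nr[rate_ord]
  L <- length(leaves)
  if (is.null(n_strata)) n_strata <- L
  if (n_strata > L) {
    stop("n_strata (", n_strata, ") exceeds the number of occupied leaves (",
         L, ")", call. = FALSE)
  }

  # merge rate-ordered leaves into n_strata contiguous groups minimizing
  # merged weighted Gini; boundaries enumerated exhaustively (<= C(3, k-1))
  grouping <- best_contiguous_grouping(leaf_n, leaf_nr, n_strata)
  labels <- strata_labels(n_strata)
  leaf_strata <- stats::setNames(labels[grouping], as.character(leaves))

  strata <- data.frame(
    stratum = labels,
    n = as.integer(tapply(leaf_n, grouping, sum)),
    n_NR = as.integer(tapply(leaf_nr, grouping, sum)),
    stringsAsFactors = FALSE)
  strata$nr_rate <- strata$n_NR / strata$n
  # strata are built in ascending leaf-rate order; assert monotonicity
  stopifnot(!is.unsorted(strata$nr_rate))

  structure(list(
    topology = list(root = pnames[best$topo[1L]],
                    left = if (is.na(best$topo[2L])) NULL else pnames[best$topo[2L]],
                    right = if (is.na(best$topo[3L])) NULL else pnames[best$topo[3L]]),
    predicates = predicates,
    topo_idx = best$topo,
    leaf_strata = leaf_strata,
    strata = strata,
    gini = best$gini,
    n_excluded = n_excluded
  ), class = "strat_model")
}

strata_labels <- function(k) {
  if (k == 2L) c("low", "high")
  else if (k == 3L) c("low", "intermediate", "high")
  else sprintf("stratum_%d", seq_len(k))
}

# All ways to cut a rate-ordered leaf sequence into k contiguous groups;
# returns the group index per leaf for the cut minimizing merged Gini.
best_contiguous_grouping <- function(leaf_n, leaf_nr, k) {
  L <- length(leaf_n)
  if (k == L) return(seq_len(L))
  cuts <- utils::combn(L - 1L, k - 1L, simplify = FALSE)
  best_g <- Inf; best_grp <- NULL
  for (cut in cuts) {
    grp <- findInterval(seq_len(L), c(0, cut) + 1L)
    g <- 0
    for (s in seq_len(k)) {
      n_s <- sum(leaf_n[grp == s]); nr_s <- sum(leaf_nr[grp == s])
      p <- nr_s / n_s
      g <- g + n_s * 2 * p * (1 - p)
    }
    if (g < best_g - 1e-12) { best_g <- g; best_grp <- grp }
  }
  best_grp
}

#' @export
print.strat_model <- function(x, ...) {
  cat("strat_model (exhaustive Gini search, depth <= 2)\n")
  cat("root:", x$topology$root)
  if (!is.null(x$topology$left)) cat(" | left child:", x$topology$left)
  if (!is.null(x$topology$right)) cat(" | right child:", x$topology$right)
  cat("\nfitted strata:\n")
  print(x$strata)
  if (x$n_excluded > 0) {
    cat(x$n_excluded, "patient(s) excluded for missing predictor values\n")
  }
  invisible(x)
}

#' Apply a fitted stratification model to a cohort
#'
#' Evaluates the model's predicates on the cohort, routes every complete
#' case to its leaf and stratum, and recomputes the per-stratum counts and
#' NR rates on this cohort. The n-weighted mean of the stratum NR rates
#' equals the cohort NR rate over complete cases (conservation).
#'
#' @param model a `strat_model` from [fit_tree()].
#' @param cohort a [cohort_table()].
#' @return List with `assignments` (data frame: patient_id, stratum) and
#'   `strata` (data frame: stratum, n, n_NR, nr_rate), plus `n_excluded`.
#' @export
apply_model <- function(model, cohort) {
  stopifnot(inherits(model, "strat_model"))
  pnames <- vapply(model$predicates, `[[`, character(1), "name")
  pv <- vapply(model$predicates, eval_predicate, logical(nrow(cohort)),
               cohort = cohort)
  pv <- matrix(pv, ncol = length(model$predicates),
               dimnames = list(NULL, pnames))
  complete <- stats::complete.cases(pv) & !is.na(cohort$response)
  leaf <- topology_leaves(model$topo_idx, pv[complete, , drop = FALSE])
  unknown <- setdiff(as.character(unique(leaf)), names(model$leaf_strata))
  if (length(unknown) > 0L) {
    # a leaf unoccupied at fit time: route to the stratum of its sibling
    # side by nearest fitted leaf id
    fitted_ids <- as.integer(names(model$leaf_strata))
    for (u in as.integer(unknown)) {
      nearest <- fitted_ids[which.min(abs(fitted_ids - u))]
      model$leaf_strata[as.character(u)] <-
        model$leaf_strata[as.character(nearest)]
    }
  }
  stratum <- unname(model$leaf_strata[as.character(leaf)])
  labels <- unique(model$strata$stratum)
  stratum <- factor(stratum, levels = labels, ordered = TRUE)
  is_nr <- cohort$response[complete] == "NR"
  strata <- data.frame(stratum = labels,
                       n = as.integer(table(stratum)[labels]),
                       n_NR = vapply(labels, function(s)
                         sum(is_nr[stratum == s]), integer(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  strata$nr_rate <- ifelse(strata$n > 0, strata$n_NR / strata$n, NA_real_)
  list(assignments = data.frame(patient_id = cohort$patient_id[complete],
                                stratum = stratum,
                                stringsAsFactors = FALSE),
       strata = strata,
       n_excluded = sum(!complete))
}

#' Combined clinical + IHC two-stratum model
#'
#' Fits the combined risk model over the three binary predicates
#' clinical-low-risk (age and stage both at or below their cutoffs), GDPD3
#' IHC positivity, and SPRED1 IHC positivity, merged to two ordered strata —
#' the model that splits a cohort into a chemo-sensitive and a
#' chemo-resistant half.
#'
#' @param cohort a [cohort_table()] with GDPD3 and SPRED1 calls.
#' @param cfg a [tree_config()].
#' @param gdpd3,spred1 marker column names.
#' @return A `strat_model` with two strata.
#' @export
combine_models <- function(cohort, cfg = tree_config(), gdpd3 = "GDPD3",
                           spred1 = "SPRED1") {
  preds <- list(pred_clinical_low(cfg),
                pred_marker_pos(gdpd3),
                pred_marker_pos(spred1))
  fit_tree(cohort, preds, n_strata = 2L)
}

#' Two-marker IHC stratification model
#'
#' Fits the tree over GDPD3 and SPRED1 positivity alone. The stratum count
#' is data-driven (every occupied leaf becomes a stratum, ordered by NR
#' rate) unless `n_strata` is given.
#'
#' @inheritParams combine_models
#' @param n_strata number of strata, or `NULL` (default) for one per leaf.
#' @return A `strat_model`.
#' @export
ihc_model <- function(cohort, gdpd3 = "GDPD3", spred1 = "SPRED1",
                      n_strata = NULL) {
  fit_tree(cohort, list(pred_marker_pos(gdpd3), pred_marker_pos(spred1)),
           n_strata = n_strata)
}
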
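#' Cluster samples on a screened gene signature
#'
#' Groups samples by their expression profile over a selected gene set, the
#' way discovery heatmaps are usually built: each gene row is standardized
#' to zero mean and unit variance, pairwise sample distance is one minus the
#' Pearson correlation over the selected genes, and the dendrogram is grown
#' by average-linkage agglomeration and cut into `k` groups. Groups are
#' relabeled by their observed NAC non-response (NR) rate so the letters
#' carry reproducible semantics regardless of dendrogram order: `A` is the
#' most chemo-responsive group (lowest NR rate), `B` the most resistant
#' (highest), and any intermediate groups take `C`, `D`, ... in ascending
#' rate order between them.
#'
#' @param x an [expression_matrix()].
#' @param genes gene ids to cluster on (subset of the matrix's genes).
#' @param k number of groups (2 <= k <= number of samples).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param metric `"correlation"` (1 - Pearson, the default) or
#'   `"euclidean"` on the standardized rows.
#' @return A `cluster_assignment`: list with `groups` (named character
#'   vector, sample id -> group label), `dendrogram` (the hclust tree),
#'   `group_rates` (data frame of per-group n, NR count and NR rate) and
#'   `genes_used` (selected genes remaining after dropping constant rows).
#' @export
cluster_samples <- function(x, genes, k, linkage = "average",
                            metric = c("correlation", "euclidean")) {
  stopifnot(inherits(x, "expression_matrix"))
  metric <- match.arg(metric)
  missing_genes <- setdiff(genes, rownames(x$signal))
  if (length(missing_genes) > 0L) {
    stop("genes not in matrix: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  n <- ncol(x$signal)
  if (k < 2L || k > n) stop("k must be in [2, n_samples]", call. = FALSE)

  sig <- x$signal[genes, , drop = FALSE]
  sds <- apply(sig, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene row(s) dropped before clustering")
    sig <- sig[sds > 0, , drop = FALSE]
    if (nrow(sig) == 0L) {
      stop("degenerate input: all selected gene rows are constant",
           call. = FALSE)
    }
  }
  z <- t(scale(t(sig)))   # per-gene standardization

  if (metric == "correlation") {
    if (nrow(z) < 2L) {
      stop("correlation distance needs >= 2 non-constant genes",
           call. = FALSE)
    }
    cc <- stats::cor(z)
    if (anyNA(cc)) {
      stop("degenerate input: constant sample profile(s) make the ",
           "correlation distance undefined", call. = FALSE)
    }
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(t(z))
  }
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, k = k)

  rates <- group_response_rates(raw, x$response)
  # ascending NR rate: A (most responsive), intermediates C, D, ...,
  # B (most resistant)
  asc_labels <- if (k == 2L) c("A", "B") else c("A", LETTERS[3:k], "B")
  relabel <- stats::setNames(asc_labels,
                             rates$group[order(rates$nr_rate, rates$group)])
  groups <- stats::setNames(unname(relabel[as.character(raw)]), names(raw))
  rates <- group_response_rates(groups, x$response)

  structure(list(groups = groups, dendrogram = hc, group_rates = rates,
                 genes_used = rownames(z)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d groups\n",
              length(x$groups), nrow(x$group_rates)))
  print(x$group_rates)
  invisible(x)
}

#' Per-group NAC non-response rates
#'
#' Exact counts and proportions of NAC-resistant (NR) samples per cluster
#' group. The n-weighted mean of the group rates equals the overall cohort
#' NR rate (conservation).
#'
#' @param groups group label per sample (named or aligned with `response`).
#' @param response per-sample R/NR labels covering all samples.
#' @return Data frame with columns `group`, `n`, `n_NR`, `nr_rate`, ordered
#'   by group label.
#' @export
group_response_rates <- function(groups, response) {
  resp <- normalize_response(response)
  stopifnot(length(groups) == length(resp), !anyNA(resp))
  g <- as.character(groups)
  tab <- table(g)
  nr <- tapply(resp == "NR", g, sum)
  out <- data.frame(group = names(tab), n = as.integer(tab),
                    n_NR = as.integer(nr[names(tab)]),
                    stringsAsFactors = FALSE)
  out$nr_rate <- out$n_NR / out$n
  out[order(out$group), , drop = FALSE]
}
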
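#' Construct and validate a patient cohort table
#'
#' A `cohort_table` is a data frame with one row per patient carrying the
#' clinical covariates and binary immunohistochemistry (IHC) marker calls
#' used throughout the stratification models: `patient_id`, `age` (years),
#' `cT` (ordinal clinical stage, 2/3/4), one column per marker with calls
#' `"positive"`/`"negative"` (NA = missing call, kept explicit), and
#' `response` with levels `"R"` (responder, <ypT2 at cystectomy) and `"NR"`
#' (resistant, >=ypT2).
#'
#' @param df data frame holding at least `patient_id`, `age`, `cT`,
#'   `response`, plus marker columns.
#' @param marker_cols character vector naming the marker columns; defaults to
#'   every column that is not one of the four mandatory fields.
#' @return A validated `cohort_table` (a data frame subclass) with a
#'   `"markers"` attribute listing the marker columns.
#' @examples
#' df <- data.frame(patient_id = c("p1", "p2"), age = c(55, 67),
#'                  cT = c("cT2", "cT3"), GDPD3 = c("pos", "neg"),
#'                  response = c("R", "NR"))
#' cohort_table(df)
#' @export
cohort_table <- function(df, marker_cols = NULL) {
  stopifnot(is.data.frame(df))
  mandatory <- c("patient_id", "age", "cT", "response")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(marker_cols)) {
    marker_cols <- setdiff(names(df), mandatory)
  } else {
    absent <- setdiff(marker_cols, names(df))
    if (length(absent) > 0L) {
      stop("marker column(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- df[c(mandatory[1:2], "cT", marker_cols, "response")]
  out$patient_id <- as.character(out$patient_id)
  if (anyDuplicated(out$patient_id)) {
    stop("duplicate patient_id values", call. = FALSE)
  }

  age <- suppressWarnings(as.numeric(out$age))
  bad_age <- which(is.na(age) | age <= 0)
  if (length(bad_age) > 0L) {
    stop("unparseable or non-positive age in row(s): ",
         paste(bad_age, collapse = ", "), call. = FALSE)
  }
  out$age <- age

  ct <- normalize_ct(out$cT)
  bad_ct <- which(is.na(ct))
  if (length(bad_ct) > 0L) {
    stop("unparseable clinical stage (expected cT2/cT3/cT4) in row(s): ",
         paste(bad_ct, collapse = ", "), call. = FALSE)
  }
  out$cT <- ct

  resp <- normalize_response(out$response)
  if (anyNA(resp)) {
    stop("response undefined or unparseable in row(s): ",
         paste(which(is.na(resp)), collapse = ", "), call. = FALSE)
  }
  out$response <- resp

  for (m in marker_cols) out[[m]] <- normalize_binary_call(out[[m]])

  structure(out, markers = marker_cols,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients, %d markers (%s)\n", nrow(x),
              length(attr(x, "markers")),
              paste(attr(x, "markers"), collapse = ", ")))
  cat(sprintf("response: %d R / %d NR\n", sum(x$response == "R"),
              sum(x$response == "NR")))
  NextMethod()
  invisible(x)
}

#' Marker columns of a cohort table
#' @param cohort a [cohort_table()].
#' @return Character vector of marker column names.
#' @export
marker_names <- function(cohort) attr(cohort, "markers")

# Normalize heterogeneous binary marker encodings ("pos"/"neg", "+"/"-",
# 1/0, TRUE/FALSE, case-insensitive) to a positive/negative factor.
# Unrecognized or empty values become NA (explicit missing call).
normalize_binary_call <- function(x) {
  if (is.logical(x)) {
    return(factor(ifelse(x, "positive", "negative"),
                  levels = c("negative", "positive")))
  }
  s <- tolower(trimws(as.character(x)))
  pos <- c("pos", "positive", "1", "+", "true", "t", "yes")
  neg <- c("neg", "negative", "0", "-", "−", "false", "f", "no")
  out <- rep(NA_character_, length(s))
  out[s %in% pos] <- "positive"
  out[s %in% neg] <- "negative"
  factor(out, levels = c("negative", "positive"))
}

# Response labels: R (responder) / NR (resistant); 0/1 accepted with 1 = NR
# (the models predict resistance).
normalize_response <- function(x) {
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("R", "RESPONDER", "0")] <- "R"
  out[s %in% c("NR", "NON-RESPONDER", "NONRESPONDER", "RESISTANT", "1")] <- "NR"
  factor(out, levels = c("R", "NR"))
}

# Clinical T stage to integer ordinal: strips a leading "cT" or "T".
normalize_ct <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s <- sub("^CT", "", s)
  s <- sub("^T", "", s)
  v <- suppressWarnings(as.integer(s))
  v[!v %in% c(2L, 3L, 4L)] <- NA_integer_
  v
}

#' Read a cohort table from a delimited file
#'
#' Reads a per-patient table (one row per patient; header row names the
#' fields) and validates it into a [cohort_table()]. Marker calls coded as
#' "pos"/"neg", "+"/"-", 1/0 or TRUE/FALSE are normalized case-insensitively;
#' response accepts R/NR (or 0/1 with 1 = resistant). Spreadsheet
#' supplements should be exported to CSV/TSV text first; the
#' `"xlsx-export"` dialect parses such a CSV export.
#'
#' @param path file path.
#' @param dialect one of `"csv"`, `"tsv"`, `"xlsx-export"` (a CSV text
#'   export of a spreadsheet sheet).
#' @param schema optional named character vector mapping canonical names
#'   (`patient_id`, `age`, `cT`, `response`) to the file's column names,
#'   for supplements with different headers.
#' @param marker_cols optional character vector of marker columns (after
#'   schema mapping); defaults to all non-mandatory columns.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, dialect = c("csv", "tsv", "xlsx-export"),
                        schema = NULL, marker_cols = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df)) {
        stop("schema maps '", canonical, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  if (!"patient_id" %in% names(df)) {
    df$patient_id <- sprintf("patient_%02d", seq_len(nrow(df)))
  }
  cohort_table(df, marker_cols = marker_cols)
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [read_cohort()]: a written table read back yields an identical
#' `cohort_table`.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(cohort)
  df$cT <- paste0("cT", df$cT)
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct and validate an expression matrix
#'
#' Container for a discovery-style expression data set: a genes x samples
#' matrix of nonnegative signal values (MAS 5.0-style arbitrary units) plus
#' one binary chemotherapy-response label per sample.
#'
#' @param signal numeric matrix, genes in rows, samples in columns; all
#'   values finite and >= 0.
#' @param response per-sample labels, coercible to R/NR.
#' @param gene_ids,sample_ids identifiers; default to dimnames.
#' @return An `expression_matrix`: a list with elements `signal` (matrix
#'   with dimnames) and `response` (factor, levels R, NR).
#' @export
expression_matrix <- function(signal, response, gene_ids = rownames(signal),
                              sample_ids = colnames(signal)) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(signal)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%02d", seq_len(ncol(signal)))
  if (length(gene_ids) != nrow(signal) || length(sample_ids) != ncol(signal)) {
    stop("id lengths do not match signal dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids) || anyDuplicated(sample_ids)) {
    stop("gene_ids and sample_ids must be unique", call. = FALSE)
  }
  bad <- which(!is.finite(signal) | signal < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite or negative signal at gene '", gene_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "'", call. = FALSE)
  }
  resp <- normalize_response(response)
  if (length(resp) != ncol(signal)) {
    stop("response length (", length(resp), ") does not match sample count (",
         ncol(signal), ")", call. = FALSE)
  }
  if (anyNA(resp)) {
    stop("unparseable response label for sample(s): ",
         paste(sample_ids[is.na(resp)], collapse = ", "), call. = FALSE)
  }
  dimnames(signal) <- list(gene_ids, sample_ids)
  names(resp) <- sample_ids
  structure(list(signal = signal, response = resp),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d R / %d NR)\n",
              nrow(x$signal), ncol(x$signal), sum(x$response == "R"),
              sum(x$response == "NR")))
  invisible(x)
}

#' Read an expression matrix with response labels
#'
#' Expects a rectangular numeric table, genes in rows (first column = gene
#' id), samples in columns, and sample labels supplied either as a sidecar
#' two-column file (`sample_id`, `response`) or as a named vector.
#'
#' @param path path to the signal table (CSV or TSV, by extension).
#' @param labels path to a sidecar label file, or a named character vector
#'   of per-sample labels.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, labels) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  signal <- as.matrix(df)
  if (!is.numeric(signal)) {
    stop("non-numeric signal values in ", path, call. = FALSE)
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lab_df <- utils::read.table(labels, header = TRUE,
                                sep = if (grepl("\\.tsv$|\\.txt$", labels)) "\t" else ",",
                                stringsAsFactors = FALSE,
                                fileEncoding = "UTF-8")
    labels <- stats::setNames(lab_df[[2L]], lab_df[[1L]])
  }
  if (is.null(names(labels))) {
    stop("labels must be named by sample id", call. = FALSE)
  }
  missing_lab <- setdiff(colnames(signal), names(labels))
  extra_lab <- setdiff(names(labels), colnames(signal))
  if (length(missing_lab) > 0L || length(extra_lab) > 0L) {
    stop("label/sample mismatch; unlabeled samples: [",
         paste(missing_lab, collapse = ", "), "]; labels without samples: [",
         paste(extra_lab, collapse = ", "), "]", call. = FALSE)
  }
  expression_matrix(signal, labels[colnames(signal)])
}

#' Write an expression matrix and its labels to text files
#'
#' @param x an [expression_matrix()].
#' @param path signal table path (TSV).
#' @param labels_path sidecar label file path (TSV).
#' @export
write_expression <- function(x, path, labels_path) {
  df <- data.frame(gene_id = rownames(x$signal), x$signal,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  lab <- data.frame(sample_id = names(x$response),
                    response = as.character(x$response))
  utils::write.table(lab, labels_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundle analysis results with provenance
#'
#' A `result_bundle` couples named payload statistics (and optional
#' per-patient stratum assignments) with the provenance needed to reproduce
#' them: input paths, the configuration used, its hash, and the seed.
#' Re-running with identical inputs, config and seed reproduces the payload
#' bit-identically.
#'
#' @param payload named list of statistics / results (JSON-serializable).
#' @param inputs character vector of input file paths.
#' @param config named list of configuration values.
#' @param seed integer seed used for any randomness.
#' @param assignments optional data frame of per-patient stratum assignments.
#' @return A `result_bundle`.
#' @export
result_bundle <- function(payload, inputs = character(), config = list(),
                          seed = NA_integer_, assignments = NULL) {
  stopifnot(is.list(payload))
  if (is.null(names(payload)) && length(payload) > 0L) {
    stop("payload entries must be named", call. = FALSE)
  }
  structure(list(
    provenance = list(inputs = inputs, config = config,
                      config_hash = rlang::hash(config), seed = seed),
    payload = payload,
    assignments = assignments
  ), class = "result_bundle")
}

#' Write a result bundle to JSON (and assignments to CSV)
#'
#' @param bundle a [result_bundle()].
#' @param path output JSON path.
#' @param assignments_path optional CSV path for the stratum assignments.
#' @export
write_results <- function(bundle, path, assignments_path = NULL) {
  stopifnot(inherits(bundle, "result_bundle"))
  doc <- list(provenance = bundle$provenance, payload = bundle$payload)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(assignments_path)) {
    if (is.null(bundle$assignments)) {
      stop("bundle has no assignments to export", call. = FALSE)
    }
    utils::write.csv(bundle$assignments, assignments_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a results JSON document
#'
#' @param path JSON path written by [write_results()].
#' @return List with `provenance` and `payload`.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
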
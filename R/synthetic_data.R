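#' Specification for a synthetic discovery expression cohort
#'
#' Describes a genes x samples microarray-style data set with a known set of
#' planted response-associated genes. Non-planted genes share one log-normal
#' signal distribution regardless of response; planted genes have group
#' means (`mean_low`, `mean_high`) straddling the 300/500 signal-window
#' filter, with the direction (which response class is high) drawn at random
#' per gene. Noise is log-normal with the given coefficient of variation —
#' the conventional positive-support model for MAS 5.0-style signals.
#'
#' @param n_samples samples (default 33, a discovery-cohort size).
#' @param n_genes total genes.
#' @param n_planted planted response-associated genes (<= n_genes).
#' @param nr_fraction fraction of NAC-resistant samples (default 0.5; the
#'   discovery response split is close to balanced).
#' @param mean_low,mean_high planted group means in signal units (defaults
#'   200 / 700, outside the 300/500 filter window).
#' @param dispersion coefficient of variation of the log-normal noise
#'   (default 0.2).
#' @param baseline_range range of non-planted gene means (signal units),
#'   sampled log-uniformly.
#' @param seed integer seed.
#' @return A `discovery_spec` list.
#' @export
discovery_spec <- function(n_samples = 33L, n_genes = 1000L,
                           n_planted = 15L, nr_fraction = 0.5,
                           mean_low = 200, mean_high = 700,
                           dispersion = 0.2,
                           baseline_range = c(30, 3000), seed = 1L) {
  stopifnot(n_planted <= n_genes, nr_fraction > 0, nr_fraction < 1,
            mean_low < 300, mean_high > 500, dispersion > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_planted = as.integer(n_planted),
                 nr_fraction = nr_fraction, mean_low = mean_low,
                 mean_high = mean_high, dispersion = dispersion,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "discovery_spec")
}

# log-normal draws with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a discovery expression matrix with planted signal genes
#'
#' Pure function of its spec (identical spec => identical output).
#'
#' @param spec a [discovery_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `planted`
#'   (character vector of the planted gene ids).
#' @export
simulate_discovery <- function(spec) {
  stopifnot(inherits(spec, "discovery_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  n_nr <- max(2L, min(n - 2L, round(n * spec$nr_fraction)))
  resp <- sample(c(rep("R", n - n_nr), rep("NR", n_nr)))
  gene_ids <- sprintf("gene_%05d", seq_len(spec$n_genes))
  planted <- if (spec$n_planted > 0L) {
    sort(sample(gene_ids, spec$n_planted))
  } else character(0)

  signal <- matrix(0, spec$n_genes, n,
                   dimnames = list(gene_ids,
                                   sprintf("sample_%02d", seq_len(n))))
  base_mean <- exp(stats::runif(spec$n_genes,
                                log(spec$baseline_range[1]),
                                log(spec$baseline_range[2])))
  for (i in seq_len(spec$n_genes)) {
    signal[i, ] <- rlnorm_mean_cv(n, base_mean[i], spec$dispersion)
  }
  is_nr <- resp == "NR"
  for (g in planted) {
    high_in_nr <- stats::runif(1) < 0.5
    m_nr <- if (high_in_nr) spec$mean_high else spec$mean_low
    m_r <- if (high_in_nr) spec$mean_low else spec$mean_high
    signal[g, is_nr] <- rlnorm_mean_cv(sum(is_nr), m_nr, spec$dispersion)
    signal[g, !is_nr] <- rlnorm_mean_cv(sum(!is_nr), m_r, spec$dispersion)
  }
  list(matrix = expression_matrix(signal, resp), planted = planted)
}

#' Specification for a synthetic validation cohort
#'
#' Describes a per-patient cohort with binary IHC marker calls drawn
#' conditionally on response, response-conditional age and clinical-stage
#' distributions, and optional extra pure-noise markers. The defaults mirror
#' the validation setting the models target: 37 patients, 21/37 resistant, a
#' GDPD3-like marker positive mostly in responders (P(+|R) = 0.8,
#' P(+|NR) = 0.15), a SPRED1-like marker positive mostly in resistant
#' patients (mirrored probabilities), six response-independent companion
#' markers with varied base rates, ages around 60 (resistant patients a few
#' years older) and a cT2-heavy stage mix (roughly 60/35/5 overall).
#'
#' @param n_patients cohort size (default 37).
#' @param nr_fraction P(resistant) (default 21/37).
#' @param marker_model named list; each element `c(p_R, p_NR)` gives
#'   P(positive | R) and P(positive | NR) for one marker.
#' @param age_model list with elements `R` and `NR`, each `c(mean, sd)` of a
#'   normal age distribution (years), truncated to `age_range`.
#' @param age_range attainable age range (years).
#' @param stage_model list with elements `R` and `NR`, each a probability
#'   vector over cT2/cT3/cT4.
#' @param n_noise_markers extra pure-noise markers (P(+) = 0.5 in both
#'   classes), named `noise_1`, ...
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 37L, nr_fraction = 21 / 37,
                        marker_model = default_marker_model(),
                        age_model = list(R = c(60, 8), NR = c(65, 8)),
                        age_range = c(40, 85),
                        stage_model = list(R = c(0.72, 0.25, 0.03),
                                           NR = c(0.50, 0.43, 0.07)),
                        n_noise_markers = 0L, seed = 1L) {
  stopifnot(n_patients >= 4L, nr_fraction > 0, nr_fraction < 1,
            length(marker_model) >= 1L, !is.null(names(marker_model)))
  probs <- unlist(marker_model)
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(abs(vapply(stage_model, sum, numeric(1)) - 1) < 1e-8))
  structure(list(n_patients = as.integer(n_patients),
                 nr_fraction = nr_fraction, marker_model = marker_model,
                 age_model = age_model, age_range = age_range,
                 stage_model = stage_model,
                 n_noise_markers = as.integer(n_noise_markers),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_marker_model <- function() {
  list(GDPD3  = c(0.80, 0.15),
       SPRED1 = c(0.15, 0.80),
       ZNF816 = c(0.50, 0.50),
       CCPG1  = c(0.35, 0.35),
       SCNN1B = c(0.55, 0.55),
       RDHE2  = c(0.30, 0.30),
       Ki67   = c(0.60, 0.60),
       p53    = c(0.45, 0.45))
}

#' Simulate a validation cohort with known marker-response structure
#'
#' Pure function of its spec: response is Bernoulli(`nr_fraction`), markers
#' are drawn conditionally on response from `marker_model`, age and stage
#' from their response-conditional models, noise markers independently of
#' response. Degenerate draws with fewer than two patients in either
#' response class are redrawn (the models downstream require both classes).
#'
#' @param spec a [cohort_spec()].
#' @return List with `cohort` (a [cohort_table()]) and `model` (the marker
#'   model used, ground truth for recovery experiments).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  repeat {
    is_nr <- stats::runif(n) < spec$nr_fraction
    if (sum(is_nr) >= 2L && sum(!is_nr) >= 2L) break
  }
  cls <- ifelse(is_nr, "NR", "R")

  age <- numeric(n)
  ct <- integer(n)
  for (k in c("R", "NR")) {
    idx <- which(cls == k)
    am <- spec$age_model[[k]]
    a <- stats::rnorm(length(idx), am[1], am[2])
    age[idx] <- round(pmin(pmax(a, spec$age_range[1]), spec$age_range[2]))
    ct[idx] <- sample(c(2L, 3L, 4L), length(idx), replace = TRUE,
                      prob = spec$stage_model[[k]])
  }

  df <- data.frame(patient_id = sprintf("sim_%03d", seq_len(n)),
                   age = age, cT = ct, stringsAsFactors = FALSE)
  for (m in names(spec$marker_model)) {
    p <- spec$marker_model[[m]]
    prob <- ifelse(is_nr, p[2], p[1])
    df[[m]] <- ifelse(stats::runif(n) < prob, "positive", "negative")
  }
  if (spec$n_noise_markers > 0L) {
    for (j in seq_len(spec$n_noise_markers)) {
      df[[sprintf("noise_%d", j)]] <-
        ifelse(stats::runif(n) < 0.5, "positive", "negative")
    }
  }
  df$response <- cls
  list(cohort = cohort_table(df), model = spec$marker_model)
}

#' Deterministic reference cohort reproducing the two-stratum split
#'
#' A synthetic, hand-constructed 37-patient cohort whose combined
#' clinical + IHC model stratifies it into the reconstructed two halves: a
#' low-risk stratum of 19 patients with 5 resistant (26%) and a high-risk
#' stratum of 18 with 16 resistant (89%), 21 resistant patients in total.
#' Low-stratum patients are clinically low risk (age <= 60, cT2), GDPD3
#' positive and SPRED1 negative; high-stratum patients are the complement on
#' all three predicates. The six companion markers carry deterministic
#' weakly-informative patterns. This is a synthetic stand-in constrained
#' only to reproduce those stratum counts — it is not a reconstruction of
#' any real patient-level table, and per-patient ages and stages are
#' arbitrary within their stratum's constraints.
#'
#' @return A [cohort_table()] with 37 rows and 8 markers; constant across
#'   calls (no randomness).
#' @export
fixture_cohort <- function() {
  n_low <- 19L; n_high <- 18L
  # low stratum: clinical low risk, GDPD3+, SPRED1-; 5 of 19 resistant
  low <- data.frame(
    patient_id = sprintf("fx_%02d", 1:19),
    age = c(44, 47, 49, 50, 52, 53, 54, 55, 56, 57,
            58, 58, 59, 60, 45, 51, 55, 59, 60),
    cT = 2L,
    GDPD3 = "positive", SPRED1 = "negative",
    response = c(rep("R", 14), rep("NR", 5)),
    stringsAsFactors = FALSE)
  # high stratum: clinically high risk (age > 60 and/or cT > 2), GDPD3-,
  # SPRED1+; 16 of 18 resistant
  high <- data.frame(
    patient_id = sprintf("fx_%02d", 20:37),
    age = c(61, 62, 63, 64, 66, 67, 68, 70, 71, 72,
            74, 76, 78, 83, 50, 55, 58, 60),
    cT = c(2L, 3L, 2L, 3L, 2L, 4L, 3L, 2L, 3L, 2L,
           3L, 2L, 3L, 2L, 3L, 3L, 4L, 3L),
    GDPD3 = "negative", SPRED1 = "positive",
    response = c(rep("R", 2), rep("NR", 16)),
    stringsAsFactors = FALSE)
  df <- rbind(low, high)
  # companion markers: deterministic index patterns, unrelated to the
  # stratification predicates and imperfectly related to response
  idx <- seq_len(n_low + n_high)
  df$ZNF816 <- ifelse(idx %% 2L == 0L, "positive", "negative")
  df$CCPG1 <- ifelse(idx %% 3L == 0L, "positive", "negative")
  df$SCNN1B <- ifelse((idx + 1L) %% 2L == 0L, "positive", "negative")
  df$RDHE2 <- ifelse(idx %% 5L == 0L, "positive", "negative")
  df$Ki67 <- ifelse(idx %% 4L < 2L, "positive", "negative")
  df$p53 <- ifelse((idx + 2L) %% 3L == 0L, "positive", "negative")
  cohort_table(df, marker_cols = c("GDPD3", "SPRED1", "ZNF816", "CCPG1",
                                   "SCNN1B", "RDHE2", "Ki67", "p53"))
}
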
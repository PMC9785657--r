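#' SURG-TLX workload dimensions
#'
#' The six self-rated workload dimensions of the SURG-TLX questionnaire, each
#' scored on a 0--20 scale: mental demands, physical demands, temporal demands,
#' task complexity, situational stress, and distractions.
#'
#' @return Character vector of the six dimension names, in instrument order.
#' @export
surgtlx_dimensions <- function() {
  c("mental", "physical", "temporal", "complexity", "stress", "distractions")
}

#' Published group-level SURG-TLX summary statistics
#'
#' Mean and standard deviation of each SURG-TLX dimension for the
#' medical-professional (MP) and control (CG) groups in a 20-trial
#' laparoscopic-cholecystectomy training cohort (11 MP trials from residents
#' and expert surgeons, 9 CG trials from non-medical subjects). These values
#' parameterize the synthetic cohort generator and the summary-statistic
#' t-test reproduction.
#'
#' @return A data.frame with columns `dimension`, `mp_mean`, `mp_sd`,
#'   `cg_mean`, `cg_sd`.
#' @export
surgtlx_group_params <- function() {
  data.frame(
    dimension = surgtlx_dimensions(),
    mp_mean = c(2.36, 7.41, 3.73, 8.73, 1.91, 5.91),
    mp_sd   = c(1.63, 3.89, 2.83, 4.27, 1.22, 7.58),
    cg_mean = c(14.89, 14.78, 6.22, 12.78, 14.67, 11.78),
    cg_sd   = c(3.18, 2.33, 2.91, 3.35, 2.24, 4.06),
    stringsAsFactors = FALSE
  )
}

#' Construct a SURG-TLX response
#'
#' @param mental,physical,temporal,complexity,stress,distractions Integer
#'   scores in \[0, 20\].
#' @return A named list of class `surgtlx_response`.
#' @export
surgtlx_response <- function(mental, physical, temporal, complexity,
                             stress, distractions) {
  scores <- c(mental = mental, physical = physical, temporal = temporal,
              complexity = complexity, stress = stress,
              distractions = distractions)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 20)) {
    stop("SURG-TLX scores must lie in [0, 20]")
  }
  if (any(scores != round(scores))) {
    stop("SURG-TLX scores must be integers")
  }
  storage.mode(scores) <- "integer"
  structure(as.list(scores), class = "surgtlx_response")
}

#' Tabulate a cohort's workload data
#'
#' Flattens a cohort (list of trials as produced by [generate_cohort()]) into
#' the rectangular dataset used by the label and statistics functions: one row
#' per trial with subject, group, trial index, outcome and the six SURG-TLX
#' scores.
#'
#' @param cohort List of trials, each with `trial_id`, `subject_id`, `group`,
#'   `trial_index`, `outcome` and a `response` (see [surgtlx_response()]).
#' @return A data.frame with one row per trial.
#' @export
workload_dataset <- function(cohort) {
  if (length(cohort) == 0L) stop("cohort is empty")
  rows <- lapply(cohort, function(tr) {
    data.frame(
      trial_id = tr$trial_id, subject_id = tr$subject_id,
      group = tr$group, trial_index = tr$trial_index,
      outcome = tr$outcome,
      as.data.frame(tr$response[surgtlx_dimensions()]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$trial_id)) stop("trial_ids must be unique")
  rownames(out) <- NULL
  out
}

#' Binarize a workload dimension about its cohort mean
#'
#' Scores strictly above the arithmetic mean of the dimension over all trials
#' become class 1 (high workload); scores at or below the mean become class 0.
#'
#' @param dataset Workload data.frame from [workload_dataset()].
#' @param dimension One of [surgtlx_dimensions()].
#' @return A list of class `binary_labels` with fields `dimension`, `labels`
#'   (named 0/1 integer vector, names = trial ids) and `threshold` (the mean).
#' @export
binarize_labels <- function(dataset, dimension) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0L) stop("dataset is empty")
  dimension <- match.arg(dimension, surgtlx_dimensions())
  scores <- dataset[[dimension]]
  thr <- mean(scores)
  labels <- as.integer(scores > thr)
  names(labels) <- dataset$trial_id
  structure(list(dimension = dimension, labels = labels, threshold = thr),
            class = "binary_labels")
}

#' Experience labels from group membership
#'
#' Medical professionals (MP) map to class 0 and the control group (CG) to
#' class 1, so that class 1 aligns with the high-workload class of the
#' mean-binarized mental-demand and situational-stress labels.
#'
#' @inheritParams binarize_labels
#' @return A `binary_labels` object with `dimension = "experience"`.
#' @export
experience_labels <- function(dataset) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0L) stop("dataset is empty")
  if (!all(dataset$group %in% c("MP", "CG"))) {
    stop("group must be 'MP' or 'CG'")
  }
  labels <- as.integer(dataset$group == "CG")
  names(labels) <- dataset$trial_id
  structure(list(dimension = "experience", labels = labels, threshold = NA_real_),
            class = "binary_labels")
}

#' Outcome labels from dissection success
#'
#' @inheritParams binarize_labels
#' @return A `binary_labels` object with `dimension = "outcome"`; success is
#'   class 1, failure class 0.
#' @export
outcome_labels <- function(dataset) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0L) stop("dataset is empty")
  if (any(is.na(dataset$outcome)) ||
      !all(dataset$outcome %in% c("success", "failure"))) {
    stop("outcome must be 'success' or 'failure' for every trial")
  }
  labels <- as.integer(dataset$outcome == "success")
  names(labels) <- dataset$trial_id
  structure(list(dimension = "outcome", labels = labels, threshold = NA_real_),
            class = "binary_labels")
}

#' Labels for every grid dimension
#'
#' @inheritParams binarize_labels
#' @param dimension A SURG-TLX dimension, `"experience"`, or `"outcome"`.
#' @return A `binary_labels` object.
#' @export
trial_labels <- function(dataset, dimension) {
  if (dimension == "experience") return(experience_labels(dataset))
  if (dimension == "outcome") return(outcome_labels(dataset))
  binarize_labels(dataset, dimension)
}

test_result <- function(t, df, p) {
  structure(list(t = t, df = df, p = p, annotation = annotate(p)),
            class = "workload_test")
}

#' @export
print.workload_test <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %g, p = %.4g %s\n", x$t, x$df, x$p, x$annotation))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's unpaired t-test with a pooled variance estimate,
#' df = n1 + n2 - 2, two-tailed p-value. Equality of variances is assumed, as
#' in the group comparisons this package reproduces.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A `workload_test` with `t`, `df`, `p` and significance `annotation`.
#' @export
pooled_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 observations")
  }
  t_test_from_summary(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y))
}

#' Pooled two-sample t-test from summary statistics
#'
#' Computes the pooled-variance Student t-test directly from group means,
#' standard deviations and sizes, as needed to reproduce published group
#' comparisons where only summaries are printed.
#'
#' @param m1,s1,n1 Mean, SD and size of the first sample.
#' @param m2,s2,n2 Mean, SD and size of the second sample.
#' @return A `workload_test` object.
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both sample sizes must be >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  if (s1 == 0 && s2 == 0 && m1 == m2) {
    return(test_result(0, n1 + n2 - 2, 1))
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) stop("zero pooled variance with unequal means")
  t <- (m1 - m2) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df))
}

#' Paired t-test over matched trials
#'
#' One-sample t-test on within-subject differences, df = pairs - 1,
#' two-tailed. Subjects missing either member of the pair are dropped, which
#' handles cohorts where one subject performed fewer trials.
#'
#' @param x,y Numeric vectors of the paired measurements.
#' @param pairing Vector of subject identifiers aligning `x` and `y`; elements
#'   of `x` and `y` with the same id form a pair. If `NULL`, `x` and `y` are
#'   taken as already aligned (NA entries dropped pairwise).
#' @return A `workload_test` object.
#' @export
paired_t_test <- function(x, y, pairing = NULL) {
  if (!is.null(pairing)) {
    ids <- intersect(pairing[!is.na(x)], pairing[!is.na(y)])
    x <- x[match(ids, pairing)]
    y <- y[match(ids, pairing)]
  }
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(test_result(0, n - 1, 1))
    stop("zero variance of non-zero differences")
  }
  t <- mean(d) / (sd_d / sqrt(n))
  test_result(t, n - 1, 2 * stats::pt(-abs(t), n - 1))
}

#' Significance annotation
#'
#' Follows the published caption literally: `"**"` for p < 0.0001
#' ("statistically extremely significant"), `"*"` for 0.01 < p < 0.05,
#' and `""` otherwise (including the unlabelled 0.0001--0.01 band).
#'
#' @param p A p-value in \[0, 1\].
#' @return `"**"`, `"*"` or `""`.
#' @export
annotate <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 1e-4) return("**")
  if (p > 0.01 && p < 0.05) return("*")
  ""
}

#' Group workload comparison table
#'
#' Runs the pooled two-sample t-test on every SURG-TLX dimension, MP versus
#' CG, either from raw trial scores or from a summary-statistics table.
#'
#' @param dataset Workload data.frame (ignored when `summary` is supplied).
#' @param summary Optional data.frame in the format of
#'   [surgtlx_group_params()]; group sizes then default to `n_mp`/`n_cg`.
#' @param n_mp,n_cg Group sizes used in summary mode (trial counts).
#' @return data.frame with per-dimension group means/SDs, t, df, p and
#'   annotation.
#' @export
group_workload_stats <- function(dataset = NULL, summary = NULL,
                                 n_mp = 11, n_cg = 9) {
  if (is.null(summary)) {
    if (is.null(dataset)) stop("either dataset or summary must be given")
    dims <- surgtlx_dimensions()
    summary <- data.frame(
      dimension = dims,
      mp_mean = vapply(dims, function(d) mean(dataset[[d]][dataset$group == "MP"]), 0),
      mp_sd   = vapply(dims, function(d) stats::sd(dataset[[d]][dataset$group == "MP"]), 0),
      cg_mean = vapply(dims, function(d) mean(dataset[[d]][dataset$group == "CG"]), 0),
      cg_sd   = vapply(dims, function(d) stats::sd(dataset[[d]][dataset$group == "CG"]), 0),
      stringsAsFactors = FALSE
    )
    n_mp <- sum(dataset$group == "MP")
    n_cg <- sum(dataset$group == "CG")
  }
  res <- lapply(seq_len(nrow(summary)), function(i) {
    r <- summary[i, ]
    tt <- t_test_from_summary(r$mp_mean, r$mp_sd, n_mp, r$cg_mean, r$cg_sd, n_cg)
    data.frame(dimension = r$dimension, mp_mean = r$mp_mean, mp_sd = r$mp_sd,
               cg_mean = r$cg_mean, cg_sd = r$cg_sd,
               t = tt$t, df = tt$df, p = tt$p, annotation = tt$annotation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Workload learning curve
#'
#' Paired t-tests of each SURG-TLX dimension between trial indexes 1-2, 2-3
#' and 1-3 across subjects; subjects lacking one of the two trials are dropped
#' from that comparison.
#'
#' @param dataset Workload data.frame.
#' @return data.frame with columns `dimension`, `comparison`, `t`, `df`, `p`,
#'   `annotation`, `n_pairs`.
#' @export
learning_curve_stats <- function(dataset) {
  combos <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  rows <- list()
  for (dim in surgtlx_dimensions()) {
    for (cmp in combos) {
      a <- dataset[dataset$trial_index == cmp[1], ]
      b <- dataset[dataset$trial_index == cmp[2], ]
      ids <- intersect(a$subject_id, b$subject_id)
      tt <- paired_t_test(a[[dim]][match(ids, a$subject_id)],
                          b[[dim]][match(ids, b$subject_id)])
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = dim, comparison = paste(cmp, collapse = "-"),
        t = tt$t, df = tt$df, p = tt$p, annotation = tt$annotation,
        n_pairs = length(ids), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
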
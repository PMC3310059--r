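# Response evaluation: EULAR DAS28 classification, cluster -> class
# identification, confusion matrices, sensitivity/specificity under the
# non-responder-positive convention, confusion reconstruction from printed
# percentages, cohort summary statistics, and the composed signature
# validation.

#' EULAR DAS28 response criteria
#'
#' Thresholds of the EULAR (van Gestel) response classification: a *good*
#' response requires a DAS28 improvement greater than `good_improvement_min`
#' with an attained DAS28 no higher than `good_present_max`; *no* response is
#' an improvement of at most `none_improvement_max`, or an improvement of at
#' most `good_improvement_min` with an attained DAS28 above
#' `none_present_min`; everything else is *moderate*.
#'
#' @param good_improvement_min Improvement threshold for good response
#'   (default 1.2 DAS28 units).
#' @param none_improvement_max Improvement at or below which response is
#'   none (default 0.6).
#' @param good_present_max Attained DAS28 ceiling for good response
#'   (default 3.2).
#' @param none_present_min Attained DAS28 above which a sub-1.2 improvement
#'   is classed as none (default 5.1).
#' @return An object of class `eular_criteria`.
#' @export
eular_criteria <- function(good_improvement_min = 1.2,
                           none_improvement_max = 0.6,
                           good_present_max = 3.2,
                           none_present_min = 5.1) {
  stopifnot(good_improvement_min > none_improvement_max,
            good_improvement_min > 0, none_improvement_max > 0,
            good_present_max > 0, none_present_min > good_present_max)
  structure(list(good_improvement_min = good_improvement_min,
                 none_improvement_max = none_improvement_max,
                 good_present_max = good_present_max,
                 none_present_min = none_present_min),
            class = "eular_criteria")
}

#' Classify EULAR response from DAS28 scores
#'
#' @param baseline,week14 DAS28 scores in `[0, 10]` (vectorised).
#' @param criteria An [eular_criteria()].
#' @return Character vector over `{"good", "moderate", "none"}`.
#' @examples
#' eular_response(5.3, 3.1)  # "good"
#' eular_response(4.8, 4.7)  # "none"
#' eular_response(6.0, 4.0)  # "moderate"
#' @export
eular_response <- function(baseline, week14, criteria = eular_criteria()) {
  stopifnot(length(baseline) == length(week14))
  if (any(baseline < 0 | baseline > 10 | week14 < 0 | week14 > 10)) {
    stop("DAS28 scores must lie in [0, 10]", call. = FALSE)
  }
  # snap to 9 decimals: DAS28 is reported to 1-2 decimals and the category
  # boundaries are exact rationals, so binary noise (4.4 - 3.2 > 1.2 in
  # doubles) must not move a patient across a class boundary
  improvement <- round(baseline - week14, 9)
  good <- improvement > criteria$good_improvement_min &
    week14 <= criteria$good_present_max
  none <- improvement <= criteria$none_improvement_max |
    (improvement <= criteria$good_improvement_min &
       week14 > criteria$none_present_min)
  ifelse(good, "good", ifelse(none, "none", "moderate"))
}

#' Identify clusters as the responder and non-responder groups
#'
#' Maps each of the two clusters to a response class. The mapping maximising
#' `tp + tn` (correctly grouped patients) is chosen; this coincides with
#' majority composition whenever each cluster has a decisive, distinct
#' majority. On an exact tie, cluster 1 is the non-responder cluster.
#'
#' @param assignments Integer cluster indices in `{1, 2}`, aligned to
#'   `true_labels`.
#' @param true_labels `good`/`none` labels; both classes must be present.
#' @return A list of class `cluster_mapping`: `mapping` (named character,
#'   `"1"`/`"2"` -> `"none"`/`"good"`), `majority_decisive` (logical: would
#'   per-cluster majority voting alone have produced this mapping), and
#'   `accuracy_counts` (`tp + tn` under each candidate mapping).
#' @export
label_clusters <- function(assignments, true_labels) {
  true_labels <- as.character(true_labels)
  stopifnot(length(assignments) == length(true_labels),
            all(assignments %in% 1:2),
            all(true_labels %in% c("good", "none")))
  if (length(unique(assignments)) < 2L) {
    stop("a cluster is empty; both clusters must be populated", call. = FALSE)
  }
  if (length(unique(true_labels)) < 2L) {
    stop("both response classes must be present", call. = FALSE)
  }
  # candidate A: cluster 1 = non-responder; candidate B: the reverse
  correct_a <- sum(assignments == 1 & true_labels == "none") +
    sum(assignments == 2 & true_labels == "good")
  correct_b <- sum(assignments == 2 & true_labels == "none") +
    sum(assignments == 1 & true_labels == "good")
  mapping <- if (correct_a >= correct_b) c("1" = "none", "2" = "good")
             else c("1" = "good", "2" = "none")
  maj <- vapply(1:2, function(cl) {
    tab <- table(factor(true_labels[assignments == cl],
                        levels = c("good", "none")))
    if (tab["none"] > tab["good"]) "none"
    else if (tab["good"] > tab["none"]) "good"
    else NA_character_
  }, character(1))
  majority_decisive <- !anyNA(maj) && maj[1] != maj[2] &&
    identical(unname(mapping), unname(maj))
  structure(list(mapping = mapping,
                 majority_decisive = majority_decisive,
                 accuracy_counts = c(cluster1_none = correct_a,
                                     cluster1_good = correct_b)),
            class = "cluster_mapping")
}

#' Build a confusion matrix under the non-responder-positive convention
#'
#' Positives are non-responders: `tp` counts true non-responders placed in
#' the non-responder cluster, `fn` true non-responders placed in the
#' responder cluster, `tn` true responders in the responder cluster, and
#' `fp` true responders in the non-responder cluster.
#'
#' @param assignments Cluster indices in `{1, 2}`.
#' @param mapping A [label_clusters()] result, or a named character vector
#'   `c("1" = ..., "2" = ...)` over `good`/`none`.
#' @param true_labels `good`/`none` labels aligned to `assignments`.
#' @return An object of class `confusion_matrix` with fields `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion <- function(assignments, mapping, true_labels) {
  if (inherits(mapping, "cluster_mapping")) mapping <- mapping$mapping
  true_labels <- as.character(true_labels)
  if (!all(true_labels %in% c("good", "none"))) {
    stop("labels must be 'good' or 'none'", call. = FALSE)
  }
  stopifnot(all(as.character(assignments) %in% names(mapping)),
            all(mapping %in% c("good", "none")))
  predicted <- unname(mapping[as.character(assignments)])
  confusion_matrix(tp = sum(predicted == "none" & true_labels == "none"),
                   fn = sum(predicted == "good" & true_labels == "none"),
                   tn = sum(predicted == "good" & true_labels == "good"),
                   fp = sum(predicted == "none" & true_labels == "good"))
}

#' @rdname confusion
#' @param tp,fn,tn,fp Nonnegative counts.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp)),
            class = "confusion_matrix")
}

#' Sensitivity and specificity (non-responders positive)
#'
#' Sensitivity is the percentage of true non-responders identified as
#' non-responders, `100 * tp / (tp + fn)`; specificity the percentage of
#' true responders identified as responders, `100 * tn / (tn + fp)`.
#' Reported at configurable rounding (integer percent, halves up, by
#' default).
#'
#' @param cm A [confusion_matrix()].
#' @param digits Decimal places to round to (default 0); `NULL` for
#'   unrounded.
#' @return Percentage in `[0, 100]`.
#' @export
sensitivity <- function(cm, digits = 0) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) {
    stop("sensitivity undefined: no true non-responders", call. = FALSE)
  }
  pct <- 100 * cm$tp / (cm$tp + cm$fn)
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm, digits = 0) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tn + cm$fp == 0) {
    stop("specificity undefined: no true responders", call. = FALSE)
  }
  pct <- 100 * cm$tn / (cm$tn + cm$fp)
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Reconstruct confusion matrices from printed integer percentages
#'
#' Exhaustively enumerates every `tp` in `[0, n_nonresponders]` and `tn` in
#' `[0, n_responders]` whose half-up-rounded sensitivity and specificity
#' match the printed integer pair, so that published percentage tables can
#' be audited back to the patient counts they imply.
#'
#' @param sens_pct,spec_pct Printed integer percentages in `[0, 100]`.
#' @param n_nonresponders,n_responders Group sizes (>= 1).
#' @return A list: `matrices` (list of [confusion_matrix()]; possibly
#'   empty), `unique` (TRUE when exactly one matrix is consistent).
#' @examples
#' reconstruct_confusion(71, 61, 24, 18)  # unique: tp = 17, tn = 11
#' @export
reconstruct_confusion <- function(sens_pct, spec_pct, n_nonresponders,
                                  n_responders) {
  stopifnot(sens_pct >= 0, sens_pct <= 100, spec_pct >= 0, spec_pct <= 100,
            n_nonresponders >= 1, n_responders >= 1)
  tp_ok <- which(round_half_up(100 * (0:n_nonresponders) / n_nonresponders)
                 == sens_pct) - 1L
  tn_ok <- which(round_half_up(100 * (0:n_responders) / n_responders)
                 == spec_pct) - 1L
  matrices <- list()
  for (tp in tp_ok) for (tn in tn_ok) {
    matrices[[length(matrices) + 1L]] <-
      confusion_matrix(tp, n_nonresponders - tp, tn, n_responders - tn)
  }
  list(matrices = matrices, unique = length(matrices) == 1L)
}

#' Welch two-sample t-test from summary statistics
#'
#' Computes the Welch statistic, Satterthwaite degrees of freedom and
#' two-sided p-value from group means, SDs and sizes — equivalent to
#' `t.test(..., var.equal = FALSE)` on the raw data, but computable from a
#' published summary table.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A list: `t`, `df`, `p`.
#' @examples
#' welch_from_summary(2.0, 0.8, 18, 0.1, 1.0, 24)  # t ~ 6.84, p < 1e-4
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohort summary table
#'
#' Summarises a metadata table per response group: group size and percentage
#' of the cohort, within-group counts and percentages for sex, RF positivity
#' and drug, mean and SD for age and the DAS28 baseline and decrease, and a
#' Welch two-sample p-value for the DAS28 decrease between groups. All
#' percentages use within-group denominators (except the group sizes, which
#' are percentages of the whole cohort) and round half-up to integers.
#'
#' @param metadata Data.frame with columns `response` (`good`/`none`),
#'   `das28_baseline`, `das28_week14`, and optionally `sex`, `rf_positive`,
#'   `drug`, `age`.
#' @return A list of class `cohort_summary` with per-group numeric fields
#'   (`n`, `pct_of_cohort`, `female_n`, `female_pct`, `rf_n`, `rf_pct`,
#'   `adalimumab_n`, `adalimumab_pct`, `infliximab_n`, `infliximab_pct`,
#'   `age_mean`, `age_sd`, `das28_baseline_mean`, `das28_baseline_sd`,
#'   `das28_decrease_mean`, `das28_decrease_sd`) and a cohort-level
#'   `das28_decrease_welch` (`t`, `df`, `p`).
#' @export
cohort_summary <- function(metadata) {
  stopifnot(all(c("response", "das28_baseline", "das28_week14")
                %in% names(metadata)))
  metadata$response <- as.character(metadata$response)
  stopifnot(all(metadata$response %in% c("good", "none")))
  n_total <- nrow(metadata)
  groups <- lapply(c(good = "good", none = "none"), function(g) {
    sub <- metadata[metadata$response == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("response group '", g, "' is empty",
                              call. = FALSE)
    decrease <- sub$das28_baseline - sub$das28_week14
    out <- list(n = nrow(sub),
                pct_of_cohort = round_half_up(100 * nrow(sub) / n_total),
                das28_baseline_mean = mean(sub$das28_baseline),
                das28_baseline_sd = stats::sd(sub$das28_baseline),
                das28_decrease_mean = mean(decrease),
                das28_decrease_sd = stats::sd(decrease))
    if (!is.null(sub$sex)) {
      out$female_n <- sum(sub$sex == "F")
      out$female_pct <- round_half_up(100 * out$female_n / out$n)
    }
    if (!is.null(sub$rf_positive)) {
      out$rf_n <- sum(sub$rf_positive)
      out$rf_pct <- round_half_up(100 * out$rf_n / out$n)
    }
    if (!is.null(sub$drug)) {
      out$adalimumab_n <- sum(sub$drug == "adalimumab")
      out$adalimumab_pct <- round_half_up(100 * out$adalimumab_n / out$n)
      out$infliximab_n <- sum(sub$drug == "infliximab")
      out$infliximab_pct <- round_half_up(100 * out$infliximab_n / out$n)
    }
    if (!is.null(sub$age)) {
      out$age_mean <- mean(sub$age)
      out$age_sd <- stats::sd(sub$age)
    }
    out
  })
  welch <- welch_from_summary(groups$good$das28_decrease_mean,
                              groups$good$das28_decrease_sd,
                              groups$good$n,
                              groups$none$das28_decrease_mean,
                              groups$none$das28_decrease_sd,
                              groups$none$n)
  structure(list(good = groups$good, none = groups$none,
                 das28_decrease_welch = welch),
            class = "cohort_summary")
}

#' Validate one signature against the cohort
#'
#' The full validation chain for a single published signature: map its
#' symbols onto the matrix, cluster the patients on the signature-restricted
#' profiles with k-means under Pearson dissimilarity (`k = 2`), identify the
#' clusters as the responder and non-responder groups, and score sensitivity
#' and specificity with non-responders as the positive class. Every
#' intermediate (mapping, clustering, mapping rule, seed) is carried in the
#' report; stage failures are re-raised tagged with the stage name.
#'
#' @param expr Genes x samples log2 matrix (gene-symbol rownames).
#' @param metadata Data.frame with `sample_id` and `response` covering all
#'   matrix columns.
#' @param signature A [gene_signature()].
#' @param config A [cluster_config()].
#' @param min_match Minimum usable signature match fraction (default 0.5).
#' @param digits Rounding for the reported percentages (default integer).
#' @return An object of class `validation_report`: `signature`, `mapping`
#'   (signature mapping), `clustering` (cluster result), `cluster_mapping`,
#'   `confusion`, `sensitivity`, `specificity`, `seed`, `objective`.
#' @export
validate_signature <- function(expr, metadata, signature,
                               config = cluster_config(), min_match = 0.5,
                               digits = 0) {
  stopifnot(is.matrix(expr), inherits(signature, "gene_signature"))
  if (!all(colnames(expr) %in% metadata$sample_id)) {
    stage_error("metadata", "metadata does not cover all samples")
  }
  labels <- metadata$response[match(colnames(expr), metadata$sample_id)]
  sm <- map_signature(signature, expr, min_match = min_match)
  if (!sm$usable) {
    stage_error("map_signature", sprintf(
      "signature '%s' unusable: %d/%d symbols matched (match_fraction %.2f)",
      signature$name, length(sm$matched),
      length(sm$matched) + length(sm$missing), sm$match_fraction))
  }
  profiles <- t(expr[sm$rows, , drop = FALSE])
  cl <- tryCatch(kmeans_partition(profiles, config),
                 error = function(e) stage_error("kmeans_partition",
                                                 conditionMessage(e)))
  cm_map <- tryCatch(label_clusters(cl$assignments, labels),
                     error = function(e) stage_error("label_clusters",
                                                     conditionMessage(e)))
  cm <- confusion(cl$assignments, cm_map, labels)
  structure(list(signature = signature$name,
                 mapping = sm,
                 clustering = cl,
                 cluster_mapping = cm_map,
                 confusion = cm,
                 sensitivity = sensitivity(cm, digits),
                 specificity = specificity(cm, digits),
                 seed = config$seed,
                 objective = cl$objective),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Signature %-20s matched %d/%d genes | sens %s%% spec %s%%\n",
              x$signature, length(x$mapping$matched),
              length(x$mapping$matched) + length(x$mapping$missing),
              format(x$sensitivity), format(x$specificity)))
  invisible(x)
}
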
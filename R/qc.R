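# Array-level quality control: control-probe ROC AUC, inter-array Pearson
# correlation outlier detection, and quantile normalisation.

#' QC thresholds
#'
#' @param auc_min Minimum control-probe ROC AUC for an array to pass
#'   (default 0.85; must lie in `[0.5, 1]`).
#' @param correlation_floor Absolute floor on a sample's mean inter-array
#'   Pearson correlation (default 0.8).
#' @param mad_multiplier Outlier cut is `median - mad_multiplier * MAD` of
#'   the mean correlations (default 3; MAD uses the usual 1.4826 consistency
#'   constant).
#' @param min_deviation Minimum absolute drop below the median required to
#'   flag (default 0.01): when arrays are extremely consistent the MAD
#'   collapses towards zero and `median - 3 * MAD` would flag harmless
#'   fluctuations, so the deviation band never shrinks below this value.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(auc_min = 0.85, correlation_floor = 0.8,
                          mad_multiplier = 3, min_deviation = 0.01) {
  stopifnot(auc_min >= 0.5, auc_min <= 1, mad_multiplier >= 0,
            min_deviation >= 0)
  structure(list(auc_min = auc_min, correlation_floor = correlation_floor,
                 mad_multiplier = mad_multiplier,
                 min_deviation = min_deviation),
            class = "qc_thresholds")
}

#' Control-probe ROC AUC
#'
#' Area under the ROC curve for separating positive from negative control
#' probes, computed as the Mann-Whitney U statistic scaled to `[0, 1]`: the
#' probability that a random positive probe exceeds a random negative one,
#' ties counting one half.
#'
#' @param pos Numeric vector of positive control intensities (nonempty).
#' @param neg Numeric vector of negative control intensities (nonempty).
#' @return AUC in `[0, 1]`.
#' @examples
#' control_probe_auc(c(5, 6, 7), c(1, 2, 3))  # 1
#' control_probe_auc(c(3, 1, 4), c(2, 0))     # 5/6
#' @export
control_probe_auc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("control_probe_auc requires nonempty positive and negative vectors",
         call. = FALSE)
  }
  stopifnot(is.numeric(pos), is.numeric(neg),
            !anyNA(pos), !anyNA(neg))
  r <- rank(c(pos, neg))  # midranks handle ties at half credit
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Flag inter-array correlation outliers
#'
#' Computes, for every sample (column), the mean Pearson correlation to all
#' other samples, and flags a sample when that mean falls below
#' `median - mad_multiplier * MAD` of the means or below the absolute floor.
#' Constant (zero-variance) samples have no defined correlation and are
#' flagged with an explicit reason.
#'
#' @param expr Genes x samples numeric matrix with at least 3 samples.
#' @param thresholds A [qc_thresholds()].
#' @return A data.frame (one row per sample): `sample_id`, `mean_correlation`,
#'   `outlier` (logical), `reason` (`""`, `"low correlation"` or
#'   `"zero variance"`), with attribute `cutoff` (the applied threshold).
#' @export
interarray_outliers <- function(expr, thresholds = qc_thresholds()) {
  stopifnot(is.matrix(expr))
  n <- ncol(expr)
  if (n < 3L) stop("interarray_outliers requires at least 3 samples",
                   call. = FALSE)
  ids <- colnames(expr)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  sds <- apply(expr, 2, stats::sd)
  constant <- sds == 0
  mean_cor <- rep(NA_real_, n)
  ok <- which(!constant)
  if (length(ok) >= 2L) {
    cm <- stats::cor(expr[, ok, drop = FALSE])
    mean_cor[ok] <- (rowSums(cm) - 1) / (length(ok) - 1)
  }
  med <- stats::median(mean_cor, na.rm = TRUE)
  band <- max(thresholds$mad_multiplier * stats::mad(mean_cor, na.rm = TRUE),
              thresholds$min_deviation)
  cutoff <- max(med - band, thresholds$correlation_floor)
  low <- !is.na(mean_cor) & mean_cor < cutoff
  out <- data.frame(sample_id = ids, mean_correlation = mean_cor,
                    outlier = constant | low,
                    reason = ifelse(constant, "zero variance",
                                    ifelse(low, "low correlation", "")))
  attr(out, "cutoff") <- cutoff
  out
}

#' Quantile-normalise an expression matrix
#'
#' Forces every column (sample) onto the same empirical distribution — the
#' row-wise mean of the sorted columns — while preserving within-column rank
#' order; ties receive the average of the values they span. A light-weight
#' normalisation for pipelines whose inputs are not already normalised.
#'
#' @param expr Numeric matrix without missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (anyNA(expr)) stop("quantile_normalize: matrix contains missing values",
                        call. = FALSE)
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Array QC report
#'
#' Runs both QC checks and assembles a machine-readable report: per-array
#' control-probe AUC pass/fail plus inter-array correlation flags.
#'
#' @param control_probes List with vectors `positive` and `negative`, or a
#'   list of such lists (one per array, named by sample).
#' @param expr Genes x samples matrix for the correlation check (optional).
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_report` with elements `auc` (data.frame),
#'   `correlation` (data.frame or NULL), `thresholds`, and `pass` (logical
#'   overall verdict). Serialise with [write_qc_json()].
#' @export
qc_report <- function(control_probes, expr = NULL,
                      thresholds = qc_thresholds()) {
  per_array <- if (!is.null(control_probes$positive)) {
    list(array = control_probes)
  } else control_probes
  auc <- data.frame(
    array = names(per_array),
    auc = vapply(per_array, function(cp) {
      control_probe_auc(cp$positive, cp$negative)
    }, numeric(1)),
    row.names = NULL
  )
  auc$pass <- auc$auc >= thresholds$auc_min
  correlation <- if (!is.null(expr)) interarray_outliers(expr, thresholds)
  pass <- all(auc$pass) &&
    (is.null(correlation) || !any(correlation$outlier))
  structure(list(auc = auc, correlation = correlation,
                 thresholds = unclass(thresholds), pass = pass),
            class = "qc_report")
}

#' Write a QC report as JSON
#'
#' @param report A [qc_report()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_qc_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
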
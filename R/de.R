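# Genome-wide two-group differential-expression screen with family-wise
# error control, and the study-design power calculation on the noncentral t
# distribution.

#' Per-gene two-sample differential expression test
#'
#' Runs a two-sided two-sample t-test on every gene (row) between the two
#' response groups, vectorised across the genome. Welch's unequal-variance
#' form is the default; the pooled-variance (classical) form is available
#' via `var_equal = TRUE`. The reported mean difference is
#' non-responder minus responder on the log2 scale, so a positive value
#' means higher expression in non-responders. Genes with zero variance in
#' both groups carry no information for the test and are returned with
#' `p = 1` and a flag rather than an error.
#'
#' @param expr Genes x samples log2 matrix, no missing values.
#' @param labels `good`/`none` labels aligned to columns; both groups need
#'   at least 2 samples.
#' @param var_equal Use the pooled-variance t-test (default FALSE = Welch).
#' @return A data.frame sorted by p-value: `gene`, `mean_diff_log2`, `t`,
#'   `df`, `p`, `zero_variance` (logical flag).
#' @export
per_gene_test <- function(expr, labels, var_equal = FALSE) {
  stopifnot(is.matrix(expr), !anyNA(expr))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expr),
            all(labels %in% c("good", "none")))
  g1 <- labels == "none"; g2 <- labels == "good"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples",
                               call. = FALSE)
  x1 <- expr[, g1, drop = FALSE]; x2 <- expr[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  zero_var <- se == 0
  t_stat <- ifelse(zero_var, NA_real_, diff / se)
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(t_stat), df))
  out <- data.frame(gene = rownames(expr) %||% seq_len(nrow(expr)),
                    mean_diff_log2 = diff, t = t_stat, df = df, p = p,
                    zero_variance = zero_var, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha Family-wise error rate to protect.
#' @param n_tests Number of tests (>= 1).
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 17881)  # 2.796e-06
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  stopifnot(family_alpha > 0, family_alpha <= 1, n_tests >= 1)
  family_alpha / n_tests
}

#' Power-calculation design
#'
#' Describes the two-group design whose detection power is computed: group
#' sizes, the log2 mean difference to detect (1.0 = a fold change of two),
#' the common per-gene SD in log2 units, the per-test alpha (a
#' genome-wide-corrected level by default) and the target power.
#'
#' @param n1,n2 Group sizes (defaults 18 and 24; >= 2).
#' @param effect_log2 Mean difference in log2 units (default 1.0).
#' @param sd Common per-gene SD in log2 units (> 0; no default is defensible,
#'   so it must be supplied where needed).
#' @param alpha Two-sided per-test significance level (default 2.7e-6).
#' @param target_power Power to solve for (default 0.80).
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(n1 = 18L, n2 = 24L, effect_log2 = 1.0, sd = NULL,
                       alpha = 0.0000027, target_power = 0.80) {
  stopifnot(n1 >= 2L, n2 >= 2L, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  if (!is.null(sd)) stopifnot(sd > 0)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 effect_log2 = effect_log2, sd = sd, alpha = alpha,
                 target_power = target_power),
            class = "power_spec")
}

#' Analytic power of the two-sided two-sample t-test
#'
#' Equal-variance formulation on the noncentral t distribution: with
#' noncentrality `delta = effect / (sd * sqrt(1/n1 + 1/n2))` and
#' `df = n1 + n2 - 2`, power is the probability that `|T|` exceeds the
#' two-sided critical value.
#'
#' @param spec A [power_spec()] with `sd` set.
#' @param sd Optional override for the spec's SD.
#' @return Power in `(0, 1)`.
#' @export
two_sample_power <- function(spec, sd = NULL) {
  stopifnot(inherits(spec, "power_spec"))
  sd <- sd %||% spec$sd
  if (is.null(sd) || sd <= 0) stop("a positive sd is required",
                                   call. = FALSE)
  df <- spec$n1 + spec$n2 - 2
  ncp <- spec$effect_log2 / (sd * sqrt(1 / spec$n1 + 1 / spec$n2))
  tcrit <- stats::qt(1 - spec$alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Solve for the per-gene SD implied by a target power
#'
#' Power is strictly decreasing in the SD (towards `alpha` as the SD grows,
#' towards 1 as it vanishes), so the SD at which the design attains
#' `target_power` is found by bisection to within 1e-6. This exposes the
#' within-gene variability a stated power claim implicitly assumes.
#'
#' @param spec A [power_spec()].
#' @return The implied SD in log2 units.
#' @export
solve_sd_for_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  f <- function(sd) two_sample_power(spec, sd = sd) - spec$target_power
  lo <- 1e-8
  if (f(lo) < 0) {
    stop("target power unattainable even as sd -> 0", call. = FALSE)
  }
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("bisection bracket error: power above target for ",
                       "all sd <= 1e6", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Monte-Carlo power of the two-sample t-test
#'
#' Empirical rejection frequency of the pooled two-sample t-test under the
#' spec's normal model, as an independent simulation cross-check of
#' [two_sample_power()]. Fully vectorised over replicates.
#'
#' @param spec A [power_spec()] with `sd` set.
#' @param n_reps Number of simulated experiments (default 1e5).
#' @param seed Integer seed.
#' @return Rejection proportion.
#' @export
mc_power <- function(spec, n_reps = 1e5, seed = 1L) {
  stopifnot(inherits(spec, "power_spec"), !is.null(spec$sd))
  n1 <- spec$n1; n2 <- spec$n2
  with_seed(seed, {
    x1 <- matrix(stats::rnorm(n1 * n_reps, mean = spec$effect_log2,
                              sd = spec$sd), nrow = n1)
    x2 <- matrix(stats::rnorm(n2 * n_reps, mean = 0, sd = spec$sd), nrow = n2)
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1)
    v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    tcrit <- stats::qt(1 - spec$alpha / 2, n1 + n2 - 2)
    mean(abs(t_stat) > tcrit)
  })
}
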
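# Synthetic-cohort generator: expression matrices, DAS28 trajectories,
# clinical covariates and control-probe intensities with the statistical
# structure the downstream validation assumes. Defaults emulate a 42-patient
# whole-blood exon-array cohort (18 EULAR good responders, 24 non-responders,
# 17881 gene-level summaries).

#' Cohort design for the synthetic expression generator
#'
#' Describes the simulated study: group sizes, gene universe, which signature
#' genes carry a class effect, the effect size and per-gene noise. Gene `g` in
#' sample `j` is drawn as `mu_g + delta_g * 1[j non-responder] + N(0, gene_sd^2)`
#' on the log2 scale, with `delta_g = effect_log2fc` for the informative subset
#' of `signature_genes` and 0 elsewhere. By convention informative genes are up
#' in non-responders; a negative `effect_log2fc` flips the direction.
#'
#' @param n_responders Number of EULAR good responders (default 18).
#' @param n_nonresponders Number of EULAR non-responders (default 24).
#' @param n_genes Size of the gene universe (default 17881). Genes are named
#'   `GENE000001 ...` unless `gene_names` is supplied.
#' @param signature_genes Character vector of gene symbols flagged as
#'   signature members; must lie inside the gene universe. Default: the first
#'   20 genes.
#' @param effect_log2fc Log2 fold-change magnitude between classes for
#'   informative genes (default 0, i.e. a null cohort).
#' @param effect_direction Direction pattern of the class effect across the
#'   informative genes: `"alternating"` (default) shifts odd-indexed
#'   informative genes up and even-indexed ones down in non-responders,
#'   `"up"` / `"down"` shift them all one way. Pearson correlation is
#'   invariant to adding a constant to a profile, so a one-directional shift
#'   applied to *every* clustered gene is invisible to correlation-based
#'   clustering; the alternating default imprints a class-specific profile
#'   shape, which is the structure a discriminative signature must have.
#' @param informative_fraction Fraction of `signature_genes` that actually
#'   carry the effect, in `[0, 1]` (default 1). Lowering it models signature
#'   decay across cohorts and platforms.
#' @param gene_sd Per-gene noise SD in log2 units (default 0.5, > 0).
#' @param baseline_mean_range Interval from which per-gene baseline means are
#'   drawn uniformly (default `c(4, 12)` log2 units, a typical array range).
#' @param gene_names Optional explicit gene symbols (length `n_genes`).
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 18L, n_nonresponders = 24L,
                        n_genes = 17881L,
                        signature_genes = NULL,
                        effect_log2fc = 0,
                        effect_direction = c("alternating", "up", "down"),
                        informative_fraction = 1,
                        gene_sd = 0.5, baseline_mean_range = c(4, 12),
                        gene_names = NULL, seed = 1L) {
  effect_direction <- match.arg(effect_direction)
  stopifnot(n_responders >= 1L, n_nonresponders >= 1L, n_genes >= 1L,
            gene_sd > 0,
            informative_fraction >= 0, informative_fraction <= 1,
            length(baseline_mean_range) == 2L,
            baseline_mean_range[1] <= baseline_mean_range[2])
  if (is.null(gene_names)) {
    gene_names <- sprintf("GENE%06d", seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes, !anyDuplicated(gene_names))
  if (is.null(signature_genes)) {
    signature_genes <- gene_names[seq_len(min(20L, n_genes))]
  }
  unknown <- setdiff(signature_genes, gene_names)
  if (length(unknown) > 0L) {
    stop("signature gene(s) not in gene universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(n_responders = as.integer(n_responders),
                 n_nonresponders = as.integer(n_nonresponders),
                 n_genes = as.integer(n_genes),
                 gene_names = gene_names,
                 signature_genes = unique(signature_genes),
                 effect_log2fc = effect_log2fc,
                 effect_direction = effect_direction,
                 informative_fraction = informative_fraction,
                 gene_sd = gene_sd,
                 baseline_mean_range = baseline_mean_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic log2 expression matrix with class labels
#'
#' Draws a genes x samples matrix under the additive two-class model of
#' [cohort_spec()]. Responders occupy the first columns. The informative
#' subset of signature genes (a seeded draw of
#' `round(informative_fraction * n)` of them) is shifted by `effect_log2fc`
#' in non-responders.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components `expr` (numeric matrix, rownames = gene
#'   symbols, colnames = sample IDs), `labels` (factor `good`/`none` aligned
#'   to columns), and `informative_genes` (symbols that carry the effect).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_responders + spec$n_nonresponders
  labels <- factor(rep(c("good", "none"),
                       c(spec$n_responders, spec$n_nonresponders)),
                   levels = c("good", "none"))
  sample_ids <- sprintf("P%03d", seq_len(n))
  with_seed(spec$seed, {
    mu <- stats::runif(spec$n_genes, spec$baseline_mean_range[1],
                       spec$baseline_mean_range[2])
    n_inf <- round(spec$informative_fraction * length(spec$signature_genes))
    informative <- if (n_inf > 0L) {
      sort(sample(spec$signature_genes, n_inf))
    } else character(0)
    sign_pattern <- switch(spec$effect_direction,
                           alternating = rep_len(c(1, -1), n_inf),
                           up = rep_len(1, n_inf),
                           down = rep_len(-1, n_inf))
    delta <- numeric(spec$n_genes)
    delta[match(informative, spec$gene_names)] <-
      spec$effect_log2fc * sign_pattern
    expr <- mu + outer(delta, as.integer(labels == "none")) +
      matrix(stats::rnorm(spec$n_genes * n, sd = spec$gene_sd),
             nrow = spec$n_genes, ncol = n)
    dimnames(expr) <- list(spec$gene_names, sample_ids)
    list(expr = expr, labels = labels, informative_genes = informative,
         informative_sign = stats::setNames(sign_pattern,
                                            as.character(informative)))
  })
}

#' DAS28 trajectory model for the synthetic cohort
#'
#' Class-specific normal distributions for the baseline DAS28 and for its
#' decrease over 14 weeks of anti-TNF therapy. Defaults are the cohort the
#' generator emulates: responders decrease by 2.0 (SD 0.8) from a baseline of
#' 5.3 (SD 1.0); non-responders decrease by 0.1 (SD 1.0) from 4.8 (SD 1.5).
#'
#' @param responder_decrease_mean,responder_decrease_sd DAS28 decrease in
#'   good responders.
#' @param nonresponder_decrease_mean,nonresponder_decrease_sd DAS28 decrease
#'   in non-responders.
#' @param responder_baseline_mean,responder_baseline_sd Baseline DAS28 in
#'   good responders.
#' @param nonresponder_baseline_mean,nonresponder_baseline_sd Baseline DAS28
#'   in non-responders.
#' @return An object of class `das28_spec`.
#' @export
das28_spec <- function(responder_decrease_mean = 2.0,
                       responder_decrease_sd = 0.8,
                       nonresponder_decrease_mean = 0.1,
                       nonresponder_decrease_sd = 1.0,
                       responder_baseline_mean = 5.3,
                       responder_baseline_sd = 1.0,
                       nonresponder_baseline_mean = 4.8,
                       nonresponder_baseline_sd = 1.5) {
  stopifnot(responder_decrease_sd > 0, nonresponder_decrease_sd > 0,
            responder_baseline_sd > 0, nonresponder_baseline_sd > 0)
  structure(list(responder_decrease_mean = responder_decrease_mean,
                 responder_decrease_sd = responder_decrease_sd,
                 nonresponder_decrease_mean = nonresponder_decrease_mean,
                 nonresponder_decrease_sd = nonresponder_decrease_sd,
                 responder_baseline_mean = responder_baseline_mean,
                 responder_baseline_sd = responder_baseline_sd,
                 nonresponder_baseline_mean = nonresponder_baseline_mean,
                 nonresponder_baseline_sd = nonresponder_baseline_sd),
            class = "das28_spec")
}

#' Generate DAS28 baseline / week-14 pairs consistent with EULAR labels
#'
#' For each patient, draws a baseline and a decrease from the class-specific
#' normals, floors week 14 at 0, and accepts the draw only if
#' [eular_response()] reproduces the intended label (`good` or `none`):
#' rejection sampling keeps the metadata internally consistent with the
#' class labels the expression generator used. The acceptance conditioning
#' shifts the accepted decrease distribution away from the nominal mean;
#' the realised acceptance rate is returned so that bias is auditable.
#'
#' @param labels Factor or character vector of `good`/`none` labels.
#' @param spec A [das28_spec()].
#' @param seed Integer seed.
#' @param criteria An [eular_criteria()] (defaults).
#' @param max_rounds Cap on vectorised rejection rounds (default 10000);
#'   exceeding it means the DAS28 model is incompatible with the EULAR
#'   constraints and raises an error.
#' @return A data.frame with columns `das28_baseline` and `das28_week14`
#'   (one row per patient, in label order), with attribute
#'   `acceptance_rate` (accepted draws / total draws).
#' @export
generate_das28 <- function(labels, spec = das28_spec(), seed = 1L,
                           criteria = eular_criteria(), max_rounds = 10000L) {
  stopifnot(inherits(spec, "das28_spec"), length(labels) > 0L)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("good", "none")))
  n <- length(labels)
  baseline <- week14 <- rep(NA_real_, n)
  b_mean <- ifelse(labels == "good", spec$responder_baseline_mean,
                   spec$nonresponder_baseline_mean)
  b_sd <- ifelse(labels == "good", spec$responder_baseline_sd,
                 spec$nonresponder_baseline_sd)
  d_mean <- ifelse(labels == "good", spec$responder_decrease_mean,
                   spec$nonresponder_decrease_mean)
  d_sd <- ifelse(labels == "good", spec$responder_decrease_sd,
                 spec$nonresponder_decrease_sd)
  n_draws <- 0L
  with_seed(seed, {
    pending <- seq_len(n)
    for (round in seq_len(max_rounds)) {
      m <- length(pending)
      b <- stats::rnorm(m, b_mean[pending], b_sd[pending])
      d <- stats::rnorm(m, d_mean[pending], d_sd[pending])
      w <- pmax(b - d, 0)
      n_draws <- n_draws + m
      ok <- b >= 0 & b <= 10 & w <= 10
      ok[ok] <- eular_response(b[ok], w[ok], criteria) ==
        labels[pending[ok]]
      baseline[pending[ok]] <- b[ok]
      week14[pending[ok]] <- w[ok]
      pending <- pending[!ok]
      if (length(pending) == 0L) break
    }
    if (length(pending) > 0L) {
      stop("DAS28 rejection sampling exceeded ", max_rounds,
           " rounds: the trajectory model is incompatible with the EULAR ",
           "constraints for label '", labels[pending[1]], "'", call. = FALSE)
    }
  })
  out <- data.frame(das28_baseline = baseline, das28_week14 = week14)
  attr(out, "acceptance_rate") <- n / n_draws
  out
}

#' Generate frequency-matched clinical covariates
#'
#' Assigns sex, rheumatoid-factor status, drug and age to the labelled
#' patients. Categorical covariates are allocated by exact within-group
#' counts (scaled from the emulated cohort's frequencies: 16/18 vs 14/24
#' female, 13/18 vs 19/24 RF positive, 4/18 vs 11/24 on adalimumab) and then
#' randomly permuted within group, mirroring a frequency-matched design; age
#' is drawn from N(58, 14.2^2) for responders and N(57, 13.6^2) for
#' non-responders.
#'
#' @param labels Factor or character `good`/`none` labels.
#' @param seed Integer seed.
#' @param female_prop,rf_prop,adalimumab_prop Numeric length-2 vectors of
#'   within-group proportions, ordered (good, none).
#' @return A data.frame with columns `sex` (`F`/`M`), `rf_positive`
#'   (logical), `drug` (`infliximab`/`adalimumab`) and `age`.
#' @export
generate_covariates <- function(labels, seed = 1L,
                                female_prop = c(16 / 18, 14 / 24),
                                rf_prop = c(13 / 18, 19 / 24),
                                adalimumab_prop = c(4 / 18, 11 / 24)) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("good", "none")))
  n <- length(labels)
  sex <- character(n); rf <- logical(n); drug <- character(n)
  age <- numeric(n)
  age_mean <- c(good = 58, none = 57)
  age_sd <- c(good = 14.2, none = 13.6)
  with_seed(seed, {
    for (g in c("good", "none")) {
      idx <- which(labels == g)
      if (length(idx) == 0L) next
      p <- if (g == "good") 1L else 2L
      n_f <- round_half_up(female_prop[p] * length(idx))
      n_rf <- round_half_up(rf_prop[p] * length(idx))
      n_ada <- round_half_up(adalimumab_prop[p] * length(idx))
      sex[sample(idx)] <- rep(c("F", "M"), c(n_f, length(idx) - n_f))
      rf[sample(idx)] <- rep(c(TRUE, FALSE), c(n_rf, length(idx) - n_rf))
      drug[sample(idx)] <- rep(c("adalimumab", "infliximab"),
                                c(n_ada, length(idx) - n_ada))
      age[idx] <- stats::rnorm(length(idx), age_mean[g], age_sd[g])
    }
  })
  data.frame(sex = sex, rf_positive = rf, drug = drug, age = age)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper composing [generate_expression()], [generate_das28()]
#' and [generate_covariates()] into an expression matrix plus a metadata
#' table, using per-stage seeds fanned out from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param das28 A [das28_spec()].
#' @return A list with `expr`, `metadata` (data.frame: sample_id, response,
#'   das28_baseline, das28_week14, sex, rf_positive, drug, age) and
#'   `informative_genes`.
#' @export
generate_cohort <- function(spec, das28 = das28_spec()) {
  ex <- generate_expression(spec)
  das <- generate_das28(ex$labels, das28,
                        seed = stage_seed(spec$seed, "das28"))
  cov <- generate_covariates(ex$labels,
                             seed = stage_seed(spec$seed, "covariates"))
  metadata <- data.frame(sample_id = colnames(ex$expr),
                         response = as.character(ex$labels),
                         das, cov)
  list(expr = ex$expr, metadata = metadata,
       informative_genes = ex$informative_genes)
}

#' Control-probe model for array QC simulation
#'
#' Negative control probes are N(0, 1); positive controls are
#' N(separation, 1), so `separation` is the difference of means in SD units.
#' The expected control-probe ROC AUC is `pnorm(separation / sqrt(2))`.
#'
#' @param n_positive,n_negative Probe counts (>= 1).
#' @param separation Mean difference in SD units (>= 0).
#' @param seed Integer seed.
#' @return An object of class `control_probe_spec`.
#' @export
control_probe_spec <- function(n_positive = 100L, n_negative = 100L,
                               separation = 3, seed = 1L) {
  stopifnot(n_positive >= 1L, n_negative >= 1L, separation >= 0)
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 separation = separation, seed = as.integer(seed)),
            class = "control_probe_spec")
}

#' Generate positive and negative control-probe intensities
#'
#' @param spec A [control_probe_spec()].
#' @return A list with numeric vectors `positive` and `negative`.
#' @export
generate_control_probes <- function(spec) {
  stopifnot(inherits(spec, "control_probe_spec"))
  with_seed(spec$seed, {
    list(positive = stats::rnorm(spec$n_positive, mean = spec$separation),
         negative = stats::rnorm(spec$n_negative, mean = 0))
  })
}

#' Write / read an expression matrix as TSV
#'
#' Tab-separated, genes as rows; first column `gene` holds the symbol and the
#' header row carries sample IDs.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @return `read_expression_tsv` returns the numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  expr
}

#' Write / read the sample metadata table as TSV
#'
#' @param metadata Data.frame with at least `sample_id` and `response`.
#' @param path File path.
#' @return `read_metadata_tsv` returns the data.frame.
#' @export
write_metadata_tsv <- function(metadata, path) {
  stopifnot(all(c("sample_id", "response") %in% names(metadata)))
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
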
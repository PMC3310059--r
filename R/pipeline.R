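# Run orchestration: validate every signature in a registry against a
# cohort, rank the results Table-style, and emit reproducible JSON/TSV
# reports stamped with the run seed and a config hash.

# Stable hash of an arbitrary config list (via its canonical JSON), so two
# runs can be compared for configuration identity.
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(js))) h <- (h * 131 + code) %% m
  sprintf("%08x", as.integer(h))
}

#' Validate every signature in a registry
#'
#' Runs [validate_signature()] for each signature, isolating per-signature
#' failures (an unusable signature yields an error entry, not an aborted
#' run), and ranks the successful reports by descending
#' sensitivity + specificity.
#'
#' @param expr Genes x samples log2 matrix.
#' @param metadata Sample metadata covering all columns.
#' @param signatures Named list of [gene_signature()] objects (e.g. from
#'   [read_gmt()]).
#' @param config A [cluster_config()]; each signature gets its own stage
#'   seed fanned out from `config$seed`.
#' @param ... Passed on to [validate_signature()].
#' @return A list of class `validation_run`: `table` (ranked data.frame:
#'   signature, n_genes, n_matched, sensitivity, specificity), `reports`
#'   (list of `validation_report`), `errors` (named character), `seed`,
#'   `config_hash`.
#' @export
validate_all_signatures <- function(expr, metadata, signatures,
                                    config = cluster_config(), ...) {
  reports <- list()
  errors <- character(0)
  for (sig in signatures) {
    sig_config <- config
    sig_config$seed <- stage_seed(config$seed, paste0("cluster:", sig$name))
    res <- tryCatch(
      validate_signature(expr, metadata, sig, config = sig_config, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[sig$name] <- conditionMessage(res)
    } else {
      reports[[sig$name]] <- res
    }
  }
  tab <- if (length(reports) > 0) {
    data.frame(
      signature = vapply(reports, `[[`, character(1), "signature"),
      n_genes = vapply(reports, function(r) {
        length(r$mapping$matched) + length(r$mapping$missing)
      }, integer(1)),
      n_matched = vapply(reports, function(r) length(r$mapping$matched),
                         integer(1)),
      sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
      specificity = vapply(reports, `[[`, numeric(1), "specificity"),
      row.names = NULL)
  } else {
    data.frame(signature = character(0), n_genes = integer(0),
               n_matched = integer(0), sensitivity = numeric(0),
               specificity = numeric(0))
  }
  tab <- tab[order(-(tab$sensitivity + tab$specificity), tab$signature), ,
             drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, reports = reports, errors = errors,
                 seed = config$seed,
                 config_hash = config_hash(unclass(config))),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat("Signature validation run (seed ", x$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  print(x$table, ...)
  if (length(x$errors) > 0) {
    cat("Errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[nm], "\n",
                                    sep = "")
  }
  invisible(x)
}

#' Write a validation run as JSON
#'
#' Serialises the ranked table, per-signature assignments (keyed by sample
#' ID), confusion matrices, seeds and the config hash.
#'
#' @param run A [validate_all_signatures()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_validation_json <- function(run, path) {
  payload <- list(
    seed = run$seed,
    config_hash = run$config_hash,
    table = run$table,
    errors = as.list(run$errors),
    reports = lapply(run$reports, function(r) {
      list(signature = r$signature,
           match_fraction = r$mapping$match_fraction,
           missing = r$mapping$missing,
           assignments = as.list(r$clustering$assignments),
           cluster_mapping = as.list(r$cluster_mapping$mapping),
           majority_decisive = r$cluster_mapping$majority_decisive,
           objective = r$objective,
           seed = r$seed,
           confusion = unclass(r$confusion),
           sensitivity = r$sensitivity,
           specificity = r$specificity)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Writes the expression TSV, metadata TSV, a control-probe TSV and a
#' manifest JSON (spec echo, seeds, config hash) into `dir`. With the same
#' spec and seed the files are byte-identical across runs.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if missing).
#' @param das28 A [das28_spec()].
#' @param probes A [control_probe_spec()].
#' @return Invisible named vector of written paths.
#' @export
simulate_cohort_files <- function(spec, dir, das28 = das28_spec(),
                                  probes = control_probe_spec(
                                    seed = stage_seed(spec$seed, "probes"))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec, das28)
  cp <- generate_control_probes(probes)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             control_probes = file.path(dir, "control_probes.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_expression_tsv(cohort$expr, paths["expression"])
  write_metadata_tsv(cohort$metadata, paths["metadata"])
  utils::write.table(
    data.frame(class = rep(c("positive", "negative"),
                           c(length(cp$positive), length(cp$negative))),
               intensity = c(cp$positive, cp$negative)),
    paths["control_probes"], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    spec = unclass(spec[setdiff(names(spec), "gene_names")]),
    das28 = unclass(das28),
    probes = unclass(probes),
    seed = spec$seed,
    config_hash = config_hash(list(spec = unclass(spec),
                                   das28 = unclass(das28),
                                   probes = unclass(probes))),
    informative_genes = cohort$informative_genes)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
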
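# Gene-signature registry: GMT input/output and mapping of published
# signatures onto an expression matrix.

#' Construct a gene signature
#'
#' A named, ordered set of unique gene symbols with free-text source
#' provenance. If `expected_size` is given the gene list must match it,
#' guarding against truncated transcriptions of published sets.
#'
#' @param name Signature identifier.
#' @param genes Character vector of gene symbols (nonempty; duplicates are
#'   removed with a warning).
#' @param source Free-text citation tag (default `""`).
#' @param expected_size Optional integer; `length(unique(genes))` must equal
#'   it.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, source = "", expected_size = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L,
            is.character(genes), length(genes) > 0L)
  if (anyDuplicated(genes)) {
    warning("signature '", name, "': duplicate gene symbols removed",
            call. = FALSE)
    genes <- unique(genes)
  }
  if (!is.null(expected_size) && length(genes) != expected_size) {
    stop("signature '", name, "' has ", length(genes),
         " genes, expected ", expected_size, call. = FALSE)
  }
  structure(list(name = name, source = source, genes = genes),
            class = "gene_signature")
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT dialect: one gene set per line, tab-separated fields
#' `name`, `description`, then member symbols. Duplicate symbols within a
#' line are dropped with a warning; a line with fewer than three fields is
#' an error citing its line number. An empty file yields an empty list.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i,
           ": expected name, description and at least one gene symbol",
           call. = FALSE)
    }
    gene_signature(fields[1], fields[-(1:2)], source = fields[2])
  })
  stats::setNames(sigs, vapply(sigs, `[[`, character(1), "name"))
}

#' Write gene signatures to a GMT file
#'
#' Round-trips bit-identically with [read_gmt()] for valid sets; an empty
#' signature list produces an empty file.
#'
#' @param signatures List of [gene_signature()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    stopifnot(inherits(s, "gene_signature"))
    paste(c(s$name, s$source, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map a signature onto an expression matrix
#'
#' Matches signature symbols against the matrix rownames (exact and
#' case-sensitive by default) and reports which rows the signature selects,
#' which symbols are absent, and the matched fraction. A mapping whose
#' `match_fraction` falls below `min_match` is marked unusable — it selects
#' too little of the published set for clustering on it to mean anything.
#'
#' @param signature A [gene_signature()].
#' @param expr Genes x samples matrix with gene-symbol rownames.
#' @param min_match Minimum usable match fraction (default 0.5).
#' @param ignore_case Match case-insensitively (default FALSE).
#' @return A list of class `signature_mapping`: `signature`, `rows` (matched
#'   row indices), `matched` / `missing` (symbol vectors),
#'   `match_fraction`, `usable`.
#' @export
map_signature <- function(signature, expr, min_match = 0.5,
                          ignore_case = FALSE) {
  stopifnot(inherits(signature, "gene_signature"), is.matrix(expr))
  symbols <- rownames(expr)
  if (is.null(symbols)) stop("expression matrix has no gene symbols",
                             call. = FALSE)
  idx <- if (ignore_case) match(tolower(signature$genes), tolower(symbols))
         else match(signature$genes, symbols)
  hit <- !is.na(idx)
  frac <- mean(hit)
  structure(list(signature = signature$name,
                 rows = idx[hit],
                 matched = signature$genes[hit],
                 missing = signature$genes[!hit],
                 match_fraction = frac,
                 usable = frac >= min_match && sum(hit) > 0L),
            class = "signature_mapping")
}

#' Path to the bundled placeholder signature registry
#'
#' A GMT file with eight signatures named after published anti-TNF response
#' transcript sets, carrying their published sizes (20, 11, 82, 8, 18, 8, 3
#' and 8 genes). The member symbols are synthetic placeholders drawn from
#' the synthetic-cohort gene universe — the real gene identities live in the
#' original publications and must be supplied by the user as a GMT file.
#'
#' @return Path to the installed GMT fixture.
#' @export
placeholder_registry_path <- function() {
  system.file("extdata", "signatures_placeholder_synthetic.gmt",
              package = "tnfsigval", mustWork = TRUE)
}
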
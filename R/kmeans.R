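# K-means partition clustering of patients under Pearson dissimilarity,
# plus an exhaustive global 2-partition oracle for small cohorts.
#
# Samples are rows (profiles over signature genes). Correlation is invariant
# to per-profile location/scale, so distances are computed on row-standardised
# profiles via one matrix product per Lloyd iteration. With standardised
# profiles the arithmetic-mean centroid maximises the summed correlation of a
# cluster to its centroid, which makes Lloyd provably monotone under the
# default configuration; runs where monotonicity fails (possible with
# standardize = FALSE) are flagged, never hidden.

#' Clustering configuration
#'
#' @param k Number of clusters (default 2: non-responder and responder).
#' @param n_restarts Number of random restarts; the minimum-objective run is
#'   returned (default 100).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param seed Integer seed making the whole multi-restart run deterministic.
#' @param init Initialisation strategy: `"random"` draws `k` distinct sample
#'   profiles as starting centroids; `"plusplus"` weights later picks by
#'   dissimilarity to the nearest centroid already chosen.
#' @param standardize Z-score each sample profile before centroid updates
#'   (default TRUE). Distances are correlation-based either way; this flag
#'   controls the space in which centroids are averaged.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(k = 2L, n_restarts = 100L, max_iter = 300L,
                           seed = 1L, init = c("random", "plusplus"),
                           standardize = TRUE) {
  init <- match.arg(init)
  stopifnot(k >= 2L, n_restarts >= 1L, max_iter >= 1L)
  structure(list(k = as.integer(k), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 init = init, standardize = isTRUE(standardize)),
            class = "cluster_config")
}

#' Pearson dissimilarity between two profiles
#'
#' `1 - r` where `r` is the Pearson correlation; ranges over `[0, 2]`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Dissimilarity in `[0, 2]`.
#' @examples
#' pearson_dissimilarity(1:5, 5:1)        # 2
#' pearson_dissimilarity(c(1, 2, 3), c(1, 2, 4))  # ~0.01802
#' @export
pearson_dissimilarity <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) {
    stop("profiles must have length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson dissimilarity undefined for a zero-variance profile",
         call. = FALSE)
  }
  1 - stats::cor(x, y)
}

# Row-standardise profiles (mean 0, sd 1 per row); errors name the offending
# sample because a flat profile has no defined correlation.
.standardize_rows <- function(x, ids) {
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile for sample(s): ",
         paste(ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  t(scale(t(x)))
}

# Pearson dissimilarity of every sample (rows of zs, already standardised)
# to every centroid row. A degenerate constant centroid has no defined
# correlation and is placed at dissimilarity 1 from everything.
.dist_to_centroids <- function(zs, centroids) {
  p <- ncol(zs)
  csd <- apply(centroids, 1, stats::sd)
  cz <- centroids
  nz <- csd > 0
  cz[nz, ] <- t(scale(t(centroids[nz, , drop = FALSE])))
  r <- zs %*% t(cz) / (p - 1)
  r[, !nz] <- 0
  1 - r
}

# Objective (sum of Pearson dissimilarity of each sample to its cluster's
# mean-profile centroid) for a given assignment.
.partition_objective <- function(zs, space, assign, k) {
  cent <- rowsum(space, assign) / as.vector(table(factor(assign, 1:k)))
  d <- .dist_to_centroids(zs, cent)
  list(objective = sum(d[cbind(seq_len(nrow(zs)), assign)]), centroids = cent)
}

# One Lloyd run from given initial centroids. Returns assignments, objective
# trace, centroid matrix, iteration count and bookkeeping flags.
.lloyd <- function(zs, space, init_centroids, k, max_iter, tol = 1e-10) {
  n <- nrow(zs)
  cent <- init_centroids
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  notes <- character(0)
  non_monotone <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- .dist_to_centroids(zs, cent)
    assign <- max.col(-d, ties.method = "first")  # tie -> lowest index
    # an emptied cluster is re-seeded with the sample farthest from its own
    # centroid rather than silently dropped
    for (guard in seq_len(k)) {
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty) == 0L) break
      j <- empty[1]
      far <- which.max(d[cbind(seq_len(n), assign)])
      notes <- c(notes, sprintf(
        "iteration %d: cluster %d emptied; re-seeded with sample %d", iter,
        j, far))
      cent[j, ] <- space[far, ]
      d <- .dist_to_centroids(zs, cent)
      assign <- max.col(-d, ties.method = "first")
    }
    obj <- sum(d[cbind(seq_len(n), assign)])
    if (length(trace) > 0 && obj > trace[length(trace)] + 1e-12) {
      non_monotone <- TRUE
      notes <- c(notes, sprintf(
        "iteration %d: objective increased (%.3e -> %.3e)", iter,
        trace[length(trace)], obj))
    }
    trace <- c(trace, obj)
    stable <- identical(assign, assign_prev)
    small_change <- length(trace) >= 2 &&
      abs(trace[length(trace)] - trace[length(trace) - 1]) < tol
    assign_prev <- assign
    if (stable || small_change) break
    cent <- rowsum(space, assign) / as.vector(table(factor(assign, 1:k)))
  }
  list(assign = assign, trace = trace, n_iter = iter,
       non_monotone = non_monotone, notes = notes)
}

# Relabel clusters in order of first appearance so labels are canonical
# (cluster 1 contains the first sample).
.canonical_labels <- function(assign) {
  match(assign, unique(assign))
}

#' K-means partition clustering under Pearson dissimilarity
#'
#' Clusters samples (rows) over signature genes (columns) by Lloyd
#' iteration: each sample joins the centroid it is least dissimilar to
#' (`1 - r`), centroids are recomputed as arithmetic means of their member
#' profiles, and iteration stops when assignments stabilise. The best of
#' `n_restarts` seeded initialisations (minimum objective, first on ties) is
#' returned; cluster labels are canonicalised by order of first appearance.
#'
#' @param x Samples x genes numeric matrix (>= `k` samples, >= 3 genes,
#'   every sample profile with nonzero variance).
#' @param config A [cluster_config()].
#' @return An object of class `cluster_result`: `assignments` (named integer
#'   vector in `1..k`), `centroids`, `objective`, `objective_trace`,
#'   `n_iter`, `restart_index`, `seed`, `non_monotone`, `notes`.
#' @export
kmeans_partition <- function(x, config = cluster_config()) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x); p <- ncol(x); k <- config$k
  if (p < 3L) stop("need at least 3 genes to cluster on", call. = FALSE)
  if (n < k) stop("need at least k = ", k, " samples", call. = FALSE)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  zs <- .standardize_rows(x, ids)
  space <- if (config$standardize) zs else x
  inits <- with_seed(config$seed, {
    lapply(seq_len(config$n_restarts), function(r) {
      if (config$init == "random") {
        sample(n, k)
      } else {
        picked <- sample(n, 1)
        while (length(picked) < k) {
          d <- .dist_to_centroids(zs, space[picked, , drop = FALSE])
          w <- apply(d, 1, min)
          w[picked] <- 0
          picked <- c(picked, sample(n, 1, prob = w + 1e-12))
        }
        picked
      }
    })
  })
  best <- NULL
  for (r in seq_along(inits)) {
    run <- .lloyd(zs, space, space[inits[[r]], , drop = FALSE], k,
                  config$max_iter)
    if (is.null(best) ||
        run$trace[length(run$trace)] < best$trace[length(best$trace)] - 1e-12) {
      best <- run
      best$restart_index <- r
    }
  }
  assign <- .canonical_labels(best$assign)
  final <- .partition_objective(zs, space, assign, k)
  rownames(final$centroids) <- paste0("cluster", seq_len(k))
  structure(list(assignments = stats::setNames(assign, ids),
                 centroids = final$centroids,
                 objective = final$objective,
                 objective_trace = best$trace,
                 n_iter = best$n_iter,
                 restart_index = best$restart_index,
                 seed = config$seed,
                 non_monotone = best$non_monotone,
                 notes = best$notes),
            class = "cluster_result")
}

#' Globally optimal 2-partition by exhaustive enumeration
#'
#' Enumerates every nonempty bipartition of the samples (`2^(n-1) - 1` of
#' them), scores each with mean-profile centroids under the Pearson
#' dissimilarity objective, and returns the minimum. Serves as an
#' independent oracle for [kmeans_partition()] on small cohorts. Ties are
#' broken by the lexicographically smallest assignment vector.
#'
#' @param x Samples x genes matrix with `2 <= n <= 14` samples.
#' @param standardize Same meaning as in [cluster_config()].
#' @return A list: `assignments` (named, sample 1 always in cluster 1),
#'   `objective`, `n_evaluated`.
#' @export
brute_force_best_partition <- function(x, standardize = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (n > 14L) stop("enumeration bound exceeded: n = ", n, " > 14",
                    call. = FALSE)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  zs <- .standardize_rows(x, ids)
  space <- if (standardize) zs else x
  best_obj <- Inf
  best_assign <- NULL
  n_eval <- 0L
  for (mask in seq_len(2^(n - 1) - 1)) {
    assign <- c(1L, 1L + as.integer(bitwAnd(
      bitwShiftR(mask, seq_len(n - 1) - 1L), 1L)))
    obj <- .partition_objective(zs, space, assign, 2L)$objective
    n_eval <- n_eval + 1L
    better <- obj < best_obj - 1e-12
    tie <- abs(obj - best_obj) <= 1e-12 && !is.null(best_assign) &&
      .lex_less(assign, best_assign)
    if (better || tie) {
      best_obj <- obj
      best_assign <- assign
    }
  }
  list(assignments = stats::setNames(best_assign, ids),
       objective = best_obj, n_evaluated = n_eval)
}

# TRUE if assignment vector a precedes b lexicographically.
.lex_less <- function(a, b) {
  i <- which(a != b)
  length(i) > 0 && a[i[1]] < b[i[1]]
}
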
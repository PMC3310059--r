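# Shared helpers: seeded evaluation, rounding, seed fan-out.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (0.5 -> 1),
#' the convention used for reporting integer percentages, rather than
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(70.8333)  # 71
#' round_half_up(16.5)     # 17
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Derive a per-stage seed from a global seed
#'
#' Fans a single run seed out to independent per-stage seeds by combining it
#' with a stable polynomial hash of the stage name, so stages never share a
#' stream and reruns are reproducible.
#'
#' @param global_seed Integer run seed.
#' @param stage Character stage name (e.g. "simulate", "cluster").
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nchar(stage) > 0L)
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((as.numeric(global_seed) %% m + h) %% m)
}

# Internal: stop() with a stage tag so composed pipelines report where a
# failure happened.
stage_error <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
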
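# Internal helpers: typed conditions, seed handling, formatting.

ceus_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ceusvv_error", "error", "condition")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate code under a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded simulation functions do not disturb the
#' global random stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is_number(seed)) ceus_stop("seed must be a single finite number", "invalid_parameter")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from a global seed
#'
#' Stages of a seeded experiment draw from independent streams derived from
#' one global seed. The derivation hashes the stage label (a small
#' polynomial rolling hash over its bytes) and mixes it with the global
#' seed modulo 2^31 - 1, so each labelled stage is independently
#' reproducible from the global seed alone.
#'
#' @param seed Global integer seed.
#' @param label Character stage label.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' child_seed(1, "simulate")
#' child_seed(1, "stats")
child_seed <- function(seed, label) {
  stopifnot(is_number(seed), is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  s <- (abs(seed) %% m)
  as.integer((s * 48271 + h) %% m + 1)
}

# Fixed-width numeric formatting used by all tabular writers: 9 significant
# digits keeps CSV output byte-stable across runs of the same build.
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.9g", v)
  }, character(1))
}
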